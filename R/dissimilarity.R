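#' Hamming distance between two binary practice vectors
#'
#' Number of positions at which the two vectors differ. For presence/absence
#' practice profiles this equals the size of the symmetric difference of the
#' two practice sets.
#'
#' @param u,v Equal-length binary (0/1) vectors.
#' @return Integer count in `[0, length(u)]`.
#' @export
#' @examples
#' hamming_distance(c(1, 0, 1), c(1, 1, 0))   # 2
hamming_distance <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  if (!all(u %in% c(0, 1)) || !all(v %in% c(0, 1)))
    stop("vectors must be binary (0/1)")
  as.integer(sum(u != v))
}

#' All-pairs Hamming dissimilarity matrix
#'
#' @param m Binary practice matrix from [encode_practices()].
#' @return Symmetric integer matrix with zero diagonal and the society names of
#'   `m` as dimnames.
#' @export
hamming_matrix <- function(m) {
  if (!all(m %in% c(0, 1))) stop("matrix must be binary (0/1)")
  m <- as.matrix(m) * 1.0
  # d(i,j) = sum u + sum v - 2 u.v for binary rows
  cross <- tcrossprod(m)
  rs <- rowSums(m)
  d <- outer(rs, rs, "+") - 2 * cross
  d <- round(d)
  storage.mode(d) <- "integer"
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of the given radius (IUGG mean Earth radius
#' by default). Vectorized over coordinate vectors.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees; latitudes in
#'   `[-90, 90]`, longitudes in `(-180, 180]`.
#' @param radius_km Sphere radius; default 6371.0088 km.
#' @return Distance(s) in km.
#' @export
#' @examples
#' great_circle_km(0, 0, 0, 180)   # half circumference, ~20015.1 km
great_circle_km <- function(lat1, lon1, lat2, lon2, radius_km = 6371.0088) {
  chk <- function(lat, lon) {
    if (any(is.na(lat)) || any(is.na(lon)))
      stop("missing coordinate")
    if (any(lat < -90 | lat > 90)) stop("latitude out of [-90, 90]")
    if (any(lon <= -180 | lon > 180)) stop("longitude out of (-180, 180]")
  }
  chk(lat1, lon1); chk(lat2, lon2)
  rad <- pi / 180
  phi1 <- lat1 * rad; phi2 <- lat2 * rad
  dphi <- (lat2 - lat1) * rad
  dlam <- (lon2 - lon1) * rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * radius_km * asin(sqrt(a))
}

#' Build the unordered-pair design table
#'
#' The backbone of the pairwise analyses: one row per unordered society pair
#' `(i < j)` in lexicographic index order, carrying the Hamming dissimilarity
#' of the two practice profiles, the great-circle distance between the two
#' locations, and the absolute difference of every roster covariate. For 22
#' societies this is the 231-row design.
#'
#' @param dataset A `society_dataset` with coordinates and a complete covariate
#'   table (any missing value is an error naming society and variable).
#' @param m Optional pre-computed binary matrix; defaults to
#'   `encode_practices(dataset)`.
#' @return A data.frame with columns `pair_a`, `pair_b`, `hamming`, `geo_km`,
#'   then `delta_<variable>` for the roster variables in roster order.
#' @export
build_pairwise_table <- function(dataset, m = encode_practices(dataset)) {
  validate_society_dataset(dataset)
  if (is.null(dataset$covariates))
    stop("dataset has no covariates; attach or generate them first")
  if (any(is.na(dataset$latitude)) || any(is.na(dataset$longitude)))
    stop("dataset has missing coordinates")
  for (v in dataset$roster) {
    bad <- is.na(dataset$covariates[[v]])
    if (any(bad))
      stop("missing covariate '", v, "' for society: ",
           paste(dataset$name[bad], collapse = ", "))
  }
  n <- n_societies(dataset)
  if (n < 2) stop("need at least 2 societies")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  # upper.tri gives column-major order; sort lexicographically by (i, j)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  i <- idx[, 1]; j <- idx[, 2]
  dh <- hamming_matrix(m)
  out <- data.frame(
    pair_a = dataset$name[i],
    pair_b = dataset$name[j],
    hamming = dh[cbind(i, j)],
    geo_km = great_circle_km(dataset$latitude[i], dataset$longitude[i],
                             dataset$latitude[j], dataset$longitude[j]),
    stringsAsFactors = FALSE
  )
  for (v in dataset$roster) {
    x <- dataset$covariates[[v]]
    out[[paste0("delta_", v)]] <- abs(x[i] - x[j])
  }
  out
}

#' Names of the transformed regressor columns of a pairwise table
#'
#' Geographic distance plus the 21 absolute covariate differences — the 22
#' regressors of the dependence screen and the predictive-null comparison.
#'
#' @param pairs A pairwise table from [build_pairwise_table()].
#' @return Character vector of column names.
#' @export
pairwise_regressors <- function(pairs) {
  setdiff(names(pairs), c("pair_a", "pair_b", "hamming"))
}
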