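#' Construct a society dataset
#'
#' The central container of the package: an ordered collection of societies,
#' each with a non-empty set of basic sharing practices, optional geographic
#' coordinates, and optional values for the 21-variable socio-ecological
#' roster. Validation is strict — unknown practice codes, duplicate society
#' names, out-of-range coordinates and roster mismatches are rejected rather
#' than silently repaired.
#'
#' @param name Character vector of unique society names.
#' @param practices List of character vectors; each element a non-empty set of
#'   codes from [practice_codes()], without duplicates.
#' @param latitude,longitude Numeric vectors in degrees (`[-90, 90]` and
#'   `(-180, 180]`), or `NA` when coordinates are not available.
#' @param alt_name Optional alternative names (e.g. the eHRAF/literature
#'   name when `name` carries the D-PLACE name).
#' @param covariates `NULL`, or a data.frame with one row per society and one
#'   column per roster variable. Missing values are kept as `NA` and rejected
#'   by downstream stages that need them (fail fast, no imputation).
#' @param roster Character vector naming the covariate roster; defaults to the
#'   21 canonical variables of [variable_roster()].
#'
#' @return An object of class `society_dataset`.
#' @export
society_dataset <- function(name, practices,
                            latitude = rep(NA_real_, length(name)),
                            longitude = rep(NA_real_, length(name)),
                            alt_name = rep(NA_character_, length(name)),
                            covariates = NULL,
                            roster = roster_names()) {
  stopifnot(is.character(name), is.list(practices))
  n <- length(name)
  if (length(practices) != n || length(latitude) != n || length(longitude) != n)
    stop("name, practices, latitude and longitude must have equal length")
  x <- structure(
    list(
      name = name,
      alt_name = as.character(alt_name),
      latitude = as.numeric(latitude),
      longitude = as.numeric(longitude),
      practices = lapply(practices, as.character),
      covariates = covariates,
      roster = roster
    ),
    class = "society_dataset"
  )
  validate_society_dataset(x)
}

#' Validate a society dataset
#'
#' @param x A `society_dataset`.
#' @return `x`, invisibly unchanged, if valid; otherwise an error naming the
#'   offending society, practice code or column.
#' @export
validate_society_dataset <- function(x) {
  if (!inherits(x, "society_dataset")) stop("not a society_dataset")
  if (anyDuplicated(x$name)) {
    stop("duplicate society names: ",
         paste(unique(x$name[duplicated(x$name)]), collapse = ", "))
  }
  vocab <- practice_codes()
  for (i in seq_along(x$name)) {
    p <- x$practices[[i]]
    if (length(p) == 0) stop("society '", x$name[i], "' has an empty practice set")
    if (anyDuplicated(p)) stop("society '", x$name[i], "' has duplicate practice codes")
    bad <- setdiff(p, vocab)
    if (length(bad) > 0) {
      stop("society '", x$name[i], "' uses unknown practice code(s): ",
           paste(bad, collapse = ", "))
    }
  }
  ok_lat <- is.na(x$latitude) | (x$latitude >= -90 & x$latitude <= 90)
  ok_lon <- is.na(x$longitude) | (x$longitude > -180 & x$longitude <= 180)
  if (!all(ok_lat)) stop("latitude out of [-90, 90] for: ",
                         paste(x$name[!ok_lat], collapse = ", "))
  if (!all(ok_lon)) stop("longitude out of (-180, 180] for: ",
                         paste(x$name[!ok_lon], collapse = ", "))
  if (!is.null(x$covariates)) {
    if (!is.data.frame(x$covariates) || nrow(x$covariates) != length(x$name))
      stop("covariates must be a data.frame with one row per society")
    extra <- setdiff(names(x$covariates), x$roster)
    if (length(extra) > 0)
      stop("covariate column(s) outside the roster: ", paste(extra, collapse = ", "))
    miss <- setdiff(x$roster, names(x$covariates))
    if (length(miss) > 0)
      stop("covariate column(s) missing from table: ", paste(miss, collapse = ", "))
  }
  invisible(x)
}

#' @export
print.society_dataset <- function(x, ...) {
  cat("society_dataset:", length(x$name), "societies,",
      length(x$roster), "roster variables\n")
  cat("  coordinates:",
      if (all(is.na(x$latitude))) "absent" else "present", "\n")
  cat("  covariates:",
      if (is.null(x$covariates)) "absent" else "present", "\n")
  sizes <- vapply(x$practices, length, integer(1))
  cat("  practice-set sizes:", paste(range(sizes), collapse = "-"),
      "(total", sum(sizes), "codes)\n")
  invisible(x)
}

#' Number of societies in a dataset
#' @param x A `society_dataset`.
#' @return Integer count.
#' @export
n_societies <- function(x) length(x$name)

#' Attach a covariate table to a dataset
#'
#' Joins covariate values (and optionally coordinates) onto an existing
#' dataset, e.g. onto the built-in practice fixture whose coordinates and
#' covariates are absent.
#'
#' @param x A `society_dataset`.
#' @param covariates Data.frame with one row per society, in dataset order (or
#'   carrying a `name` column used to reorder), covering the full roster.
#' @param latitude,longitude Optional replacement coordinate vectors.
#' @return The updated, validated `society_dataset`.
#' @export
attach_covariates <- function(x, covariates, latitude = NULL, longitude = NULL) {
  stopifnot(inherits(x, "society_dataset"), is.data.frame(covariates))
  if ("name" %in% names(covariates)) {
    idx <- match(x$name, covariates$name)
    if (anyNA(idx)) stop("covariate table is missing societies: ",
                         paste(x$name[is.na(idx)], collapse = ", "))
    covariates <- covariates[idx, setdiff(names(covariates), "name"), drop = FALSE]
    rownames(covariates) <- NULL
  }
  x$covariates <- covariates[, x$roster, drop = FALSE]
  if (!is.null(latitude)) x$latitude <- as.numeric(latitude)
  if (!is.null(longitude)) x$longitude <- as.numeric(longitude)
  validate_society_dataset(x)
  x
}

#' Encode practice sets as a binary presence/absence matrix
#'
#' Each society becomes a 14-position binary vector, one position per practice
#' code in the fixed vocabulary order; a cell is 1 iff the code occurs in the
#' society's sharing sequence. The order of appearance within the sequence is
#' deliberately discarded.
#'
#' @param dataset A validated `society_dataset`.
#' @return Integer matrix of shape `n_societies x 14` with society rownames and
#'   practice-code colnames.
#' @export
#' @examples
#' m <- encode_practices(sharing_fixture())
#' dim(m)      # 22 x 14
#' sum(m)      # total number of recorded practice codes
encode_practices <- function(dataset) {
  validate_society_dataset(dataset)
  codes <- practice_codes()
  m <- t(vapply(dataset$practices,
                function(p) as.integer(codes %in% p),
                integer(length(codes))))
  dimnames(m) <- list(dataset$name, codes)
  m
}

#' Per-practice marginal frequencies
#'
#' Fraction of societies whose sharing sequence contains each code.
#'
#' @param dataset A `society_dataset`; defaults to the built-in fixture.
#' @return Named numeric vector of 14 probabilities in vocabulary order.
#' @export
#' @examples
#' practice_marginals()[["KS"]]   # 12/22
practice_marginals <- function(dataset = sharing_fixture()) {
  colMeans(encode_practices(dataset))
}
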