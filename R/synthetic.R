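# Evaluate fn with a locally-seeded RNG, restoring the caller's stream.
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

default_covariate_params <- function() {
  list(
    means = c(
      temp_mean = 0, temp_variance = 120, temp_constancy = 0.45,
      temp_contingency = 0.35, precip_mean = 800, precip_variance = 4000,
      precip_constancy = 0.5, precip_contingency = 0.3, dist_coast = 300,
      elevation = 500, slope = 3, npp_mean = 40, npp_variance = 300,
      npp_constancy = 0.5, npp_contingency = 0.3,
      population = log(1000),  # log scale; drawn log-normally
      pct_hunting = 30, pct_gathering = 20, pct_husbandry = 10,
      pct_fishing = 25, pct_agriculture = 15
    ),
    sds = c(
      temp_mean = 12, temp_variance = 60, temp_constancy = 0.15,
      temp_contingency = 0.15, precip_mean = 500, precip_variance = 2000,
      precip_constancy = 0.15, precip_contingency = 0.12, dist_coast = 250,
      elevation = 400, slope = 2, npp_mean = 25, npp_variance = 150,
      npp_constancy = 0.15, npp_contingency = 0.12,
      population = 1,
      pct_hunting = 15, pct_gathering = 15, pct_husbandry = 15,
      pct_fishing = 15, pct_agriculture = 15
    )
  )
}

#' Configuration for the synthetic society generator
#'
#' Describes the statistical structure of a simulated cross-cultural dataset.
#' Three regimes realize the three competing hypotheses about sharing
#' practices: `"null"` (practices independent of everything), \
#' `"covariate_effect"` (presence probability of each practice shifts with a
#' named socio-ecological driver — local adaptation), and `"diffusion"`
#' (presence probability follows a spatial Gaussian random field — geographic
#' transmission between neighbours).
#'
#' @param n_societies Number of societies (>= 3; pairwise stages need 3).
#' @param regime One of `"null"`, `"covariate_effect"`, `"diffusion"`.
#' @param beta Effect size on the log-odds scale, per SD of the driver (or of
#'   the spatial field). Forced to 0 under the null regime.
#' @param driving_variable Roster variable that drives practice presence under
#'   `covariate_effect`.
#' @param practice_base_freqs 14 baseline presence probabilities; defaults to
#'   the marginal frequencies of the built-in 22-society fixture.
#' @param covariate_means,covariate_sds Named per-variable location/scale
#'   parameters (population on the log scale).
#' @param coordinate_box Named vector `lat_min`, `lat_max`, `lon_min`,
#'   `lon_max`; coordinates are uniform in the box.
#' @param diffusion_range_km Correlation length (km) of the exponential
#'   covariance of the spatial field under `diffusion`.
#' @param seed Integer seed; every draw of [generate_dataset()] is a pure
#'   function of the config.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_societies = 22,
                             regime = c("null", "covariate_effect", "diffusion"),
                             beta = 0,
                             driving_variable = "npp_mean",
                             practice_base_freqs = practice_marginals(),
                             covariate_means = default_covariate_params()$means,
                             covariate_sds = default_covariate_params()$sds,
                             coordinate_box = c(lat_min = -55, lat_max = 72,
                                                lon_min = -170, lon_max = 170),
                             diffusion_range_km = 2000,
                             seed = 1L) {
  regime <- match.arg(regime)
  if (n_societies < 3) stop("n_societies must be >= 3 (pairwise stages need 3)")
  if (any(practice_base_freqs < 0 | practice_base_freqs > 1))
    stop("practice_base_freqs must lie in [0, 1]")
  if (length(practice_base_freqs) != length(practice_codes()))
    stop("need one base frequency per practice code")
  if (any(covariate_sds <= 0)) stop("covariate sds must be positive")
  if (!driving_variable %in% roster_names())
    stop("unknown driving_variable: ", driving_variable)
  if (regime == "null") beta <- 0
  structure(list(
    n_societies = as.integer(n_societies), regime = regime, beta = beta,
    driving_variable = driving_variable,
    practice_base_freqs = stats::setNames(practice_base_freqs, practice_codes()),
    covariate_means = covariate_means, covariate_sds = covariate_sds,
    coordinate_box = coordinate_box,
    diffusion_range_km = diffusion_range_km, seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Standardized spatial Gaussian field with exponential covariance.
spatial_field <- function(lat, lon, range_km) {
  n <- length(lat)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d[i, ] <- great_circle_km(rep(lat[i], n), rep(lon[i], n), lat, lon)
  }
  cc <- exp(-d / range_km) + diag(1e-8, n)
  z <- drop(t(chol(cc)) %*% stats::rnorm(n))
  as.numeric(scale(z))
}

#' Generate a synthetic society dataset
#'
#' Draws coordinates uniformly in the configured box, covariates as
#' independent Gaussians (population size log-normal; subsistence percentages
#' truncated at zero and renormalized to sum 100), and practice presence as
#' independent Bernoulli draws whose log-odds are the baseline logit plus
#' `beta` times a standardized driver: the chosen covariate under
#' `covariate_effect`, a per-practice spatial Gaussian field under
#' `diffusion`, nothing under `null`. Societies whose draw yields an empty
#' practice set are redrawn (the data model requires non-empty sets); if fifty
#' redraws fail — possible only when every presence probability is near zero,
#' e.g. in the extreme-effect limit — a single practice is assigned, drawn
#' proportionally to the presence probabilities.
#'
#' @param config A [synthetic_config()].
#' @return A validated `society_dataset` with coordinates and full covariates.
#' @export
#' @examples
#' d <- generate_dataset(synthetic_config(seed = 7))
#' n_societies(d)
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, function() {
    n <- config$n_societies
    box <- config$coordinate_box
    lat <- stats::runif(n, box[["lat_min"]], box[["lat_max"]])
    lon <- stats::runif(n, box[["lon_min"]], box[["lon_max"]])
    roster <- roster_names()
    mu <- config$covariate_means; sd <- config$covariate_sds
    cov <- as.data.frame(lapply(roster, function(v)
      stats::rnorm(n, mu[[v]], sd[[v]])))
    names(cov) <- roster
    cov$population <- exp(cov$population)
    pct <- c("pct_hunting", "pct_gathering", "pct_husbandry",
             "pct_fishing", "pct_agriculture")
    p <- pmax(as.matrix(cov[, pct]), 0)
    zero <- rowSums(p) == 0
    p[zero, ] <- 1
    cov[, pct] <- 100 * p / rowSums(p)

    pk <- config$practice_base_freqs
    shift <- switch(config$regime,
      null = matrix(0, n, length(pk)),
      covariate_effect = {
        z <- as.numeric(scale(if (config$driving_variable == "population")
          log(cov$population) else cov[[config$driving_variable]]))
        matrix(rep(config$beta * z, length(pk)), n, length(pk))
      },
      diffusion = vapply(seq_along(pk), function(k)
        config$beta * spatial_field(lat, lon, config$diffusion_range_km),
        numeric(n))
    )
    logit <- function(p) stats::qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12))
    prob <- stats::plogis(sweep(shift, 2, logit(pk), "+"))
    prob[, pk == 0] <- 0; prob[, pk == 1] <- 1
    draw_row <- function(i) {
      for (attempt in 1:50) {
        row <- stats::rbinom(length(pk), 1, prob[i, ])
        if (sum(row) > 0) return(practice_codes()[row == 1])
      }
      # the data model requires a non-empty set; when every presence
      # probability is essentially zero, fall back to a single practice drawn
      # proportionally to the (relative) presence probabilities
      w <- prob[i, ]
      if (sum(w) == 0) w <- pk
      if (sum(w) == 0) w <- rep(1, length(pk))
      practice_codes()[sample.int(length(pk), 1, prob = w)]
    }
    practices <- lapply(seq_len(n), draw_row)
    society_dataset(
      name = sprintf("synthetic_%03d", seq_len(n)),
      practices = practices,
      latitude = lat, longitude = lon,
      covariates = cov
    )
  })
}

#' Generate a regression test problem shaped like the pairwise design
#'
#' Produces a 22-column regressor table with the column names of a transformed
#' pairwise table (`geo_km` plus the 21 `delta_` columns) and a response with
#' controlled signal: pure noise (`"none"`), a linear combination of three
#' named columns (`"linear"`), or a smooth nonlinear function of the same
#' three (`"nonlinear"`). Under `"linear"` the standardized true columns carry
#' coefficients (1, 0.8, 0.6), so the signal variance is 2.0 and e.g.
#' `noise_sd = 0.7` gives a population R^2 close to 0.8.
#'
#' @param n_pairs Number of rows (>= 20).
#' @param signal `"none"`, `"linear"` or `"nonlinear"`.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param seed Integer seed.
#' @return List with `X` (data.frame), `y` (numeric), `true_columns`,
#'   `coefficients` (linear case).
#' @export
generate_regression_problem <- function(n_pairs,
                                        signal = c("none", "linear", "nonlinear"),
                                        noise_sd = 1, seed = 1L) {
  signal <- match.arg(signal)
  if (n_pairs < 20) stop("n_pairs must be >= 20")
  with_seed(seed, function() {
    roster <- roster_names()
    sds <- default_covariate_params()$sds
    X <- data.frame(geo_km = stats::runif(n_pairs, 0, 15000))
    for (v in roster) {
      # absolute difference of two iid Gaussians: folded normal, sd_v * sqrt(2)
      X[[paste0("delta_", v)]] <-
        abs(stats::rnorm(n_pairs, 0, sds[[v]]) - stats::rnorm(n_pairs, 0, sds[[v]]))
    }
    true_cols <- c("delta_npp_mean", "delta_temp_mean", "geo_km")
    z <- scale(as.matrix(X[, true_cols]))
    coefs <- c(1, 0.8, 0.6)
    mu <- switch(signal,
      none = rep(0, n_pairs),
      linear = drop(z %*% coefs),
      nonlinear = sin(pi * z[, 1]) + z[, 2]^2 + z[, 1] * z[, 3]
    )
    list(X = X, y = mu + stats::rnorm(n_pairs, 0, noise_sd),
         true_columns = true_cols,
         coefficients = if (signal == "linear") coefs else NULL)
  })
}
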