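test_that("fixture-derived marginals are consistent with the practice counts", {
  p <- practice_marginals()
  expect_length(p, 14)
  expect_equal(unname(p["KS"]), 12 / 22)
  # sum of marginals times 22 recovers the total number of listed codes
  m <- encode_practices(sharing_fixture())
  expect_equal(sum(p) * 22, sum(m))
})

test_that("generation is a pure function of the config", {
  cfg <- synthetic_config(n_societies = 22, regime = "null", seed = 7)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$practices, d2$practices)
  expect_identical(d1$covariates, d2$covariates)
  expect_identical(d1$latitude, d2$latitude)
  # the generator does not disturb the caller's RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(generate_dataset(cfg)); b <- runif(1)
  expect_identical(a, b)
})

test_that("null-regime marginals match the configured base frequencies", {
  freqs <- rep(0.5, 14)
  d <- generate_dataset(synthetic_config(n_societies = 2000, regime = "null",
                                         practice_base_freqs = freqs,
                                         seed = 11))
  m <- encode_practices(d)
  expect_true(all(colMeans(m) > 0.47 & colMeans(m) < 0.53))
})

test_that("subsistence percentages sum to 100 and population is positive", {
  d <- generate_dataset(synthetic_config(n_societies = 200, seed = 3))
  pct <- d$covariates[, c("pct_hunting", "pct_gathering", "pct_husbandry",
                          "pct_fishing", "pct_agriculture")]
  expect_equal(unname(rowSums(pct)), rep(100, 200), tolerance = 1e-9)
  expect_true(all(d$covariates$population > 0))
  box <- synthetic_config()$coordinate_box
  expect_true(all(d$latitude >= box["lat_min"] & d$latitude <= box["lat_max"]))
})

test_that("a huge covariate effect makes presence a threshold function of the driver", {
  cfg <- synthetic_config(n_societies = 300, regime = "covariate_effect",
                          beta = 200, driving_variable = "npp_mean",
                          practice_base_freqs = rep(0.5, 14), seed = 5)
  d <- generate_dataset(cfg)
  z <- as.numeric(scale(d$covariates$npp_mean))
  m <- encode_practices(d)
  # outside a narrow indifference band the logistic limit is deterministic:
  # every practice is present above the threshold, and below it only the
  # single fallback practice required by the non-empty data model survives
  expect_true(all(m[z > 0.1, ] == 1))
  expect_true(all(rowSums(m[z < -0.1, , drop = FALSE]) == 1))
})

test_that("diffusion regime makes sharing similarity decay with distance", {
  for (s in 1:2) {
    d <- generate_dataset(synthetic_config(n_societies = 100,
                                           regime = "diffusion", beta = 4,
                                           diffusion_range_km = 5000,
                                           seed = s))
    m <- encode_practices(d)
    w <- tcrossprod(m)
    n <- 100
    gd <- vapply(seq_len(n), function(i)
      great_circle_km(rep(d$latitude[i], n), rep(d$longitude[i], n),
                      d$latitude, d$longitude), numeric(n))
    ut <- upper.tri(w)
    expect_lt(stats::cor(w[ut], gd[ut], method = "spearman"), 0)
    expect_gt(stats::cor(hamming_matrix(m)[ut], gd[ut], method = "spearman"),
              0.1)
  }
})

test_that("generator refuses degenerate configurations", {
  expect_error(synthetic_config(n_societies = 2), ">= 3")
  expect_error(synthetic_config(practice_base_freqs = rep(1.5, 14)), "\\[0, 1\\]")
  expect_error(synthetic_config(driving_variable = "nope"), "driving_variable")
  # null regime forces beta to zero
  expect_equal(synthetic_config(regime = "null", beta = 3)$beta, 0)
})

test_that("regression problems carry the stated signal structure", {
  # no signal: the response is pure noise, zero when noise is off
  p0 <- generate_regression_problem(50, "none", noise_sd = 0, seed = 1)
  expect_equal(p0$y, rep(0, 50))
  expect_equal(ncol(p0$X), 22)
  expect_true(all(c("geo_km", paste0("delta_", roster_names())) %in%
                  names(p0$X)))
  # linear, noiseless: the response is an exact function of the 3 true columns
  p1 <- generate_regression_problem(100, "linear", noise_sd = 0, seed = 2)
  z <- scale(as.matrix(p1$X[, p1$true_columns]))
  expect_equal(p1$y, drop(z %*% p1$coefficients), tolerance = 1e-12)
  # linear with noise: OLS on the true columns recovers coefficients within 3 SE
  p2 <- generate_regression_problem(231, "linear", noise_sd = 1, seed = 3)
  z2 <- as.data.frame(scale(as.matrix(p2$X[, p2$true_columns])))
  names(z2) <- c("z1", "z2", "z3")
  fit <- summary(stats::lm(p2$y ~ ., data = z2))$coefficients
  for (i in 1:3) {
    expect_lt(abs(fit[i + 1, "Estimate"] - p2$coefficients[i]),
              3 * fit[i + 1, "Std. Error"])
  }
  expect_error(generate_regression_problem(10, "none"), ">= 20")
})
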