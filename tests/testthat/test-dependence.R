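test_that("distance correlation matches the literal double-centring oracle", {
  set.seed(21)
  for (r in 1:100) {
    n <- sample(4:12, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(distance_correlation(x, y), oracle_dcor(x, y),
                 tolerance = 1e-12)
  }
  # the fixed n = 6 case is hand-checkable from the 6x6 distance matrices
  x <- 1:6; y <- c(2, 1, 4, 3, 6, 5)
  expect_equal(distance_correlation(x, y), oracle_dcor(x, y), tolerance = 1e-12)
})

test_that("distance correlation is affine-invariant, symmetric and bounded", {
  set.seed(22)
  x <- rnorm(30)
  expect_equal(as.numeric(distance_correlation(x, x)), 1, tolerance = 1e-12)
  expect_equal(as.numeric(distance_correlation(x, 3 * x + 7)), 1,
               tolerance = 1e-12)
  y <- rnorm(30)
  expect_identical(distance_correlation(x, y), distance_correlation(y, x))
  expect_true(distance_correlation(x, y) >= 0 && distance_correlation(x, y) <= 1)
  cst <- distance_correlation(x, rep(1, 30))
  expect_equal(as.numeric(cst), 0)
  expect_true(attr(cst, "degenerate"))
})

test_that("MIC attains 1 on bijections and stays low under independence", {
  x <- seq_len(50)
  expect_equal(mic(x, x), 1)
  expect_equal(mic(x, -2 * x + 5), 1)
  set.seed(23)
  for (s in 1:3) {
    u <- runif(500); v <- runif(500)
    expect_lt(mic(u, v), 0.25)
  }
  expect_identical(mic(u, v), mic(v, u))
  expect_error(mic(rep(1, 20), rnorm(20)), "zero-variation")
  expect_error(mic(rnorm(5), rnorm(5)), "n >= 10")
})

test_that("the grid heuristic is admissible against exhaustive search", {
  # the equipartition/clump search is an approximation: it can never exceed
  # the true grid maximum, and it attains it on most inputs
  set.seed(24)
  heur <- ex <- numeric(0)
  for (r in 1:8) {
    n <- sample(20:28, 1)
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    if (var(x) == 0 || var(y) == 0) next
    heur <- c(heur, mic(x, y))
    ex <- c(ex, oracle_mic_exhaustive(x, y))
  }
  expect_true(all(heur <= ex + 1e-10))
  expect_gte(sum(abs(heur - ex) < 1e-10), length(ex) - 3)
})

test_that("HHG statistics equal the quadruple-loop oracle exactly", {
  set.seed(25)
  for (r in 1:8) {
    n <- sample(5:12, 1)
    # mixture of tied and continuous inputs
    x <- if (r %% 2) sample(0:3, n, TRUE) else rnorm(n)
    y <- rnorm(n)
    dx <- abs(outer(x, x, "-")); dy <- abs(outer(y, y, "-"))
    expect_equal(unname(hhg_statistics(dx, dy)), unname(oracle_hhg(dx, dy)),
                 tolerance = 1e-10)
  }
  # constant y: one margin is always empty, every table contributes zero
  x <- rnorm(8)
  dx <- abs(outer(x, x, "-")); dy <- matrix(0, 8, 8)
  expect_equal(unname(hhg_statistics(dx, dy)), rep(0, 4))
  expect_error(hhg_statistics(matrix(1:9, 3), dy), "symmetric")
})

test_that("HHG permutation p-values are reproducible with a floor of 1/(B+1)", {
  set.seed(26)
  # tied integer input, the data type the screen actually sees: perfect
  # dependence attains the permutation floor on all four statistics
  x <- sample(1:6, 60, TRUE)
  h1 <- hhg_test(x, x, n_perm = 99, seed = 31)
  h2 <- hhg_test(x, x, n_perm = 99, seed = 31)
  expect_identical(h1$p_values, h2$p_values)
  expect_equal(unname(h1$p_values), rep(1 / 100, 4))
  # on continuous input the sum statistics still attain the floor
  z <- rnorm(40)
  hc <- hhg_test(z, z, n_perm = 99, seed = 5)
  expect_equal(unname(hc$p_values[c("pval_sc", "pval_sl")]), rep(0.01, 2))
  expect_error(hhg_test(z, z, n_perm = 50), ">= 99")
})

test_that("dependence on a permuted copy never exceeds the aligned statistic", {
  set.seed(27)
  n <- 20
  x <- rnorm(n)
  dx <- abs(outer(x, x, "-"))
  obs <- hhg_statistics(dx, dx)["sum_chisq"]
  perm_max <- max(replicate(200, {
    s <- sample(n)
    hhg_statistics(dx[s, s], dx)["sum_chisq"]
  }))
  expect_gt(obs, perm_max)
})

test_that("MIC, dCor and HHG all detect a sinusoidal signal", {
  n <- 200
  # null thresholds for the two measures without built-in inference
  set.seed(28)
  null_mic <- replicate(100, mic(runif(n), runif(n)))
  null_dcor <- replicate(100, distance_correlation(runif(n), runif(n)))
  thr_mic <- quantile(null_mic, 0.95)
  thr_dcor <- quantile(null_dcor, 0.95)
  hits <- c(mic = 0, dcor = 0, hhg = 0)
  reps <- 50
  for (r in 1:reps) {
    x <- runif(n)
    y <- sin(4 * pi * x) + rnorm(n, 0, 0.3)
    hits["mic"] <- hits["mic"] + (mic(x, y) > thr_mic)
    hits["dcor"] <- hits["dcor"] + (distance_correlation(x, y) > thr_dcor)
    hits["hhg"] <- hits["hhg"] +
      (hhg_test(x, y, n_perm = 99, seed = r)$p_values[["pval_sc"]] <= 0.05)
  }
  expect_true(all(hits / reps >= 0.8))
})

test_that("the screen tests every transformed column plus the self row", {
  d <- fixture_with_covariates()
  pt <- build_pairwise_table(d)
  scr <- dependence_screen(pt, n_perm = 99, seed = 6)
  expect_equal(nrow(scr), 23)
  expect_equal(scr$variable[23], "hamming")
  expect_equal(scr$dcor[23], 1, tolerance = 1e-12)
  expect_gt(scr$mic[23], 0.95)
  expect_equal(unname(unlist(scr[23, c("pval_sc", "pval_sl", "pval_mc",
                                       "pval_ml")])), rep(0.01, 4))
  expect_true(all(scr$mic >= 0 & scr$mic <= 1))
  expect_true(all(scr$dcor >= 0 & scr$dcor <= 1))
  corr <- dependence_corrections(scr)
  expect_named(corr, c("pval_sc", "pval_sl", "pval_mc", "pval_ml"))
  for (tab in corr) {
    expect_equal(nrow(tab), 23)
    expect_true(all(tab$bonferroni >= tab$raw - 1e-15))
    expect_true(all(tab$hochberg <= tab$holm + 1e-15))
  }
})
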