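test_that("splitting by practice partitions the societies", {
  d <- fixture_with_covariates()
  sp <- split_by_practice(d, "MM", "npp_mean")
  expect_length(sp$present, 3)    # Naskapi, Western Apache, Nivkh
  expect_length(sp$absent, 19)
  expect_true(sp$sufficient)
  for (code in practice_codes()) {
    s <- split_by_practice(d, code, "elevation")
    expect_equal(length(s$present) + length(s$absent), 22)
  }
  expect_error(split_by_practice(d, "XX", "elevation"), "unknown practice")
})

test_that("exact Wilcoxon-Mann-Whitney agrees with full enumeration", {
  w <- wilcoxon_mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p_value, 0.1)
  expect_equal(w$p_value, oracle_wmw_enum(c(1, 2, 3), c(4, 5, 6)))
  set.seed(14)
  for (r in 1:15) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    g1 <- rnorm(n1); g2 <- rnorm(n2)   # continuous, no ties
    expect_equal(wilcoxon_mann_whitney(g1, g2)$p_value,
                 oracle_wmw_enum(g1, g2), tolerance = 1e-12)
  }
})

test_that("the normal approximation tracks the exact WMW tail at n = 6 + 6", {
  # enumerate every attainable U; the worst-case gap of the continuity-corrected
  # approximation at these sizes is ~0.0155
  n1 <- 6; n2 <- 6; mu <- n1 * n2 / 2
  diffs <- vapply(0:(n1 * n2), function(u) {
    exact <- min(1, if (u > mu) 2 * (1 - pwilcox(u - 1, n1, n2))
                 else if (u < mu) 2 * pwilcox(u, n1, n2) else 1)
    cc <- if (u == mu) 0 else 0.5 * sign(u - mu)
    z <- (u - mu - cc) / sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
    abs(exact - min(1, 2 * pnorm(-abs(z))))
  }, numeric(1))
  expect_lt(max(diffs), 0.02)
  expect_lt(mean(diffs), 0.01)
})

test_that("all four tests are symmetric under identical groups", {
  g <- c(1, 2, 3, 4)
  for (res in list(t_test(g, g), wilcoxon_mann_whitney(g, g),
                   fligner_policello(g, g), brunner_munzel(g, g))) {
    expect_equal(res$statistic, 0)
    expect_equal(res$p_value, 1)
  }
  expect_equal(brunner_munzel(g, g)$estimate, 0.5)
  # degenerate: both groups constant with equal means
  res <- t_test(c(2, 2, 2), c(2, 2, 2))
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
})

test_that("swapping the groups flips the statistic but not the p-value", {
  set.seed(8)
  g1 <- rnorm(10); g2 <- rnorm(12, 1)
  for (f in list(t_test, wilcoxon_mann_whitney, fligner_policello,
                 brunner_munzel)) {
    a <- f(g1, g2); b <- f(g2, g1)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-10)
    expect_equal(a$statistic, -b$statistic, tolerance = 1e-10)
  }
})

test_that("assumption checks route to the appropriate battery", {
  set.seed(2)
  g1 <- rnorm(11); g2 <- rnorm(11)
  r <- route_and_test(g1, g2)
  # verify the routing decision against the checks it claims to have made
  expect_gt(r$shapiro_p1[1], 0.05)
  expect_gt(r$shapiro_p2[1], 0.05)
  expect_gt(r$levene_p[1], 0.05)
  expect_equal(r$route[1], "t")
  expect_equal(nrow(r), 1)

  set.seed(7)
  h1 <- rcauchy(11); h2 <- 10 * rcauchy(11)
  r2 <- route_and_test(h1, h2)
  expect_lt(min(r2$shapiro_p1[1], r2$shapiro_p2[1]), 0.05)
  expect_lt(r2$levene_p[1], 0.05)
  expect_equal(r2$route[1], "fp_bm_wmw")
  expect_equal(nrow(r2), 3)
  expect_setequal(r2$test, c("fligner_policello", "brunner_munzel", "wmw"))
})

test_that("the full sweep schedules 294 combinations on the fixture", {
  d <- fixture_with_covariates()
  sw <- exploratory_sweep(d)
  expect_equal(attr(sw, "n_scheduled"), 294)
  # every fixture practice has >= 3 present and absent, so nothing is skipped
  expect_equal(sum(sw$test == "skipped"), 0)
  expect_equal(length(unique(paste(sw$practice, sw$variable))), 294)
  expect_lte(nrow(sw), 294 * 3)
  expect_true(all(sw$p_value > 0 & sw$p_value <= 1))
})

test_that("correction procedures match their defining step formulas", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "holm")$adjusted,
               c(0.03, 0.04, 0.04))
  expect_equal(adjust_pvalues(0.01, "bonferroni")$adjusted, 0.01)
  # m = 1: every method is the identity
  for (mth in c("bonferroni", "sidak", "holm", "hochberg", "hommel", "bh", "by"))
    expect_equal(adjust_pvalues(0.2, mth)$adjusted, 0.2)
  expect_equal(adjust_pvalues(rep(0.01, 294), "bonferroni")$adjusted[1], 1)
  expect_equal(adjust_pvalues(c(0.02, 0.5), "sidak")$adjusted,
               1 - (1 - c(0.02, 0.5))^2)
  expect_error(adjust_pvalues(c(0.1, 0), "holm"), "\\(0, 1\\]")
  expect_error(adjust_pvalues(c(0.1, 1.2), "holm"), "\\(0, 1\\]")
})

test_that("corrections are ordered and monotone", {
  set.seed(5)
  for (r in 1:25) {
    p <- runif(sample(2:60, 1))
    bon <- adjust_pvalues(p, "bonferroni")$adjusted
    holm <- adjust_pvalues(p, "holm")$adjusted
    hoch <- adjust_pvalues(p, "hochberg")$adjusted
    hom <- adjust_pvalues(p, "hommel")$adjusted
    bh <- adjust_pvalues(p, "bh")$adjusted
    expect_true(all(hoch <= holm + 1e-15))
    expect_true(all(holm <= bon + 1e-15))
    expect_true(all(hom <= holm + 1e-15))
    expect_true(all(bh <= hoch + 1e-15))
    expect_true(all(holm >= p - 1e-15))
    # monotone in the raw p-values
    o <- order(p)
    for (adj in list(bon, holm, hoch, hom, bh))
      expect_false(is.unsorted(adj[o]))
  }
})
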