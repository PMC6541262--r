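test_that("the mean baseline predicts the training mean everywhere", {
  expect_equal(mean_baseline_fit_predict(c(2, 4), 3), c(3, 3, 3))
  expect_error(mean_baseline_fit_predict(numeric(0), 2), "empty")
  # constant response: zero test error by construction
  expect_equal(mean((5 - mean_baseline_fit_predict(rep(5, 10), 4))^2), 0)
})

test_that("rotation forest fits a noiseless linear signal almost perfectly", {
  prob <- generate_regression_problem(150, "linear", noise_sd = 0, seed = 31)
  fit <- rotation_forest(prob$X, prob$y, n_trees = 10, n_subsets = 3,
                         minsplit = 2, cp = 1e-4, seed = 1)
  pred <- predict(fit, prob$X)
  r2 <- 1 - mean((prob$y - pred)^2) / var(prob$y)
  expect_gt(r2, 0.95)
})

test_that("rotation forest is deterministic and handles edge cases", {
  prob <- generate_regression_problem(60, "nonlinear", noise_sd = 0.5, seed = 32)
  f1 <- rotation_forest(prob$X, prob$y, n_trees = 3, n_subsets = 2, seed = 7)
  f2 <- rotation_forest(prob$X, prob$y, n_trees = 3, n_subsets = 2, seed = 7)
  expect_identical(predict(f1, prob$X), predict(f2, prob$X))
  # a single tree with one subset is a tree on one globally rotated space
  f3 <- rotation_forest(prob$X, prob$y, n_trees = 1, n_subsets = 1, seed = 3)
  expect_identical(predict(f3, prob$X), predict(f3, prob$X))
  # constant response: every prediction equals that constant
  fc <- rotation_forest(prob$X, rep(2.5, 60), n_trees = 2, n_subsets = 2,
                        seed = 1)
  expect_equal(unname(predict(fc, prob$X)), rep(2.5, 60))
  expect_error(rotation_forest(prob$X[, 1:3], prob$y, n_subsets = 5),
               "exceeds")
})

test_that("outer folds partition the rows and are shared across methods", {
  prob <- generate_regression_problem(231, "none", seed = 33)
  ctrl <- cv_control(rf_trees = 30, boost_rounds = 30, boost_depth_grid = 2,
                     boost_eta_grid = 0.1, rot_trees = 2, rot_subsets_grid = 2,
                     svm_cost_grid = 1, svm_gamma_scale = 1)
  fm <- nested_cv(prob$X, prob$y, methods = c("mean_baseline", "svm_rbf"),
                  k_outer = 10, k_inner = 2, control = ctrl, seed = 12)
  sizes <- attr(fm, "fold_sizes")
  expect_equal(sort(sizes), c(rep(23L, 9), 24L))
  expect_equal(sum(sizes), 231)
  fold <- attr(fm, "fold_assignment")
  expect_equal(length(fold), 231)
  # mean-baseline fold MSE is recomputable from the assignment alone
  for (f in 1:10) {
    te <- fold == f
    expect_equal(fm$mean_baseline[f],
                 mean((prob$y[te] - mean(prob$y[!te]))^2), tolerance = 1e-12)
  }
  # same seed, same table
  fm2 <- nested_cv(prob$X, prob$y, methods = c("mean_baseline", "svm_rbf"),
                   k_outer = 10, k_inner = 2, control = ctrl, seed = 12)
  expect_identical(fm, fm2)
})

test_that("the fold ANOVA reproduces closed-form hand computations", {
  # two methods, three folds: SSB = 13.5, SSW = 4, df = (1, 4)
  tab <- data.frame(A = c(1, 2, 3), B = c(4, 5, 6))
  an <- anova_on_folds(tab)
  expect_equal(an$df_model, 1L)
  expect_equal(an$df_residual, 4L)
  expect_equal(an$ss_model, 13.5)
  expect_equal(an$ss_residual, 4)
  expect_equal(an$F, 13.5)
  expect_equal(an$p, 0.0213, tolerance = 1e-3)
  # the published layout: 5 methods x 10 folds gives Df 4 and 45
  tab5 <- as.data.frame(matrix(rnorm(50), 10, 5))
  an5 <- anova_on_folds(tab5)
  expect_equal(an5$df_model, 4L)
  expect_equal(an5$df_residual, 45L)
  # all cells equal: no between-method variance
  anc <- anova_on_folds(data.frame(A = rep(1, 4), B = rep(1, 4)))
  expect_equal(anc$ss_model, 0)
  expect_equal(anc$F, 0)
  expect_true(anc$degenerate)
})

test_that("the fold ANOVA agrees with the reference implementation", {
  set.seed(34)
  tab <- as.data.frame(matrix(rexp(40), 8, 5))
  an <- anova_on_folds(tab)
  long <- data.frame(mse = unlist(tab),
                     method = factor(rep(names(tab), each = 8)))
  ref <- summary(stats::aov(mse ~ method, data = long))[[1]]
  expect_equal(an$F, ref[1, "F value"], tolerance = 1e-10)
  expect_equal(an$p, ref[1, "Pr(>F)"], tolerance = 1e-10)
  expect_equal(an$ss_model, ref[1, "Sum Sq"], tolerance = 1e-10)
  # invariant to the column order of the table
  an_perm <- anova_on_folds(tab[, c(3, 1, 5, 2, 4)])
  expect_equal(an_perm$F, an$F, tolerance = 1e-12)
})

test_that("fold-MSE summaries append mean, sd and se rows", {
  tab <- data.frame(A = c(1, 3), B = c(2, 2))
  s <- fold_mse_summary(tab)
  expect_equal(nrow(s), 5)
  expect_equal(s$A[s$fold == "mean"], 2)
  expect_equal(s$A[s$fold == "sd"], sd(c(1, 3)))
  expect_equal(s$A[s$fold == "se"], sd(c(1, 3)) / sqrt(2))
})
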