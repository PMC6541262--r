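#' Mean-prediction baseline
#'
#' The null reference model of the predictive comparison: predicts the
#' training-set mean everywhere.
#'
#' @param train_y Numeric training responses (non-empty).
#' @param test_n Number of predictions to emit.
#' @return Constant numeric vector of length `test_n`.
#' @export
mean_baseline_fit_predict <- function(train_y, test_n) {
  if (length(train_y) == 0) stop("empty training response")
  rep(mean(train_y), test_n)
}

#' Rotation forest for regression
#'
#' Ensemble of regression trees on randomly rotated feature spaces: for each
#' tree the features are randomly partitioned into `n_subsets` groups, a
#' principal-axis rotation is fitted per group on a random instance subsample
#' of fraction `sample_fraction`, the block-diagonal rotation is applied to
#' the full data, and a fully grown tree is trained on the rotated features.
#' Predictions average the trees.
#'
#' @param X Data.frame or matrix of >= 2 numeric features.
#' @param y Numeric response.
#' @param n_trees Number of trees.
#' @param n_subsets Number of feature groups per tree (must not exceed the
#'   number of features).
#' @param sample_fraction Fraction of instances used to fit each rotation.
#' @param minsplit,cp Tree-growing controls passed to the underlying regression
#'   trees; the defaults are the usual pruned-tree settings, while
#'   `minsplit = 2, cp = 1e-4` grows trees to (near) full depth for
#'   capacity studies.
#' @param seed Integer seed; fits are deterministic given the seed.
#' @return An object of class `rotation_forest` with a `predict` method.
#' @export
rotation_forest <- function(X, y, n_trees = 10, n_subsets = 3,
                            sample_fraction = 0.75, minsplit = 20, cp = 0.01,
                            seed = 1L) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 2) stop("need >= 2 features")
  if (n_subsets > p) stop("n_feature_subsets exceeds the number of features")
  n <- nrow(X)
  with_seed(seed, function() {
    trees <- lapply(seq_len(n_trees), function(t) {
      groups <- split(sample.int(p), rep(seq_len(n_subsets),
                                         length.out = p))
      rot <- matrix(0, p, p)
      centers <- numeric(p)
      for (g in groups) {
        sub <- sample.int(n, max(2, round(sample_fraction * n)))
        pc <- stats::prcomp(X[sub, g, drop = FALSE], center = TRUE,
                            scale. = FALSE)
        centers[g] <- pc$center
        k <- ncol(pc$rotation)
        rot[g, g[seq_len(k)]] <- pc$rotation
        if (k < length(g))  # degenerate subsample: complete with identity axes
          rot[g[(k + 1):length(g)], g[(k + 1):length(g)]] <-
            diag(length(g) - k)
      }
      Z <- sweep(X, 2, centers) %*% rot
      colnames(Z) <- paste0("r", seq_len(p))
      fit <- rpart::rpart(y ~ ., data = data.frame(Z, y = y),
                          method = "anova",
                          control = rpart::rpart.control(minsplit = minsplit,
                                                         cp = cp, xval = 0))
      list(centers = centers, rot = rot, fit = fit)
    })
    structure(list(trees = trees, p = p), class = "rotation_forest")
  })
}

#' @rdname rotation_forest
#' @param object A fitted `rotation_forest`.
#' @param newdata Feature table with the same columns as at fit time.
#' @param ... Unused.
#' @export
predict.rotation_forest <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  preds <- vapply(object$trees, function(tr) {
    Z <- sweep(newdata, 2, tr$centers) %*% tr$rot
    colnames(Z) <- paste0("r", seq_len(object$p))
    unname(stats::predict(tr$fit, data.frame(Z)))
  }, numeric(nrow(newdata)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  rowMeans(preds)
}

#' Learner settings for the nested cross-validation
#'
#' Hyperparameter grids and ensemble sizes for the four learners. The
#' defaults are the full-size settings used for the 231-row pairwise design;
#' the `light` preset shrinks ensembles and grids for simulation studies
#' where the comparison of interest is learners-versus-baseline, not
#' learner-versus-learner.
#'
#' @param rf_trees Random-forest ensemble size.
#' @param boost_rounds Gradient-boosting rounds.
#' @param boost_depth_grid,boost_eta_grid Boosting grids.
#' @param rot_trees,rot_subsets_grid,rot_sample_fraction Rotation-forest
#'   settings.
#' @param svm_cost_grid,svm_gamma_scale,svm_epsilon SVM-RBF grids; gamma is
#'   `svm_gamma_scale / p` for `p` features.
#' @return List of class `cv_control`.
#' @export
cv_control <- function(rf_trees = 500,
                       boost_rounds = 500,
                       boost_depth_grid = c(1, 2, 3),
                       boost_eta_grid = c(0.05, 0.1),
                       rot_trees = 10,
                       rot_subsets_grid = c(2, 3),
                       rot_sample_fraction = 0.75,
                       svm_cost_grid = c(0.1, 1, 10, 100),
                       svm_gamma_scale = c(0.1, 1, 10),
                       svm_epsilon = 0.1) {
  structure(as.list(environment()), class = "cv_control")
}

#' @rdname cv_control
#' @export
cv_control_light <- function() {
  cv_control(rf_trees = 100, boost_rounds = 100,
             boost_depth_grid = c(2, 3), boost_eta_grid = 0.1,
             rot_trees = 5, rot_subsets_grid = 2,
             svm_cost_grid = c(1, 10), svm_gamma_scale = 1)
}

learner_grid <- function(method, p, control) {
  switch(method,
    random_forest = lapply(unique(pmax(1, c(floor(p / 3), floor(sqrt(p)), p))),
                           function(m) list(mtry = m)),
    boosting = {
      g <- expand.grid(depth = control$boost_depth_grid,
                       eta = control$boost_eta_grid)
      lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
    },
    rotation_forest = lapply(control$rot_subsets_grid,
                             function(s) list(n_subsets = min(s, p))),
    svm_rbf = {
      g <- expand.grid(cost = control$svm_cost_grid,
                       gamma = control$svm_gamma_scale / p)
      lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
    },
    mean_baseline = list(list())
  )
}

learner_fit_predict <- function(method, Xtr, ytr, Xte, params, control, seed) {
  switch(method,
    mean_baseline = mean_baseline_fit_predict(ytr, nrow(Xte)),
    random_forest = with_seed(seed, function() {
      fit <- randomForest::randomForest(x = Xtr, y = ytr,
                                        ntree = control$rf_trees,
                                        mtry = min(params$mtry, ncol(Xtr)))
      unname(stats::predict(fit, Xte))
    }),
    boosting = {
      dtr <- xgboost::xgb.DMatrix(as.matrix(Xtr), label = ytr)
      fit <- xgboost::xgb.train(
        params = list(max_depth = params$depth, eta = params$eta,
                      objective = "reg:squarederror", nthread = 1,
                      seed = seed),
        dtr, nrounds = control$boost_rounds, verbose = 0)
      unname(stats::predict(fit, as.matrix(Xte)))
    },
    rotation_forest = {
      fit <- rotation_forest(Xtr, ytr, n_trees = control$rot_trees,
                             n_subsets = params$n_subsets,
                             sample_fraction = control$rot_sample_fraction,
                             seed = seed)
      predict(fit, Xte)
    },
    svm_rbf = {
      # scale = TRUE standardizes on the training set and applies the same
      # transform to test rows; tree methods use raw features
      fit <- e1071::svm(x = as.matrix(Xtr), y = ytr, kernel = "radial",
                        cost = params$cost, gamma = params$gamma,
                        epsilon = control$svm_epsilon, scale = TRUE)
      unname(stats::predict(fit, as.matrix(Xte)))
    },
    stop("unknown method: ", method)
  )
}

#' Nested cross-validation fold-MSE table
#'
#' Ten-fold (by default) outer cross-validation with an inner k-fold grid
#' search per outer training set: hyperparameters minimizing inner CV MSE are
#' selected, the model is refit on the full outer-train, and the MSE on the
#' held-out outer fold is recorded. All methods share identical outer folds
#' (paired design); the entire run is a deterministic function of `seed`.
#'
#' @param X Feature data.frame.
#' @param y Numeric response.
#' @param methods Character vector of learners among `"random_forest"`,
#'   `"boosting"`, `"rotation_forest"`, `"svm_rbf"`, `"mean_baseline"`.
#' @param k_outer,k_inner Outer and inner fold counts.
#' @param control A [cv_control()].
#' @param seed Integer master seed; per-fold per-method seeds are derived
#'   from it.
#' @return Data.frame of `k_outer` rows (folds) by method columns of MSEs,
#'   with attributes `fold_assignment` and `fold_sizes`.
#' @export
nested_cv <- function(X, y, methods = c("random_forest", "boosting",
                                        "rotation_forest", "svm_rbf",
                                        "mean_baseline"),
                      k_outer = 10, k_inner = 5,
                      control = cv_control(), seed = 1L) {
  X <- as.data.frame(X)
  n <- nrow(X)
  if (n < 2 * k_outer) stop("need at least 2 rows per outer fold")
  grids <- lapply(methods, learner_grid, p = ncol(X), control = control)
  names(grids) <- methods
  if (any(vapply(grids, length, integer(1)) == 0)) stop("empty grid")
  with_seed(seed, function() {
    fold <- sample(rep(seq_len(k_outer), length.out = n))
    seeds <- matrix(sample.int(2^30, k_outer * length(methods)),
                    k_outer, length(methods))
    inner_seeds <- sample.int(2^30, k_outer)
    mse <- matrix(NA_real_, k_outer, length(methods),
                  dimnames = list(NULL, methods))
    for (f in seq_len(k_outer)) {
      te <- fold == f
      Xtr <- X[!te, , drop = FALSE]; ytr <- y[!te]
      Xte <- X[te, , drop = FALSE]; yte <- y[te]
      ifold <- with_seed(inner_seeds[f], function()
        sample(rep(seq_len(k_inner), length.out = nrow(Xtr))))
      for (mi in seq_along(methods)) {
        mth <- methods[mi]
        grid <- grids[[mth]]
        best <- grid[[1]]
        if (length(grid) > 1) {
          inner_mse <- vapply(grid, function(par) {
            errs <- vapply(seq_len(k_inner), function(g) {
              ite <- ifold == g
              pr <- learner_fit_predict(mth, Xtr[!ite, , drop = FALSE],
                                        ytr[!ite], Xtr[ite, , drop = FALSE],
                                        par, control,
                                        seed = seeds[f, mi] + g)
              mean((ytr[ite] - pr)^2)
            }, numeric(1))
            mean(errs)
          }, numeric(1))
          best <- grid[[which.min(inner_mse)]]
        }
        pr <- learner_fit_predict(mth, Xtr, ytr, Xte, best, control,
                                  seed = seeds[f, mi])
        mse[f, mi] <- mean((yte - pr)^2)
      }
    }
    out <- as.data.frame(mse)
    attr(out, "fold_assignment") <- fold
    attr(out, "fold_sizes") <- as.integer(table(fold))
    out
  })
}

#' One-way ANOVA on the fold-MSE table
#'
#' Fixed-effects one-way ANOVA with method as the factor and per-fold MSEs as
#' observations, exactly as the comparison table lays it out: with M methods
#' and K folds the model has `M - 1` degrees of freedom and the residuals
#' `M * (K - 1)`. Fold pairing is deliberately ignored here, replicating the
#' published analysis (the caveat is documented in the methods vignette).
#'
#' @param table Fold-by-method MSE data.frame from [nested_cv()].
#' @return List with `df_model`, `df_residual`, `ss_model`, `ss_residual`,
#'   `ms_model`, `ms_residual`, `F`, `p`, `degenerate`, and `table` (a
#'   Df / Sum Sq / Mean Sq / F value / Pr(>F) data.frame).
#' @export
anova_on_folds <- function(table) {
  m <- as.matrix(table)
  if (anyNA(m)) stop("fold-MSE table has missing cells")
  k <- nrow(m); M <- ncol(m)
  grand <- mean(m)
  means <- colMeans(m)
  ss_model <- k * sum((means - grand)^2)
  ss_resid <- sum(sweep(m, 2, means)^2)
  df_model <- M - 1L
  df_resid <- M * (k - 1L)
  ms_model <- ss_model / df_model
  ms_resid <- ss_resid / df_resid
  degenerate <- ss_model + ss_resid == 0
  f <- if (degenerate) 0 else if (ss_model == 0) 0
       else if (ms_resid == 0) Inf else ms_model / ms_resid
  p <- if (degenerate) NA_real_ else stats::pf(f, df_model, df_resid,
                                               lower.tail = FALSE)
  tab <- data.frame(
    term = c("Model", "Residuals"),
    Df = c(df_model, df_resid),
    `Sum Sq` = c(ss_model, ss_resid),
    `Mean Sq` = c(ms_model, ms_resid),
    `F value` = c(f, NA),
    `Pr(>F)` = c(p, NA),
    check.names = FALSE
  )
  list(df_model = df_model, df_residual = df_resid,
       ss_model = ss_model, ss_residual = ss_resid,
       ms_model = ms_model, ms_residual = ms_resid,
       F = f, p = p, degenerate = degenerate, table = tab)
}

#' Predictive-null pattern test on a pairwise design
#'
#' Stage-6 analysis: can any of the four learners predict Hamming
#' dissimilarity from the 22 transformed variables better than the mean
#' predictor? Runs the paired nested cross-validation and the one-way ANOVA
#' on fold MSEs; the verdict is `"no detectable pattern"` when the ANOVA
#' p-value is at least `alpha`.
#'
#' @param pairs A pairwise table from [build_pairwise_table()].
#' @param k_outer,k_inner Fold counts.
#' @param control A [cv_control()].
#' @param seed Master seed.
#' @param alpha Significance level of the verdict.
#' @param methods Learners to compare against the baseline.
#' @return List with `fold_mse`, `anova`, `verdict`, `alpha`.
#' @export
pattern_test <- function(pairs, k_outer = 10, k_inner = 5,
                         control = cv_control(), seed = 1L, alpha = 0.05,
                         methods = c("random_forest", "boosting",
                                     "rotation_forest", "svm_rbf",
                                     "mean_baseline")) {
  X <- pairs[, pairwise_regressors(pairs), drop = FALSE]
  y <- pairs$hamming
  if (!"mean_baseline" %in% methods)
    methods <- c(methods, "mean_baseline")
  fm <- nested_cv(X, y, methods = methods, k_outer = k_outer,
                  k_inner = k_inner, control = control, seed = seed)
  an <- anova_on_folds(fm)
  list(fold_mse = fm, anova = an,
       verdict = if (!is.na(an$p) && an$p < alpha) "pattern detected"
                 else "no detectable pattern",
       alpha = alpha)
}

#' Fold-MSE summary in the supplementary-table layout
#'
#' Appends mean, standard deviation and standard error rows to a fold-MSE
#' table.
#'
#' @param table Fold-by-method MSE data.frame.
#' @return Data.frame with a leading `fold` column and summary rows.
#' @export
fold_mse_summary <- function(table) {
  m <- as.matrix(table)
  out <- data.frame(fold = c(as.character(seq_len(nrow(m))),
                             "mean", "sd", "se"),
                    rbind(m, colMeans(m), apply(m, 2, stats::sd),
                          apply(m, 2, stats::sd) / sqrt(nrow(m))),
                    check.names = FALSE)
  rownames(out) <- NULL
  out
}
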