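test_result <- function(test, statistic, p_value, n1, n2,
                        estimate = NA_real_, degenerate = FALSE) {
  data.frame(test = test, statistic = statistic, p_value = p_value,
             n_present = n1, n_absent = n2, estimate = estimate,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

both_constant <- function(g1, g2) {
  stats::var(g1) == 0 && stats::var(g2) == 0
}

degenerate_result <- function(test, g1, g2) {
  if (mean(g1) == mean(g2)) {
    test_result(test, 0, 1, length(g1), length(g2), degenerate = TRUE)
  } else {
    test_result(test, Inf, .Machine$double.eps, length(g1), length(g2),
                degenerate = TRUE)
  }
}

#' Two-sample location tests
#'
#' The four unpaired tests of the exploratory battery, all two-sided, each
#' returning a one-row data.frame with `test`, `statistic`, `p_value`,
#' `n_present`, `n_absent`, `estimate` and a `degenerate` flag.
#'
#' * `t_test()` — Student's pooled-variance t-test (the route only reaches it
#'   when normality and homogeneity hold).
#' * `wilcoxon_mann_whitney()` — Mann-Whitney U. Exact enumeration of the U
#'   null distribution when `n1 + n2 <= 12` and there are no ties; otherwise a
#'   normal approximation with mid-ranks, tie-corrected variance and
#'   continuity correction. The reported statistic is the centred
#'   `U - n1*n2/2`.
#' * `fligner_policello()` — placement-based robust rank test: with placements
#'   `P_i = #(y < x_i)` and `Q_j = #(x < y_j)` (ties counted 1/2), the
#'   statistic `(sum P - sum Q) / (2 sqrt(V_P + V_Q + Pbar Qbar))` is referred
#'   to the standard normal.
#' * `brunner_munzel()` — rank-based test of the relative effect
#'   `P(X < Y) + 0.5 P(X = Y)` with Welch-Satterthwaite degrees of freedom and
#'   a t reference; valid under unequal variances and shapes.
#'
#' @param g1,g2 Numeric samples (present/absent groups); each of size >= 3
#'   (>= 4 for Brunner-Munzel).
#' @param exact_if_small Use the exact U distribution when admissible.
#' @return One-row data.frame as described.
#' @export
t_test <- function(g1, g2) {
  if (length(g1) < 3 || length(g2) < 3) stop("each group needs >= 3 values")
  if (both_constant(g1, g2)) return(degenerate_result("t", g1, g2))
  ht <- stats::t.test(g1, g2, var.equal = TRUE)
  test_result("t", unname(ht$statistic), ht$p.value, length(g1), length(g2),
              estimate = mean(g1) - mean(g2))
}

#' @rdname t_test
#' @export
wilcoxon_mann_whitney <- function(g1, g2, exact_if_small = TRUE) {
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 3 || n2 < 3) stop("each group needs >= 3 values")
  if (both_constant(g1, g2)) return(degenerate_result("wmw", g1, g2))
  pooled <- c(g1, g2)
  ties <- anyDuplicated(pooled) > 0
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # #{(x,y): x > y} + 0.5 ties
  mu <- n1 * n2 / 2
  if (exact_if_small && !ties && n1 + n2 <= 12) {
    p <- if (u > mu) 2 * (1 - stats::pwilcox(u - 1, n1, n2))
         else if (u < mu) 2 * stats::pwilcox(u, n1, n2)
         else 1
    p <- min(1, p)
    return(test_result("wmw", u - mu, p, n1, n2, estimate = u / (n1 * n2)))
  }
  nn <- n1 + n2
  tie_tab <- table(pooled)
  sigma2 <- n1 * n2 / 12 * ((nn + 1) - sum(tie_tab^3 - tie_tab) / (nn * (nn - 1)))
  if (sigma2 <= 0) return(degenerate_result("wmw", g1, g2))
  cc <- if (u == mu) 0 else 0.5 * sign(u - mu)
  z <- (u - mu - cc) / sqrt(sigma2)
  test_result("wmw", u - mu, min(1, 2 * stats::pnorm(-abs(z))), n1, n2,
              estimate = u / (n1 * n2))
}

#' @rdname t_test
#' @export
fligner_policello <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 3 || n2 < 3) stop("each group needs >= 3 values")
  placements <- function(a, b)  # for each a_i: #{b < a_i} + 0.5 #{b == a_i}
    vapply(a, function(v) sum(b < v) + 0.5 * sum(b == v), numeric(1))
  p <- placements(g1, g2)
  q <- placements(g2, g1)
  vp <- sum((p - mean(p))^2)
  vq <- sum((q - mean(q))^2)
  denom <- 2 * sqrt(vp + vq + mean(p) * mean(q))
  num <- sum(p) - sum(q)
  if (denom == 0) {
    return(if (num == 0) test_result("fligner_policello", 0, 1, n1, n2,
                                     degenerate = TRUE)
           else test_result("fligner_policello", Inf * sign(num),
                            .Machine$double.eps, n1, n2, degenerate = TRUE))
  }
  u_hat <- num / denom
  test_result("fligner_policello", u_hat, min(1, 2 * stats::pnorm(-abs(u_hat))),
              n1, n2)
}

#' @rdname t_test
#' @export
brunner_munzel <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 4 || n2 < 4) stop("each group needs >= 4 values for Brunner-Munzel")
  nn <- n1 + n2
  r <- rank(c(g1, g2))
  r1 <- r[seq_len(n1)]; r2 <- r[n1 + seq_len(n2)]
  ri1 <- rank(g1); ri2 <- rank(g2)
  m1 <- mean(r1); m2 <- mean(r2)
  phat <- (m2 - (n2 + 1) / 2) / n1   # relative effect P(X<Y) + 0.5 P(X=Y)
  v1 <- sum((r1 - ri1 - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  v2 <- sum((r2 - ri2 - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  s2 <- n1 * v1 + n2 * v2
  if (s2 == 0) {
    return(if (m1 == m2) test_result("brunner_munzel", 0, 1, n1, n2,
                                     estimate = phat, degenerate = TRUE)
           else test_result("brunner_munzel", Inf * sign(m2 - m1),
                            .Machine$double.eps, n1, n2, estimate = phat,
                            degenerate = TRUE))
  }
  w <- n1 * n2 * (m2 - m1) / (nn * sqrt(s2))
  df <- s2^2 / ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1))
  test_result("brunner_munzel", w, min(1, 2 * stats::pt(-abs(w), df)), n1, n2,
              estimate = phat)
}

#' Split a covariate by practice presence
#'
#' @param dataset A `society_dataset` with covariates.
#' @param practice One of the 14 practice codes.
#' @param variable A roster variable name.
#' @return List with `present` and `absent` numeric vectors and `sufficient`
#'   (logical: both groups have >= 3 members, the minimum any test in the
#'   battery accepts).
#' @export
split_by_practice <- function(dataset, practice, variable) {
  validate_society_dataset(dataset)
  if (!practice %in% practice_codes()) stop("unknown practice code: ", practice)
  if (!variable %in% dataset$roster) stop("unknown variable: ", variable)
  if (is.null(dataset$covariates)) stop("dataset has no covariates")
  x <- dataset$covariates[[variable]]
  if (anyNA(x)) stop("missing values in variable '", variable, "'")
  present <- vapply(dataset$practices, function(p) practice %in% p, logical(1))
  list(present = x[present], absent = x[!present],
       sufficient = sum(present) >= 3 && sum(!present) >= 3)
}

shapiro_p <- function(g) {
  if (stats::var(g) == 0) return(0)      # a constant sample is not Gaussian-like
  if (length(g) > 5000) g <- sample(g, 5000)
  stats::shapiro.test(g)$p.value
}

brown_forsythe_p <- function(g1, g2) {
  grp <- factor(rep(c("a", "b"), c(length(g1), length(g2))))
  res <- tryCatch(car::leveneTest(c(g1, g2), grp, center = stats::median),
                  error = function(e) NULL)
  p <- if (is.null(res)) NA_real_ else res[["Pr(>F)"]][1]
  if (is.na(p)) 1 else p   # no computable evidence against homogeneity
}

#' Assumption-based routing of the two-sample battery
#'
#' Decides which test(s) to run from the data: Shapiro-Wilk per group for
#' normality and the Brown-Forsythe (median-centred Levene) test for variance
#' homogeneity, both at `alpha_assumptions`. Both assumptions pass: Student's
#' t-test alone. Normality fails but homogeneity holds: Wilcoxon-Mann-Whitney
#' alone. When homogeneity fails (whatever the normality outcome) all three of
#' Fligner-Policello, Brunner-Munzel and Wilcoxon-Mann-Whitney are reported,
#' matching the three-p-value convention for assumption-violating cells.
#'
#' @param g1,g2 Numeric samples (>= 3 each; Brunner-Munzel additionally needs
#'   >= 4 and is dropped from the battery below that).
#' @param alpha_assumptions Significance level of the assumption checks.
#' @return Data.frame with one row per executed test, plus columns `route`,
#'   `shapiro_p1`, `shapiro_p2`, `levene_p`.
#' @export
route_and_test <- function(g1, g2, alpha_assumptions = 0.05) {
  if (length(g1) < 3 || length(g2) < 3) stop("each group needs >= 3 values")
  sp1 <- shapiro_p(g1); sp2 <- shapiro_p(g2)
  lp <- brown_forsythe_p(g1, g2)
  normal_ok <- sp1 > alpha_assumptions && sp2 > alpha_assumptions
  var_ok <- lp > alpha_assumptions
  if (normal_ok && var_ok) {
    out <- t_test(g1, g2); route <- "t"
  } else if (var_ok) {
    out <- wilcoxon_mann_whitney(g1, g2); route <- "wmw"
  } else {
    pieces <- list(fligner_policello(g1, g2))
    if (length(g1) >= 4 && length(g2) >= 4)
      pieces <- c(pieces, list(brunner_munzel(g1, g2)))
    pieces <- c(pieces, list(wilcoxon_mann_whitney(g1, g2)))
    out <- do.call(rbind, pieces); route <- "fp_bm_wmw"
  }
  out$route <- route
  out$shapiro_p1 <- sp1; out$shapiro_p2 <- sp2; out$levene_p <- lp
  out
}

#' Exploratory sweep over all practice-variable combinations
#'
#' Stage-1 analysis: for each of the 14 practices and each roster variable,
#' societies are split by practice presence and the routed two-sample battery
#' is applied. With the full roster this schedules `14 * 21 = 294`
#' combinations; combinations whose present or absent group has fewer than 3
#' societies are recorded as skipped rather than tested.
#'
#' @param dataset A `society_dataset` with complete covariates.
#' @param alpha_assumptions Level of the assumption checks used for routing.
#' @return Data.frame with columns `practice`, `variable`, `test`,
#'   `statistic`, `p_value`, `n_present`, `n_absent`, `route`, assumption
#'   p-values and `degenerate`; skipped combinations appear once with
#'   `test = "skipped"` and `route = "insufficient_group_size"`. The attribute
#'   `n_scheduled` carries the number of combinations considered.
#' @export
exploratory_sweep <- function(dataset, alpha_assumptions = 0.05) {
  validate_society_dataset(dataset)
  if (is.null(dataset$covariates)) stop("dataset has no covariates")
  combos <- expand.grid(practice = practice_codes(),
                        variable = dataset$roster,
                        stringsAsFactors = FALSE)
  rows <- vector("list", nrow(combos))
  for (k in seq_len(nrow(combos))) {
    pr <- combos$practice[k]; v <- combos$variable[k]
    sp <- split_by_practice(dataset, pr, v)
    if (!sp$sufficient) {
      res <- data.frame(test = "skipped", statistic = NA_real_,
                        p_value = NA_real_, n_present = length(sp$present),
                        n_absent = length(sp$absent), estimate = NA_real_,
                        degenerate = FALSE, route = "insufficient_group_size",
                        shapiro_p1 = NA_real_, shapiro_p2 = NA_real_,
                        levene_p = NA_real_, stringsAsFactors = FALSE)
    } else {
      res <- route_and_test(sp$present, sp$absent, alpha_assumptions)
    }
    res <- cbind(data.frame(practice = pr, variable = v,
                            stringsAsFactors = FALSE), res)
    rows[[k]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_scheduled") <- nrow(combos)
  out
}

#' Multiple-testing corrections
#'
#' Explicit implementations of the seven correction procedures used by the
#' exploratory sweep: Bonferroni `min(1, m p)`; Sidak `1 - (1 - p)^m`; Holm's
#' step-down; Hochberg's step-up; Hommel's Simes-based procedure (Wright's
#' algorithm); Benjamini-Hochberg step-up FDR; and Benjamini-Yekutieli with
#' the harmonic factor `c(m) = sum_{i<=m} 1/i`.
#'
#' @param raw Vector of raw p-values, all in `(0, 1]`.
#' @param method One of `"bonferroni"`, `"sidak"`, `"holm"`, `"hochberg"`,
#'   `"hommel"`, `"bh"`, `"by"`.
#' @return List of class `corrected_pvalues` with `method`, `raw`, `adjusted`.
#' @export
#' @examples
#' adjust_pvalues(c(0.01, 0.02, 0.03), "holm")$adjusted   # 0.03 0.04 0.04
adjust_pvalues <- function(raw, method = c("bonferroni", "sidak", "holm",
                                           "hochberg", "hommel", "bh", "by")) {
  method <- match.arg(method)
  if (any(is.na(raw)) || any(raw <= 0 | raw > 1))
    stop("raw p-values must lie in (0, 1]")
  m <- length(raw)
  o <- order(raw); ps <- raw[o]
  unsort <- function(a) { out <- numeric(m); out[o] <- pmin(a, 1); out }
  adjusted <- switch(method,
    bonferroni = pmin(1, m * raw),
    sidak = 1 - (1 - raw)^m,
    holm = unsort(cummax((m - seq_len(m) + 1) * ps)),
    hochberg = unsort(rev(cummin(rev((m - seq_len(m) + 1) * ps)))),
    hommel = unsort(hommel_adjust_sorted(ps)),
    bh = unsort(rev(cummin(rev(m / seq_len(m) * ps)))),
    by = unsort(rev(cummin(rev(sum(1 / seq_len(m)) * m / seq_len(m) * ps))))
  )
  structure(list(method = method, raw = raw, adjusted = adjusted),
            class = "corrected_pvalues")
}

# Wright's (1992) quadratic-time algorithm for Hommel-adjusted p-values,
# applied to sorted input.
hommel_adjust_sorted <- function(ps) {
  m <- length(ps)
  if (m == 1) return(ps)
  a <- pmax(ps, min(m * ps / seq_len(m)))
  if (m >= 3) {
    for (j in (m - 1):2) {
      tail_idx <- (m - j + 2):m
      cj <- min(j * ps[tail_idx] / (2:j))
      head_idx <- seq_len(m - j + 1)
      a[head_idx] <- pmax(a[head_idx], pmin(j * ps[head_idx], cj))
      a[tail_idx] <- pmax(a[tail_idx], cj)
    }
  }
  a
}

#' Correction table across all seven methods
#'
#' @param raw Vector of raw p-values in `(0, 1]`.
#' @return Data.frame with the raw values and one adjusted column per method.
#' @export
correction_table <- function(raw) {
  methods <- c("bonferroni", "sidak", "holm", "hochberg", "hommel", "bh", "by")
  out <- data.frame(raw = raw)
  for (mth in methods) out[[mth]] <- adjust_pvalues(raw, mth)$adjusted
  out
}
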