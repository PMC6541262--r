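#' Maximal Information Coefficient
#'
#' The MIC of two real vectors: the maximum, over all grids of k columns by l
#' rows with `k * l < n^alpha`, of the normalized mutual information
#' `I(k, l) / log2(min(k, l))` of the induced discretization. The grid search
#' uses the equipartition/clump dynamic program with the clump budget factor
#' `c`, run in both axis orientations; the heuristic is deterministic.
#'
#' @param x,y Equal-length numeric vectors, `n >= 10`, neither constant.
#' @param alpha Exponent of the grid-size bound `B(n) = n^alpha`.
#' @param c Superclump budget factor: when optimizing an axis into at most k
#'   bins, up to `c * k` clumps are retained.
#' @return MIC in `[0, 1]`; symmetric in its arguments.
#' @export
#' @examples
#' x <- seq_len(50)
#' mic(x, x)   # 1: a bijective grid attains normalized MI 1
mic <- function(x, y, alpha = 0.6, c = 15) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 10) stop("need n >= 10")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("zero-variation input")
  mine_mic_cpp(as.numeric(x), as.numeric(y), alpha, c)
}

#' Distance correlation
#'
#' Szekely-Rizzo distance correlation of two real vectors from double-centred
#' absolute-difference matrices: `dCor = dCov / sqrt(dVar_x * dVar_y)`. The
#' population value is zero exactly under independence; the statistic is
#' invariant to shifts and positive rescalings of either input, and equals 1
#' when `y` is an affine image of `x`.
#'
#' @param x,y Equal-length numeric vectors, `n >= 4`.
#' @return Value in `[0, 1]`; 0 (with a `degenerate` attribute) when either
#'   input is constant.
#' @export
#' @examples
#' distance_correlation(1:20, 3 * (1:20) + 7)   # 1
distance_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4) stop("need n >= 4")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  dc <- function(v) {
    d <- abs(outer(v, v, "-"))
    d - outer(rowMeans(d), rep(1, n)) - outer(rep(1, n), colMeans(d)) + mean(d)
  }
  a <- dc(as.numeric(x)); b <- dc(as.numeric(y))
  dcov2 <- mean(a * b)
  dvx <- mean(a * a); dvy <- mean(b * b)
  if (dvx == 0 || dvy == 0)
    return(structure(0, degenerate = TRUE))
  sqrt(max(dcov2, 0) / sqrt(dvx * dvy))
}

#' Heller-Heller-Gorfine dependence statistics
#'
#' For every ordered pair of points `(i, j)` the remaining `n - 2` points are
#' cross-classified into a 2x2 table by `dx(i, k) <= dx(i, j)` and
#' `dy(i, k) <= dy(i, j)`; Pearson chi-squared and likelihood-ratio (G)
#' statistics of those tables are accumulated (sum statistics) and tracked
#' (max statistics). Tables with an empty margin contribute zero.
#'
#' @param dx,dy Square symmetric distance matrices over the same points.
#' @return Named numeric vector `sum_chisq`, `sum_lr`, `max_chisq`, `max_lr`.
#' @export
hhg_statistics <- function(dx, dy) {
  dx <- as.matrix(dx); dy <- as.matrix(dy)
  if (!isSymmetric(unname(dx)) || !isSymmetric(unname(dy)))
    stop("distance matrices must be symmetric")
  if (!all(dim(dx) == dim(dy))) stop("matrices must have equal size")
  if (nrow(dx) < 5) stop("need n >= 5")
  res <- hhg_engine_cpp(dx, dy, matrix(integer(0), nrow = nrow(dx), ncol = 0))
  stats::setNames(res$statistics, c("sum_chisq", "sum_lr", "max_chisq", "max_lr"))
}

#' HHG permutation test for two scalar variables
#'
#' Runs the HHG test on the absolute-difference (Euclidean, one-dimensional)
#' distances of two scalar vectors, with permutation p-values computed by the
#' add-one estimator `p = (1 + #{permuted >= observed}) / (1 + n_perm)`, so
#' the attainable floor is `1 / (n_perm + 1)`.
#'
#' @param x,y Equal-length numeric vectors.
#' @param n_perm Number of permutations (>= 99); 999 by default, giving a
#'   p-value floor of 0.001.
#' @param seed Integer seed for the permutation stream.
#' @return List with `statistics` (the four observed values) and `p_values`
#'   (named `pval_sc`, `pval_sl`, `pval_mc`, `pval_ml`).
#' @export
hhg_test <- function(x, y, n_perm = 999, seed = 1L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (n_perm < 99) stop("n_perm must be >= 99")
  n <- length(x)
  if (n < 5) stop("need n >= 5")
  dx <- abs(outer(as.numeric(x), as.numeric(x), "-"))
  dy <- abs(outer(as.numeric(y), as.numeric(y), "-"))
  sigmas <- with_seed(seed, function()
    vapply(seq_len(n_perm), function(i) sample.int(n), integer(n)))
  res <- hhg_engine_cpp(dx, dy, sigmas)
  list(
    statistics = stats::setNames(res$statistics,
                                 c("sum_chisq", "sum_lr", "max_chisq", "max_lr")),
    p_values = stats::setNames((1 + res$n_geq) / (1 + n_perm),
                               c("pval_sc", "pval_sl", "pval_mc", "pval_ml"))
  )
}

#' Dependence screen of the pairwise design
#'
#' Stage-5 analysis: the Hamming dissimilarity vector is tested against each
#' transformed variable of the pairwise table — geographic distance, the 21
#' absolute covariate differences, and finally against itself (the
#' self-comparison row is retained, making 23 comparisons) — with MIC, dCor
#' and the four HHG permutation p-values per row.
#'
#' @param pairs A pairwise table from [build_pairwise_table()].
#' @param n_perm Permutations per HHG test (999 by default).
#' @param seed Integer seed; one stream drives all rows in order.
#' @param mic_alpha,mic_c MIC parameters.
#' @return Data.frame with one row per comparison: `variable`, `mic`, `dcor`,
#'   `pval_sc`, `pval_sl`, `pval_mc`, `pval_ml`. The self row is labelled
#'   `"hamming"` and comes last.
#' @export
dependence_screen <- function(pairs, n_perm = 999, seed = 1L,
                              mic_alpha = 0.6, mic_c = 15) {
  regs <- pairwise_regressors(pairs)
  ham <- pairs$hamming
  cols <- c(regs, "hamming")
  seeds <- with_seed(seed, function()
    sample.int(.Machine$integer.max, length(cols)))
  rows <- lapply(seq_along(cols), function(k) {
    v <- cols[k]
    x <- pairs[[v]]
    ht <- hhg_test(ham, x, n_perm = n_perm, seed = seeds[k])
    data.frame(variable = v,
               mic = mic(ham, x, alpha = mic_alpha, c = mic_c),
               dcor = as.numeric(distance_correlation(ham, x)),
               pval_sc = ht$p_values[["pval_sc"]],
               pval_sl = ht$p_values[["pval_sl"]],
               pval_mc = ht$p_values[["pval_mc"]],
               pval_ml = ht$p_values[["pval_ml"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Corrected p-value tables for the dependence screen
#'
#' Applies Bonferroni, Holm and Hochberg corrections to each of the four HHG
#' p-value families of a screen (one table per family, self row included in
#' the correction family).
#'
#' @param screen Output of [dependence_screen()].
#' @return Named list of four data.frames (`pval_sc`, `pval_sl`, `pval_mc`,
#'   `pval_ml`), each with `variable`, `raw`, `bonferroni`, `holm`,
#'   `hochberg`.
#' @export
dependence_corrections <- function(screen) {
  fams <- c("pval_sc", "pval_sl", "pval_mc", "pval_ml")
  out <- lapply(fams, function(f) {
    raw <- screen[[f]]
    data.frame(variable = screen$variable, raw = raw,
               bonferroni = adjust_pvalues(raw, "bonferroni")$adjusted,
               holm = adjust_pvalues(raw, "holm")$adjusted,
               hochberg = adjust_pvalues(raw, "hochberg")$adjusted,
               stringsAsFactors = FALSE)
  })
  stats::setNames(out, fams)
}
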