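# Independent brute-force oracles used to validate the package's own
# implementations. These deliberately share no code with the package.

# HHG statistics by literal quadruple loop over (i, j, k).
oracle_hhg <- function(dx, dy) {
  n <- nrow(dx); m <- n - 2
  sc <- sl <- mc <- ml <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a11 <- a12 <- a21 <- a22 <- 0
    for (k in seq_len(n)) {
      if (k == i || k == j) next
      cx <- dx[i, k] <= dx[i, j]
      cy <- dy[i, k] <= dy[i, j]
      if (cx && cy) a11 <- a11 + 1
      else if (cx) a12 <- a12 + 1
      else if (cy) a21 <- a21 + 1
      else a22 <- a22 + 1
    }
    r1 <- a11 + a12; r2 <- a21 + a22; c1 <- a11 + a21; c2 <- a12 + a22
    if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) next
    chi <- m * (a11 * a22 - a12 * a21)^2 / (r1 * r2 * c1 * c2)
    g <- 0
    for (o in c(a11, a12, a21, a22)) if (o > 0) g <- g + o * log(o)
    g <- 2 * (g - r1 * log(r1) - r2 * log(r2) - c1 * log(c1) - c2 * log(c2) +
              m * log(m))
    sc <- sc + chi; sl <- sl + g
    mc <- max(mc, chi); ml <- max(ml, g)
  }
  c(sum_chisq = sc, sum_lr = sl, max_chisq = mc, max_lr = ml)
}

# Distance correlation by literal double centering with explicit loops.
oracle_dcor <- function(x, y) {
  n <- length(x)
  a <- abs(outer(x, x, "-")); b <- abs(outer(y, y, "-"))
  A <- matrix(0, n, n); B <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    A[i, j] <- a[i, j] - mean(a[i, ]) - mean(a[, j]) + mean(a)
    B[i, j] <- b[i, j] - mean(b[i, ]) - mean(b[, j]) + mean(b)
  }
  dcov2 <- sum(A * B) / n^2
  dvx <- sum(A * A) / n^2; dvy <- sum(B * B) / n^2
  if (dvx == 0 || dvy == 0) return(0)
  sqrt(max(dcov2, 0) / sqrt(dvx * dvy))
}

# Exact two-sided WMW p-value by full enumeration of group labellings.
oracle_wmw_enum <- function(g1, g2) {
  n1 <- length(g1); pooled <- c(g1, g2); n <- length(pooled)
  u_of <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  obs <- u_of(seq_len(n1))
  mu <- n1 * (n - n1) / 2
  labelings <- utils::combn(n, n1)
  us <- apply(labelings, 2, u_of)
  min(1, mean(abs(us - mu) >= abs(obs - mu)))
}

# Exhaustive MIC for small inputs: maximize normalized MI over all grids whose
# cut points sit between distinct values, subject to k * l <= B(n).
oracle_mic_exhaustive <- function(x, y, alpha = 0.6) {
  n <- length(x)
  B <- max(n^alpha, 4)
  cuts_of <- function(v) sort(unique(v))[-1] - .Machine$double.eps
  all_partitions <- function(v, k) {
    cu <- cuts_of(v)
    if (k - 1 > length(cu)) return(list())
    combs <- utils::combn(length(cu), k - 1, simplify = FALSE)
    lapply(combs, function(ix) findInterval(v, cu[ix]) + 1)
  }
  best <- 0
  for (k in 2:floor(B / 2)) for (l in 2:floor(B / k)) {
    px <- all_partitions(x, k); py <- all_partitions(y, l)
    for (bx in px) for (by in py) {
      tab <- table(bx, by)
      pxy <- tab / n
      pr <- rowSums(pxy); pc <- colSums(pxy)
      mi <- 0
      for (i in seq_along(pr)) for (j in seq_along(pc))
        if (pxy[i, j] > 0)
          mi <- mi + pxy[i, j] * log2(pxy[i, j] / (pr[i] * pc[j]))
      val <- mi / log2(min(k, l))
      if (val > best) best <- val
    }
  }
  best
}

# The fixture joined with deterministic synthetic coordinates and covariates.
fixture_with_covariates <- function(seed = 2024) {
  fx <- sharing_fixture()
  syn <- generate_dataset(synthetic_config(n_societies = 22, regime = "null",
                                           seed = seed))
  attach_covariates(fx, syn$covariates,
                    latitude = syn$latitude, longitude = syn$longitude)
}

# Random practice datasets for property tests.
random_dataset <- function(n, seed) {
  generate_dataset(synthetic_config(n_societies = n, regime = "null",
                                    seed = seed))
}
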