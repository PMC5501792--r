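# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the implementation paths.

# Product-limit estimator computed directly from the definition.
km_oracle <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    n_i <- sum(time >= ts[i])
    d_i <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d_i / n_i)
    surv[i] <- s
  }
  list(times = ts, survival = surv)
}

# Two-group Mantel-Cox log-rank statistic assembled from the O/E/V sums
# over pooled event times (hypergeometric variance, simultaneous risk set).
logrank2_oracle <- function(time, event, group) {
  g <- as.integer(factor(group))
  O <- sum(event[g == 1])
  E <- 0
  V <- 0
  for (t0 in sort(unique(time[event == 1]))) {
    n_t <- sum(time >= t0)
    n1 <- sum(time >= t0 & g == 1)
    d_t <- sum(time == t0 & event == 1)
    E <- E + d_t * n1 / n_t
    if (n_t > 1)
      V <- V + d_t * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d_t) / (n_t - 1)
  }
  list(statistic = (O - E)^2 / V, observed1 = O, expected1 = E, variance = V)
}

# Exhaustive minimum of the k-means objective over all 2-partitions with
# both sides nonempty (feasible for n <= 12 or so).
kmeans2_enumeration_oracle <- function(U) {
  n <- nrow(U)
  best <- Inf
  for (code in seq_len(2^(n - 1) - 1)) {
    side <- as.logical(bitwAnd(code, 2^(seq_len(n) - 1)))
    for (part in list(side)) {
      a <- U[part, , drop = FALSE]
      b <- U[!part, , drop = FALSE]
      obj <- sum(sweep(a, 2, colMeans(a))^2) + sum(sweep(b, 2, colMeans(b))^2)
      if (obj < best) best <- obj
    }
  }
  best
}

# Dense evaluation of the approximate degree vector: assemble the full
# Nystrom-reconstructed similarity and take row sums.
degrees_dense_oracle <- function(A, B) {
  AinvB <- solve(A, B)
  Stilde <- rbind(cbind(A, B), cbind(t(B), crossprod(B, AinvB)))
  rowSums(Stilde)
}

# Gaussian kernel by an explicit double loop (no linear algebra shortcuts).
gaussian_bruteforce_oracle <- function(x, sigma) {
  n <- ncol(x)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j)
      S[i, j] <- exp(-sum((x[, i] - x[, j])^2) / (2 * sigma^2))
  }
  S
}

# ARI from an explicitly expanded pair-counting definition.
ari_pairs_oracle <- function(a, b) {
  n <- length(a)
  s00 <- s01 <- s10 <- s11 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]
    sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (sa && !sb) s10 <- s10 + 1
    else if (!sa && sb) s01 <- s01 + 1
    else s00 <- s00 + 1
  }
  np <- s11 + s10 + s01 + s00
  expected <- (s11 + s10) * (s11 + s01) / np
  maxi <- ((s11 + s10) + (s11 + s01)) / 2
  if (maxi == expected) return(1)
  (s11 - expected) / (maxi - expected)
}
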