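# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (explicit loops, textbook formulas) so that they stay
# independent of the implementation paths they check.

# Brute-force Passing-Bablok: enumerate all pairwise slopes, apply the
# shifted-median rule and the rank-based CI directly.
pb_oracle <- function(x, y, conf.level = 0.95) {
  n <- length(x)
  slopes <- c()
  K <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]
      dy <- y[j] - y[i]
      if (dx == 0 && dy == 0) next
      s <- if (dx == 0) ifelse(dy > 0, Inf, -Inf) else dy / dx
      if (identical(s, -1)) next
      if (s < -1) K <- K + 1
      slopes <- c(slopes, s)
    }
  }
  slopes <- sort(slopes)
  N <- length(slopes)
  pick <- function(idx) slopes[min(max(idx, 1), N)]
  b <- if (N %% 2 == 1) pick((N + 1) / 2 + K) else
    (pick(N / 2 + K) + pick(N / 2 + 1 + K)) / 2
  w <- qnorm(1 - (1 - conf.level) / 2) *
    sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- max(1, round((N - w) / 2))
  M2 <- N - M1 + 1
  lo <- pick(M1 + K)
  hi <- pick(M2 + K)
  a <- median(y - b * x)
  list(slope = b, slope.ci = c(lo, hi),
       intercept = a,
       intercept.ci = c(median(y - hi * x), median(y - lo * x)))
}

# Permutation oracle for the cusum linearity statistic: under linearity the
# score sequence is exchangeable with respect to the ordering.
cusum_perm_p <- function(data, fit, n_perm = 2000) {
  resid <- data$y - (fit$intercept + fit$slope * data$x)
  side <- sign(resid)
  na <- sum(side > 0)
  nb <- sum(side < 0)
  sc <- ifelse(side > 0, sqrt(nb / na), ifelse(side < 0, -sqrt(na / nb), 0))
  obs <- cusum_linearity(data, fit)$statistic
  perm <- replicate(n_perm, max(abs(cumsum(sample(sc)))) / sqrt(na + nb))
  mean(perm >= obs)
}

# random paired dataset with optional ties in x
random_pairs <- function(n, tie_prob = 0, unit = "ifcc") {
  x <- round(runif(n, 30, 73), ifelse(runif(n) < tie_prob, 0, 3))
  y <- round(x * runif(1, 0.8, 1.2) + runif(1, -3, 3) + rnorm(n, 0, 1.5), 3)
  y[y <= 0] <- 0.1
  paired_dataset(x, y, unit = unit)
}
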