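#' Nonparametric percentile with an exact binomial confidence interval
#'
#' Point estimate by Hazen order-statistic interpolation (rank
#' `h = p/100 * n + 0.5`, linear interpolation between the bracketing order
#' statistics). The confidence interval endpoints are the order statistics
#' whose cumulative binomial coverage first reaches the requested level:
#' with `q = p/100`, the lower rank is the largest `l` with
#' `P(Bin(n, q) <= l - 1) <= (1 - conf)/2` and the upper rank the smallest
#' `u` with `P(Bin(n, q) <= u - 1) >= 1 - (1 - conf)/2`, so that
#' `P(X_(l) <= xi_q <= X_(u)) >= conf` up to the discreteness of the
#' binomial. Ranks are clamped to the sample, so for extreme percentiles at
#' small n the interval may be truncated at the sample minimum or maximum.
#'
#' @param values numeric vector, `n >= 2`.
#' @param p percentile in (0, 100).
#' @param conf.level confidence level for the interval.
#' @return list with `estimate`, `ci` (length-2, `NA` when `n < 20`),
#'   `ranks` (the order-statistic ranks used) and `coverage` (the attained
#'   binomial coverage, `NA` when `n < 20`).
#' @examples
#' percentile_ci(1:100, 50)$estimate  # 50.5
#' @export
percentile_ci <- function(values, p, conf.level = 0.95) {
  values <- check_numeric(values, "values")
  n <- length(values)
  if (n < 2) stop("percentile needs n >= 2", call. = FALSE)
  if (p <= 0 || p >= 100) stop("`p` must be in (0, 100)", call. = FALSE)
  sorted <- sort(values)
  q <- p / 100
  # Hazen rule: rank h = qn + 0.5 (quantile type 5)
  h <- q * n + 0.5
  lo_i <- max(1, min(n, floor(h)))
  hi_i <- max(1, min(n, ceiling(h)))
  frac <- h - floor(h)
  estimate <- if (lo_i == hi_i || h <= 1 || h >= n) {
    sorted[max(1, min(n, round(h)))]
  } else {
    (1 - frac) * sorted[lo_i] + frac * sorted[hi_i]
  }
  if (n < 20) {
    return(list(estimate = estimate, ci = c(NA_real_, NA_real_),
                ranks = c(NA_integer_, NA_integer_), coverage = NA_real_))
  }
  alpha <- 1 - conf.level
  # largest l with P(Bin <= l-1) <= alpha/2; qbinom gives smallest m with
  # P(Bin <= m) >= alpha/2, so start there and step down if needed
  l <- qbinom(alpha / 2, n, q)
  while (l >= 1 && pbinom(l - 1, n, q) > alpha / 2) l <- l - 1
  l <- max(1L, as.integer(l))
  u <- as.integer(qbinom(1 - alpha / 2, n, q)) + 1L
  while (u > 1 && pbinom(u - 2, n, q) >= 1 - alpha / 2) u <- u - 1
  u <- min(as.integer(n), max(u, l))
  coverage <- pbinom(u - 1, n, q) - pbinom(l - 1, n, q)
  list(estimate = estimate, ci = c(sorted[l], sorted[u]),
       ranks = c(l, u), coverage = coverage)
}

#' Bland-Altman difference analysis with ATE adjudication
#'
#' Computes the distribution of the paired differences (candidate minus
#' comparative): the mean bias with a t-based confidence interval, and the
#' nonparametric 2.5th and 97.5th percentile limits of agreement with exact
#' binomial order-statistic confidence intervals (see [percentile_ci()]).
#' Each percentile point estimate is compared with the corresponding
#' allowable-total-error bound: the method passes a bound when the
#' percentile lies within it. A CI-based verdict (requiring the whole
#' percentile interval inside the band) is reported alongside as
#' informational. An ordinary least-squares regression of the differences
#' on the comparative values is included to flag proportional bias.
#'
#' @param data a [paired_dataset()]; differences are `y - x`.
#' @param ate an [ate_limits()] object (defaults to the conventional
#'   +/-5 mmol/mol / +/-0.46 % band for the dataset's unit).
#' @param conf.level confidence level for all intervals.
#' @return an object of class `bland_altman`: list with `bias`, `bias.ci`,
#'   `lower` and `upper` (each a [percentile_ci()] result), `ate`,
#'   `verdict` (per-bound `"passed"`/`"failed"`), `verdict.ci`,
#'   `slope.diff` (OLS slope of differences vs comparative, with CI), `n`.
#' @examples
#' d <- simulate_comparison(n = 60, intercept = -1, seed = 1)
#' bland_altman(d)
#' @export
bland_altman <- function(data, ate = default_ate(data$unit),
                         conf.level = 0.95) {
  stopifnot(inherits(data, "paired_dataset"), inherits(ate, "ate_limits"))
  if (ate$unit != data$unit) {
    stop("ATE limits and dataset use different unit systems", call. = FALSE)
  }
  d <- paired_differences(data)
  n <- length(d)
  bias <- mean(d)
  se <- sd(d) / sqrt(n)
  tq <- qt(1 - (1 - conf.level) / 2, n - 1)
  bias_ci <- c(bias - tq * se, bias + tq * se)
  if (n < 20) {
    warning("n < 20: percentile confidence intervals unavailable",
            call. = FALSE)
  }
  lower <- percentile_ci(d, 2.5, conf.level)
  upper <- percentile_ci(d, 97.5, conf.level)
  verdict <- c(
    lower = if (lower$estimate >= -ate$half_width) "passed" else "failed",
    upper = if (upper$estimate <= ate$half_width) "passed" else "failed"
  )
  verdict_ci <- c(
    lower = if (!anyNA(lower$ci) && lower$ci[1] >= -ate$half_width)
      "passed" else "failed",
    upper = if (!anyNA(upper$ci) && upper$ci[2] <= ate$half_width)
      "passed" else "failed"
  )
  # OLS of differences on comparative values flags proportional bias
  # (slope CI computed directly so zero-residual edge cases stay exact)
  fit <- lm(d ~ x, data = data.frame(x = data$x, d = d))
  b1 <- unname(coef(fit)[2])
  sxx <- sum((data$x - mean(data$x))^2)
  se_b <- sqrt(sum(residuals(fit)^2) / (n - 2) / sxx)
  slope_ci <- b1 + c(-1, 1) * qt(1 - (1 - conf.level) / 2, n - 2) * se_b
  slope_p <- if (se_b == 0) NA_real_ else 2 * pt(-abs(b1 / se_b), n - 2)
  structure(
    list(bias = bias, bias.ci = bias_ci, lower = lower, upper = upper,
         ate = ate, verdict = verdict, verdict.ci = verdict_ci,
         slope.diff = list(slope = b1, ci = slope_ci, p.value = slope_p),
         n = n, conf.level = conf.level, unit = data$unit),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  u <- unit_label(x$unit)
  cat("Bland-Altman analysis (n = ", x$n, ", candidate - comparative, ",
      u, ")\n", sep = "")
  cat(sprintf("  bias: %.3f (%.3f to %.3f)\n",
              x$bias, x$bias.ci[1], x$bias.ci[2]))
  cat(sprintf("  P2.5:  %.3f (%.3f to %.3f) vs ATE %.3f [%s]\n",
              x$lower$estimate, x$lower$ci[1], x$lower$ci[2],
              -x$ate$half_width, x$verdict["lower"]))
  cat(sprintf("  P97.5: %.3f (%.3f to %.3f) vs ATE %.3f [%s]\n",
              x$upper$estimate, x$upper$ci[1], x$upper$ci[2],
              x$ate$half_width, x$verdict["upper"]))
  invisible(x)
}

#' Lin's concordance correlation coefficient
#'
#' `rho_c = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with
#' population (1/n) moment estimators. The coefficient factors into
#' precision (Pearson's rho) and accuracy (`C_b = rho_c / rho`, the bias
#' correction factor measuring how far the best-fit line deviates from the
#' identity line). The confidence interval applies the Fisher z transform
#' to `rho_c` with Lin's asymptotic variance and back-transforms.
#'
#' Agreement strength is banded on `rho_c`: below 0.90 poor, 0.90-0.95
#' moderate, 0.95-0.99 substantial, above 0.99 nearly perfect.
#'
#' @param data a [paired_dataset()] with `n >= 4` and non-constant series.
#' @param conf.level confidence level for the interval.
#' @return an object of class `ccc`: list with `rho` (Pearson), `c_b`,
#'   `rho_c`, `rho_c.ci`, `strength`, `n`.
#' @references Lin LI. A concordance correlation coefficient to evaluate
#'   reproducibility. Biometrics 1989;45:255-68.
#' @export
lin_ccc <- function(data, conf.level = 0.95) {
  stopifnot(inherits(data, "paired_dataset"))
  n <- data$n
  if (n < 4) stop("concordance coefficient needs n >= 4", call. = FALSE)
  x <- data$x
  y <- data$y
  sx2 <- mean((x - mean(x))^2)
  sy2 <- mean((y - mean(y))^2)
  if (sx2 == 0 || sy2 == 0) {
    stop("constant series: concordance undefined", call. = FALSE)
  }
  sxy <- mean((x - mean(x)) * (y - mean(y)))
  dm <- mean(x) - mean(y)
  rho_c <- 2 * sxy / (sx2 + sy2 + dm^2)
  rho <- sxy / sqrt(sx2 * sy2)
  c_b <- rho_c / rho
  # Lin's asymptotic variance of the z-transformed rho_c
  u <- dm / (sx2 * sy2)^0.25
  sz2 <- ((1 - rho^2) * rho_c^2 / ((1 - rho_c^2) * rho^2) +
            2 * rho_c^3 * (1 - rho_c) * u^2 / (rho * (1 - rho_c^2)^2) -
            rho_c^4 * u^4 / (2 * rho^2 * (1 - rho_c^2)^2)) / (n - 2)
  z <- atanh(min(max(rho_c, -1 + 1e-15), 1 - 1e-15))
  zq <- qnorm(1 - (1 - conf.level) / 2)
  ci <- tanh(z + c(-1, 1) * zq * sqrt(max(sz2, 0)))
  strength <- if (rho_c < 0.90) "poor" else if (rho_c < 0.95) "moderate"
    else if (rho_c <= 0.99) "substantial" else "nearly perfect"
  structure(
    list(rho = rho, c_b = c_b, rho_c = rho_c, rho_c.ci = ci,
         strength = strength, n = n, conf.level = conf.level),
    class = "ccc"
  )
}

#' @export
print.ccc <- function(x, ...) {
  cat("Lin's concordance correlation coefficient (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  Pearson rho = %.4f, C_b = %.4f\n", x$rho, x$c_b))
  cat(sprintf("  rho_c = %.4f (%.4f to %.4f) -> %s agreement\n",
              x$rho_c, x$rho_c.ci[1], x$rho_c.ci[2], x$strength))
  invisible(x)
}

#' Mountain-plot points (folded empirical percentiles)
#'
#' For each sorted difference with empirical percentile
#' `p_i = 100 (i - 0.5) / n` the folded value is `min(p_i, 100 - p_i)`.
#' Plotting folded percentile against difference gives a "mountain" peaking
#' at the median: a peak off zero reveals bias, asymmetric slopes reveal
#' skew, long flanks reveal heavy tails.
#'
#' @param differences numeric vector of paired differences, `n >= 2`.
#' @return a data.frame with columns `difference` and `folded_percentile`
#'   (values in (0, 50]), sorted by difference.
#' @export
mountain_plot_points <- function(differences) {
  d <- check_numeric(differences, "differences")
  n <- length(d)
  if (n < 2) stop("mountain plot needs n >= 2", call. = FALSE)
  sorted <- sort(d)
  p <- 100 * (seq_len(n) - 0.5) / n
  data.frame(difference = sorted, folded_percentile = pmin(p, 100 - p))
}
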