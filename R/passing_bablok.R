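#' Passing-Bablok regression
#'
#' Rank-based linear regression for method comparison, robust to measurement
#' error in both variables. The slope is the shifted median of all pairwise
#' slopes S_ij = (y_j - y_i)/(x_j - x_i), i < j: slopes equal to -1 are
#' excluded and the median index is offset by K, the number of slopes below
#' -1, so that the estimator is invariant to exchanging the axes. The slope
#' confidence interval comes from the rank statistics at
#' `M1 = round((N - w)/2)` and `M2 = N - M1 + 1` (each offset by K), with
#' `w = z * sqrt(n (n-1) (2n+5) / 18)`. The intercept is
#' `median(y - slope * x)`; its CI bounds re-use the slope CI bounds
#' (the upper slope bound gives the lower intercept bound and vice versa).
#'
#' Ties in x with differing y contribute signed infinite slopes ordered
#' above/below all finite slopes; identical points contribute nothing.
#' On noise-free collinear data all pairwise slopes coincide, so the
#' estimate equals the generating line and the CI has zero width.
#'
#' @param data a [paired_dataset()] with at least 3 pairs and non-constant x.
#' @param conf.level confidence level for the slope/intercept intervals.
#' @return an object of class `pb_fit`: list with `slope`, `slope.ci`,
#'   `intercept`, `intercept.ci`, `n`, `conf.level`, `unit`.
#' @examples
#' d <- paired_dataset(c(1, 2, 3), c(3, 5, 7), unit = "ngsp")
#' passing_bablok(d)  # slope 2, intercept 1
#' @references Passing H, Bablok W. A new biometrical procedure for testing
#'   the equality of measurements from two different analytical methods.
#'   J Clin Chem Clin Biochem 1983;21:709-20.
#' @export
passing_bablok <- function(data, conf.level = 0.95) {
  stopifnot(inherits(data, "paired_dataset"))
  if (data$n < 3) stop("Passing-Bablok regression needs n >= 3", call. = FALSE)
  if (length(unique(data$x)) == 1) {
    stop("degenerate input: all comparative values identical", call. = FALSE)
  }
  zq <- qnorm(1 - (1 - conf.level) / 2)
  fit <- .pb_fit_cpp(data$x, data$y, zq)
  if (!is.finite(fit$slope)) {
    stop("degenerate input: no usable pairwise slopes", call. = FALSE)
  }
  intercept <- median(data$y - fit$slope * data$x)
  int_lo <- median(data$y - fit$slope_hi * data$x)
  int_hi <- median(data$y - fit$slope_lo * data$x)
  structure(
    list(
      slope = fit$slope,
      slope.ci = c(fit$slope_lo, fit$slope_hi),
      intercept = intercept,
      intercept.ci = c(int_lo, int_hi),
      n = data$n,
      n_slopes = fit$N,
      conf.level = conf.level,
      unit = data$unit
    ),
    class = "pb_fit"
  )
}

#' @export
print.pb_fit <- function(x, ...) {
  cat("Passing-Bablok regression (n = ", x$n, ", ",
      round(100 * x$conf.level), "% CI)\n", sep = "")
  cat(sprintf("  slope:     %.4f (%.4f to %.4f)\n",
              x$slope, x$slope.ci[1], x$slope.ci[2]))
  cat(sprintf("  intercept: %.4f (%.4f to %.4f) %s\n",
              x$intercept, x$intercept.ci[1], x$intercept.ci[2],
              unit_label(x$unit)))
  if (!is.null(x$cusum.p)) {
    cat(sprintf("  Cusum linearity p = %.3f\n", x$cusum.p))
  }
  if (!is.null(x$spearman)) {
    cat(sprintf("  Spearman rho = %.3f (%.3f to %.3f)\n",
                x$spearman$rho, x$spearman$ci[1], x$spearman$ci[2]))
  }
  invisible(x)
}

#' Predict candidate-method values from a Passing-Bablok fit
#'
#' @param object a `pb_fit`.
#' @param newdata numeric vector of comparative-method values.
#' @param ... unused.
#' @return predicted candidate values `intercept + slope * newdata`.
#' @export
predict.pb_fit <- function(object, newdata, ...) {
  object$intercept + object$slope * check_numeric(newdata, "newdata")
}

#' Cusum test for linearity of a Passing-Bablok fit
#'
#' Scores each point by its side of the fitted line (+sqrt(n_below/n_above)
#' if above, -sqrt(n_above/n_below) if below, 0 on the line), orders the
#' points by ascending projection onto the fitted line (key `x + y/slope`,
#' ties broken by x then by index), and takes the maximum absolute
#' cumulative score scaled by `sqrt(n_above + n_below)` as the test
#' statistic. The p-value uses the Kolmogorov-Smirnov asymptotic
#' distribution `p = 2 * sum_k (-1)^(k-1) exp(-2 k^2 lambda^2)`.
#'
#' A small p-value indicates systematic curvature: the linearity assumption
#' of the Passing-Bablok model is then untenable.
#'
#' @param data the [paired_dataset()] the fit was computed on.
#' @param fit the corresponding [passing_bablok()] fit.
#' @return a list with `statistic` (lambda) and `p.value`.
#' @export
cusum_linearity <- function(data, fit) {
  stopifnot(inherits(data, "paired_dataset"), inherits(fit, "pb_fit"))
  if (length(data$x) != fit$n) {
    stop("`fit` was not computed on `data`", call. = FALSE)
  }
  resid <- data$y - (fit$intercept + fit$slope * data$x)
  # guard against floating noise classifying on-line points as off-line
  tol <- 1e-10 * max(1, max(abs(data$y)))
  side <- ifelse(resid > tol, 1L, ifelse(resid < -tol, -1L, 0L))
  n_above <- sum(side == 1L)
  n_below <- sum(side == -1L)
  if (n_above == 0 || n_below == 0) {
    return(list(statistic = 0, p.value = 1))
  }
  score <- numeric(length(resid))
  score[side == 1L] <- sqrt(n_below / n_above)
  score[side == -1L] <- -sqrt(n_above / n_below)
  key <- if (fit$slope != 0) data$x + data$y / fit$slope else data$x
  ord <- order(key, data$x, seq_along(key))
  cum <- cumsum(score[ord])
  lambda <- max(abs(cum)) / sqrt(n_above + n_below)
  list(statistic = lambda, p.value = ks_pvalue(lambda))
}

# Asymptotic Kolmogorov distribution tail: 2 * sum (-1)^(k-1) exp(-2 k^2 l^2)
ks_pvalue <- function(lambda) {
  if (lambda < 0.05) return(1)
  k <- seq_len(101)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Spearman rank correlation with a Fisher-z confidence interval
#'
#' Spearman's rho with average ranks for ties; the confidence interval uses
#' the Fisher z transform with standard error `1/sqrt(n - 3)`.
#'
#' @param data a [paired_dataset()] with at least 4 pairs.
#' @param conf.level confidence level for the interval.
#' @return a list with `rho`, `ci` (length-2), `n`, `conf.level`.
#' @export
spearman_ci <- function(data, conf.level = 0.95) {
  stopifnot(inherits(data, "paired_dataset"))
  if (data$n < 4) stop("Spearman CI needs n >= 4", call. = FALSE)
  if (length(unique(data$x)) == 1 || length(unique(data$y)) == 1) {
    stop("constant series: correlation undefined", call. = FALSE)
  }
  rho <- cor(data$x, data$y, method = "spearman")
  z <- atanh(min(max(rho, -1 + 1e-15), 1 - 1e-15))
  se <- 1 / sqrt(data$n - 3)
  zq <- qnorm(1 - (1 - conf.level) / 2)
  list(rho = rho, ci = tanh(c(z - zq * se, z + zq * se)),
       n = data$n, conf.level = conf.level)
}

#' Full method-comparison summary (regression table)
#'
#' Convenience wrapper producing the regression comparison record for a
#' paired dataset: medians and ranges of both methods, the Passing-Bablok
#' slope and intercept with confidence intervals, the Cusum linearity
#' p-value, and Spearman's rho with its interval.
#'
#' @param data a [paired_dataset()].
#' @param conf.level confidence level used throughout.
#' @return a `pb_fit` augmented with `cusum.p`, `spearman`, and summary
#'   statistics `median.x`, `median.y`, `range.x`, `range.y`.
#' @export
compare_methods <- function(data, conf.level = 0.95) {
  fit <- passing_bablok(data, conf.level = conf.level)
  fit$cusum.p <- cusum_linearity(data, fit)$p.value
  fit$spearman <- spearman_ci(data, conf.level = conf.level)
  fit$median.x <- median(data$x)
  fit$median.y <- median(data$y)
  fit$range.x <- range(data$x)
  fit$range.y <- range(data$y)
  fit
}
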