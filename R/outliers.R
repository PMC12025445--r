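#' Outlier screens and normality check for method-comparison differences
#'
#' Pre-screening applied to the paired differences before regression and
#' agreement analysis. Three complementary screens are provided:
#' `tukey_outliers()` flags values outside `[Q1 - k*IQR, Q3 + k*IQR]`;
#' `grubbs_test()` tests the single most extreme value with the two-sided
#' Grubbs statistic `G = max|v - mean|/sd` against its t-based critical
#' value; `gesd_test()` iterates the extreme studentised deviate up to
#' `max_k` candidates with per-step critical values, which keeps its power
#' in the presence of masking. `normality_test()` is the Shapiro-Wilk test.
#'
#' The screens report; they never remove points. Removal is an explicit
#' caller decision.
#'
#' @param values numeric vector to screen.
#' @param k Tukey fence multiplier (1.5 by convention).
#' @param alpha significance level for Grubbs/gESD.
#' @param max_k maximum number of outliers the gESD screen may declare.
#' @return an object of class `outlier_report`: list with `method`,
#'   `flagged` (integer indices into `values`), `statistics` and auxiliary
#'   fields.
#' @examples
#' tukey_outliers(c(1, 2, 3, 4, 100))$flagged  # 5
#' @export
tukey_outliers <- function(values, k = 1.5) {
  values <- check_numeric(values, "values")
  if (length(values) < 4) stop("Tukey screen needs n >= 4", call. = FALSE)
  q <- quantile(values, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  fence <- c(q[1] - k * iqr, q[2] + k * iqr)
  flagged <- which(values < fence[1] | values > fence[2])
  structure(list(method = "tukey", flagged = flagged, statistics = values,
                 fence = fence),
            class = "outlier_report")
}

#' @rdname tukey_outliers
#' @export
grubbs_test <- function(values, alpha = 0.05) {
  values <- check_numeric(values, "values")
  n <- length(values)
  if (n < 3) stop("Grubbs test needs n >= 3", call. = FALSE)
  s <- sd(values)
  if (s == 0) {
    return(structure(list(method = "grubbs", flagged = integer(0),
                          statistics = rep(0, n), G = 0, critical = NA_real_),
                     class = "outlier_report"))
  }
  dev <- abs(values - mean(values)) / s
  G <- max(dev)
  idx <- which.max(dev)
  crit <- grubbs_critical(n, alpha)
  flagged <- if (G > crit) idx else integer(0)
  structure(list(method = "grubbs", flagged = flagged, statistics = dev,
                 G = G, critical = crit),
            class = "outlier_report")
}

# two-sided Grubbs critical value at level alpha
grubbs_critical <- function(n, alpha) {
  t <- qt(1 - alpha / (2 * n), n - 2)
  (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

#' @rdname tukey_outliers
#' @export
gesd_test <- function(values, max_k, alpha = 0.05) {
  values <- check_numeric(values, "values")
  n <- length(values)
  if (n < 3) stop("generalised ESD needs n >= 3", call. = FALSE)
  if (max_k < 1 || max_k > n - 2) {
    stop("`max_k` must be in [1, n - 2]", call. = FALSE)
  }
  remaining <- seq_len(n)
  R <- lambda <- numeric(max_k)
  removed <- integer(max_k)
  for (i in seq_len(max_k)) {
    v <- values[remaining]
    s <- sd(v)
    if (s == 0) {
      R[i] <- 0
      removed[i] <- remaining[1]
    } else {
      dev <- abs(v - mean(v)) / s
      j <- which.max(dev)
      R[i] <- dev[j]
      removed[i] <- remaining[j]
    }
    ni <- length(remaining)
    t <- qt(1 - alpha / (2 * ni), ni - 2)
    lambda[i] <- (ni - 1) * t / sqrt((ni - 2 + t^2) * ni)
    remaining <- setdiff(remaining, removed[i])
  }
  n_out <- {
    hits <- which(R > lambda)
    if (length(hits) == 0) 0L else max(hits)
  }
  structure(list(method = "gesd", flagged = sort(removed[seq_len(n_out)]),
                 statistics = R, critical = lambda,
                 removal_order = removed),
            class = "outlier_report")
}

#' @rdname tukey_outliers
#' @export
normality_test <- function(values) {
  values <- check_numeric(values, "values")
  if (length(unique(values)) == 1) {
    stop("normality test undefined for constant values", call. = FALSE)
  }
  sw <- shapiro.test(values)
  list(statistic = unname(sw$statistic), p.value = sw$p.value)
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("Outlier screen (", x$method, "): ", sep = "")
  if (length(x$flagged) == 0) {
    cat("no outliers flagged\n")
  } else {
    cat("flagged indices", paste(x$flagged, collapse = ", "), "\n")
  }
  invisible(x)
}
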