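#' Bootstrap bias of the candidate method at medical decision limits
#'
#' Evaluates the full-data Passing-Bablok fit at each clinical decision
#' limit (`yhat = intercept + slope * limit`) and attaches percentile
#' bootstrap confidence intervals: each replicate resamples specimen pairs
#' with replacement, refits the regression, and re-evaluates the
#' predictions; the 2.5th/97.5th percentiles of the replicate predictions
#' form the interval. Replicates with degenerate resamples (all comparative
#' values equal) are redrawn with a capped retry count.
#'
#' Results are reproducible for a fixed `seed` within this implementation;
#' bit-compatibility with other software's RNG streams is not a goal.
#'
#' @param data a [paired_dataset()] with `n >= 20`.
#' @param limits a [decision_limits()] object, or a numeric vector taken to
#'   be in the dataset's units. Limits outside the observed comparative
#'   range trigger an extrapolation warning.
#' @param n_boot number of bootstrap replications (1000 by convention).
#' @param seed integer seed for the resampling stream (optional).
#' @param conf.level confidence level for the percentile intervals.
#' @return an object of class `decision_bias`: a data.frame with one row
#'   per limit and columns `limit`, `modeled`, `modeled_lo`, `modeled_hi`,
#'   `difference`, `difference_lo`, `difference_hi`, `relative_difference`
#'   (percent of the limit), `relative_lo`, `relative_hi`. Attributes
#'   `seed`, `n_boot`, `unit`.
#' @examples
#' d <- simulate_comparison(n = 178, intercept = -1, seed = 7)
#' bootstrap_decision_bias(d, c(39, 47, 53, 64), n_boot = 200, seed = 42)
#' @export
bootstrap_decision_bias <- function(data, limits, n_boot = 1000,
                                    seed = NULL, conf.level = 0.95) {
  stopifnot(inherits(data, "paired_dataset"))
  if (!inherits(limits, "decision_limits")) {
    limits <- decision_limits(limits, unit = data$unit)
  }
  if (limits$unit != data$unit) {
    stop("decision limits and dataset use different unit systems",
         call. = FALSE)
  }
  if (data$n < 20) {
    stop("bootstrap bias estimation needs n >= 20", call. = FALSE)
  }
  lim <- limits$limits
  if (any(lim < min(data$x)) || any(lim > max(data$x))) {
    warning("decision limit(s) outside the observed comparative range: ",
            "predictions are extrapolations", call. = FALSE)
  }
  fit <- passing_bablok(data, conf.level = conf.level)
  point <- predict(fit, lim)
  if (!is.null(seed)) set.seed(seed)
  reps <- .pb_boot_cpp(data$x, data$y, lim, as.integer(n_boot), 100L)
  alpha <- 1 - conf.level
  qs <- apply(reps, 2, quantile, probs = c(alpha / 2, 1 - alpha / 2),
              names = FALSE, type = 5)
  out <- data.frame(
    limit = lim,
    modeled = point,
    modeled_lo = qs[1, ],
    modeled_hi = qs[2, ],
    difference = point - lim,
    difference_lo = qs[1, ] - lim,
    difference_hi = qs[2, ] - lim
  )
  out$relative_difference <- 100 * out$difference / out$limit
  out$relative_lo <- 100 * out$difference_lo / out$limit
  out$relative_hi <- 100 * out$difference_hi / out$limit
  structure(out, class = c("decision_bias", "data.frame"),
            seed = seed, n_boot = n_boot, unit = data$unit,
            conf.level = conf.level)
}

#' @export
print.decision_bias <- function(x, ...) {
  cat("Bootstrap bias at decision limits (", attr(x, "n_boot"),
      " replications", sep = "")
  if (!is.null(attr(x, "seed"))) cat(", seed ", attr(x, "seed"), sep = "")
  cat(", ", unit_label(attr(x, "unit")), ")\n", sep = "")
  for (i in seq_len(nrow(x))) {
    cat(sprintf(
      "  %6.1f -> %.2f (%.2f to %.2f); diff %+.2f; rel %+.2f%% (%+.2f to %+.2f%%)\n",
      x$limit[i], x$modeled[i], x$modeled_lo[i], x$modeled_hi[i],
      x$difference[i], x$relative_difference[i], x$relative_lo[i],
      x$relative_hi[i]))
  }
  invisible(x)
}
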