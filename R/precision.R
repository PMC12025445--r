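#' Replicate precision design (level x day x replicate)
#'
#' Container for a single-level precision experiment: `values[d, r]` holds
#' replicate `r` measured within the single run of day `d`. The
#' conventional HbA1c protocol uses five replicates per run over five
#' consecutive days (a 5 x 5 design) at each concentration level.
#'
#' @param values numeric matrix, days in rows and replicates in columns;
#'   at least 2 x 2, complete, all values > 0.
#' @param level optional label for the concentration level.
#' @param unit `"ifcc"` or `"ngsp"`.
#' @return an object of class `replicate_design`.
#' @export
replicate_design <- function(values, level = "", unit = c("ifcc", "ngsp")) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (days x replicates)",
         call. = FALSE)
  }
  if (nrow(values) < 2 || ncol(values) < 2) {
    stop("design needs at least 2 days and 2 replicates", call. = FALSE)
  }
  if (anyNA(values)) {
    stop("incomplete designs are not supported: the nested analysis ",
         "assumes a balanced day x replicate table", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("all values must be finite and > 0", call. = FALSE)
  }
  structure(list(values = values, level = as.character(level)[1],
                 unit = unit_system(unit),
                 days = nrow(values), reps = ncol(values)),
            class = "replicate_design")
}

#' @export
print.replicate_design <- function(x, ...) {
  cat("Replicate precision design", if (nzchar(x$level))
    paste0(" '", x$level, "'") else "", ": ", x$days, " days x ", x$reps,
    " replicates, ", unit_label(x$unit), "\n", sep = "")
  cat("  grand mean", format(mean(x$values)), "\n")
  invisible(x)
}

#' Precision analysis by nested variance components
#'
#' One-way nested analysis of variance with day as the grouping factor,
#' the single-site form of the CLSI EP05-style precision experiment (one
#' run per day collapses run and day into a single between-day component):
#' `V_r = MS_within` (repeatability), `V_day = max(0,
#' (MS_between - MS_within)/R)` (between-day component, truncated at zero),
#' `V_wl = V_r + V_day` (within-laboratory). Coefficients of variation are
#' `100 * sqrt(V) / grand mean`, so `CV_wl^2 = CV_r^2 + CV_day^2` on the
#' variance scale by construction.
#'
#' @param design a [replicate_design()].
#' @return an object of class `precision_result`: list with `mean`, `cv_r`,
#'   `cv_day`, `cv_wl` (all percent), the variance components `v_r`,
#'   `v_day`, `v_wl`, the design dimensions, `level` and `unit`.
#' @examples
#' des <- simulate_precision(mean = 35, cv_r = 1.5, cv_day = 1.5, seed = 1)
#' ep05_precision(des)
#' @export
ep05_precision <- function(design) {
  stopifnot(inherits(design, "replicate_design"))
  vals <- design$values
  D <- nrow(vals)
  R <- ncol(vals)
  # one-way mean squares with day as grouping factor (computed directly so
  # zero-spread designs stay exact)
  day_means <- rowMeans(vals)
  grand <- mean(vals)
  ms_between <- R * sum((day_means - grand)^2) / (D - 1)
  ms_within <- sum((vals - day_means)^2) / (D * (R - 1))
  v_r <- ms_within
  v_day <- max(0, (ms_between - ms_within) / R)
  v_wl <- v_r + v_day
  gm <- mean(vals)
  structure(
    list(mean = gm,
         cv_r = 100 * sqrt(v_r) / gm,
         cv_day = 100 * sqrt(v_day) / gm,
         cv_wl = 100 * sqrt(v_wl) / gm,
         v_r = v_r, v_day = v_day, v_wl = v_wl,
         days = D, reps = R, level = design$level, unit = design$unit),
    class = "precision_result"
  )
}

#' @export
print.precision_result <- function(x, ...) {
  cat("Precision analysis", if (nzchar(x$level))
    paste0(" '", x$level, "'") else "", " (", x$days, " x ", x$reps,
    " design, ", unit_label(x$unit), ")\n", sep = "")
  cat(sprintf("  mean %.4g; CV_r %.2f%%; CV_day %.2f%%; CV_wl %.2f%%\n",
              x$mean, x$cv_r, x$cv_day, x$cv_wl))
  invisible(x)
}

#' Multi-level precision report
#'
#' Assembles per-level precision results into a report table and flags
#' each level against the within-laboratory performance criterion for
#' HbA1c (CV_wl below 2.5 %, per the IFCC working-group recommendation).
#'
#' @param results a list of [ep05_precision()] results (>= 1 level).
#' @param criterion within-laboratory CV threshold in percent.
#' @return an object of class `precision_report`: a data.frame with one
#'   row per level (`level`, `unit`, `mean`, `cv_r`, `cv_day`, `cv_wl`,
#'   `flag`), with the `criterion` as an attribute.
#' @export
precision_report <- function(results, criterion = 2.5) {
  if (inherits(results, "precision_result")) results <- list(results)
  if (length(results) == 0) stop("no precision results given", call. = FALSE)
  ok <- vapply(results, inherits, logical(1), what = "precision_result")
  if (!all(ok)) stop("`results` must be ep05_precision() outputs",
                     call. = FALSE)
  rows <- do.call(rbind, lapply(results, function(r) {
    data.frame(level = r$level, unit = r$unit, mean = r$mean,
               cv_r = r$cv_r, cv_day = r$cv_day, cv_wl = r$cv_wl,
               flag = if (r$cv_wl <= criterion) "within criterion"
                      else "exceeds criterion",
               stringsAsFactors = FALSE)
  }))
  structure(rows, class = c("precision_report", "data.frame"),
            criterion = criterion)
}

#' @export
print.precision_report <- function(x, ...) {
  cat("Precision report (criterion CV_wl <= ", attr(x, "criterion"),
      " %)\n", sep = "")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-8s %-5s mean %8.4g  CV_r %5.2f  CV_day %5.2f  CV_wl %5.2f  [%s]\n",
                x$level[i], x$unit[i], x$mean[i], x$cv_r[i], x$cv_day[i],
                x$cv_wl[i], x$flag[i]))
  }
  invisible(x)
}
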