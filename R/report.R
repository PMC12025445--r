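#' Full method-comparison validation run
#'
#' Executes the comparison stages in protocol order on a paired dataset:
#' outlier screens and normality on the differences (reported, never
#' applied), Passing-Bablok regression with the Cusum linearity test and
#' Spearman correlation, Bland-Altman agreement with ATE adjudication,
#' Lin's concordance coefficient, mountain-plot points, and bootstrap bias
#' at the medical decision limits.
#'
#' @param data a [paired_dataset()].
#' @param ate an [ate_limits()] object; defaults to the conventional band
#'   for the dataset's unit.
#' @param limits decision limits (numeric vector or [decision_limits()]);
#'   defaults to 39/47/53/64 mmol/mol or their NGSP equivalents
#'   5.7/6.4/7.0/8.0 %.
#' @param n_boot bootstrap replications for the decision-limit bias.
#' @param seed integer seed for the bootstrap stream.
#' @param conf.level confidence level used throughout.
#' @return an object of class `validation_report`: list with elements
#'   `metadata`, `screens`, `comparison`, `agreement`, `ccc`, `mountain`,
#'   `decision_bias`.
#' @examples
#' d <- simulate_comparison(n = 60, intercept = -1, seed = 3)
#' rep <- run_compare(d, n_boot = 200, seed = 1)
#' rep$comparison$slope
#' @export
run_compare <- function(data, ate = default_ate(data$unit), limits = NULL,
                        n_boot = 1000, seed = NULL, conf.level = 0.95) {
  stopifnot(inherits(data, "paired_dataset"))
  if (is.null(limits)) {
    limits <- if (data$unit == "ifcc") c(39, 47, 53, 64)
              else c(5.7, 6.4, 7.0, 8.0)
  }
  d <- paired_differences(data)
  screens <- list(
    tukey = tukey_outliers(d),
    grubbs = grubbs_test(d),
    gesd = gesd_test(d, max_k = max(1L, min(5L, data$n - 2L))),
    # constant differences (perfect agreement) leave normality undefined
    normality = tryCatch(normality_test(d), error = function(e) {
      list(statistic = NA_real_, p.value = NA_real_)
    })
  )
  comparison <- with_stage("method comparison",
                           compare_methods(data, conf.level = conf.level))
  agreement <- with_stage("agreement analysis",
                          bland_altman(data, ate, conf.level = conf.level))
  ccc <- with_stage("concordance", lin_ccc(data, conf.level = conf.level))
  mountain <- mountain_plot_points(d)
  bias_rows <- with_stage(
    "decision-limit bias",
    bootstrap_decision_bias(data, limits, n_boot = n_boot, seed = seed,
                            conf.level = conf.level)
  )
  structure(
    list(
      metadata = list(n = data$n, unit = data$unit, seed = seed,
                      n_boot = n_boot, conf.level = conf.level,
                      version = as.character(utils::packageVersion("hba1cval"))),
      screens = screens,
      comparison = comparison,
      agreement = agreement,
      ccc = ccc,
      mountain = mountain,
      decision_bias = bias_rows
    ),
    class = "validation_report"
  )
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' @export
print.validation_report <- function(x, ...) {
  cat("=== HbA1c method-validation report (n = ", x$metadata$n, ", ",
      unit_label(x$metadata$unit), ") ===\n\n", sep = "")
  n_flag <- length(unique(c(x$screens$tukey$flagged, x$screens$grubbs$flagged,
                            x$screens$gesd$flagged)))
  cat("Outlier screens: ", n_flag, " value(s) flagged; Shapiro-Wilk p = ",
      signif(x$screens$normality$p.value, 3), "\n\n", sep = "")
  print(x$comparison)
  cat("\n")
  print(x$agreement)
  cat("\n")
  print(x$ccc)
  cat("\n")
  print(x$decision_bias)
  invisible(x)
}

#' Serialize a result object as JSON
#'
#' Writes any of the package's result objects (validation report,
#' precision report, risk curve, ...) as JSON with full numeric precision
#' and embedded unit labels.
#'
#' @param x a result object.
#' @param path output path; `NULL` returns the JSON string.
#' @return `path` (invisibly), or the JSON string when `path` is `NULL`.
#' @export
report_json <- function(x, path = NULL) {
  payload <- strip_classes(x)
  if (is.null(path)) {
    return(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                            null = "null", na = "null"))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

strip_classes <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(unclass(x), strip_classes))
  x
}

#' Run the precision stage on one or more replicate designs
#'
#' @param designs a [replicate_design()] or list of them.
#' @param criterion within-laboratory CV criterion in percent.
#' @return a [precision_report()].
#' @export
run_precision <- function(designs, criterion = 2.5) {
  if (inherits(designs, "replicate_design")) designs <- list(designs)
  precision_report(lapply(designs, ep05_precision), criterion = criterion)
}

#' Run the misinterpretation-risk stage
#'
#' Evaluates the risk curves for a test with the given bias and
#' within-laboratory CV against the ideal test, and summarises the
#' probabilities at the decision limits (as percentages, one decimal).
#'
#' @param unit `"ifcc"` or `"ngsp"`.
#' @param bias analytical bias, dataset units.
#' @param cv_wl within-laboratory CV, percent.
#' @param grid optional grid of true values.
#' @param ... further arguments passed to [risk_params()].
#' @return a list with `params`, `curves` (a [risk_curves()] frame), and
#'   `summary` (probabilities at `R = U` falling below `L` and at `R = L`
#'   rising above `U`, for the test and the ideal test, in percent).
#' @export
run_risk <- function(unit = c("ifcc", "ngsp"), bias = 0, cv_wl = 0,
                     grid = NULL, ...) {
  params <- risk_params(unit, bias = bias, cv_wl = cv_wl, ...)
  ideal <- ideal_test(params)
  curves <- risk_curves(params, grid)
  summary <- list(
    underdx_at_U = 100 * prob_underdiagnosis(params$U, params),
    underdx_at_U_ideal = 100 * prob_underdiagnosis(params$U, ideal),
    overdx_at_L = 100 * prob_overdiagnosis(params$L, params),
    overdx_at_L_ideal = 100 * prob_overdiagnosis(params$L, ideal),
    individuality_index = individuality_index(params$bv_w, params$bv_b)$index
  )
  list(params = params, curves = curves, summary = summary)
}
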