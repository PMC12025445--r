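#' Parameters of the HbA1c misinterpretation-risk model
#'
#' The model treats a reported HbA1c value for a patient with true level
#' `R` as normally distributed with mean `R + B` (analytical bias `B`) and
#' a standard deviation combining, as percent coefficients of variation of
#' `R`, the within-laboratory analytical imprecision (`cv_wl`) and the
#' within- and between-subject biological variation (`bv_w`, `bv_b`).
#' Probabilities of crossing the clinical decision limits `L` (excluding
#' diabetes) and `U` (defining diabetes), or of exceeding the minimum
#' therapy-changing difference `delta` between two consecutive
#' measurements, are then read off the standard normal distribution.
#'
#' Defaults per unit system follow the conventional HbA1c figures:
#' IFCC `bv_w` 1.6 %, `bv_b` 7.1 %, `L` 39, `U` 47, `delta` 5 mmol/mol;
#' NGSP `bv_w` 1.2 %, `bv_b` 5.4 %, `L` 5.7, `U` 6.4, `delta` 0.46 %.
#' An "ideal test" sets `B = 0` and `cv_wl = 0`, leaving biological
#' variation only.
#'
#' @param unit `"ifcc"` or `"ngsp"`.
#' @param bias analytical bias `B`, absolute, in dataset units.
#' @param cv_wl within-laboratory CV, percent.
#' @param bv_w,bv_b within-/between-subject biological variation, percent.
#' @param L,U lower/upper decision limits, dataset units (`L < U`).
#' @param delta minimum therapy-changing difference, dataset units.
#' @return an object of class `risk_params`.
#' @examples
#' risk_params("ifcc", bias = -1, cv_wl = 2.1)
#' @export
risk_params <- function(unit = c("ifcc", "ngsp"), bias = 0, cv_wl = 0,
                        bv_w = NULL, bv_b = NULL, L = NULL, U = NULL,
                        delta = NULL) {
  unit <- unit_system(unit)
  defaults <- if (unit == "ifcc") {
    list(bv_w = 1.6, bv_b = 7.1, L = 39, U = 47, delta = 5)
  } else {
    list(bv_w = 1.2, bv_b = 5.4, L = 5.7, U = 6.4, delta = 0.46)
  }
  p <- list(
    unit = unit,
    bias = check_numeric(bias, "bias"),
    cv_wl = check_numeric(cv_wl, "cv_wl"),
    bv_w = if (is.null(bv_w)) defaults$bv_w else check_numeric(bv_w, "bv_w"),
    bv_b = if (is.null(bv_b)) defaults$bv_b else check_numeric(bv_b, "bv_b"),
    L = if (is.null(L)) defaults$L else check_numeric(L, "L"),
    U = if (is.null(U)) defaults$U else check_numeric(U, "U"),
    delta = if (is.null(delta)) defaults$delta
            else check_numeric(delta, "delta")
  )
  if (p$cv_wl < 0 || p$bv_w < 0 || p$bv_b < 0) {
    stop("CV terms must be >= 0", call. = FALSE)
  }
  if (p$L >= p$U) stop("`L` must be below `U`", call. = FALSE)
  if (p$delta <= 0) stop("`delta` must be > 0", call. = FALSE)
  structure(p, class = "risk_params")
}

#' @export
print.risk_params <- function(x, ...) {
  cat("Risk-model parameters (", unit_label(x$unit), ")\n", sep = "")
  cat(sprintf("  B = %g, CV_wl = %g%%, BV_w = %g%%, BV_b = %g%%\n",
              x$bias, x$cv_wl, x$bv_w, x$bv_b))
  cat(sprintf("  L = %g, U = %g, delta = %g\n", x$L, x$U, x$delta))
  invisible(x)
}

#' Ideal-test counterpart of a parameter set
#'
#' @param params a [risk_params()] object.
#' @return the same parameters with `bias = 0` and `cv_wl = 0`.
#' @export
ideal_test <- function(params) {
  stopifnot(inherits(params, "risk_params"))
  params$bias <- 0
  params$cv_wl <- 0
  params
}

#' Dispersion of a single reported value around the true level
#'
#' `sigma = (R/100) * sqrt(cv_wl^2 + bv_w^2 + bv_b^2)`: the combined
#' analytical and biological spread used for diagnosis-type decisions,
#' where a single value is compared against population decision limits.
#'
#' @param R true HbA1c level(s), dataset units, > 0.
#' @param params a [risk_params()] object.
#' @return standard deviation(s) in dataset units.
#' @export
sigma_diagnosis <- function(R, params) {
  stopifnot(inherits(params, "risk_params"))
  R <- check_numeric(R, "R")
  if (any(R <= 0)) stop("`R` must be > 0", call. = FALSE)
  R / 100 * sqrt(params$cv_wl^2 + params$bv_w^2 + params$bv_b^2)
}

#' Misclassification probabilities at the diagnostic decision limits
#'
#' With the reported value distributed Normal(`R + B`, `sigma`),
#' `prob_underdiagnosis()` is the probability that a patient with true
#' level `R` is reported below the exclusion limit `L`
#' (`z = (R + B - L)/sigma`, `p = 1 - Phi(z)`), and
#' `prob_overdiagnosis()` the probability of being reported above the
#' diagnostic limit `U` (`z = (U - (R + B))/sigma`, `p = 1 - Phi(z)`).
#' When `sigma` is zero the exact indicator is returned.
#'
#' @inheritParams sigma_diagnosis
#' @return probability vector in `[0, 1]`.
#' @examples
#' p <- risk_params("ifcc", bias = -1, cv_wl = 2.1)
#' prob_underdiagnosis(47, p)   # ~0.025
#' prob_overdiagnosis(39, p)    # ~0.001
#' @export
prob_underdiagnosis <- function(R, params) {
  sig <- sigma_diagnosis(R, params)
  m <- R + params$bias
  ifelse(sig == 0, as.numeric(m < params$L),
         1 - pnorm((m - params$L) / ifelse(sig == 0, 1, sig)))
}

#' @rdname prob_underdiagnosis
#' @export
prob_overdiagnosis <- function(R, params) {
  sig <- sigma_diagnosis(R, params)
  m <- R + params$bias
  ifelse(sig == 0, as.numeric(m > params$U),
         1 - pnorm((params$U - m) / ifelse(sig == 0, 1, sig)))
}

#' Misinterpretation probabilities in serial monitoring
#'
#' For two consecutive measurements on the same patient, the relevant
#' spread excludes between-subject variation and doubles the remaining
#' components: `sigma_mon = (R/100) * sqrt(2 (cv_wl^2 + bv_w^2))`.
#' Undertreatment is missing a true change of `delta`
#' (`z = (delta - B)/sigma_mon`); overtreatment is seeing a spurious
#' change of `delta` (`z = (delta + B)/sigma_mon`); both are converted by
#' `p = 1 - Phi(z)`. With `B = 0` the two probabilities coincide by
#' symmetry.
#'
#' @inheritParams sigma_diagnosis
#' @return a list with `undertreatment` and `overtreatment` probability
#'   vectors.
#' @export
prob_monitoring <- function(R, params) {
  stopifnot(inherits(params, "risk_params"))
  R <- check_numeric(R, "R")
  if (any(R <= 0)) stop("`R` must be > 0", call. = FALSE)
  sig <- R / 100 * sqrt(2 * (params$cv_wl^2 + params$bv_w^2))
  safe <- ifelse(sig == 0, 1, sig)
  under <- ifelse(sig == 0, as.numeric(params$delta - params$bias < 0),
                  1 - pnorm((params$delta - params$bias) / safe))
  over <- ifelse(sig == 0, as.numeric(params$delta + params$bias < 0),
                 1 - pnorm((params$delta + params$bias) / safe))
  list(undertreatment = under, overtreatment = over)
}

#' Risk curves over a grid of true values
#'
#' Evaluates the four misinterpretation probabilities (under-/over-
#' diagnosis, under-/over-treatment) across a grid of true HbA1c levels,
#' for the test under evaluation and for the ideal test (zero bias and
#' analytical imprecision). Default grid: 30-90 mmol/mol in steps of 1
#' (IFCC) or 4.9-10.4 % in steps of 0.1 (NGSP).
#'
#' @param params a [risk_params()] object.
#' @param grid numeric vector of true values (> 0); `NULL` for the default.
#' @return an object of class `risk_curve`: a data.frame with columns `R`,
#'   `p_underdx`, `p_overdx`, `p_undertx`, `p_overtx`,
#'   `p_underdx_ideal`, `p_overdx_ideal`, `p_undertx_ideal`,
#'   `p_overtx_ideal`; the parameter set is attached as an attribute.
#' @export
risk_curves <- function(params, grid = NULL) {
  stopifnot(inherits(params, "risk_params"))
  if (is.null(grid)) {
    grid <- if (params$unit == "ifcc") seq(30, 90, by = 1)
            else seq(4.9, 10.4, by = 0.1)
  }
  grid <- check_numeric(grid, "grid")
  if (any(grid <= 0)) stop("grid values must be > 0", call. = FALSE)
  ideal <- ideal_test(params)
  mon <- prob_monitoring(grid, params)
  mon_i <- prob_monitoring(grid, ideal)
  out <- data.frame(
    R = grid,
    p_underdx = prob_underdiagnosis(grid, params),
    p_overdx = prob_overdiagnosis(grid, params),
    p_undertx = mon$undertreatment,
    p_overtx = mon$overtreatment,
    p_underdx_ideal = prob_underdiagnosis(grid, ideal),
    p_overdx_ideal = prob_overdiagnosis(grid, ideal),
    p_undertx_ideal = mon_i$undertreatment,
    p_overtx_ideal = mon_i$overtreatment
  )
  structure(out, class = c("risk_curve", "data.frame"), params = params)
}

#' Individuality index of an analyte
#'
#' The ratio of within-subject to between-subject biological variation,
#' net of analytical uncertainty. Analytes with an index at or below 0.6
#' are "highly individual": population reference intervals are insensitive
#' for them and serial monitoring against the patient's own baseline is
#' preferred. For HbA1c the conventional IFCC figures 1.6/7.1 give 0.23.
#'
#' @param bv_w within-subject biological variation, percent.
#' @param bv_b between-subject biological variation, percent (> 0).
#' @return a list with `index` and `classification`
#'   (`"highly individual"` when index <= 0.6, else `"not individual"`).
#' @examples
#' individuality_index(1.6, 7.1)
#' @export
individuality_index <- function(bv_w, bv_b) {
  bv_w <- check_numeric(bv_w, "bv_w")
  bv_b <- check_numeric(bv_b, "bv_b")
  if (any(bv_b <= 0)) stop("`bv_b` must be > 0", call. = FALSE)
  idx <- bv_w / bv_b
  list(index = idx,
       classification = ifelse(idx <= 0.6, "highly individual",
                               "not individual"))
}
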