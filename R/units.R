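#' HbA1c unit systems and the NGSP/IFCC master equation
#'
#' HbA1c is reported on two scales: the NGSP scale in percent of total
#' haemoglobin and the IFCC scale in mmol glycated haemoglobin per mol
#' haemoglobin. The two are related by the linear master equation
#' `NGSP = 0.09148 * IFCC + 2.152`.
#'
#' `ifcc_to_ngsp()` and `ngsp_to_ifcc()` convert absolute values;
#' `ifcc_diff_to_ngsp_diff()` and `ngsp_diff_to_ifcc_diff()` convert
#' differences (the intercept cancels, only the slope applies).
#'
#' @param value numeric vector of HbA1c values (must be non-negative).
#' @param delta numeric vector of HbA1c differences (any sign).
#' @return numeric vector on the target scale.
#' @examples
#' ifcc_to_ngsp(39)   # 5.72, reported clinically as 5.7
#' ifcc_diff_to_ngsp_diff(5)  # 0.4574, the +/-0.46 % ATE half-width
#' @export
ifcc_to_ngsp <- function(value) {
  value <- check_numeric(value, "value")
  if (any(value < 0)) stop("IFCC values must be >= 0", call. = FALSE)
  NGSP_SLOPE * value + NGSP_INTERCEPT
}

#' @rdname ifcc_to_ngsp
#' @export
ngsp_to_ifcc <- function(value) {
  value <- check_numeric(value, "value")
  if (any(value < NGSP_INTERCEPT)) {
    stop("NGSP values below the master-equation intercept (", NGSP_INTERCEPT,
         " %) have no IFCC equivalent", call. = FALSE)
  }
  (value - NGSP_INTERCEPT) / NGSP_SLOPE
}

#' @rdname ifcc_to_ngsp
#' @export
ifcc_diff_to_ngsp_diff <- function(delta) {
  delta <- check_numeric(delta, "delta")
  NGSP_SLOPE * delta
}

#' @rdname ifcc_to_ngsp
#' @export
ngsp_diff_to_ifcc_diff <- function(delta) {
  delta <- check_numeric(delta, "delta")
  delta / NGSP_SLOPE
}

# NGSP master equation constants (NGSP % = 0.09148 * IFCC + 2.152)
NGSP_SLOPE <- 0.09148
NGSP_INTERCEPT <- 2.152

#' Validate and normalise a unit-system label
#'
#' @param unit one of `"ifcc"` (mmol/mol) or `"ngsp"` (percent).
#' @return the matched label.
#' @export
unit_system <- function(unit = c("ifcc", "ngsp")) {
  match.arg(tolower(unit[1]), c("ifcc", "ngsp"))
}

unit_label <- function(unit) {
  switch(unit, ifcc = "mmol/mol (IFCC)", ngsp = "% (NGSP)")
}

# Display rounding conventions: IFCC whole numbers, NGSP one decimal.
round_display <- function(value, unit) {
  if (unit == "ifcc") round(value) else round(value, 1)
}

check_numeric <- function(x, name) {
  if (!is.numeric(x)) stop("`", name, "` must be numeric", call. = FALSE)
  if (any(!is.finite(x))) stop("`", name, "` must be finite", call. = FALSE)
  as.numeric(x)
}
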