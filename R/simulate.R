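#' Simulate a paired method-comparison dataset
#'
#' Draws true analyte levels `R_i` over `true_range` (uniform by default;
#' lognormal, truncated to the range, for skewed populations) and observes
#' them with both methods under multiplicative analytical noise:
#' `x_i = R_i (1 + e_xi)` for the comparative method and
#' `y_i = (intercept + slope * R_i)(1 + e_yi)` for the candidate, with
#' `e ~ Normal(0, cv/100)`. Noise is multiplicative because assay
#' imprecision is specified as a CV; setting `heteroscedastic = FALSE`
#' freezes the noise standard deviation at its value for the mid-range
#' level (constant-SD noise for edge-case testing).
#'
#' Defaults emulate a typical HbA1c comparison study: 178 specimens
#' spanning 30-73 mmol/mol with ~2 % analytical CV on both methods.
#' A fixed seed reproduces the dataset exactly.
#'
#' @param n number of specimens (>= 3).
#' @param true_range `(lo, hi)` range of true values, dataset units.
#' @param distribution `"uniform"` or `"lognormal"`.
#' @param slope,intercept generating relationship of the candidate method.
#' @param cv_x,cv_y analytical CVs in percent for comparative and
#'   candidate methods.
#' @param heteroscedastic if `TRUE` (default) noise SD is proportional to
#'   the level; if `FALSE` it is constant at the mid-range value.
#' @param unit `"ifcc"` or `"ngsp"`.
#' @param seed optional integer seed.
#' @return a [paired_dataset()].
#' @examples
#' d <- simulate_comparison(n = 178, intercept = -1, seed = 1)
#' passing_bablok(d)
#' @export
simulate_comparison <- function(n = 178, true_range = c(30, 73),
                                distribution = c("uniform", "lognormal"),
                                slope = 1, intercept = 0,
                                cv_x = 2, cv_y = 2,
                                heteroscedastic = TRUE,
                                unit = c("ifcc", "ngsp"), seed = NULL) {
  distribution <- match.arg(distribution)
  if (n < 3) stop("`n` must be >= 3", call. = FALSE)
  if (true_range[1] >= true_range[2] || true_range[1] <= 0) {
    stop("`true_range` must be positive and increasing", call. = FALSE)
  }
  if (cv_x < 0 || cv_y < 0) stop("CV terms must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  truth <- if (distribution == "uniform") {
    runif(n, true_range[1], true_range[2])
  } else {
    # lognormal matched to the range midpoint, resampled into the range
    mu <- log(mean(true_range))
    sdl <- log(true_range[2] / true_range[1]) / 4
    v <- exp(rnorm(n, mu, sdl))
    while (any(bad <- v < true_range[1] | v > true_range[2])) {
      v[bad] <- exp(rnorm(sum(bad), mu, sdl))
    }
    v
  }
  mid <- mean(true_range)
  sd_x <- if (heteroscedastic) truth * cv_x / 100 else rep(mid * cv_x / 100, n)
  y_true <- intercept + slope * truth
  sd_y <- if (heteroscedastic) y_true * cv_y / 100
          else rep((intercept + slope * mid) * cv_y / 100, n)
  x <- truth + rnorm(n, 0, 1) * sd_x
  y <- y_true + rnorm(n, 0, 1) * sd_y
  # assay values are strictly positive; redraw the rare negative deviate
  while (any(bad <- x <= 0)) x[bad] <- truth[bad] + rnorm(sum(bad)) * sd_x[bad]
  while (any(bad <- y <= 0)) y[bad] <- y_true[bad] + rnorm(sum(bad)) * sd_y[bad]
  paired_dataset(x, y, unit = unit)
}

#' Simulate a replicate precision design
#'
#' Generates `value(d, r) = mean * (1 + delta_d + e_dr)` with day effects
#' `delta_d ~ Normal(0, cv_day/100)` and within-run errors
#' `e_dr ~ Normal(0, cv_r/100)`: the additive-on-the-CV-scale structure
#' the nested variance-component analysis assumes. A fixed seed
#' reproduces the table exactly.
#'
#' @param mean level mean, dataset units (> 0).
#' @param cv_r,cv_day generating repeatability and between-day CVs in
#'   percent.
#' @param days,reps design size (>= 2 each; 5 x 5 by convention).
#' @param level label for the concentration level.
#' @param unit `"ifcc"` or `"ngsp"`.
#' @param seed optional integer seed.
#' @return a [replicate_design()].
#' @examples
#' des <- simulate_precision(mean = 35, cv_r = 1.5, cv_day = 1.5, seed = 1)
#' ep05_precision(des)
#' @export
simulate_precision <- function(mean, cv_r, cv_day, days = 5, reps = 5,
                               level = "", unit = c("ifcc", "ngsp"),
                               seed = NULL) {
  if (mean <= 0) stop("`mean` must be > 0", call. = FALSE)
  if (cv_r < 0 || cv_day < 0) stop("CV terms must be >= 0", call. = FALSE)
  if (days < 2 || reps < 2) stop("design needs >= 2 days and >= 2 replicates",
                                 call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  day_eff <- rnorm(days, 0, cv_day / 100)
  eps <- matrix(rnorm(days * reps, 0, cv_r / 100), nrow = days)
  vals <- mean * (1 + day_eff + eps)
  replicate_design(vals, level = level, unit = unit)
}
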