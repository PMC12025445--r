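---
title: "Validating an HbA1c assay: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating an HbA1c assay: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hba1cval)
```

# The problem

Glycated haemoglobin (HbA1c) integrates glycaemia over the preceding two to
three months and anchors both the diagnosis and the monitoring of diabetes
mellitus. When a laboratory wants to replace or supplement an HPLC
comparator with a cheaper candidate assay (for example an
immunoturbidimetric method on a general chemistry analyser), it must show
that the two methods agree across the clinical range, that the candidate is
precise enough, and that whatever bias and imprecision remain do not
meaningfully raise the probability of a wrong clinical call. `hba1cval`
implements that whole chain: method comparison, agreement against allowable
total error, bias at medical decision limits, nested-design precision, and
a closed-form misinterpretation-risk model — plus a synthetic-data module
so the pipeline can be exercised and property-tested without patient data.

HbA1c is reported on two scales linked by the linear master equation
`NGSP % = 0.09148 × IFCC mmol/mol + 2.152`. All functions work on either
scale; converters are provided for values (`ifcc_to_ngsp()`) and for
differences (`ifcc_diff_to_ngsp_diff()`, slope only, because the intercept
cancels). Display rounding follows the clinical convention — whole numbers
for IFCC, one decimal for NGSP — which is why a threshold stated as
47 mmol/mol circulates as 6.4 % even though the master equation evaluates
to 6.45: we keep full precision internally and round only for display.

# Method comparison

## Passing–Bablok regression

`passing_bablok()` fits `y = a + b x` through the shifted median of all
pairwise slopes `S_ij = (y_j − y_i)/(x_j − x_i)`. The estimator assumes a
positive association: slopes equal to −1 are excluded and the median index
is offset by `K`, the count of slopes below −1, which makes the fit
equivariant under exchanging the axes. The slope confidence interval uses
the rank statistics at `M1 = round((N − w)/2)` and `M2 = N − M1 + 1` with
`w = z·sqrt(n(n−1)(2n+5)/18)`; the intercept is `median(y − b x)` with CI
bounds re-using the slope bounds. Ties in `x` with unequal `y` enter as
signed infinite slopes (ordered beyond all finite ones); identical points
contribute nothing. On exactly collinear data every pairwise slope
coincides, so the estimate equals the generating line and the intervals
have zero width — a property the tests pin.

The pairwise-slope enumeration and the bootstrap refits are implemented in
C++ (via Rcpp): the estimator is O(n²) per fit and the bootstrap coverage
studies refit it hundreds of thousands of times. The C++ code draws from
R's own RNG stream, so `set.seed()` governs every resampling result.

## Cusum linearity test

The Passing–Bablok model presumes a linear relation, so `cusum_linearity()`
checks it: each point is scored by its side of the fitted line
(`+sqrt(n_below/n_above)` above, `−sqrt(n_above/n_below)` below), the
points are walked in order of their projection onto the fitted line
(key `x + y/b`, ties by `x` then input order), and the statistic is the
maximum absolute cumulative score divided by `sqrt(n_above + n_below)`.
The p-value uses the asymptotic Kolmogorov–Smirnov tail.

Two numerical caveats, both verified against a permutation oracle in the
test suite. First, the asymptotic p agrees closely with permutation of the
score sequence (the two differ by < 0.03 on curved fixtures). Second, the
test is conservative on null data: the sides are assigned relative to the
*fitted* line, which soaks up part of any imbalance, so the null rejection
rate at the 5 % threshold is well below 5 %. That is acceptable for its
screening role — a small p still indicates real curvature — but the
p-values should not be treated as uniformly distributed under the null.

## Pre-screens

`tukey_outliers()`, `grubbs_test()` and `gesd_test()` screen the paired
differences; `normality_test()` is Shapiro–Wilk (delegated to
`stats::shapiro.test`, whose coefficient generation is standard). The
screens only *report*. Nothing is ever removed silently: deleting a
specimen is a user decision, taken outside the pipeline.

# Agreement

## Bland–Altman with nonparametric limits and ATE

`bland_altman()` works on differences `candidate − comparative`. The mean
bias gets a t-interval. The limits of agreement are the empirical 2.5th and
97.5th percentiles — not mean ± 1.96 SD — because HbA1c difference
distributions are routinely heavier-tailed than normal. The percentile
rule is Hazen interpolation (rank `p·n + 0.5`, R's `type = 5`); the paper
trail for every golden value in the tests pins that rule. Percentile
confidence intervals are exact binomial order-statistic intervals: the
endpoints are the order statistics whose cumulative binomial coverage
first reaches 95 %. Their attained coverage is slightly above nominal by
discreteness (~96 % at n = 178 for the 97.5th percentile), which the
coverage simulation in the acceptance suite confirms; below n = 20 the
intervals are reported as unavailable rather than fabricated.

The allowable-total-error verdict compares the percentile *point
estimates* with the ±ATE band (±5 mmol/mol / ±0.46 %, the minimum
difference that would change therapy). A stricter verdict requiring the
whole percentile CI inside the band is reported alongside as
informational, never as the headline call — the point-estimate convention
is how EP21-style adjudication is quoted in practice. An OLS slope of the
differences against the comparative values is attached purely to flag
proportional bias.

## Lin's concordance correlation coefficient

`lin_ccc()` uses the population-moment form
`rho_c = 2 s_xy / (s_x² + s_y² + (x̄ − ȳ)²)` and factorises it as
`rho_c = rho × C_b` (precision × accuracy); the identity holds to 1e-12 by
construction and is asserted in the acceptance suite. The interval applies
Lin's asymptotic variance on the Fisher-z scale. Strength-of-agreement
labels follow the usual bands (< 0.90 poor, 0.90–0.95 moderate, 0.95–0.99
substantial, > 0.99 nearly perfect).

## Mountain plot

`mountain_plot_points()` folds the empirical percentiles
(`p_i = 100(i − 0.5)/n`, folded value `min(p_i, 100 − p_i)`), so the curve
peaks at the median; the function emits the point set only — plotting is
left to the caller.

# Bias at medical decision limits

`bootstrap_decision_bias()` evaluates the full-data Passing–Bablok fit at
each decision limit (default 39/47/53/64 mmol/mol or 5.7/6.4/7.0/8.0 %)
and surrounds the predictions with percentile bootstrap intervals from
case resampling: specimen pairs are resampled with replacement, the
regression refit, the predictions re-evaluated, and the 2.5/97.5
percentiles of 1000 replicate predictions taken. Design choices, each the
plain reading of standard practice: case resampling (not residual
resampling, which would presume a residual model), percentile intervals
(not BCa), and the "modelled" value derived from the Passing–Bablok fit.
Degenerate resamples — all comparative values equal — are redrawn with a
capped retry count. Reproducibility is contracted for a fixed seed within
this implementation only; matching another package's RNG stream is not a
goal, so a recorded seed documents provenance rather than bit-equality.

# Precision by nested variance components

`ep05_precision()` analyses a balanced day × replicate table (5 days × 5
replicates per run is the default protocol; one run per day collapses the
run and day components, so the between component is labelled "day"):
`V_r = MS_within`, `V_day = max(0, (MS_between − MS_within)/R)`,
`V_wl = V_r + V_day`, each converted to a CV as `100·sqrt(V)/mean`. The
zero-truncation of a negative between-day estimate is standard practice;
its half-normal behaviour under a true zero day effect (truncation in
roughly half the runs) is asserted in the tests. Unbalanced or incomplete
designs are rejected rather than approximated. `precision_report()` flags
each level against the 2.5 % within-laboratory CV performance criterion.

A sampling-theory point worth stating explicitly: with only `D − 1 = 4`
degrees of freedom behind the day component, the standard deviation of an
estimated `CV_wl` near 2.1 % is ≈ 0.45 CV points at the 5 × 5 size. Recovery
simulations at that design size therefore scatter substantially — about
80–85 % of runs land within ±0.6 points of the truth, not 90+ % — and the
test suite documents this honestly rather than widening the band. `CV_r`,
resting on 20 degrees of freedom, recovers within ±0.6 points in ~99 % of
runs.

# The misinterpretation-risk model

A reported value for a patient with true level `R` is modelled as
`Normal(R + B, σ)`. For diagnosis-type use (one value against population
limits) `σ = (R/100)·sqrt(CV_wl² + BV_w² + BV_b²)`, combining analytical
imprecision with within- and between-subject biological variation. The
error probabilities are `P(reported < L) = 1 − Φ((R + B − L)/σ)` and
`P(reported > U) = 1 − Φ((U − (R + B))/σ)`. One sign convention needs
care: the upper-limit numerator must be `U − (R + B)` — bias shifts the
reported value, so it enters with `R` — and only that convention
reproduces the quoted probabilities at the decision limits; the package
adopts it on both rows. For monitoring-type use (two consecutive values in
the same patient) the between-subject term drops out and the remaining
variance doubles: `σ_mon = (R/100)·sqrt(2(CV_wl² + BV_w²))`, with
`z = (Δ ∓ B)/σ_mon` against the minimum therapy-changing difference
`Δ = 5 mmol/mol (0.46 %)`.

Defaults: biological variation `BV_w` 1.6 %, `BV_b` 7.1 % (IFCC scale;
1.2 %/5.4 % for NGSP), limits `L = 39`, `U = 47` mmol/mol. The `cv_wl`
plugged in for risk evaluation should be the within-laboratory CV of the
level nearest the decision region (2.1 % for the low IFCC level here); the
discussion-level value 2.2 % rounds to the same probabilities. The "ideal
test" sets `B = 0, CV_wl = 0` and thus isolates biological variation — its
curves are invariant to the analytical parameters, which the tests assert.
Note that the monitoring error probabilities of a mildly biased, mildly
imprecise test are small but *not* identically zero (~1 % overtreatment at
`R = 47` with `B = −1`, `CV_wl = 2.1`): the model computes the formulas
faithfully instead of forcing zeros. All four closed-form probabilities
are validated against a 10⁶-draw Monte-Carlo oracle to within 3 standard
errors.

`individuality_index()` is `BV_w/BV_b` (0.23 for HbA1c): well below the
0.6 threshold, marking HbA1c as highly individual — population reference
intervals are insensitive for it, and serial monitoring against the
patient's own baseline is the informative use.

# The synthetic-data generator

`simulate_comparison()` draws true levels uniformly over 30–73 mmol/mol
(the span a deliberately range-covering comparison study samples;
lognormal available for skewed-population tests), then observes each level
with both methods under multiplicative noise: `x = R(1 + ε_x)`,
`y = (a + bR)(1 + ε_y)`, `ε ~ N(0, cv/100)`. Multiplicative noise is the
right default because assay imprecision is specified as a CV;
`heteroscedastic = FALSE` freezes the SD at the mid-range level for
edge-case testing. Defaults (n = 178, slope 1, intercept 0, 2 % CV per
method) emulate the scale and noise of a real HbA1c comparison.
`simulate_precision()` generates `mean·(1 + δ_d + ε_dr)` with day effects
and within-run errors on the CV scale — exactly the structure the nested
analysis assumes.

What the generator does *not* emulate: haemoglobin-variant interference,
pre-analytical artefacts, drift within a run, rounding of reported values,
or a realistic patient-mix distribution. Passing tests therefore certify
the statistical machinery under the stated model, not the behaviour of any
physical assay.

# Problem sizes and numerical choices

The simulation-backed tests run at: 500 seeds for the 5 × 5 precision
recovery, 500 synthetic datasets × 1000 bootstrap replicates for
decision-limit CI coverage (n = 178), 2000 seeds for percentile-CI
coverage, 10⁶ draws for the Monte-Carlo risk oracle, and 40–60 random
fixtures (n ≤ 12) for the brute-force Passing–Bablok oracle. These sizes
keep each Monte-Carlo standard error several times smaller than the
property band being asserted. Ties in the Cusum ordering break by `x`
then input order; percentile ranks clamp to the sample; bootstrap
degenerate resamples are redrawn up to 100 times before erroring;
`atanh` arguments are clipped away from ±1 before Fisher-z transforms.

# Known limitations

- Unbalanced precision designs are rejected, not analysed.
- The Cusum p-value is conservative under the null (see above).
- Bootstrap intervals are percentile-type; BCa or studentised intervals
  are out of scope.
- The risk model treats biological and analytical variation as jointly
  normal on the absolute scale with CV-proportional σ; skewed
  within-person distributions are not modelled.
- Replicate-aware limits of agreement and percentage-difference
  Bland–Altman variants are not implemented.
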