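test_that("diagnosis dispersion combines analytical and biological CVs", {
  p <- risk_params("ifcc", bias = -1, cv_wl = 2.1)
  expect_equal(sigma_diagnosis(47, p), 0.47 * sqrt(2.1^2 + 1.6^2 + 7.1^2),
               tolerance = 1e-12)
  expect_equal(round(sigma_diagnosis(47, p), 3), 3.56)
  expect_equal(round(sigma_diagnosis(47, ideal_test(p)), 3), 3.421)
  p0 <- risk_params("ifcc", bias = 0, cv_wl = 0, bv_w = 0, bv_b = 0)
  expect_equal(sigma_diagnosis(47, p0), 0)
  expect_error(sigma_diagnosis(0, p), "> 0")
})

test_that("at a decision limit the ideal test misclassifies half the time", {
  p <- risk_params("ifcc")
  ideal <- ideal_test(p)
  expect_equal(prob_underdiagnosis(ideal$L, ideal), 0.5)
  expect_equal(prob_overdiagnosis(ideal$U, ideal), 0.5)
})

test_that("zero-dispersion parameters give exact indicator outcomes", {
  p0 <- risk_params("ifcc", bias = -1, cv_wl = 0, bv_w = 0, bv_b = 0)
  expect_equal(prob_underdiagnosis(39.5, p0), 1)  # 38.5 < L = 39
  expect_equal(prob_underdiagnosis(41, p0), 0)
  expect_equal(prob_overdiagnosis(49, p0), 1)     # 48 > U = 47
  expect_equal(prob_overdiagnosis(47.5, p0), 0)
})

test_that("monitoring probabilities follow the doubled within-person spread", {
  p <- risk_params("ifcc", bias = -1, cv_wl = 2.1)
  m <- prob_monitoring(47, p)
  sig <- 0.47 * sqrt(2 * (2.1^2 + 1.6^2))
  expect_equal(m$undertreatment, 1 - pnorm((5 + 1) / sig), tolerance = 1e-12)
  expect_equal(m$overtreatment, 1 - pnorm((5 - 1) / sig), tolerance = 1e-12)
  expect_lt(m$undertreatment, 0.001)
  expect_equal(round(m$overtreatment, 3), 0.011)

  # symmetric when unbiased
  p0 <- risk_params("ifcc", bias = 0, cv_wl = 2.1)
  m0 <- prob_monitoring(50, p0)
  expect_equal(m0$undertreatment, m0$overtreatment)

  # a huge therapy-changing difference is never exceeded
  pbig <- risk_params("ifcc", bias = 0, cv_wl = 2.1, delta = 500)
  mbig <- prob_monitoring(50, pbig)
  expect_lt(mbig$undertreatment, 1e-10)
})

test_that("ideal-test curves do not depend on bias or imprecision", {
  grid <- seq(31, 80, by = 1)
  c1 <- risk_curves(risk_params("ifcc", bias = -1, cv_wl = 2.1), grid)
  c2 <- risk_curves(risk_params("ifcc", bias = 3, cv_wl = 9), grid)
  for (col in c("p_underdx_ideal", "p_overdx_ideal", "p_undertx_ideal",
                "p_overtx_ideal")) {
    expect_equal(c1[[col]], c2[[col]])
  }
})

test_that("risk curves are monotone and positive between the limits", {
  p <- risk_params("ifcc", bias = -1, cv_wl = 2.1)
  cv <- risk_curves(p)
  expect_true(all(as.matrix(cv[, -1]) >= 0 & as.matrix(cv[, -1]) <= 1))
  above_L <- cv$R > p$L
  expect_true(all(diff(cv$p_underdx[above_L]) < 0))
  inside <- cv$R > p$L & cv$R < p$U
  expect_true(all(cv$p_underdx_ideal[inside] > 0))
  expect_true(all(cv$p_overdx_ideal[inside] > 0))
})

test_that("inflating the analytical CV never shrinks an error probability", {
  base <- risk_params("ifcc", bias = 0, cv_wl = 1)
  worse <- risk_params("ifcc", bias = 0, cv_wl = 4)
  R <- seq(40, 46.5, by = 0.5)  # correct side of L for underdiagnosis
  expect_true(all(prob_underdiagnosis(R, worse) >=
                    prob_underdiagnosis(R, base)))
  R2 <- seq(39.5, 46.5, by = 0.5)  # correct side of U for overdiagnosis
  expect_true(all(prob_overdiagnosis(R2, worse) >=
                    prob_overdiagnosis(R2, base)))
})

test_that("individuality index classifies HbA1c as highly individual", {
  r <- individuality_index(1.6, 7.1)
  expect_equal(r$index, 1.6 / 7.1, tolerance = 1e-12)
  expect_equal(round(r$index, 2), 0.23)
  expect_equal(r$classification, "highly individual")
  expect_equal(individuality_index(2, 2)$index, 1)
  expect_equal(individuality_index(2, 2)$classification, "not individual")
  expect_equal(individuality_index(1.2, 5.4)$index, 1.2 / 5.4,
               tolerance = 1e-12)
  expect_error(individuality_index(1, 0), "bv_b")
})

test_that("parameter defaults and validation follow the unit system", {
  p_i <- risk_params("ifcc")
  expect_equal(c(p_i$bv_w, p_i$bv_b, p_i$L, p_i$U, p_i$delta),
               c(1.6, 7.1, 39, 47, 5))
  p_n <- risk_params("ngsp")
  expect_equal(c(p_n$bv_w, p_n$bv_b, p_n$L, p_n$U, p_n$delta),
               c(1.2, 5.4, 5.7, 6.4, 0.46))
  expect_error(risk_params("ifcc", L = 50, U = 47), "below")
  expect_error(risk_params("ifcc", delta = 0), "delta")
  expect_error(risk_params("ifcc", cv_wl = -1), ">= 0")
})
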