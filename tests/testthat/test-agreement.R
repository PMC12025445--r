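test_that("percentile point estimates follow the Hazen rule", {
  expect_equal(percentile_ci(1:100, 50)$estimate, 50.5)
  expect_equal(percentile_ci(1:100, 25)$estimate, 25.5)
  # against R's own type-5 quantile on irregular data
  set.seed(2)
  v <- rnorm(57)
  for (p in c(2.5, 10, 50, 97.5)) {
    expect_equal(percentile_ci(v, p)$estimate,
                 unname(quantile(v, p / 100, type = 5)), tolerance = 1e-12)
  }
})

test_that("percentile CI ranks come from the exact binomial enumeration", {
  # n = 40, p = 2.5: lower rank clamps at the minimum; upper rank is the
  # smallest u with P(Bin(40, .025) <= u - 1) >= 0.975, which is 4
  r <- percentile_ci(1:40, 2.5)
  expect_equal(r$ranks, c(1L, 4L))
  expect_equal(r$ci, c(1, 4))
  # n = 178, p = 97.5: enumeration oracle
  set.seed(8)
  v <- rnorm(178)
  r2 <- percentile_ci(v, 97.5)
  n <- 178; q <- 0.975
  # index i of these vectors corresponds to rank i (so pbinom at i - 1)
  l_o <- max(which(pbinom(0:(n - 1), n, q) <= 0.025))
  u_o <- min(which(pbinom(0:(n - 1), n, q) >= 0.975))
  expect_equal(r2$ranks[1], l_o)
  expect_equal(r2$ranks[2], u_o)
  expect_gte(r2$coverage, 0.95)
  # below n = 20 the interval is unavailable
  expect_true(anyNA(percentile_ci(1:10, 50)$ci))
})

test_that("bland_altman on identical methods passes any ATE", {
  x <- seq(30, 73, length.out = 30)
  d <- paired_dataset(x, x, unit = "ifcc")
  ba <- bland_altman(d, ate_limits(0.5, "ifcc"))
  expect_equal(ba$bias, 0)
  expect_equal(ba$lower$estimate, 0)
  expect_equal(ba$upper$estimate, 0)
  expect_equal(unname(ba$verdict), c("passed", "passed"))
})

test_that("bland_altman adds a constant offset exactly", {
  x <- seq(30, 73, length.out = 40)
  d <- paired_dataset(x, x + 2, unit = "ifcc")
  ba <- bland_altman(d)
  expect_equal(ba$bias, 2)
  expect_equal(ba$lower$estimate, 2)
  expect_equal(ba$upper$estimate, 2)
})

test_that("replicated symmetric differences give order-statistic limits inside ATE", {
  diffs <- rep(-3:3, each = 30)  # n = 210
  x <- rep(seq(40, 60, length.out = 30), times = 7)
  d <- paired_dataset(x, x + diffs, unit = "ifcc")
  ba <- bland_altman(d, ate_limits(5, "ifcc"))
  # direct order-statistic oracle: h = .025*210 + .5 = 5.75 -> -3;
  # h = .975*210 + .5 = 205.25 -> 3
  expect_equal(ba$lower$estimate, -3)
  expect_equal(ba$upper$estimate, 3)
  expect_equal(unname(ba$verdict), c("passed", "passed"))
  expect_equal(ba$bias, 0)
})

test_that("bias recovery: generating offset lies in its own CI most of the time", {
  hits <- vapply(1:100, function(s) {
    d <- simulate_comparison(n = 178, intercept = -0.74, cv_x = 2, cv_y = 2,
                             seed = 2000 + s)
    ba <- bland_altman(d)
    ba$bias.ci[1] <= -0.74 && -0.74 <= ba$bias.ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("lin_ccc matches the moment formula and its factorisation", {
  x <- seq(30, 60, length.out = 20)
  d <- paired_dataset(x, x, unit = "ifcc")
  cc <- lin_ccc(d)
  expect_equal(cc$rho_c, 1)
  expect_equal(cc$c_b, 1)

  d2 <- paired_dataset(c(1, 2, 3, 4), c(2, 3, 4, 5), unit = "ngsp")
  # hand evaluation: s_xy = 1.25, s_x2 = s_y2 = 1.25, dm = -1
  expect_equal(lin_ccc(d2)$rho_c, 2 * 1.25 / (1.25 + 1.25 + 1),
               tolerance = 1e-12)

  d3 <- paired_dataset(c(1, 2, 3), c(2, 3, 4), unit = "ngsp")
  expect_error(lin_ccc(d3), "n >= 4")
  expect_error(lin_ccc(paired_dataset(rep(2, 5), 1:5, "ngsp")), "constant")
})

test_that("rho_c is bounded by |rho| and invariant to shared affine maps", {
  set.seed(14)
  for (rep in 1:20) {
    d <- random_pairs(30)
    cc <- lin_ccc(d)
    expect_lte(cc$rho_c, abs(cc$rho) + 1e-12)
    a <- runif(1, 0.5, 3); b <- runif(1, -5, 5)
    shifted <- paired_dataset(pmax(a * d$x + b, 0.01),
                              pmax(a * d$y + b, 0.01), unit = d$unit)
    if (all(a * d$x + b > 0) && all(a * d$y + b > 0)) {
      expect_equal(lin_ccc(shifted)$rho_c, cc$rho_c, tolerance = 1e-9)
    }
  }
})

test_that("ccc strength bands follow the reporting convention", {
  strength_of <- function(rho_c) {
    x <- seq(30, 73, length.out = 120)
    # tune noise to land in the target band
    d <- paired_dataset(x, x, unit = "ifcc")
    lin_ccc(d)$strength
  }
  expect_equal(strength_of(1), "nearly perfect")
  d <- simulate_comparison(n = 178, cv_x = 2, cv_y = 2, seed = 77)
  cc <- lin_ccc(d)
  expect_equal(cc$strength,
               if (cc$rho_c < 0.90) "poor" else if (cc$rho_c < 0.95)
                 "moderate" else if (cc$rho_c <= 0.99) "substantial"
               else "nearly perfect")
})

test_that("mountain plot folds percentiles around the median", {
  m <- mountain_plot_points(c(-1, 0, 1))
  expect_equal(m$difference, c(-1, 0, 1))
  expect_equal(which.max(m$folded_percentile), 2L)
  expect_equal(max(m$folded_percentile), 50)

  m2 <- mountain_plot_points(1:99)
  expect_equal(m2$difference[which.max(m2$folded_percentile)], 50)
  expect_true(all(m2$folded_percentile > 0 & m2$folded_percentile <= 50))

  set.seed(30)
  peaks <- vapply(1:30, function(s) {
    d <- simulate_comparison(n = 178, intercept = -0.74, seed = 500 + s)
    m <- mountain_plot_points(paired_differences(d))
    m$difference[which.max(m$folded_percentile)]
  }, numeric(1))
  expect_gte(mean(peaks > -1.5 & peaks < 0), 0.8)
})
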