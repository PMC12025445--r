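test_that("identical replicates give zero CVs", {
  des <- replicate_design(matrix(35, 5, 5), unit = "ifcc")
  r <- ep05_precision(des)
  expect_equal(r$cv_r, 0)
  expect_equal(r$cv_day, 0)
  expect_equal(r$cv_wl, 0)
  expect_equal(r$mean, 35)
})

test_that("pure day shifts load only the between-day component", {
  vals <- matrix(rep(c(10, 12, 14), each = 4), nrow = 3, byrow = TRUE)
  des <- replicate_design(vals, unit = "ifcc")
  r <- ep05_precision(des)
  expect_equal(r$cv_r, 0)
  expect_gt(r$cv_day, 0)
  expect_equal(r$cv_wl, r$cv_day)
})

test_that("within-laboratory CV decomposes on the variance scale", {
  set.seed(9)
  for (rep in 1:20) {
    des <- simulate_precision(mean = runif(1, 30, 120), cv_r = runif(1, 0.5, 3),
                              cv_day = runif(1, 0, 3), seed = 9000 + rep)
    r <- ep05_precision(des)
    expect_equal(r$cv_wl^2, r$cv_r^2 + r$cv_day^2, tolerance = 1e-9)
    expect_true(all(c(r$cv_r, r$cv_day, r$cv_wl) >= 0))
  }
})

test_that("CVs are invariant to rescaling all values", {
  des <- simulate_precision(mean = 35, cv_r = 1.5, cv_day = 1.5, seed = 21)
  r1 <- ep05_precision(des)
  des2 <- replicate_design(3.2 * des$values, unit = "ifcc")
  r2 <- ep05_precision(des2)
  expect_equal(r2$cv_r, r1$cv_r, tolerance = 1e-10)
  expect_equal(r2$cv_day, r1$cv_day, tolerance = 1e-10)
})

test_that("mean squares match R's one-way ANOVA on random designs", {
  set.seed(31)
  for (rep in 1:10) {
    des <- simulate_precision(mean = 50, cv_r = 2, cv_day = 1.5,
                              days = sample(3:6, 1), reps = sample(2:6, 1),
                              seed = 31000 + rep)
    r <- ep05_precision(des)
    day <- factor(rep(seq_len(des$days), times = des$reps))
    tab <- anova(lm(as.vector(des$values) ~ day))
    msb <- tab["day", "Mean Sq"]
    msw <- tab["Residuals", "Mean Sq"]
    expect_equal(r$v_r, msw, tolerance = 1e-10)
    expect_equal(r$v_day, max(0, (msb - msw) / des$reps), tolerance = 1e-10)
  }
})

test_that("between-day variance estimate is unbiased away from truncation", {
  # large day effect so the zero-truncation practically never binds
  v_hat <- vapply(1:2000, function(s) {
    des <- simulate_precision(mean = 100, cv_r = 1, cv_day = 3,
                              seed = 50000 + s)
    ep05_precision(des)$v_day
  }, numeric(1))
  expect_lt(abs(mean(v_hat) - 9) / 9, 0.05)
})

test_that("with no true day effect the estimate truncates to zero often", {
  zeros <- vapply(1:300, function(s) {
    des <- simulate_precision(mean = 35, cv_r = 1.5, cv_day = 0,
                              seed = 70000 + s)
    ep05_precision(des)$v_day == 0
  }, logical(1))
  expect_gte(mean(zeros), 0.4)
})

test_that("design container rejects malformed tables", {
  expect_error(replicate_design(matrix(1, 1, 5)), "at least 2")
  m <- matrix(35, 5, 5); m[2, 3] <- NA
  expect_error(replicate_design(m), "balanced")
  m2 <- matrix(35, 5, 5); m2[1, 1] <- -1
  expect_error(replicate_design(m2), "> 0")
})

test_that("precision report flags levels against the 2.5 % criterion", {
  mk <- function(cv_wl_target, seed) {
    # build a design whose realised CV_wl is near the target
    simulate_precision(mean = 100, cv_r = cv_wl_target / sqrt(2),
                       cv_day = cv_wl_target / sqrt(2), seed = seed)
  }
  r_low <- ep05_precision(simulate_precision(100, 0.3, 0.3, seed = 1))
  rep1 <- precision_report(list(r_low))
  expect_equal(rep1$flag, "within criterion")

  r_fake <- r_low
  r_fake$cv_wl <- 2.6
  expect_equal(precision_report(list(r_fake))$flag, "exceeds criterion")
  r_edge <- r_low
  r_edge$cv_wl <- 2.4
  expect_equal(precision_report(list(r_edge))$flag, "within criterion")
  expect_error(precision_report(list()), "no precision results")
})
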