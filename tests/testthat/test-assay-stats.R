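test_that("adjusted Wald intervals match the closed form on the worked
           examples", {
  ci <- adjusted_wald_ci(12, 24)
  expect_equal(ci$estimate, 0.5)
  expect_equal(ci$lower, 0.3142743, tolerance = 1e-6)
  expect_equal(ci$upper, 0.6857257, tolerance = 1e-6)
  ci0 <- adjusted_wald_ci(0, 24)
  expect_equal(ci0$estimate, 0)
  expect_equal(ci0$lower, 0)  # clipped at 0
  expect_equal(ci0$upper, 0.1631265, tolerance = 1e-6)
  ci24 <- adjusted_wald_ci(24, 24)
  expect_equal(ci24$upper, 1)  # clipped at 1
})

test_that("the interval for (x, n) mirrors the interval for (n-x, n)", {
  for (x in 0:24) {
    a <- adjusted_wald_ci(x, 24)
    b <- adjusted_wald_ci(24 - x, 24)
    expect_equal(a$lower, 1 - b$upper, tolerance = 1e-12)
    expect_equal(a$upper, 1 - b$lower, tolerance = 1e-12)
  }
})

test_that("exhaustive-enumeration coverage at n = 24 is at least 0.92
           across the probability grid", {
  n <- 24
  ci <- adjusted_wald_ci(0:n, n)
  for (p in seq(0.1, 0.9, by = 0.1)) {
    covered <- ci$lower <= p & p <= ci$upper
    coverage <- sum(dbinom(0:n, n, p)[covered])
    expect_gte(coverage, 0.92)
  }
})

test_that("adjusted Wald rejects invalid counts", {
  expect_error(adjusted_wald_ci(25, 24), "exceed")
  expect_error(adjusted_wald_ci(1, 0), "n must")
  expect_error(adjusted_wald_ci(-1, 24), "nonnegative")
  expect_error(adjusted_wald_ci(3, 24, confidence = 1.2), "confidence")
})

test_that("growth fractions pool wells within groups and contain the point
           estimate", {
  tab <- data.frame(
    plate = rep(1:2, each = 4),
    condition = rep(c("clump", "single"), times = 4),
    grew = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE))
  out <- growth_fraction_summary(tab, by = "condition")
  expect_equal(nrow(out), 2)
  expect_true(all(out$fraction >= 0 & out$fraction <= 1))
  expect_true(all(out$lower <= out$fraction & out$fraction <= out$upper))
  # pooling two half-plates of 12/24 equals one group of 24/48
  tab2 <- data.frame(condition = "a",
                     grew = rep(c(TRUE, FALSE), each = 24))
  pooled <- growth_fraction_summary(tab2, by = "condition")
  direct <- adjusted_wald_ci(24, 48)
  expect_equal(pooled$fraction, direct$estimate)
  expect_equal(pooled$lower, direct$lower)
  expect_equal(pooled$upper, direct$upper)
  # all-grown group hits the clipped upper bound
  allg <- growth_fraction_summary(
    data.frame(condition = "b", grew = rep(TRUE, 24)), by = "condition")
  expect_equal(allg$fraction, 1)
  expect_equal(allg$upper, 1)
})

test_that("competition log-ratio matches the frozen t-interval example", {
  wells <- data.frame(producer_count = c(2, 2, 2, 1),
                      nonproducer_count = c(1, 1, 1, 1))
  adv <- competition_advantage(wells)
  expect_equal(adv$mean_log_ratio, 0.5198604, tolerance = 1e-6)
  expect_equal(adv$ci_lower, -0.03161554, tolerance = 1e-6)
  expect_equal(adv$ci_upper, 1.0713363, tolerance = 1e-6)
  expect_equal(adv$df, 3)
})

test_that("competition handles equal counts, single-well arithmetic and
           zero-count exclusion", {
  eq <- competition_advantage(data.frame(producer_count = rep(1000, 5),
                                         nonproducer_count = rep(1000, 5)))
  expect_equal(eq$mean_log_ratio, 0)
  expect_equal(eq$ci_upper - eq$ci_lower, 0)
  # ln(2000/1000) per-well statistic
  expect_equal(log(2000 / 1000), 0.6931, tolerance = 1e-4)
  mixed <- competition_advantage(data.frame(
    producer_count = c(2000, 2000, 0, 1000),
    nonproducer_count = c(1000, 1000, 500, 0)))
  expect_equal(mixed$n_wells_used, 2)
  expect_equal(mixed$n_excluded, 2)
  expect_error(competition_advantage(data.frame(
    producer_count = c(0, 1), nonproducer_count = c(1, 0))), "fewer than 2")
})

test_that("competition recovers the growth-rate difference from noise-free
           exponential counts", {
  r_p <- 0.3486; r_n <- 0.35; t <- 72; n0 <- 60
  wells <- data.frame(producer_count = rep(n0 * exp(r_p * t), 6),
                      nonproducer_count = rep(n0 * exp(r_n * t), 6))
  adv <- competition_advantage(wells)
  expect_equal(adv$mean_log_ratio, (r_p - r_n) * t, tolerance = 1e-10)
})

test_that("OD conversion interpolates the standard curve and applies the
           clump multiplier", {
  cal <- od_calibration(c(0.05, 0.1, 0.4, 0.8), c(1e6, 2.2e6, 9e6, 1.9e7))
  # knots are reproduced exactly
  expect_equal(od_to_cells(c(0.05, 0.4), cal), c(1e6, 9e6))
  # clump multiplier: 1000 particle-equivalents -> 6400 cells
  cal2 <- od_calibration(c(0.1, 0.5), c(1000, 5000))
  expect_equal(od_to_cells(0.1, cal2, clumpy = TRUE), 6400)
  # doubling the curve's densities doubles every conversion
  cal3 <- od_calibration(cal$od, cal$cells_per_ml * 2)
  x <- c(0.07, 0.2, 0.63)
  expect_equal(od_to_cells(x, cal3), 2 * od_to_cells(x, cal))
  # outside the calibrated range warns
  expect_warning(od_to_cells(0.9, cal), "extrapolating")
  expect_error(od_calibration(c(0.2, 0.1), c(1, 2)), "increasing")
})
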