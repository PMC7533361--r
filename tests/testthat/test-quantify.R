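# XIC integration, calibration, ICH limits, back-calculation and the
# replicability / matrix-effect statistics.

test_that("trapezoidal integration handles rectangles, windows and baselines", {
  tr <- data.frame(time_min = seq(0, 1, 0.1), intensity = 100)
  expect_equal(integrate_xic(tr), 100)
  expect_equal(integrate_xic(tr, window = c(0.25, 0.75)), 50)
  zero <- data.frame(time_min = 0:5, intensity = 0)
  expect_equal(integrate_xic(zero), 0)
  # linear-baseline subtraction removes a ramp exactly
  ramp <- data.frame(time_min = 0:10, intensity = 0:10 * 3 + 7)
  expect_equal(integrate_xic(ramp, baseline = "linear"), 0)
  # multiple fragment traces are summed, not averaged
  multi <- rbind(cbind(tr, transition_id = "P1:y2"),
                 cbind(tr, transition_id = "P1:b4"))
  expect_equal(integrate_xic(multi), 200)
  expect_error(integrate_xic(tr, window = c(0.5, 0.2)), "start < end")
  expect_error(integrate_xic(tr, window = c(-1, 0.5)), "outside")
  expect_error(integrate_xic(data.frame(time_min = c(1, 1),
                                        intensity = c(1, 1))),
               "ascending")
})

test_that("calibration fits reproduce exact lines and symmetric designs", {
  cu <- fit_calibration(c(1, 2, 3), c(3, 5, 7))
  expect_equal(cu$slope, 2, tolerance = 1e-12)
  expect_equal(cu$intercept, 1, tolerance = 1e-12)
  expect_equal(cu$r, 1)
  expect_equal(cu$rss, 0, tolerance = 1e-18)
  # symmetric +/-d replicates: line through the means, RSS = sum d^2
  d <- 0.5
  cu2 <- fit_calibration(rep(c(1, 2, 3), each = 2),
                         c(3 - d, 3 + d, 5 - d, 5 + d, 7 - d, 7 + d))
  expect_equal(cu2$slope, 2, tolerance = 1e-12)
  expect_equal(cu2$intercept, 1, tolerance = 1e-12)
  expect_equal(cu2$rss, 6 * d^2, tolerance = 1e-9)
  expect_error(fit_calibration(c(1, 1, 1), c(1, 2, 3)), "distinct")
  expect_error(fit_calibration(c(1, 2), c(1, 2)), "three")
})

test_that("calibration agrees with the normal-equations oracle", {
  set.seed(17)
  for (i in 1:25) {
    x <- rep(c(0.5, 1, 2, 5, 10), each = sample(1:3, 1))
    y <- 3e6 * x + 4e5 + rnorm(length(x), 0, 5e5)
    cu <- fit_calibration(x, y)
    or <- oracle_ols(x, y)
    expect_equal(cu$slope, or$slope, tolerance = 1e-9)
    expect_equal(cu$intercept, or$intercept, tolerance = 1e-9)
    expect_equal(cu$rss, or$rss, tolerance = 1e-9)
  }
})

test_that("residual sd follows sqrt(RSS/(n-2)) and a direct computation", {
  expect_equal(residual_sd(list(rss = 0, n = 5)), 0)
  expect_equal(residual_sd(list(rss = 8, n = 4)), 2)
  expect_error(residual_sd(list(rss = 1, n = 2)), "n > 2")
  set.seed(23)
  x <- c(0.5, 1, 2, 5, 10); y <- 2e6 * x + rnorm(5, 0, 1e5)
  cu <- fit_calibration(x, y)
  or <- oracle_ols(x, y)
  res <- y - (or$intercept + or$slope * x)
  expect_equal(residual_sd(cu), sqrt(sum(res^2) / (length(x) - 2)),
               tolerance = 1e-9)
})

test_that("ICH limits scale as 10 and 3.3 times S over slope", {
  expect_equal(loq(0, 10), 0)
  expect_equal(lod(0, 10), 0)
  expect_equal(loq(1, 10), 1)
  expect_equal(lod(1, 10), 0.33)
  expect_error(loq(1, 0), "non-zero")
  set.seed(31)
  for (i in 1:20) {
    S <- runif(1, 0, 1e6); sl <- runif(1, 1e5, 5e6) * sample(c(-1, 1), 1)
    expect_equal(loq(S, sl) / lod(S, sl), 10 / 3.3, tolerance = 1e-12)
  }
})

test_that("blank-based LOD uses mean + k * sd with configurable k", {
  expect_equal(lod_blank(c(100, 100, 100)), 100)
  blanks <- c(95, 100, 105)
  expect_equal(lod_blank(blanks, k = 10), 100 + 10 * 5)
  expect_equal(lod_blank(blanks, k = 3.3), 100 + 3.3 * 5)
  expect_error(lod_blank(100), "two blank")
})

test_that("back-calculation applies dilution and recovery corrections", {
  cu <- structure(list(slope = 10, intercept = 100, rss = 0, n = 5),
                  class = "calibration_curve")
  expect_equal(back_calculate(100, cu)$raw, 0)
  r <- back_calculate(120, cu, dilution_factor = 2.1, recovery = 0.8)
  expect_equal(r$raw, 2)
  expect_equal(r$final, 2 * 2.1 / 0.8)
  # conservation: final / raw == DF / recovery exactly
  expect_equal(r$final / r$raw, r$dilution_factor / r$recovery,
               tolerance = 1e-15)
  # doubling the suppression (halving recovery) doubles the correction
  r2 <- back_calculate(120, cu, dilution_factor = 2.1, recovery = 0.4)
  expect_equal(r2$final, 2 * r$final)
  neg <- back_calculate(50, cu, limits = list(loq = 1))
  expect_equal(neg$raw, 0)
  expect_true(neg$clipped)
  expect_true(neg$below_loq)
  expect_error(back_calculate(1, cu, recovery = 0), "recovery")
  expect_error(back_calculate(1, cu, recovery = 2), "recovery")
})

test_that("internal-standard recovery is the simple abundance ratio", {
  expect_equal(internal_standard_recovery(1000, 1000), 1)
  expect_equal(internal_standard_recovery(800, 1000), 0.8)
  expect_error(internal_standard_recovery(1, 0), "positive")
})

test_that("matrix-effect percentages are relative to the pure control", {
  me <- matrix_effect(1000, c(`0.75` = 1000, `0.5` = 800, `0.2` = 1100))
  expect_equal(me$effect_pct, c(0, 0, 20, -10))
  expect_equal(me$fraction[1], 1)
  expect_error(matrix_effect(0, c(`0.5` = 1)), "positive")
  # simulated 30% suppression recovered through the full chain
  m <- peak_model(rt = 5, slope = 1e6, noise_sd = 2e3)
  s <- matrix_series(m, spike = 3, suppression = c(1, 1, 0.7, 1), seed = 4)
  ab <- integrate_samples(s$chromatograms)
  ctrl <- ab$abundance[ab$sample_id == "matrix_f1"]
  sup <- ab$abundance[ab$sample_id == "matrix_f0.5"]
  est <- matrix_effect(ctrl, data.frame(fraction = 0.5, abundance = sup))
  noise_pct <- 100 * 3 * propagated_area_sd(m) / 3e6
  expect_lt(abs(est$effect_pct[2] - 30), noise_pct)
})

test_that("CV is the sample-sd percent of the mean and scale invariant", {
  expect_equal(cv(c(5, 5, 5)), 0)
  expect_equal(cv(c(8, 10, 12)), 20)
  set.seed(41)
  v <- rlnorm(20)
  expect_equal(cv(7 * v), cv(v), tolerance = 1e-12)
  expect_error(cv(5), "two values")
  expect_error(cv(c(-1, 1)), "zero mean")
})

test_that("replicability reports day means and the <10% pass rule", {
  conc <- c(10, 10.2, 9.8, 10.6, 10.4, 10.5, 9.5, 9.6, 9.4)
  day <- rep(1:3, each = 3)
  rr <- replicability(conc, day)
  expect_equal(as.numeric(rr$day_means), c(10, 10.5, 9.5))
  expect_equal(rr$grand_mean, 10)
  expect_equal(rr$cv_pct, cv(c(10, 10.5, 9.5)))
  expect_true(rr$pass)
  expect_false(replicability(c(1, 1, 2, 2, 4, 4), c(1, 1, 2, 2, 3, 3))$pass)
})
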