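# The ground-truth chromatogram simulator.

quiet_model <- function(slope = 1e6, intercept = 0, ...) {
  peak_model(rt = 5, slope = slope, intercept = intercept, noise_sd = 0, ...)
}

test_that("zero concentration, intercept and noise give a flat baseline", {
  tr <- simulate_trace(quiet_model(baseline = 120), 0, seed = 1)
  expect_true(all(tr$intensity == 120))
  tr0 <- simulate_trace(quiet_model(), 0, seed = 1)
  expect_true(all(tr0$intensity == 0))
})

test_that("noise-free integrated area matches the linear response closed form", {
  models <- default_peak_models(noise_sd = 0)
  for (pep in c("P1", "P5", "P6")) {
    m <- models[[pep]]
    for (conc in c(0.5, 3, 10)) {
      tr <- simulate_trace(m, conc, window = m$rt + c(-5, 5) * m$sigma * 2)
      area <- integrate_xic(tr)
      truth <- oracle_gauss_area(m$slope, conc, m$intercept)
      expect_lt(abs(area - truth) / truth, 0.005)
    }
  }
})

test_that("area accuracy holds whenever sigma >= 4 sampling intervals", {
  m <- peak_model(rt = 5, slope = 1e6, sigma = 0.04, dt = 0.01)
  tr <- simulate_trace(m, 2, window = c(4.5, 5.5))
  expect_lt(abs(integrate_xic(tr) - 2e6) / 2e6, 0.005)
})

test_that("identical seeds give bit-identical traces, different seeds differ", {
  m <- quiet_model()
  m$noise_sd <- 1000
  a <- simulate_trace(m, 2, seed = 99)
  b <- simulate_trace(m, 2, seed = 99)
  c <- simulate_trace(m, 2, seed = 100)
  expect_identical(a, b)
  expect_false(identical(a$intensity, c$intensity))
  # series-level determinism
  models <- default_peak_models(noise_sd = 2e4)
  s1 <- calibration_series(models, replicates = 1, seed = 7)
  s2 <- calibration_series(models, replicates = 1, seed = 7)
  expect_identical(s1, s2)
})

test_that("the simulator does not disturb the session RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_trace(default_peak_models()$P1, 1, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("calibration and LOD/LOQ series carry the stated default levels", {
  models <- default_peak_models(noise_sd = 0)["P1"]
  s <- calibration_series(models, replicates = 2, seed = 1)
  expect_setequal(unique(s$manifest$level), c(0.5, 1, 2, 5, 10))
  expect_equal(nrow(s$manifest), 5 * 2)
  expect_true(all(table(s$manifest$level) == 2))
  ll <- lodloq_series(models, replicates = 5, seed = 1)
  expect_setequal(unique(ll$manifest$level),
                  c(10, 5, 2, 1, 0.5, 0.3, 0.1, 0.05, 0.03, 0.01))
  expect_true(all(table(ll$manifest$level) >= 5))
  expect_warning(empty <- calibration_series(models, replicates = 0),
                 "empty series")
  expect_equal(nrow(empty$manifest), 0L)
})

test_that("matrix series applies the configured suppression", {
  m <- quiet_model(slope = 1e6)
  # no suppression anywhere: all areas equal the control
  s <- matrix_series(m, spike = 3, suppression = 1, seed = 2)
  ab <- integrate_samples(s$chromatograms)
  expect_lt(diff(range(ab$abundance)) / mean(ab$abundance), 1e-9)
  expect_setequal(s$manifest$fraction, c(1, 0.75, 0.5, 0.2))
  # 20% suppression in the pure control is recovered from the areas
  s2 <- matrix_series(m, spike = 3, suppression = c(0.8, 1, 1, 1), seed = 2)
  ab2 <- integrate_samples(s2$chromatograms)
  ctrl <- ab2$abundance[ab2$sample_id == "matrix_f1"]
  pure <- 3e6
  expect_equal(100 * (pure - ctrl) / pure, 20, tolerance = 1e-6)
})

test_that("parameter recovery: quantify returns the simulated truth", {
  models <- default_peak_models(noise_sd = 3e4)["P1"]
  cal <- calibration_series(models, replicates = 3, seed = 21)
  ab <- integrate_samples(cal$chromatograms)
  merged <- merge(cal$manifest, ab, by = "sample_id")
  curve <- fit_calibration(merged$level, merged$abundance)
  lim <- lodloq(curve)
  for (true_conc in c(1, 4, 8)) {
    unk <- simulate_trace(models$P1, true_conc, seed = 500 + true_conc)
    est <- back_calculate(integrate_xic(unk), curve, dilution_factor = 1)
    tol3sigma <- 3 * propagated_area_sd(models$P1) / curve$slope
    if (true_conc >= lim$loq) {
      expect_lt(abs(est$raw - true_conc), tol3sigma + 1e-6)
    }
  }
})

test_that("day-to-day series have the configured between-day variability", {
  d <- day_series(10, cv_pct = 5, n_days = 5, replicates = 3, seed = 9)
  expect_equal(nrow(d), 15L)
  expect_equal(sort(unique(d$day)), 1:5)
  cvs <- vapply(1:200, function(s) {
    dd <- day_series(10, cv_pct = 5, seed = s)
    replicability(dd$concentration, dd$day)$cv_pct
  }, numeric(1))
  expect_gt(mean(cvs), 3)
  expect_lt(mean(cvs), 7)
})

test_that("write_series emits the chromatogram CSV dialect", {
  models <- default_peak_models(noise_sd = 0)["P1"]
  s <- calibration_series(models, replicates = 1, seed = 1)
  chrom <- tempfile(fileext = ".csv"); man <- tempfile(fileext = ".csv")
  on.exit(unlink(c(chrom, man)))
  write_series(s, chrom, man)
  back <- read.csv(chrom)
  expect_identical(names(back),
                   c("sample_id", "transition_id", "time_min", "intensity"))
  expect_equal(nrow(back), nrow(s$chromatograms))
})
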