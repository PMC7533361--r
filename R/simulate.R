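# Ground-truth generator: simulated PRM extracted-ion chromatograms,
# calibration and dilution series, matrix-suppression scenarios and
# day-to-day variation series. Every downstream stage is testable against
# the construction parameters without instrument data.

#' Elution peak model for one peptide transition
#'
#' A chromatographic peak parameterised so that the integrated area follows
#' the linear response `area = slope * concentration + intercept`, on the
#' abundance scale of the shipped calibration curves. Gaussian shape by
#' default; an exponentially modified Gaussian (`shape = "emg"`) is available
#' for robustness testing of integration against tailing.
#'
#' @param rt Retention time (min).
#' @param slope Area per concentration (counts*min per ug/mL), `> 0`.
#' @param intercept Area at zero concentration (counts*min).
#' @param sigma Peak width sigma (min), `> 0`.
#' @param noise_sd Additive Gaussian intensity noise sd (counts), `>= 0`.
#' @param baseline Constant baseline offset (counts).
#' @param dt Sampling interval (min), `> 0`.
#' @param shape `"gaussian"` or `"emg"`.
#' @param tau EMG exponential time constant (min), used when `shape = "emg"`.
#' @return Object of class `peak_model`.
#' @export
peak_model <- function(rt, slope, intercept = 0, sigma = 0.05, noise_sd = 0,
                       baseline = 0, dt = 0.01,
                       shape = c("gaussian", "emg"), tau = 0.05) {
  shape <- match.arg(shape)
  stopifnot(sigma > 0, dt > 0, noise_sd >= 0, tau > 0)
  structure(list(rt = rt, slope = slope, intercept = intercept, sigma = sigma,
                 noise_sd = noise_sd, baseline = baseline, dt = dt,
                 shape = shape, tau = tau),
            class = "peak_model")
}

#' Shipped per-peptide peak models
#'
#' Slopes and intercepts of the shipped calibration curves and the scheduled
#' retention times, so simulated abundances live on the same scale as the
#' real method. The internal standard P1H shares P1's response.
#'
#' @param noise_sd Intensity noise sd (counts) applied to every model;
#'   default 5e4, roughly 0.2 percent of a mid-calibration peak apex.
#' @param ... Passed on to [peak_model()] (e.g. `sigma`, `dt`, `shape`).
#' @return Named list of [peak_model()]s (P1--P6, P1H).
#' @export
default_peak_models <- function(noise_sd = 5e4, ...) {
  resp <- data.frame(
    peptide   = c("P1", "P2", "P3", "P4", "P5", "P6"),
    slope     = c(3405436, 1776389, 1637587, 2063579, 420669, 1140396),
    intercept = c(404809, 224381, 63340, -13216, 16042, -729751),
    rt        = c(6.11, 6.59, 7.12, 6.43, 7.29, 3.48))
  models <- lapply(seq_len(nrow(resp)), function(i)
    peak_model(rt = resp$rt[i], slope = resp$slope[i],
               intercept = resp$intercept[i], noise_sd = noise_sd, ...))
  names(models) <- resp$peptide
  models$P1H <- peak_model(rt = 6.11, slope = resp$slope[1],
                           intercept = resp$intercept[1],
                           noise_sd = noise_sd, ...)
  models
}

peak_density <- function(model, t) {
  if (model$shape == "gaussian") {
    stats::dnorm(t, model$rt, model$sigma)
  } else {
    # exponentially modified Gaussian, unit area
    s <- model$sigma; tau <- model$tau; mu <- model$rt
    z <- (s / tau - (t - mu) / s) / sqrt(2)
    (1 / (2 * tau)) * exp(s^2 / (2 * tau^2) - (t - mu) / tau) *
      2 * stats::pnorm(-z * sqrt(2))
  }
}

#' Simulate one extracted-ion chromatogram trace
#'
#' Draws a peak of area `slope * concentration + intercept` centred at the
#' model retention time, on a constant baseline, with seeded additive
#' Gaussian intensity noise. Identical seed and parameters give bit-identical
#' traces.
#'
#' @param model A [peak_model()].
#' @param concentration True concentration (ug/mL), `>= 0`.
#' @param seed Integer seed for the noise; `NULL` draws from the current RNG
#'   stream (used internally by the series generators).
#' @param window Time window `c(start, end)` (min); default RT +/- 0.5 min.
#' @return `data.frame` with columns `time_min`, `intensity`; attributes
#'   `true_area` and `concentration` carry the construction ground truth.
#' @export
simulate_trace <- function(model, concentration, seed = NULL, window = NULL) {
  stopifnot(inherits(model, "peak_model"), concentration >= 0)
  if (is.null(window)) window <- model$rt + c(-0.5, 0.5)
  times <- seq(window[1], window[2], by = model$dt)
  area <- model$slope * concentration + model$intercept
  make <- function() {
    y <- model$baseline + area * peak_density(model, times)
    if (model$noise_sd > 0) y <- y + stats::rnorm(length(times), 0, model$noise_sd)
    y
  }
  intensity <- if (is.null(seed)) make() else with_seed(seed, make())
  structure(data.frame(time_min = times, intensity = intensity),
            true_area = area, concentration = concentration)
}

#' Expected abundance-scale noise of an integrated trace
#'
#' Standard deviation that the model's intensity noise propagates onto a
#' trapezoidal area over a window of length `width`:
#' `noise_sd * sqrt(dt * width)`.
#'
#' @param model A [peak_model()].
#' @param width Integration window length (min); default the full simulated
#'   window (1 min).
#' @return Area sd (counts*min).
#' @export
propagated_area_sd <- function(model, width = 1) {
  model$noise_sd * sqrt(model$dt * width)
}

# Shared machinery for the labelled sample-set generators. One top-level
# seed drives every trace, drawn sequentially, so the whole set is
# reproducible from the scenario alone.
simulate_set <- function(models, samples, seed) {
  with_seed(seed, {
    chrom <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
      m <- models[[samples$peptide[i]]]
      area_scale <- samples$suppression[i]
      m2 <- m
      m2$slope <- m$slope * area_scale
      m2$intercept <- m$intercept * area_scale
      tr <- simulate_trace(m2, samples$concentration[i], seed = NULL)
      data.frame(sample_id = samples$sample_id[i],
                 transition_id = samples$peptide[i],
                 time_min = tr$time_min, intensity = tr$intensity,
                 stringsAsFactors = FALSE)
    }))
    chrom
  })
}

#' Simulate an external calibration series
#'
#' Labelled traces for every calibration level and replicate, for each
#' peptide model. Default levels are the shipped standard-curve dilutions
#' (0.5--10 ug/mL).
#'
#' @param models Named list of [peak_model()]s (names are peptide ids).
#' @param levels Concentration levels (ug/mL).
#' @param replicates Injections per level.
#' @param seed Integer seed; fixes all randomness in the set.
#' @return List of class `prm_series`: `chromatograms` (`sample_id`,
#'   `transition_id`, `time_min`, `intensity`) and `manifest` (`sample_id`,
#'   `peptide`, `level`, `replicate`, `suppression`).
#' @export
#' @examples
#' s <- calibration_series(default_peak_models(noise_sd = 0), seed = 1,
#'                         replicates = 1)
#' unique(s$manifest$level)
calibration_series <- function(models, levels = c(0.5, 1, 2, 5, 10),
                               replicates = 3, seed = 1) {
  stopifnot(length(levels) > 0, all(levels >= 0))
  if (replicates < 1) {
    warning("replicates < 1: returning an empty series", call. = FALSE)
    empty <- data.frame(sample_id = character(), transition_id = character(),
                        time_min = numeric(), intensity = numeric())
    return(structure(list(chromatograms = empty,
                          manifest = data.frame(sample_id = character(),
                                                peptide = character(),
                                                level = numeric(),
                                                replicate = integer(),
                                                suppression = numeric())),
                     class = "prm_series"))
  }
  grid <- expand.grid(replicate = seq_len(replicates), level = levels,
                      peptide = names(models), stringsAsFactors = FALSE)
  grid$sample_id <- sprintf("cal_L%g_r%d", grid$level, grid$replicate)
  grid$concentration <- grid$level
  grid$suppression <- 1
  chrom <- simulate_set(models, grid, seed)
  manifest <- grid[, c("sample_id", "peptide", "level", "replicate",
                       "suppression")]
  rownames(manifest) <- NULL
  structure(list(chromatograms = chrom, manifest = manifest),
            class = "prm_series")
}

#' Simulate the LOD/LOQ dilution series
#'
#' [calibration_series()] with the shipped limit-study levels
#' (10 down to 0.01 ug/mL) and at least five injections per level.
#'
#' @inheritParams calibration_series
#' @export
lodloq_series <- function(models,
                          levels = c(10, 5, 2, 1, 0.5, 0.3, 0.1, 0.05, 0.03,
                                     0.01),
                          replicates = 5, seed = 1) {
  calibration_series(models, levels = levels, replicates = replicates,
                     seed = seed)
}

#' Simulate a matrix-effect dilution series
#'
#' A control sample (pure eluate, fraction 1.0) and serially diluted matrix
#' samples, each spiked with the internal standard at the same concentration,
#' with a configurable per-sample suppression factor (fraction of signal
#' retained) applied to the response.
#'
#' @param model [peak_model()] for the spiked internal standard.
#' @param spike Spiked concentration (ug/mL); default 3.
#' @param matrix_fractions Matrix fractions including the 1.0 control;
#'   default `c(1, 0.75, 0.5, 0.2)`; all in `(0, 1]`.
#' @param suppression Fraction of signal retained per sample, recycled over
#'   `matrix_fractions`; 1 = no matrix effect.
#' @param peptide Transition id used in the output; default `"P1H"`.
#' @param seed Integer seed.
#' @return `prm_series` whose manifest carries `fraction` and the true
#'   `suppression` per sample.
#' @export
matrix_series <- function(model, spike = 3,
                          matrix_fractions = c(1, 0.75, 0.5, 0.2),
                          suppression = 1, peptide = "P1H", seed = 1) {
  stopifnot(all(matrix_fractions > 0 & matrix_fractions <= 1))
  suppression <- rep_len(suppression, length(matrix_fractions))
  stopifnot(all(suppression > 0 & suppression <= 1))
  grid <- data.frame(
    sample_id = sprintf("matrix_f%g", matrix_fractions),
    peptide = peptide, concentration = spike,
    fraction = matrix_fractions, suppression = suppression,
    stringsAsFactors = FALSE)
  models <- stats::setNames(list(model), peptide)
  chrom <- simulate_set(models, grid, seed)
  structure(list(chromatograms = chrom,
                 manifest = grid[, c("sample_id", "peptide", "fraction",
                                     "suppression")]),
            class = "prm_series")
}

#' Simulate a day-to-day replicability series
#'
#' Concentrations measured on successive days with a between-day coefficient
#' of variation `cv_pct` and a smaller within-day replicate CV, emulating a
#' frozen digesta aliquot re-prepared and re-injected each day.
#'
#' @param mean_conc True mean concentration (ug/mL).
#' @param cv_pct Between-day CV (percent), default 5.
#' @param n_days Number of days.
#' @param replicates Injections per day.
#' @param within_cv_pct Within-day CV (percent), default 2.
#' @param seed Integer seed.
#' @return `data.frame` with columns `day`, `replicate`, `concentration`.
#' @export
day_series <- function(mean_conc, cv_pct = 5, n_days = 5, replicates = 3,
                       within_cv_pct = 2, seed = 1) {
  stopifnot(mean_conc > 0, cv_pct >= 0, n_days >= 2, replicates >= 1)
  with_seed(seed, {
    day_means <- mean_conc * (1 + stats::rnorm(n_days, 0, cv_pct / 100))
    out <- expand.grid(replicate = seq_len(replicates), day = seq_len(n_days))
    out$concentration <- day_means[out$day] *
      (1 + stats::rnorm(nrow(out), 0, within_cv_pct / 100))
    out[, c("day", "replicate", "concentration")]
  })
}

#' Write a simulated series to the chromatogram CSV dialect
#'
#' Writes the long chromatogram table (`sample_id`, `transition_id`,
#' `time_min`, `intensity`) consumed by the quantification front end, plus
#' the ground-truth manifest.
#'
#' @param series A `prm_series`.
#' @param chrom_path,manifest_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_series <- function(series, chrom_path, manifest_path) {
  stopifnot(inherits(series, "prm_series"))
  utils::write.csv(series$chromatograms, chrom_path, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(series$manifest, manifest_path, row.names = FALSE,
                   quote = FALSE)
  invisible(c(chrom_path, manifest_path))
}
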