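# The quantitative core: extracted-ion-chromatogram integration, external
# calibration by ordinary least squares, residual-based LOD/LOQ, internal-
# standard and dilution correction, matrix-effect and replicability reports.

#' Integrate an extracted-ion chromatogram
#'
#' Trapezoidal integral of intensity over a time window, floored at zero.
#' When the input holds several transitions of the same precursor (a
#' `transition_id` column with more than one value), the per-transition
#' integrals are summed: the abundance is the total extracted ion current
#' over the defined fragment ions. Window endpoints falling between samples
#' are handled by linear interpolation.
#'
#' @param trace `data.frame` with columns `time_min` (strictly ascending per
#'   transition) and `intensity` (`>= 0` up to noise), optionally
#'   `transition_id`.
#' @param window `c(start, end)` in minutes, `start < end`, within the trace
#'   span; default the full trace.
#' @param baseline `"none"` (default) or `"linear"` (subtract the chord
#'   between the window endpoints before integrating).
#' @return Abundance in counts*min (`>= 0`).
#' @export
#' @examples
#' tr <- data.frame(time_min = c(0, 1), intensity = c(100, 100))
#' integrate_xic(tr) # 100
integrate_xic <- function(trace, window = NULL,
                          baseline = c("none", "linear")) {
  baseline <- match.arg(baseline)
  stopifnot(all(c("time_min", "intensity") %in% names(trace)))
  if ("transition_id" %in% names(trace) &&
      length(unique(trace$transition_id)) > 1L) {
    parts <- split(trace[, c("time_min", "intensity")], trace$transition_id)
    return(sum(vapply(parts, integrate_xic, numeric(1), window = window,
                      baseline = baseline)))
  }
  t <- trace$time_min; y <- trace$intensity
  if (length(t) < 2L) stop("trace needs at least two points", call. = FALSE)
  if (is.unsorted(t, strictly = TRUE)) {
    stop("trace times must be strictly ascending", call. = FALSE)
  }
  if (is.null(window)) window <- range(t)
  if (!(is.numeric(window) && length(window) == 2L && window[1] < window[2])) {
    stop("window must be c(start, end) with start < end", call. = FALSE)
  }
  if (window[1] < t[1] - 1e-9 || window[2] > t[length(t)] + 1e-9) {
    stop("integration window lies outside the trace time span", call. = FALSE)
  }
  window <- pmin(pmax(window, t[1]), t[length(t)])
  inside <- t > window[1] & t < window[2]
  tt <- c(window[1], t[inside], window[2])
  yy <- c(stats::approx(t, y, xout = window[1])$y, y[inside],
          stats::approx(t, y, xout = window[2])$y)
  if (baseline == "linear") {
    yy <- yy - (yy[1] + (tt - tt[1]) / (tt[length(tt)] - tt[1]) *
                  (yy[length(yy)] - yy[1]))
  }
  area <- sum(diff(tt) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
  max(area, 0)
}

#' Integrate every sample in a long chromatogram table
#'
#' Groups a long table by sample and peptide, sums the fragment transitions
#' belonging to one peptide, and integrates each over its scheduled window.
#' Transition ids map to peptides either through `map` or, by default, by
#' stripping a `:<fragment>` suffix (`"P1:y2"` -> `"P1"`).
#'
#' @param chromatograms `data.frame` with `sample_id`, `transition_id`,
#'   `time_min`, `intensity`.
#' @param windows Optional `data.frame` with `peptide`, `window_start`,
#'   `window_end`; peptides absent from it are integrated over the full
#'   trace.
#' @param map Optional `data.frame` with `transition_id`, `peptide`.
#' @param baseline Passed to [integrate_xic()].
#' @return `data.frame` with `sample_id`, `peptide`, `abundance`.
#' @export
integrate_samples <- function(chromatograms, windows = NULL, map = NULL,
                              baseline = "none") {
  stopifnot(all(c("sample_id", "transition_id", "time_min", "intensity") %in%
                  names(chromatograms)))
  if (is.null(map)) {
    peptide <- sub(":.*$", "", chromatograms$transition_id)
  } else {
    peptide <- map$peptide[match(chromatograms$transition_id,
                                 map$transition_id)]
    if (anyNA(peptide)) {
      stop("transition id(s) missing from map", call. = FALSE)
    }
  }
  key <- paste(chromatograms$sample_id, peptide, sep = "\r")
  groups <- split(seq_len(nrow(chromatograms)), key)
  out <- do.call(rbind, lapply(groups, function(idx) {
    sm <- chromatograms$sample_id[idx[1]]
    pep <- peptide[idx[1]]
    w <- NULL
    if (!is.null(windows)) {
      j <- match(pep, windows$peptide)
      if (!is.na(j)) w <- c(windows$window_start[j], windows$window_end[j])
    }
    tr <- chromatograms[idx, c("transition_id", "time_min", "intensity")]
    if (!is.null(w)) {
      # clip the scheduled window to what the trace actually covers
      w <- c(max(w[1], min(tr$time_min)), min(w[2], max(tr$time_min)))
    }
    data.frame(sample_id = sm, peptide = pep,
               abundance = integrate_xic(tr, window = w, baseline = baseline),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$sample_id, out$peptide), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit an external calibration curve
#'
#' Unweighted ordinary least squares of abundance on concentration, as used
#' for the shipped standard curves; optional `1/x` or `1/x^2` weighting.
#'
#' @param levels Concentrations (ug/mL); at least three distinct values.
#' @param abundances Integrated abundances (counts*min), same length.
#' @param weighting `"none"` (default), `"1/x"` or `"1/x2"`.
#' @return Object of class `calibration_curve`: `slope`, `intercept`,
#'   `r` (Pearson correlation), `rss` (residual sum of squares), `n`,
#'   `range` (concentration range).
#' @export
#' @examples
#' fit_calibration(c(1, 2, 3), c(3, 5, 7)) # slope 2, intercept 1, r = 1
fit_calibration <- function(levels, abundances,
                            weighting = c("none", "1/x", "1/x2")) {
  weighting <- match.arg(weighting)
  stopifnot(is.numeric(levels), is.numeric(abundances),
            length(levels) == length(abundances))
  if (length(unique(levels)) < 3L) {
    stop("calibration needs at least three distinct concentration levels",
         call. = FALSE)
  }
  w <- switch(weighting, none = NULL, `1/x` = 1 / levels, `1/x2` = 1 / levels^2)
  fit <- if (is.null(w)) stats::lm(abundances ~ levels) else
    stats::lm(abundances ~ levels, weights = w)
  cf <- stats::coef(fit)
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 r = stats::cor(levels, abundances),
                 rss = sum(stats::resid(fit)^2),
                 n = length(levels), range = range(levels),
                 weighting = weighting),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration> y = %.6g x %+.6g   r = %.4f  RSS = %.4g  n = %d  (%g-%g ug/mL)\n",
              x$slope, x$intercept, x$r, x$rss, x$n, x$range[1], x$range[2]))
  invisible(x)
}

#' Residual standard deviation of a calibration curve
#'
#' `S = sqrt(RSS / (n - 2))`: the standard deviation of the regression
#' residuals with two parameters estimated, the "standard deviation of the
#' response" of the ICH limit equations.
#'
#' @param curve A [fit_calibration()] result, or a list with `rss` and `n`.
#' @return `S`, on the abundance scale.
#' @export
residual_sd <- function(curve) {
  stopifnot(!is.null(curve$rss), !is.null(curve$n))
  if (curve$n <= 2L) stop("residual sd needs n > 2 points", call. = FALSE)
  sqrt(curve$rss / (curve$n - 2))
}

#' ICH limits of quantification and detection from residual sd and slope
#'
#' `LOQ = 10 * S / |slope|` and `LOD = 3.3 * S / |slope|`; their ratio is
#' 10/3.3 by construction.
#'
#' @param S Residual standard deviation (abundance scale), `>= 0`.
#' @param slope Calibration slope, non-zero.
#' @return Concentration (ug/mL).
#' @export
#' @examples
#' loq(1, 10) # 1.0
#' lod(1, 10) # 0.33
loq <- function(S, slope) {
  stopifnot(S >= 0)
  if (!is.numeric(slope) || slope == 0) stop("slope must be non-zero",
                                             call. = FALSE)
  10 * S / abs(slope)
}

#' @rdname loq
#' @export
lod <- function(S, slope) {
  stopifnot(S >= 0)
  if (!is.numeric(slope) || slope == 0) stop("slope must be non-zero",
                                             call. = FALSE)
  3.3 * S / abs(slope)
}

#' Blank-based limit of detection (abundance scale)
#'
#' `LOD = mean(blanks) + k * sd(blanks)` with the sample (n-1) standard
#' deviation. `k` defaults to 10 as in the shipped method; 3.3 gives the
#' conventional blank rule.
#'
#' @param blank_abundances At least two blank measurements.
#' @param k Multiplication coefficient.
#' @return Abundance threshold.
#' @export
lod_blank <- function(blank_abundances, k = 10) {
  stopifnot(is.numeric(blank_abundances))
  if (length(blank_abundances) < 2L) {
    stop("blank-based LOD needs at least two blank measurements",
         call. = FALSE)
  }
  mean(blank_abundances) + k * stats::sd(blank_abundances)
}

#' Convenience: S, LOD and LOQ from a fitted curve
#'
#' @param curve A [fit_calibration()] result.
#' @return List with `S`, `lod`, `loq` (ug/mL).
#' @export
lodloq <- function(curve) {
  S <- residual_sd(curve)
  list(S = S, lod = lod(S, curve$slope), loq = loq(S, curve$slope))
}

#' Back-calculate concentrations from abundances
#'
#' `raw = (abundance - intercept) / slope`, then
#' `final = raw * dilution_factor / recovery`. Negative raw concentrations
#' are reported as zero and flagged rather than propagated. When a
#' [lodloq()] result is supplied, raw concentrations below its LOQ are
#' flagged `below_loq`.
#'
#' @param abundance Numeric vector of integrated abundances.
#' @param curve A [fit_calibration()] result.
#' @param dilution_factor Dilution applied during sample preparation; the
#'   shipped SPE default is 2.1 (200 uL loaded, 2 x 210 uL eluted).
#' @param recovery Internal-standard recovery fraction, in `(0, 1.5]`.
#' @param limits Optional [lodloq()] result for the below-LOQ flag.
#' @param sample_id,peptide Optional identifiers carried into the output.
#' @return `data.frame`: `sample_id`, `peptide`, `abundance`, `raw`,
#'   `dilution_factor`, `recovery`, `final`, `below_loq`, `clipped`.
#'   `final / raw = dilution_factor / recovery` exactly (where `raw > 0`).
#' @export
back_calculate <- function(abundance, curve, dilution_factor = 2.1,
                           recovery = 1, limits = NULL,
                           sample_id = NA_character_, peptide = NA_character_) {
  stopifnot(inherits(curve, "calibration_curve") || !is.null(curve$slope))
  if (curve$slope == 0) stop("calibration slope is zero", call. = FALSE)
  if (any(recovery <= 0) || any(recovery > 1.5)) {
    stop("recovery must lie in (0, 1.5]", call. = FALSE)
  }
  raw <- (abundance - curve$intercept) / curve$slope
  clipped <- raw < 0
  raw_out <- pmax(raw, 0)
  below <- if (is.null(limits)) rep(NA, length(raw)) else raw_out < limits$loq
  data.frame(sample_id = sample_id, peptide = peptide,
             abundance = abundance, raw = raw_out,
             dilution_factor = dilution_factor, recovery = recovery,
             final = raw_out * dilution_factor / recovery,
             below_loq = below, clipped = clipped,
             stringsAsFactors = FALSE)
}

#' Internal-standard recovery
#'
#' Ratio of the observed to the expected abundance of the spiked isotope-
#' labelled standard; feeds the recovery correction of [back_calculate()].
#'
#' @param observed Observed abundance (`>= 0`).
#' @param expected Expected abundance (`> 0`).
#' @return Recovery fraction.
#' @export
internal_standard_recovery <- function(observed, expected) {
  if (any(expected <= 0)) stop("expected abundance must be positive",
                               call. = FALSE)
  observed / expected
}

#' Matrix-effect report
#'
#' Percent signal change of each diluted-matrix sample relative to the pure
#' control: positive values are suppression, negative enhancement. The
#' control row is zero by construction.
#'
#' @param control_abundance Abundance in the pure control (`> 0`).
#' @param sample_abundances Named numeric vector or `data.frame`
#'   (`fraction`, `abundance`) of abundances per matrix fraction.
#' @return `data.frame`: `fraction`, `abundance`, `effect_pct`, with the
#'   control (fraction 1) first.
#' @export
#' @examples
#' matrix_effect(1000, c(`0.75` = 900, `0.5` = 800)) # 10, 20 percent
matrix_effect <- function(control_abundance, sample_abundances) {
  if (!is.numeric(control_abundance) || control_abundance <= 0) {
    stop("control abundance must be positive", call. = FALSE)
  }
  if (is.data.frame(sample_abundances)) {
    fr <- sample_abundances$fraction
    ab <- sample_abundances$abundance
  } else {
    fr <- as.numeric(names(sample_abundances))
    ab <- unname(sample_abundances)
  }
  out <- data.frame(fraction = c(1, fr),
                    abundance = c(control_abundance, ab))
  out$effect_pct <- 100 * (control_abundance - out$abundance) /
    control_abundance
  out
}

#' Coefficient of variation
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation.
#'
#' @param values At least two numeric values with non-zero mean.
#' @return CV in percent.
#' @export
#' @examples
#' cv(c(8, 10, 12)) # 20
cv <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) < 2L) stop("CV needs at least two values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("CV undefined for zero mean", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Day-to-day replicability report
#'
#' Per-day mean concentrations, grand mean and the CV across day means; a
#' CV below 10 percent indicates low day-to-day variability.
#'
#' @param concentrations Measured concentrations (ug/mL).
#' @param day Day label per measurement (same length).
#' @param threshold Pass threshold on the CV (percent).
#' @return List: `day_means`, `grand_mean`, `cv_pct`, `pass`.
#' @export
replicability <- function(concentrations, day, threshold = 10) {
  stopifnot(length(concentrations) == length(day))
  day_means <- tapply(concentrations, day, mean)
  if (length(day_means) < 2L) {
    stop("replicability needs at least two days", call. = FALSE)
  }
  cvp <- cv(as.numeric(day_means))
  list(day_means = day_means, grand_mean = mean(day_means),
       cv_pct = cvp, pass = cvp < threshold)
}
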