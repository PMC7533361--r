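# PRM inclusion-list construction, fragment selection from observed spectra,
# retention-time scheduling, and the transition CSV exchange format.

#' Build a PRM inclusion list
#'
#' One transition per peptide and charge state, with the precursor m/z
#' recomputed from the sequence (label included) and the supplied fragment
#' ions attached. Peptides without a retention time are emitted unscheduled
#' (full-run window) with a warning.
#'
#' @param peptides List of [peptide()] objects.
#' @param fragments Optional `data.frame` with columns `peptide`,
#'   `fragment_label`, `fragment_mz`; rows are matched to peptides by name.
#'   `NULL` emits precursor-only entries.
#' @param rt_half_width Scheduled retention window half-width (min).
#' @param run_end Gradient end time (min) used to clip windows.
#' @return `data.frame` in the transition CSV shape (`peptide`, `sequence`,
#'   `precursor_mz`, `charge`, `fragment_label`, `fragment_mz`, `rt_min`,
#'   `window_min`), one row per fragment (or per precursor when no fragments
#'   are supplied), in deterministic order.
#' @export
#' @examples
#' build_inclusion_list(list(peptide("P1", "LQLQPFPQPQLPY", 2, rt = 6.11)))
build_inclusion_list <- function(peptides, fragments = NULL,
                                 rt_half_width = 0.5, run_end = 15.07) {
  if (!length(peptides)) {
    return(data.frame(peptide = character(), sequence = character(),
                      precursor_mz = numeric(), charge = integer(),
                      fragment_label = character(), fragment_mz = numeric(),
                      rt_min = numeric(), window_min = numeric()))
  }
  rows <- lapply(peptides, function(p) {
    stopifnot(inherits(p, "peptide"))
    if (is.na(p$rt)) {
      warning(sprintf("peptide %s has no retention time; emitted unscheduled",
                      p$name), call. = FALSE)
    }
    frg <- if (!is.null(fragments)) {
      fragments[fragments$peptide == p$name, , drop = FALSE]
    } else NULL
    do.call(rbind, lapply(sort(p$charges), function(z) {
      base <- data.frame(peptide = p$name, sequence = p$sequence,
                         precursor_mz = precursor_mz(p, z), charge = z,
                         rt_min = p$rt, window_min = rt_half_width,
                         stringsAsFactors = FALSE)
      if (is.null(frg) || !nrow(frg)) {
        base$fragment_label <- NA_character_
        base$fragment_mz <- NA_real_
        base
      } else {
        out <- base[rep(1L, nrow(frg)), , drop = FALSE]
        out$fragment_label <- frg$fragment_label
        out$fragment_mz <- frg$fragment_mz
        out
      }
    }))
  })
  out <- do.call(rbind, rows)
  out <- out[, c("peptide", "sequence", "precursor_mz", "charge",
                 "fragment_label", "fragment_mz", "rt_min", "window_min")]
  rownames(out) <- NULL
  out
}

#' Match theoretical fragment ions to an observed spectrum
#'
#' Each observed peak is assigned to the nearest theoretical ion within the
#' tolerance; equidistant candidates are broken towards the lower ordinal and
#' the tie is reported. Peaks with no candidate inside the tolerance are
#' returned unmatched.
#'
#' @param theoretical `data.frame` as produced by [fragment_table()]
#'   (columns `series`, `ordinal`, `charge`, `mz`, `label`).
#' @param observed `data.frame` with columns `mz` (ascending), `intensity`
#'   (`>= 0`).
#' @param tolerance Match tolerance, in Thomson (`unit = "mz"`, default 0.01)
#'   or parts-per-million (`unit = "ppm"`).
#' @param unit `"mz"` or `"ppm"`.
#' @return List with `matches` (one row per assigned peak: theoretical ion
#'   columns plus `obs_mz`, `intensity`, `delta`, `tie`) and `unmatched`
#'   (the unassigned peaks).
#' @export
match_ions <- function(theoretical, observed, tolerance = 0.01,
                       unit = c("mz", "ppm")) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(tolerance), tolerance > 0)
  stopifnot(all(c("mz", "intensity") %in% names(observed)))
  if (is.unsorted(observed$mz, strictly = FALSE)) {
    stop("observed m/z values must be ascending", call. = FALSE)
  }
  if (any(observed$intensity < 0)) {
    stop("observed intensities must be non-negative", call. = FALSE)
  }
  hit <- vector("list", nrow(observed))
  matched <- logical(nrow(observed))
  for (i in seq_len(nrow(observed))) {
    tol <- if (unit == "ppm") tolerance * 1e-6 * observed$mz[i] else tolerance
    d <- abs(theoretical$mz - observed$mz[i])
    cand <- which(d <= tol)
    if (!length(cand)) next
    best <- min(d[cand])
    at_best <- cand[d[cand] <= best + 1e-12]
    tie <- length(at_best) > 1L
    pick <- at_best[order(theoretical$ordinal[at_best],
                          theoretical$mz[at_best])][1L]
    row <- theoretical[pick, , drop = FALSE]
    row$obs_mz <- observed$mz[i]
    row$intensity <- observed$intensity[i]
    row$delta <- observed$mz[i] - theoretical$mz[pick]
    row$tie <- tie
    hit[[i]] <- row
    matched[i] <- TRUE
  }
  matches <- do.call(rbind, hit[matched])
  if (is.null(matches)) {
    matches <- cbind(theoretical[0, , drop = FALSE],
                     data.frame(obs_mz = numeric(), intensity = numeric(),
                                delta = numeric(), tie = logical()))
  }
  rownames(matches) <- NULL
  list(matches = matches,
       unmatched = observed[!matched, , drop = FALSE])
}

#' Select the top-k direct-sequence fragment ions
#'
#' Picks the highest-intensity matched b/y ions (a ions only when explicitly
#' allowed) for use as identifier/quantifier ions. Ties are broken
#' deterministically: higher intensity first, then lower m/z. If fewer than
#' `k` ions matched, all are returned with a warning.
#'
#' @param matches The `matches` data.frame from [match_ions()].
#' @param k Number of ions to select (the shipped method uses 4--5).
#' @param allow_a Also consider a ions.
#' @return Subset of `matches`, at most `k` rows.
#' @export
select_fragments <- function(matches, k = 5L, allow_a = FALSE) {
  stopifnot(k >= 1, k == round(k))
  keep <- matches$series %in% c("b", "y", if (allow_a) "a")
  pool <- matches[keep, , drop = FALSE]
  if (!nrow(pool)) stop("no direct-sequence ions to select from", call. = FALSE)
  pool <- pool[order(-pool$intensity, pool$mz), , drop = FALSE]
  if (nrow(pool) < k) {
    warning(sprintf("only %d matched ions available (k = %d); returning all",
                    nrow(pool), k), call. = FALSE)
    k <- nrow(pool)
  }
  out <- pool[seq_len(k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach scheduled retention windows to a transition list
#'
#' Windows are `RT +/- half_width`, clipped to `[0, run_end]`. Transitions
#' without a retention time get the full run.
#'
#' @param transitions Transition `data.frame` with an `rt_min` column.
#' @param half_width Window half-width (min), `> 0`.
#' @param run_end Gradient end (min).
#' @return The input with `window_start` and `window_end` columns added.
#' @export
#' @examples
#' schedule_windows(data.frame(peptide = "P6", rt_min = 3.48))
schedule_windows <- function(transitions, half_width = 0.5, run_end = 15.07) {
  stopifnot(half_width > 0, run_end > 0, "rt_min" %in% names(transitions))
  rt <- transitions$rt_min
  transitions$window_start <- ifelse(is.na(rt), 0, pmax(0, rt - half_width))
  transitions$window_end <- ifelse(is.na(rt), run_end,
                                   pmin(run_end, rt + half_width))
  transitions
}

#' Read / write a transition list CSV
#'
#' The de facto targeted-MS exchange shape: one row per fragment with columns
#' `peptide`, `sequence`, `precursor_mz`, `charge`, `fragment_label`,
#' `fragment_mz`, `rt_min`, `window_min`. Fragment labels are free text so
#' printed-but-unassignable ions survive a round trip unchanged.
#'
#' @param path File path.
#' @return `read_transitions()`: the transition `data.frame`.
#' @export
read_transitions <- function(path) {
  cols <- c("peptide", "sequence", "precursor_mz", "charge", "fragment_label",
            "fragment_mz", "rt_min", "window_min")
  out <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = c(peptide = "character",
                                        sequence = "character",
                                        fragment_label = "character"))
  missing <- setdiff(cols, names(out))
  if (length(missing)) {
    stop(sprintf("transition file %s lacks column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out[, cols]
}

#' @param transitions Transition `data.frame` to write.
#' @rdname read_transitions
#' @export
write_transitions <- function(transitions, path) {
  utils::write.csv(transitions, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Shipped acquisition metadata
#'
#' The chromatography gradient program and the instrument parameter set of
#' the shipped quantitative method.
#'
#' @return `default_gradient()`: `data.frame` of `time_min`, `percent_b`,
#'   `flow_ml_min`, `event`; times strictly increasing, `percent_b` in
#'   `[0, 100]`. `default_instrument()`: `data.frame` of `parameter`, `value`.
#' @export
default_gradient <- function() {
  g <- utils::read.csv(pkg_extdata("gradient.csv"), comment.char = "#",
                       stringsAsFactors = FALSE)
  stopifnot(!is.unsorted(g$time_min, strictly = TRUE),
            all(g$percent_b >= 0 & g$percent_b <= 100))
  g
}

#' @rdname default_gradient
#' @export
default_instrument <- function() {
  utils::read.csv(pkg_extdata("instrument.csv"), comment.char = "#",
                  stringsAsFactors = FALSE)
}

pkg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "glutenPRM")
  if (!nzchar(path)) stop(sprintf("shipped data file %s not found", file),
                          call. = FALSE)
  path
}
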