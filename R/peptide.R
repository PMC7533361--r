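# Peptide objects, exact mass / m/z arithmetic, composition metrics and
# epitope motif counting: the in silico MS/MS engine.

#' Describe a stable-isotope label on a single residue
#'
#' The label is placed at a 1-based position in the sequence. Its mass delta
#' is derived from the isotope substitution counts (13C, 15N) unless an
#' explicit `delta` override is given, in which case the override wins. The
#' override exists because printed transition tables sometimes imply a label
#' mass that disagrees with the stated composition.
#'
#' @param position 1-based residue index carrying the label.
#' @param c13 Number of 13C substitutions.
#' @param n15 Number of 15N substitutions.
#' @param delta Optional explicit mass delta (Da) overriding the composition.
#' @return An object of class `isotope_label`.
#' @export
#' @examples
#' isotope_label(6, c13 = 9, n15 = 1)        # 13C9,15N phenylalanine, +10.027 Da
#' isotope_label(6, c13 = 9, n15 = 1, 6.006) # explicit override wins
isotope_label <- function(position, c13 = 0, n15 = 0, delta = NULL) {
  stopifnot(is.numeric(position), length(position) == 1L, position >= 1,
            position == round(position))
  if (!is.null(delta)) stopifnot(is.numeric(delta), length(delta) == 1L)
  structure(list(position = as.integer(position), c13 = as.integer(c13),
                 n15 = as.integer(n15), delta = delta),
            class = "isotope_label")
}

#' Effective mass delta of an isotope label
#'
#' @param label An [isotope_label()], or `NULL` (returns 0).
#' @return Mass delta in Da.
#' @export
label_delta <- function(label) {
  if (is.null(label)) return(0)
  stopifnot(inherits(label, "isotope_label"))
  if (!is.null(label$delta)) return(label$delta)
  label$c13 * .CONSTANTS[["c13_delta"]] + label$n15 * .CONSTANTS[["n15_delta"]]
}

#' Construct a peptide
#'
#' @param name Peptide name (e.g. `"P1"`).
#' @param sequence One-letter amino-acid sequence; must use the 20 standard
#'   residues.
#' @param charges Integer vector of precursor charge states to monitor.
#' @param label Optional [isotope_label()] for a single heavy residue.
#' @param rt Expected retention time (min), `NA` if unscheduled.
#' @return An object of class `peptide`.
#' @export
#' @examples
#' p1 <- peptide("P1", "LQLQPFPQPQLPY", charges = 2, rt = 6.11)
#' precursor_mz(p1, 2)
peptide <- function(name, sequence, charges = 2L, label = NULL, rt = NA_real_) {
  res <- check_sequence(sequence)
  charges <- as.integer(charges)
  if (!length(charges) || anyNA(charges) || any(charges < 1L)) {
    stop("charges must be positive integers", call. = FALSE)
  }
  if (!is.null(label)) {
    stopifnot(inherits(label, "isotope_label"))
    if (label$position > length(res)) {
      stop(sprintf("label position %d exceeds sequence length %d",
                   label$position, length(res)), call. = FALSE)
    }
  }
  structure(list(name = as.character(name), sequence = sequence,
                 residues = res, charges = charges, label = label,
                 rt = as.numeric(rt)),
            class = "peptide")
}

as_peptide <- function(x) {
  if (inherits(x, "peptide")) return(x)
  if (is.character(x) && length(x) == 1L) return(peptide(x, x, charges = 1L))
  stop("expected a peptide object or a sequence string", call. = FALSE)
}

#' @export
print.peptide <- function(x, ...) {
  lab <- if (is.null(x$label)) "" else
    sprintf(" [label @%d, +%.4f Da]", x$label$position, label_delta(x$label))
  cat(sprintf("<peptide> %s  %s (%d aa)%s  z = %s  RT = %s min\n",
              x$name, x$sequence, length(x$residues), lab,
              paste(x$charges, collapse = "/"),
              ifelse(is.na(x$rt), "?", format(x$rt))))
  invisible(x)
}

#' Monoisotopic peptide mass
#'
#' Sum of monoisotopic residue masses plus one water, plus the isotope-label
#' mass delta if the peptide carries a label.
#'
#' @param x A [peptide()] or a plain sequence string.
#' @return Mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("G")               # 75.0320
#' monoisotopic_mass("LQLQPFPQPQLPY")   # 1567.840 -> printed as 1.568 kDa
monoisotopic_mass <- function(x) {
  p <- as_peptide(x)
  sum(.AA_MONO[p$residues]) + .CONSTANTS[["water_mono"]] + label_delta(p$label)
}

#' Average peptide mass
#'
#' @inheritParams monoisotopic_mass
#' @return Mass in Da. Always `>=` the monoisotopic mass.
#' @export
average_mass <- function(x) {
  p <- as_peptide(x)
  sum(.AA_AVG[p$residues]) + .CONSTANTS[["water_avg"]] + label_delta(p$label)
}

#' Precursor m/z
#'
#' `(M + z * proton) / z` with the monoisotopic mass `M` (label included).
#'
#' @inheritParams monoisotopic_mass
#' @param charge Positive integer charge state (vectorised).
#' @return m/z in Thomson.
#' @export
#' @examples
#' precursor_mz(peptide("P1", "LQLQPFPQPQLPY"), 2) # 784.927
precursor_mz <- function(x, charge) {
  charge <- as.numeric(charge)
  if (!length(charge) || anyNA(charge) || any(charge < 1) ||
      any(charge != round(charge))) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  (monoisotopic_mass(x) + charge * .CONSTANTS[["proton"]]) / charge
}

#' Fragment-ion m/z (b, y and a series)
#'
#' b ions are N-terminal prefixes plus a proton; y ions are C-terminal
#' suffixes plus water and a proton; a ions are b ions minus CO. A single
#' isotope label contributes its mass delta to exactly the fragments that
#' contain the labeled residue.
#'
#' @inheritParams monoisotopic_mass
#' @param series One of `"b"`, `"y"`, `"a"`.
#' @param ordinal Fragment ordinal, `1 <= ordinal < length(sequence)`.
#' @param charge Positive integer fragment charge.
#' @return m/z in Thomson.
#' @export
#' @examples
#' p1 <- peptide("P1", "LQLQPFPQPQLPY")
#' fragment_mz(p1, "y", 2) # 279.134
#' fragment_mz(p1, "b", 4) # 483.293
fragment_mz <- function(x, series = c("b", "y", "a"), ordinal, charge = 1L) {
  series <- match.arg(series)
  p <- as_peptide(x)
  n <- length(p$residues)
  stopifnot(is.numeric(ordinal), length(ordinal) == 1L)
  if (ordinal < 1 || ordinal >= n || ordinal != round(ordinal)) {
    stop(sprintf("ordinal must be in 1..%d for a %d-residue peptide",
                 n - 1L, n), call. = FALSE)
  }
  if (charge < 1 || charge != round(charge)) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  delta <- label_delta(p$label)
  pos <- if (is.null(p$label)) 0L else p$label$position
  pr <- .CONSTANTS[["proton"]]
  if (series %in% c("b", "a")) {
    neutral <- sum(.AA_MONO[p$residues[seq_len(ordinal)]]) +
      if (pos >= 1L && pos <= ordinal) delta else 0
    mz <- (neutral + charge * pr) / charge
    if (series == "a") mz <- mz - .CONSTANTS[["co"]] / charge
  } else {
    neutral <- sum(.AA_MONO[p$residues[(n - ordinal + 1L):n]]) +
      .CONSTANTS[["water_mono"]] +
      if (pos > n - ordinal) delta else 0
    mz <- (neutral + charge * pr) / charge
  }
  mz
}

#' Full in silico fragment table
#'
#' All a, b and y ions for ordinals `1..n-1` and charges `1..max_charge`,
#' ordered deterministically by series (a, b, y), ordinal, charge.
#'
#' @inheritParams monoisotopic_mass
#' @param max_charge Highest fragment charge to tabulate.
#' @return `data.frame` with columns `series`, `ordinal`, `charge`, `mz`,
#'   `label` (e.g. `"y2"`).
#' @export
fragment_table <- function(x, max_charge = 1L) {
  p <- as_peptide(x)
  stopifnot(max_charge >= 1, max_charge == round(max_charge))
  n <- length(p$residues)
  grid <- expand.grid(charge = seq_len(max_charge), ordinal = seq_len(n - 1L),
                      series = c("a", "b", "y"), stringsAsFactors = FALSE)
  grid <- grid[, c("series", "ordinal", "charge")]
  grid$mz <- mapply(function(s, o, z) fragment_mz(p, s, o, z),
                    grid$series, grid$ordinal, grid$charge)
  grid$label <- sprintf("%s%d", grid$series, grid$ordinal)
  rownames(grid) <- NULL
  grid
}

#' Percent proline of a sequence
#'
#' @inheritParams monoisotopic_mass
#' @return Percent proline, rounded to one decimal as conventionally reported.
#' @export
#' @examples
#' proline_percent("LQLQPFPQPQLPY") # 30.8
proline_percent <- function(x) {
  p <- as_peptide(x)
  round(100 * sum(p$residues == "P") / length(p$residues), 1)
}

#' Count (possibly overlapping) motif occurrences
#'
#' Exact substring matches with shift-by-one overlap, as required to
#' reproduce epitope multiplicities in proline/glutamine-rich repeats.
#'
#' @param sequence Sequence string (or [peptide()]).
#' @param motif Non-empty motif string.
#' @return Integer count.
#' @export
#' @examples
#' count_motif("AAAA", "AA") # 3
count_motif <- function(sequence, motif) {
  p <- as_peptide(sequence)
  if (!is.character(motif) || length(motif) != 1L || !nzchar(motif)) {
    stop("motif must be a non-empty string", call. = FALSE)
  }
  n <- nchar(p$sequence); m <- nchar(motif)
  if (m > n) return(0L)
  starts <- seq_len(n - m + 1L)
  sum(vapply(starts, function(i) substr(p$sequence, i, i + m - 1L) == motif,
             logical(1)))
}

#' Epitope-core occurrence table
#'
#' Counts every epitope core motif in every peptide (overlapping matches).
#'
#' @param peptides Named list of [peptide()]s; default the shipped set.
#' @param epitopes `data.frame` with columns `epitope`, `core`; default the
#'   shipped DQ2.5 glia-alpha cores.
#' @return Integer matrix, peptides x epitopes.
#' @export
epitope_counts <- function(peptides = default_peptides(),
                           epitopes = default_epitopes()) {
  out <- sapply(epitopes$core, function(core)
    vapply(peptides, count_motif, integer(1), motif = core))
  out <- matrix(as.integer(out), nrow = length(peptides),
                dimnames = list(names(peptides), epitopes$epitope))
  out
}
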