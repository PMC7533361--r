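# Residue mass tables and physical constants used throughout.
# Monoisotopic values are for the neutral residue (amino acid minus water).

.AA_MONO <- c(
  A =  71.037114, R = 156.101111, N = 114.042927, D = 115.026943,
  C = 103.009185, E = 129.042593, Q = 128.058578, G =  57.021464,
  H = 137.058912, I = 113.084064, L = 113.084064, K = 128.094963,
  M = 131.040485, F = 147.068414, P =  97.052764, S =  87.032028,
  T = 101.047679, W = 186.079313, Y = 163.063329, V =  99.068414
)

.AA_AVG <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
  C = 103.1388, E = 129.1155, Q = 128.1307, G =  57.0519,
  H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
  M = 131.1926, F = 147.1766, P =  97.1167, S =  87.0782,
  T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326
)

.CONSTANTS <- c(
  water_mono = 18.010565,    # H2O, monoisotopic
  water_avg  = 18.01528,     # H2O, average
  proton     = 1.007276467,  # charge carrier in positive-mode ESI
  co         = 27.994915,    # carbon monoxide (b -> a ion loss)
  c13_delta  = 1.0033548,    # 13C - 12C
  n15_delta  = 0.9970349     # 15N - 14N
)

#' Amino-acid residue mass table
#'
#' Residue (not free amino acid) masses for the 20 standard amino acids, as
#' used for peptide and fragment-ion m/z arithmetic.
#'
#' @param type `"monoisotopic"` (default) or `"average"`.
#' @return Named numeric vector, one entry per one-letter residue code (Da).
#' @seealso [mass_constants()]
#' @export
#' @examples
#' aa_mass_table()[["G"]] # glycine residue, 57.021464
aa_mass_table <- function(type = c("monoisotopic", "average")) {
  type <- match.arg(type)
  if (type == "monoisotopic") .AA_MONO else .AA_AVG
}

#' Physical constants for mass spectrometry arithmetic
#'
#' @return Named numeric vector (Da): monoisotopic and average water mass,
#'   proton mass, carbon-monoxide mass (the b-to-a ion loss), and the
#'   13C-12C and 15N-14N isotope mass differences.
#' @export
mass_constants <- function() .CONSTANTS

# Split a sequence into residues, failing with the offending position.
check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      !nzchar(sequence)) {
    stop("sequence must be a single non-empty string", call. = FALSE)
  }
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!res %in% names(.AA_MONO))
  if (length(bad)) {
    stop(sprintf("unknown residue '%s' at position %d of '%s'",
                 res[bad[1]], bad[1], sequence), call. = FALSE)
  }
  res
}
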