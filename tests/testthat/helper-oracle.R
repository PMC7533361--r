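# Independent brute-force oracles. These deliberately re-derive everything
# from their own residue mass table (ExPASy values, 4-5 decimals) and simple
# character-by-character loops, sharing no code with the package.

ORACLE_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
ORACLE_WATER <- 18.010565
ORACLE_PROTON <- 1.00728
ORACLE_CO <- 27.99491

oracle_residues <- function(seq) strsplit(seq, "")[[1]]

oracle_mono_mass <- function(seq, delta = 0) {
  total <- ORACLE_WATER + delta
  for (ch in oracle_residues(seq)) total <- total + ORACLE_MONO[[ch]]
  total
}

oracle_precursor <- function(seq, z, delta = 0) {
  (oracle_mono_mass(seq, delta) + z * ORACLE_PROTON) / z
}

oracle_fragment <- function(seq, series, i, z = 1, label_pos = 0, delta = 0) {
  res <- oracle_residues(seq)
  n <- length(res)
  if (series %in% c("b", "a")) {
    s <- 0
    for (k in 1:i) s <- s + ORACLE_MONO[[res[k]]]
    if (label_pos >= 1 && label_pos <= i) s <- s + delta
    mz <- (s + z * ORACLE_PROTON) / z
    if (series == "a") mz <- mz - ORACLE_CO / z
  } else {
    s <- ORACLE_WATER
    for (k in (n - i + 1):n) s <- s + ORACLE_MONO[[res[k]]]
    if (label_pos > n - i) s <- s + delta
    mz <- (s + z * ORACLE_PROTON) / z
  }
  mz
}

# random peptide sequences for property tests (fixed RNG state per call site)
random_sequence <- function(len) {
  paste(sample(names(ORACLE_MONO), len, replace = TRUE), collapse = "")
}

# normal-equations least squares: solve X'X beta = X'y directly
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- X %*% beta
  list(intercept = beta[1], slope = beta[2], rss = sum((y - fitted)^2))
}

# closed-form Gaussian peak area over an infinite window
oracle_gauss_area <- function(slope, concentration, intercept) {
  slope * concentration + intercept
}
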