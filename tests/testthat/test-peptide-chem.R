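# Peptide and fragment-ion mass arithmetic, composition metrics, motifs.

P1_SEQ <- "LQLQPFPQPQLPY"
P5_SEQ <- "LQLQPFPQPQLPYPQPQLPYPQPQLPYPQPQPF"

test_that("monoisotopic and average masses reproduce hand sums and printed kDa", {
  expect_equal(monoisotopic_mass("G"), 75.0320, tolerance = 1e-3 / 75)
  expect_equal(average_mass("G"), 75.07, tolerance = 0.01 / 75)
  # P1 printed as 1.568 kDa (monoisotopic); P5 kDa column matches average mass
  expect_equal(monoisotopic_mass(P1_SEQ), 1567.840, tolerance = 0.01 / 1568)
  expect_lt(abs(average_mass(P5_SEQ) / 1000 - 3.912), 0.004)
  # label delta enters the peptide mass
  p1h <- peptide("P1H", P1_SEQ, label = isotope_label(6, 9, 1))
  expect_equal(monoisotopic_mass(p1h) - monoisotopic_mass(P1_SEQ),
               9 * 1.0033548 + 0.9970349, tolerance = 1e-9)
})

test_that("invalid sequences are rejected with the offending position", {
  expect_error(monoisotopic_mass(""), "non-empty")
  expect_error(peptide("bad", "LQXZ"), "'X' at position 3")
  expect_error(peptide("bad", "LQLB"), "position 4")
})

test_that("average mass dominates monoisotopic mass on random sequences", {
  set.seed(42)
  for (i in 1:25) {
    s <- random_sequence(sample(2:40, 1))
    expect_gte(average_mass(s), monoisotopic_mass(s))
  }
})

test_that("precursor m/z matches printed values and is monotone in charge", {
  p1 <- peptide("P1", P1_SEQ, charges = 2)
  expect_equal(precursor_mz(p1, 2), 784.927, tolerance = 0.005 / 785)
  expect_equal(precursor_mz(P5_SEQ, 4), 978.264, tolerance = 0.005 / 978)
  mz <- precursor_mz(p1, 1:3)
  expect_true(all(diff(mz) < 0))
  # neutral mass recovered from any charge state
  neutral <- mz * (1:3) - (1:3) * mass_constants()[["proton"]]
  expect_lt(max(neutral) - min(neutral), 1e-6)
  expect_error(precursor_mz(p1, 0), "positive integer")
  expect_error(precursor_mz(p1, -2), "positive integer")
})

test_that("fragment m/z reproduces printed and hand-computed ions", {
  p1 <- peptide("P1", P1_SEQ)
  expect_equal(fragment_mz(p1, "y", 2), 279.134, tolerance = 0.005 / 279)
  expect_equal(fragment_mz(p1, "b", 4), 483.293, tolerance = 0.005 / 483)
  # hand sum for the LQ prefix: 113.084064 + 128.058578 + proton
  expect_equal(fragment_mz(peptide("x", "LQA"), "b", 2), 242.150,
               tolerance = 1e-3 / 242)
  # a = b - CO at any charge
  p6 <- peptide("P6", "RPQQPYPQPQPQY")
  expect_equal(fragment_mz(p6, "a", 8),
               fragment_mz(p6, "b", 8) - 27.995, tolerance = 1e-3 / 968)
  expect_equal(fragment_mz(p6, "a", 8, 2),
               fragment_mz(p6, "b", 8, 2) - 27.994915 / 2, tolerance = 1e-9)
  expect_error(fragment_mz(p1, "b", 13), "ordinal")
  expect_error(fragment_mz(p1, "y", 0), "ordinal")
})

test_that("isotope label lands in exactly the fragments containing residue 6", {
  delta <- 6.006
  p1 <- peptide("P1", P1_SEQ)
  p1h <- peptide("P1H", P1_SEQ, label = isotope_label(6, 9, 1, delta = delta))
  n <- nchar(P1_SEQ)
  for (i in 1:(n - 1)) {
    b_shift <- fragment_mz(p1h, "b", i) - fragment_mz(p1, "b", i)
    y_shift <- fragment_mz(p1h, "y", i) - fragment_mz(p1, "y", i)
    expect_equal(b_shift, if (i >= 6) delta else 0, tolerance = 1e-12)
    expect_equal(y_shift, if (i > n - 6) delta else 0, tolerance = 1e-12)
  }
})

test_that("fragment_table enumerates all ions with the pair invariant", {
  p1 <- peptide("P1", P1_SEQ)
  tab <- fragment_table(p1, max_charge = 1)
  expect_equal(nrow(tab), 36) # 12 b + 12 y + 12 a
  expect_equal(tab, tab[order(tab$series, tab$ordinal, tab$charge), ],
               ignore_attr = TRUE)
  m <- monoisotopic_mass(p1)
  pr <- mass_constants()[["proton"]]
  n <- nchar(P1_SEQ)
  b <- tab$mz[tab$series == "b"]
  y <- tab$mz[tab$series == "y"]
  expect_equal(b[1:(n - 1)] + y[(n - 1):1], rep(m + 2 * pr, n - 1),
               tolerance = 1e-4 / m)
})

test_that("fragments and precursors agree with the brute-force oracle", {
  set.seed(7)
  for (rep in 1:20) {
    s <- random_sequence(sample(2:40, 1))
    n <- nchar(s)
    z <- sample(1:3, 1)
    # absolute tolerance: the oracle's table is 5-decimal, so agreement is
    # bounded by ~5e-6 Da per residue
    expect_lt(abs(precursor_mz(s, z) - oracle_precursor(s, z)), 5e-4)
    i <- sample(seq_len(n - 1), 1)
    for (series in c("b", "y", "a")) {
      expect_lt(abs(fragment_mz(peptide(s, s), series, i, z) -
                      oracle_fragment(s, series, i, z)), 5e-4)
    }
  }
})

test_that("proline percent matches the marker-peptide table", {
  expect_identical(proline_percent(P1_SEQ), 30.8)
  expect_identical(proline_percent(P5_SEQ), 39.4)
  expect_identical(proline_percent("PPPP"), 100)
  expect_identical(proline_percent("LQLQPFPQPQLPYPQPHLPYPQPQPF"), 38.5)
  for (s in c(P1_SEQ, P5_SEQ, "G", "PPPP")) {
    expect_gte(proline_percent(s), 0)
    expect_lte(proline_percent(s), 100)
  }
})

test_that("overlapping motif counting reproduces epitope multiplicities", {
  expect_identical(count_motif(P5_SEQ, "PQPQLPYPQ"), 3L) # glia-a2 x3
  expect_identical(count_motif(P5_SEQ, "PYPQPQLPY"), 2L) # glia-a1b x2
  expect_identical(count_motif("AAAA", "AA"), 3L)
  expect_identical(count_motif("LQ", "LQLQ"), 0L)
  expect_error(count_motif("LQ", ""), "non-empty")
  # bounds: 0 <= count <= n - m + 1
  set.seed(11)
  for (i in 1:10) {
    s <- random_sequence(sample(5:30, 1))
    motif <- substr(s, 1, 3)
    cnt <- count_motif(s, motif)
    expect_gte(cnt, 1L)
    expect_lte(cnt, nchar(s) - 2L)
  }
})

test_that("the shipped epitope cores reproduce the full multiplicity table", {
  counts <- epitope_counts()
  expected <- rbind(
    P1  = c(1, 0, 0, 0), P1H = c(1, 0, 0, 0), P2 = c(1, 0, 1, 0),
    P3  = c(1, 0, 1, 0), P4  = c(1, 1, 2, 0), P5 = c(1, 2, 3, 0),
    P6  = c(0, 0, 0, 1))
  colnames(expected) <- c("DQ2.5-glia-a1a", "DQ2.5-glia-a1b",
                          "DQ2.5-glia-a2", "DQ2.5-glia-a3")
  expect_equal(counts[rownames(expected), colnames(expected)],
               expected, ignore_attr = FALSE)
})
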