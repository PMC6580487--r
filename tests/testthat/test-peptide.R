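test_that("parse_sequence canonicalizes and counts cysteines", {
  p <- parse_sequence("ACDCK")
  expect_equal(p$sequence, "ACDCK")
  expect_equal(p$n_cys, 2L)
  expect_equal(p$n_disulfides, 1L)
  expect_equal(parse_sequence("GGGGG")$n_cys, 0L)
  expect_equal(parse_sequence(" ac dK\n")$sequence, "ACDK")
  expect_equal(parse_sequence("CCCCC")$n_disulfides, 2L)  # odd count
  expect_error(parse_sequence("ACXDK"), "'X'")
  expect_error(parse_sequence("AUK"), "selenocysteine")
  expect_error(parse_sequence(""), "empty")
})

test_that("masses match the atomic-composition oracle", {
  expect_equal(monoisotopic_mass("G"), 75.03203, tolerance = 1e-4)
  expect_equal(average_mass("G"), 75.067, tolerance = 5e-3)
  expect_equal(monoisotopic_mass("CC"),
               monoisotopic_mass("CC", n_disulfides = 0) - 2.01565,
               tolerance = 1e-4)
  # cysteine-free peptides need no correction
  expect_identical(monoisotopic_mass("GAVLK"),
                   monoisotopic_mass("GAVLK", n_disulfides = 0))

  set.seed(301)
  for (i in 1:200) {
    s <- random_peptide()
    expect_equal(monoisotopic_mass(s), oracle_mass(s, "mono"),
                 tolerance = 1e-4)
    expect_equal(average_mass(s), oracle_mass(s, "avg"),
                 tolerance = 5e-3)
    expect_gte(average_mass(s), monoisotopic_mass(s))
  }
})

test_that("the disulfide correction is exactly -2 n m_H for both masses", {
  m_h_mono <- cdp_constants()$element_mono[["H"]]
  m_h_avg <- cdp_constants()$element_avg[["H"]]
  for (s in c("CC", "CCCC", "ACCDCCK")) {
    n <- parse_sequence(s)$n_disulfides
    expect_equal(monoisotopic_mass(s),
                 monoisotopic_mass(s, n_disulfides = 0) - 2 * n * m_h_mono,
                 tolerance = 1e-12)
    expect_equal(average_mass(s),
                 average_mass(s, n_disulfides = 0) - 2 * n * m_h_avg,
                 tolerance = 1e-12)
  }
})

test_that("net charge follows Henderson-Hasselbalch arithmetic", {
  pka <- cdp_constants()$pka_tables$emboss
  # "GG" has only the two termini: hand-computed two-term sum
  for (ph in c(3.6, 7.4, 8.6)) {
    oracle <- 1 / (1 + 10^(ph - pka[["Nterm"]])) -
      1 / (1 + 10^(pka[["Cterm"]] - ph))
    expect_equal(net_charge("GG", ph = ph), oracle, tolerance = 1e-6)
  }
  # a single group evaluated at its own pKa contributes exactly +/- 0.5
  q_at <- net_charge("GG", ph = pka[["Nterm"]])
  base <- -1 / (1 + 10^(pka[["Cterm"]] - pka[["Nterm"]]))
  expect_equal(q_at - base, 0.5, tolerance = 1e-12)
  q_ct <- net_charge("GG", ph = pka[["Cterm"]])
  expect_equal(q_ct - 1 / (1 + 10^(pka[["Cterm"]] - pka[["Nterm"]])), -0.5,
               tolerance = 1e-12)

  # disulfide-engaged cysteines are excluded from the acidic set: a fully
  # bonded CC pair ionizes like a non-ionizable pair, a lone C does not
  expect_equal(net_charge("GCCG", ph = 10), net_charge("GAAG", ph = 10),
               tolerance = 1e-12)
  expect_lt(net_charge("GCG", ph = 10), net_charge("GAG", ph = 10))

  expect_error(net_charge("GG", pka_table = "nope"), "unknown pKa")
  expect_error(net_charge("GG", ph = 0), "ph")
})

test_that("net charge is strictly decreasing in pH and has the right limits", {
  set.seed(302)
  grid <- seq(1, 13, by = 0.5)
  for (i in 1:20) {
    s <- random_peptide()
    q <- vapply(grid, function(p) net_charge(s, ph = p), numeric(1))
    expect_true(all(diff(q) < 0))
    chars <- strsplit(s, "")[[1]]
    p <- parse_sequence(s)
    q_lo <- net_charge(s, ph = 0.5)
    q_hi <- net_charge(s, ph = 13.5)
    expect_equal(q_lo, 1 + sum(chars %in% c("K", "R", "H")),
                 tolerance = 0.2)
    free_c <- p$n_cys - 2 * p$n_disulfides
    expect_equal(q_hi,
                 -(1 + sum(chars %in% c("D", "E", "Y")) + free_c),
                 tolerance = 0.2)
  }
})

test_that("hydrophobicity is the mean Kyte-Doolittle scale value", {
  kd <- cdp_constants()$hydro_scales$kyte_doolittle
  expect_identical(hydrophobicity("I"), kd[["I"]])
  expect_identical(hydrophobicity("GG"), kd[["G"]])
  set.seed(303)
  for (i in 1:20) {
    a <- random_peptide()
    b <- random_peptide()
    expect_equal(hydrophobicity(paste0(a, b)),
                 (nchar(a) * hydrophobicity(a) +
                    nchar(b) * hydrophobicity(b)) / (nchar(a) + nchar(b)),
                 tolerance = 1e-12)
  }
  expect_error(hydrophobicity("GG", scale = "nope"), "unknown")
})

test_that("m/z validation round-trips all charge states", {
  s <- "ACDEFGHIKCMNPQRSTVWY"
  for (z in 1:6) {
    hit <- validate_mz(theoretical_mz(s, z), s, max_charge = 6)
    expect_true(hit$valid)
    expect_equal(hit$matched_charge, z)
  }
  # z = 1 is the mass plus one proton
  expect_equal(theoretical_mz(s, 1), monoisotopic_mass(s) + 1.00728,
               tolerance = 1e-4)
  # out of band by 10x the tolerance
  mz <- theoretical_mz(s, 2)
  off <- validate_mz(mz * (1 + 10 * 20e-6), s, max_charge = 6,
                     tol_ppm = 20)
  expect_false(off$valid)
  expect_true(is.na(off$matched_charge))
  expect_error(validate_mz(-5, s), "observed_mz")
})

test_that("duplicate detection is canonical and order-aware", {
  rep1 <- find_duplicates("ACD", registry = "ACD")
  expect_equal(sum(rep1$duplicate), 1L)
  expect_equal(rep1$duplicate_of, "registry")
  rep2 <- find_duplicates(c("ACD", "ACD"))
  expect_equal(rep2$duplicate, c(FALSE, TRUE))
  expect_equal(rep2$duplicate_of[2], "batch")
  rep3 <- find_duplicates("acd", registry = "ACD")
  expect_true(rep3$duplicate)
  expect_equal(find_duplicates(c("AAA", "CCC"))$duplicate, c(FALSE, FALSE))
})

test_that("peptide_properties tabulates values and tolerates bad records", {
  props <- peptide_properties(c(a = "ACDCK", b = "ACXDK", c = "GGGG",
                                d = "acdck"))
  expect_equal(nrow(props), 4L)
  expect_true(is.na(props$average_mass[2]))
  expect_match(props$error[2], "'X'")
  expect_equal(props$monoisotopic_mass[1], oracle_mass("ACDCK", "mono"),
               tolerance = 1e-4)
  expect_true(props$duplicate[4])  # case-insensitive duplicate of row 1
  expect_false(props$duplicate[1])
})

test_that("FASTA batches are read and propertied", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "ACDCK", ">p2", "GGGG"), f)
  seqs <- read_fasta_sequences(f)
  expect_equal(unname(seqs), c("ACDCK", "GGGG"))
  expect_equal(names(seqs), c("p1", "p2"))
  props <- peptide_properties(seqs)
  expect_equal(props$id, c("p1", "p2"))
})
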