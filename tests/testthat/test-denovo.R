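test_that("consensus calling emits residues for unique mass differences", {
  mc <- list(contig_id = "c",
             consensus = data.frame(mass = c(97.05276, 194.10552, 309.13246),
                                    score = 1),
             M = 426.21652)
  dn <- sequence_consensus(mc)
  expect_equal(dn$elements$kind, c("residue", "residue", "residue", "gap"))
  expect_equal(dn$elements$letter[1:3], c("P", "P", "D"))
  # final difference 117.084 matches no single residue within 0.02
  expect_equal(dn$elements$mass[4], 117.08406, tolerance = 1e-4)

  # a full ideal ladder reads back the peptide
  lad <- prefix_masses("PEPTIDE")
  dn2 <- sequence_consensus(list(contig_id = "c2",
                                 consensus = data.frame(mass = lad, score = 1),
                                 M = sum(metaspec::residue_masses()[
                                   strsplit("PEPTIDE", "")[[1]]])))
  expect_equal(format_denovo_string(dn2), "PEPTIDE")

  # single mass: 114.043 is uniquely asparagine among single residues
  dn3 <- sequence_consensus(list(contig_id = "c3",
                                 consensus = data.frame(mass = 114.043,
                                                        score = 1),
                                 M = 114.043 + 99.06841))
  expect_equal(dn3$elements$letter[1], "N")
  expect_error(sequence_consensus(list(contig_id = "x",
                                       consensus = data.frame(
                                         mass = c(200, 100), score = 1),
                                       M = 300)), "increasing")
})

test_that("K and Q are split by the default tolerance but not looser ones", {
  mk <- function(d) list(contig_id = "c",
                         consensus = data.frame(mass = d, score = 1),
                         M = d + 99.06841)
  expect_equal(sequence_consensus(mk(128.09496))$elements$letter[1], "K")
  expect_equal(sequence_consensus(mk(128.05858))$elements$letter[1], "Q")
  loose <- sequence_consensus(mk(128.09496), call_tol = 0.05)
  expect_equal(loose$elements$kind[1], "gap")   # K and Q both qualify
  # I/L isobars report as I
  expect_equal(sequence_consensus(mk(113.08406))$elements$letter[1], "I")
})

test_that("the gapped-string grammar parses and formats verbatim", {
  s <- "[168.09]PDATIVY[128.106]"
  dn <- parse_denovo_string(s)
  expect_equal(dn$elements$kind,
               c("gap", rep("residue", 7), "gap"))
  expect_equal(dn$elements$letter[2:8],
               c("P", "D", "A", "T", "I", "V", "Y"))
  expect_equal(dn$elements$mass[c(1, 9)], c(168.09, 128.106))
  expect_equal(format_denovo_string(dn), s)

  all_res <- parse_denovo_string("GNMFSCWSTVGMR")
  expect_equal(n_residues(all_res), 13)
  expect_equal(n_gaps(all_res), 0)
  expect_equal(format_denovo_string(all_res), "GNMFSCWSTVGMR")

  # formatting rule: 3 decimals, trailing zeros trimmed
  g <- parse_denovo_string("A")
  g$elements <- rbind(g$elements, data.frame(
    kind = "gap", letter = NA_character_, mass = 212.0797,
    label = NA_character_, confidence = NA_real_))
  expect_equal(format_denovo_string(g), "A[212.08]")

  expect_error(parse_denovo_string(""), "position 1")
  expect_error(parse_denovo_string("AB[12.3]"), "illegal letter")
  expect_error(parse_denovo_string("A[12.3"), "unbalanced")
  expect_error(parse_denovo_string("A12]"), "unbalanced|illegal")
  expect_error(parse_denovo_string("A[x]"), "non-numeric")
})

test_that("the published-notation corpus round-trips exactly", {
  corpus <- readLines(corpus_path())
  expect_gt(length(corpus), 150)
  for (s in corpus) {
    dn <- parse_denovo_string(s)
    expect_identical(format_denovo_string(dn), s)
    dn2 <- parse_denovo_string(format_denovo_string(dn))
    expect_identical(dn2$elements$kind, dn$elements$kind)
    expect_identical(dn2$elements$letter, dn$elements$letter)
    expect_equal(dn2$elements$mass, dn$elements$mass)
  }
})

test_that("consensus element masses conserve the precursor mass", {
  set.seed(61)
  for (i in 1:20) {
    pep <- random_peptide(sample(6:15, 1))
    lad <- prefix_masses(pep)
    keep <- sort(sample(length(lad), max(2, length(lad) - 3)))
    M <- sum(residue_masses()[strsplit(pep, "")[[1]]])
    dn <- sequence_consensus(list(contig_id = "c",
                                  consensus = data.frame(mass = lad[keep],
                                                         score = 1),
                                  M = M))
    expect_equal(denovo_mass(dn), M,
                 tolerance = nrow(dn$elements) * 0.02)
  }
})

test_that("noiseless complete ladders yield gap-free exact calls", {
  set.seed(63)
  for (i in 1:10) {
    pep <- random_peptide(sample(7:16, 1))
    mc <- list(contig_id = "c",
               consensus = data.frame(mass = prefix_masses(pep), score = 1),
               M = sum(residue_masses()[strsplit(pep, "")[[1]]]))
    dn <- sequence_consensus(mc)
    expect_equal(n_gaps(dn), 0)
    expect_equal(format_denovo_string(dn), gsub("L", "I", pep))
  }
})

test_that("gap compositions enumerate qualifying residue multisets", {
  comps <- gap_compositions(114.043, tol = 0.01)
  expect_setequal(vapply(comps, paste, character(1), collapse = ""),
                  c("N", "GG"))
  expect_equal(gap_compositions(57.0215, tol = 0.01), list("G"))
  expect_length(gap_compositions(10.0, tol = 0.01), 0)
})

test_that("gap composition enumeration matches an independent oracle", {
  set.seed(67)
  for (i in 1:20) {
    mass <- runif(1, 50, 600)
    got <- gap_compositions(mass, tol = 0.02, max_residues = 5)
    want <- oracle_gap_comps(mass, tol = 0.02, max_residues = 5)
    key <- function(l) sort(vapply(l, paste, character(1), collapse = ""))
    expect_equal(key(got), key(want))
  }
})
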