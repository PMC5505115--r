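test_that("generate_proteome is seeded, bounded and near-uniform", {
  a <- generate_proteome(10, c(60, 200), seed = 42)
  b <- generate_proteome(10, c(60, 200), seed = 42)
  expect_identical(a, b)
  lens <- nchar(a$sequence)
  expect_true(all(lens >= 60 & lens <= 200))
  expect_error(generate_proteome(3, c(2, 10)), "len_range")

  # residue frequencies of ~10,000 residues consistent with uniform
  big <- generate_proteome(80, c(120, 130), seed = 99)
  res <- table(factor(strsplit(paste(big$sequence, collapse = ""), "")[[1]],
                      levels = names(residue_masses())))
  expect_gt(chisq.test(res)$p.value, 0.01)
})

test_that("fractionate partitions by residue-mass sum plus water", {
  g200 <- paste(rep("G", 200), collapse = "")   # ~11,422 Da
  recs <- data.frame(accession = c("A", "B"), description = "",
                     sequence = c(g200, "GGGG"), stringsAsFactors = FALSE)
  fr <- fractionate(recs, 10000)
  expect_equal(fr$above$accession, "A")
  expect_equal(fr$below$accession, "B")
  expect_equal(nrow(fr$above) + nrow(fr$below), nrow(recs))
  empty <- fractionate(recs[0, ], 10000)
  expect_equal(nrow(empty$above) + nrow(empty$below), 0)
})

test_that("deterministic digestion applies the cleavage rule", {
  tryp <- digest_spec(standard_protease("trypsin"), max_missed = 0,
                      len_min = 4L, len_max = 50L)
  out <- digest("AKRPGKR", tryp)
  expect_equal(out$peptide, "RPGK")   # AK and R fail the length filter
  tryp2 <- digest_spec(standard_protease("trypsin"), max_missed = 0,
                       len_min = 4L, len_max = 50L)
  tryp2$len_min <- 2L                 # relaxed: AK retained as well
  out2 <- digest("AKRPGKR", tryp2)
  expect_setequal(out2$peptide, c("AK", "RPGK"))
  expect_equal(out2$start[out2$peptide == "RPGK"], 2)
  expect_error(digest("AKZ", tryp), "unknown residue")
})

test_that("stochastic digestion limits match deterministic enumeration", {
  seqn <- "MKAVLRPTIDKWERGHKLMNPQR"
  spec1 <- digest_spec(standard_protease("trypsin"), p_cleave = 1,
                       max_missed = 0, len_min = 4L, len_max = 60L)
  expect_equal(digest(seqn, spec1, seed = 5)$peptide,
               digest(seqn, spec1, seed = NULL)$peptide)
  spec0 <- digest_spec(standard_protease("trypsin"), p_cleave = 0,
                       len_min = 4L, len_max = 100L)
  expect_equal(digest(seqn, spec0, seed = 5)$peptide, seqn)
})

test_that("zero-missed-cleavage products tile the protein", {
  set.seed(3)
  for (enz in c("trypsin", "chymotrypsin", "pepsin")) {
    seqn <- random_peptide(80)
    sp <- digest_spec(standard_protease(enz), max_missed = 0)
    sp$len_min <- 1L; sp$len_max <- 1000L
    out <- digest(seqn, sp, seed = NULL)
    expect_equal(paste(out$peptide[order(out$start)], collapse = ""), seqn)
  }
})

test_that("theoretical ion masses follow standard fragment arithmetic", {
  cid <- theoretical_ions("AG", "CID")
  b1 <- cid[cid$series == "b" & cid$cut == 1, ]
  y1 <- cid[cid$series == "y" & cid$cut == 1, ]
  expect_equal(b1$mz, 72.04439, tolerance = 1e-5)
  expect_equal(y1$mz, 76.03930, tolerance = 1e-5)
  expect_equal(nrow(theoretical_ions("G", "CID")), 0)
  # fixed carbamidomethyl on cysteine
  bC <- theoretical_ions("CG", "CID")
  expect_equal(bC$mz[bC$series == "b"],
               103.00919 + 57.02146 + 1.007276, tolerance = 1e-5)
  # ETD c/z offsets
  etd <- theoretical_ions("AG", "ETD")
  expect_equal(etd$mz[etd$series == "c"],
               71.03711 + 17.02655 + 1.007276, tolerance = 1e-5)
})

test_that("b/y complementarity holds exactly for random peptides", {
  set.seed(17)
  for (i in 1:50) {
    pep <- random_peptide(sample(5:20, 1))
    th <- theoretical_ions(pep, "CID")
    n <- nchar(pep)
    b <- th[th$series == "b", ]; y <- th[th$series == "y", ]
    bk <- b$mz[order(b$cut)] - mass_constants()[["proton"]]
    ynk <- y$mz[order(y$cut)] - mass_constants()[["proton"]]
    expect_equal(bk + ynk, rep(peptide_mass(pep), n - 1), tolerance = 1e-9)
  }
})

test_that("simulate_triple noiseless preset reproduces theory and is seeded", {
  tr <- simulate_triple("PEPTIDEK", charge = 2L,
                        model = fragmentation_model(noiseless = TRUE))
  for (mode in c("CID", "HCD", "ETD")) {
    s <- tr[[tolower(mode)]]
    th <- theoretical_ions("PEPTIDEK", mode)
    expect_equal(s$peaks$mz, sort(th$mz), tolerance = 1e-9)
  }
  noisy <- fragmentation_model()
  t1 <- simulate_triple("PEPTIDEK", 2L, noisy, seed = 12)
  t2 <- simulate_triple("PEPTIDEK", 2L, noisy, seed = 12)
  expect_identical(t1, t2)
  # detection probability 0 -> only noise peaks
  m0 <- fragmentation_model()
  for (mode in c("CID", "HCD", "ETD")) m0[[mode]]$series$detect <- 0
  t0 <- simulate_triple("PEPTIDEK", 2L, m0, seed = 3)
  th <- theoretical_ions("PEPTIDEK", "CID")
  expect_false(any(round(t0$cid$peaks$mz, 3) %in% round(th$mz, 3)))
})

test_that("acquisition applies the survey window and records ground truth", {
  pools <- list(tryp = data.frame(peptide = c("PEPTIDEK", "GGGG"),
                                  accession = "P1", start = c(0L, 10L),
                                  stringsAsFactors = FALSE))
  acq <- simulate_acquisition(pools, seed = 1)
  # GGGG at 2+ is ~124 Th, outside 350-1800 at every charge
  expect_equal(acq$ground_truth$peptide, "PEPTIDEK")
  expect_length(acq$spectra$tryp, 3)
  # noiseless neutral precursor mass equals residue sum + water
  s <- acq$spectra$tryp[[1]]
  expect_equal(neutral_precursor_mass(s), peptide_mass("PEPTIDEK"),
               tolerance = 1e-4)
})

test_that("top-3 DDA acquires co-eluting peptides once per exclusion period", {
  pools <- list(d = data.frame(
    peptide = c("PEPTIDEKR", "AGAGAGAGKR", "VVVVPPPPKR"),
    accession = "P1", start = 0L, abundance = c(3, 2, 1),
    stringsAsFactors = FALSE))
  acq <- simulate_acquisition(pools, seed = 4, dda = TRUE,
                              gradient_s = 120, exclusion_s = 200)
  # exclusion longer than the gradient: each peptide at most once
  expect_equal(sort(unique(acq$ground_truth$peptide)),
               sort(pools$d$peptide))
  expect_equal(nrow(acq$ground_truth), 3)
})

test_that("acquisition output is reproducible and writes valid MGF", {
  pools <- list(d = data.frame(peptide = c("PEPTIDEKR", "MKAVIDPTWER"),
                               accession = "P1", start = 0L,
                               stringsAsFactors = FALSE))
  dir <- withr::local_tempdir()
  a1 <- simulate_acquisition(pools, seed = 9, out_dir = dir)
  a2 <- simulate_acquisition(pools, seed = 9)
  expect_identical(a1$ground_truth, a2$ground_truth)
  back <- read_mgf(file.path(dir, "d.mgf"))
  expect_length(back, 6)
  expect_true(file.exists(file.path(dir, "ground_truth.tsv")))
})
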