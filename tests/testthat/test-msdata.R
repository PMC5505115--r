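test_that("MGF round-trip is lossless at stated precision", {
  set.seed(11)
  spectra <- lapply(1:30, function(i) {
    random_spectrum(sprintf("spec%02d mode=CID", i),
                    n_peaks = sample(0:20, 1),
                    mode = sample(c("CID", "HCD", "ETD"), 1),
                    charge = sample(2:3, 1), scan = i)
  })
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(spectra, path)
  back <- read_mgf(path)
  expect_length(back, length(spectra))
  for (i in seq_along(spectra)) {
    expect_equal(back[[i]]$spectrum_id, spectra[[i]]$spectrum_id)
    expect_equal(back[[i]]$mode, spectra[[i]]$mode)
    expect_equal(back[[i]]$scan, spectra[[i]]$scan)
    expect_equal(back[[i]]$precursor_charge, spectra[[i]]$precursor_charge)
    expect_equal(back[[i]]$precursor_mz, spectra[[i]]$precursor_mz,
                 tolerance = 1e-5)
    expect_equal(back[[i]]$peaks$mz, spectra[[i]]$peaks$mz, tolerance = 1e-5)
    expect_equal(back[[i]]$peaks$intensity, spectra[[i]]$peaks$intensity,
                 tolerance = 1e-3)
  }
  # empty list -> valid empty file
  empty <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(list(), empty)
  expect_length(read_mgf(empty), 0)
})

test_that("read_mgf parses headers, sorts peaks and applies defaults", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c(
    "BEGIN IONS", "TITLE=one", "PEPMASS=500.25000", "CHARGE=2+",
    "FRAGMODE=HCD", "300.1 10", "100.2 5", "200.3 7", "END IONS",
    "BEGIN IONS", "TITLE=nocharge", "PEPMASS=400.10000",
    "FRAGMODE=CID", "150.0 1", "END IONS",
    "BEGIN IONS", "TITLE=nopepmass", "CHARGE=2+", "FRAGMODE=CID",
    "END IONS"), path)
  expect_warning(sp <- read_mgf(path), "PEPMASS")
  expect_length(sp, 2)
  expect_equal(sp[[1]]$mode, "HCD")
  expect_equal(sp[[1]]$peaks$mz, c(100.2, 200.3, 300.1))  # sorted
  expect_equal(sp[[2]]$precursor_charge, 2L)              # default charge

  # mode from TITLE token, else default_mode, else hard error
  path2 <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=x mode=etd", "PEPMASS=400.1",
               "CHARGE=2+", "150.0 1", "END IONS",
               "BEGIN IONS", "TITLE=y", "PEPMASS=400.1", "CHARGE=2+",
               "150.0 1", "END IONS"), path2)
  sp2 <- read_mgf(path2, default_mode = "CID")
  expect_equal(vapply(sp2, function(s) s$mode, character(1)),
               c("ETD", "CID"))
  expect_error(read_mgf(path2), "no fragmentation mode")
})

test_that("FASTA round-trip preserves records and rejects illegal residues", {
  set.seed(7)
  recs <- data.frame(
    accession = sprintf("P%03d", 1:50),
    description = ifelse(runif(50) < 0.5, "a toxin protein", ""),
    sequence = vapply(1:50, function(i) random_peptide(sample(20:120, 1)),
                      character(1)),
    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, path)
  back <- read_fasta(path)
  expect_equal(back$accession, recs$accession)
  expect_equal(back$description, recs$description)
  expect_equal(back$sequence, recs$sequence)

  bad <- rbind(recs[1:2, ],
               data.frame(accession = "BAD1", description = "has X",
                          sequence = "PEPTXIDE", stringsAsFactors = FALSE))
  path2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(bad, path2)
  expect_message(back2 <- read_fasta(path2), "excluded")
  expect_equal(nrow(back2), 2)
  expect_equal(attr(back2, "n_excluded"), 1L)
})

test_that("group_triples groups in scan order within tolerance", {
  mk <- function(scan, mode, mz, z = 2L) {
    spectrum(paste0("s", scan), mz, z, mode, mz = 200, intensity = 1,
             scan = scan)
  }
  g <- group_triples(list(mk(1, "CID", 500.25), mk(2, "HCD", 500.25),
                          mk(3, "ETD", 500.25)))
  expect_length(g$triples, 1)
  expect_length(g$unpaired, 0)

  # ETD precursor outside tolerance -> no triple
  g2 <- group_triples(list(mk(1, "CID", 500.25), mk(2, "HCD", 500.25),
                           mk(3, "ETD", 620.10)))
  expect_length(g2$triples, 0)
  expect_length(g2$unpaired, 3)

  # interleaved precursors
  g3 <- group_triples(list(mk(1, "CID", 500.25), mk(2, "CID", 600.50),
                           mk(3, "HCD", 500.25), mk(4, "HCD", 600.50),
                           mk(5, "ETD", 500.25), mk(6, "ETD", 600.50)))
  expect_length(g3$triples, 2)
  for (tr in g3$triples) {
    expect_s3_class(tr, "SpectrumTriple")
    expect_equal(tr$cid$mode, "CID")
    expect_equal(tr$hcd$mode, "HCD")
    expect_equal(tr$etd$mode, "ETD")
  }
})

test_that("group_triples count identity and oracle equivalence hold", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(3:18, 1)
    spectra <- lapply(seq_len(n), function(i) {
      spectrum(paste0("r", i),
               precursor_mz = sample(c(400.2, 400.21, 500.5, 603.3), 1),
               precursor_charge = sample(2:3, 1),
               mode = sample(c("CID", "HCD", "ETD"), 1),
               mz = 200, intensity = 1, scan = i)
    })
    g <- group_triples(spectra, precursor_tol = 0.015)
    expect_equal(3 * length(g$triples) + length(g$unpaired), n)
    expect_equal(length(g$triples),
                 oracle_group_count(spectra, 0.015))
  }
})
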