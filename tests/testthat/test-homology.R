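prot <- function(acc, seqn) list(accession = acc, sequence = seqn)
db1 <- data.frame(accession = "P1", description = "test protein",
                  sequence = "MKPEPTIDER", stringsAsFactors = FALSE)

test_that("exact residue runs place as substrings", {
  m <- align_denovo_to_protein(parse_denovo_string("PEPTIDE"),
                               prot("P1", "MKPEPTIDER"), min_matched = 6)
  expect_equal(m$start, 2)
  expect_equal(m$end, 9)
  expect_equal(m$matched_residues, 7)
  expect_null(align_denovo_to_protein(parse_denovo_string("PEPTIDE"),
                                      prot("P2", "GGGGGGGGGG"),
                                      min_matched = 6))
})

test_that("gap elements consume substrings matching their mass", {
  m <- align_denovo_to_protein(parse_denovo_string("PE[198.1]IDE"),
                               prot("P1", "MKPEPTIDER"), gap_tol = 0.05,
                               min_matched = 5)
  expect_false(is.null(m))
  expect_equal(m$matched_residues, 5)
  expect_length(m$gap_spans, 1)
  sp <- m$gap_spans[[1]]
  # gap consumed "PT" (97.05276 + 101.04768 = 198.10044)
  expect_equal(unname(sp["from"]), 4)
  expect_equal(unname(sp["to"]), 6)
  # independent recomputation of the gap-span mass constraint
  consumed <- substr("MKPEPTIDER", sp["from"] + 1, sp["to"])
  expect_equal(sum(residue_masses()[strsplit(consumed, "")[[1]]]),
               198.1, tolerance = 0.05)
  # unsatisfiable gap mass -> no match
  expect_null(align_denovo_to_protein(parse_denovo_string("PE[500.0]IDE"),
                                      prot("P1", "MKPEPTIDER"),
                                      gap_tol = 0.05, min_matched = 5))
})

test_that("I/L equivalence applies in both directions", {
  m <- align_denovo_to_protein(parse_denovo_string("PEPTIDE"),
                               prot("P1", "MKPEPTLDER"), min_matched = 6)
  expect_false(is.null(m))
  m2 <- align_denovo_to_protein(parse_denovo_string("PEPTLDE"),
                                prot("P1", "MKPEPTIDER"), min_matched = 6)
  expect_false(is.null(m2))
})

test_that("database search orders matches and flags a deterministic best", {
  db <- data.frame(accession = c("ISO2", "ISO1", "OTHER"),
                   description = "x",
                   sequence = c("MKPEPTIDER", "MKPEPTIDER", "GWGWGWGWGW"),
                   stringsAsFactors = FALSE)
  hits <- search_database(list(parse_denovo_string("PEPTIDE")), db,
                          min_matched = 6)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$accession, c("ISO1", "ISO2"))  # score desc, acc asc
  expect_equal(hits$best, c(TRUE, FALSE))
  expect_error(search_database(list(), db1[0, ]), "empty")
})

test_that("contaminant filtering removes flagged accessions and partitions", {
  db <- data.frame(accession = c("P1", "TRYP_PIG"), description = "x",
                   sequence = c("MKPEPTIDER", "WWGASPKWVTFR"),
                   stringsAsFactors = FALSE)
  seqs <- list(parse_denovo_string("PEPTIDE", "c1"),
               parse_denovo_string("GASPKWVTF", "c2"))
  hits <- search_database(seqs, db, min_matched = 6)
  flt <- filter_contaminants(hits)
  expect_equal(unique(flt$kept$contig_id), "c1")
  expect_equal(unique(flt$removed$contig_id), "c2")
  expect_equal(nrow(flt$kept) + nrow(flt$removed), nrow(hits))
  # empty contaminant list is the identity
  flt2 <- filter_contaminants(hits, character(0))
  expect_equal(nrow(flt2$kept), nrow(hits))
})

test_that("greedy parsimony reduces to a minimal explaining set", {
  matches <- data.frame(
    contig_id = c("c1", "c1", "c2", "c3", "c3"),
    accession = c("P1", "P2", "P1", "P1", "P3"),
    best = TRUE, stringsAsFactors = FALSE)
  rep <- parsimony_group(matches)
  expect_equal(rep$selected, "P1")
  expect_setequal(rep$support$P1, c("c1", "c2", "c3"))

  # every contig on its own protein -> all selected
  uniq <- data.frame(contig_id = c("c1", "c2"), accession = c("P1", "P2"),
                     best = TRUE, stringsAsFactors = FALSE)
  expect_setequal(parsimony_group(uniq)$selected, c("P1", "P2"))
})

test_that("greedy cover stays close to the exact optimum on small instances", {
  set.seed(71)
  for (i in 1:20) {
    n_prot <- sample(3:7, 1); n_contig <- sample(3:8, 1)
    rows <- list()
    for (cg in seq_len(n_contig)) {
      for (p in sample(n_prot, sample(1:3, 1))) {
        rows[[length(rows) + 1L]] <- data.frame(
          contig_id = paste0("c", cg), accession = paste0("P", p),
          best = TRUE, stringsAsFactors = FALSE)
      }
    }
    matches <- unique(do.call(rbind, rows))
    greedy <- length(parsimony_group(matches)$selected)
    # exact minimum cover by exhaustive subset search
    prots <- unique(matches$accession)
    covers <- function(sel) {
      all(unique(matches$contig_id) %in%
            matches$contig_id[matches$accession %in% sel])
    }
    exact <- min(vapply(seq_along(prots), function(k) {
      combos <- utils::combn(prots, k, simplify = FALSE)
      if (any(vapply(combos, covers, logical(1)))) k else Inf
    }, numeric(1)))
    expect_gte(greedy, exact)
    expect_lte(greedy, max(1, ceiling(exact * log(n_contig + 1))))
  }
})

test_that("score independence: other records do not affect a match", {
  seqs <- list(parse_denovo_string("PEPTIDE", "c1"))
  db2 <- rbind(db1, data.frame(accession = "P9", description = "extra",
                               sequence = "AAAPEPTIDEKKK",
                               stringsAsFactors = FALSE))
  h1 <- search_database(seqs, db1, min_matched = 6)
  h2 <- search_database(seqs, db2, min_matched = 6)
  p1 <- h2[h2$accession == "P1", ]
  expect_equal(p1$score, h1$score)
  expect_equal(p1$start, h1$start)
})

test_that("report tables carry the documented layout and counts", {
  seqs <- list(parse_denovo_string("PEPTIDE", "c1"))
  hits <- search_database(seqs, db1, min_matched = 6)
  rep <- parsimony_group(hits)
  dir <- withr::local_tempdir()
  out <- report_tables(seqs, hits, rep, db1,
                       counts = list(spectral_triplets = 5L, raw_files = 2L),
                       out_dir = dir)
  expect_equal(names(out$contig_table),
               c("denovo_string", "accession", "description", "species"))
  expect_equal(out$summary_table$category,
               c("spectral_triplets", "contigs", "denovo_sequences",
                 "homologous_sequences", "proteins", "raw_files"))
  expect_equal(out$summary_table$count,
               c(5L, 1L, 1L, 1L, 1L, 2L))
  expect_true(file.exists(file.path(dir, "contigs.tsv")))
  hdr <- readLines(file.path(dir, "contigs.tsv"), n = 1)
  expect_identical(hdr, "denovo_string\taccession\tdescription\tspecies")

  # zero matches still writes a zero summary
  empty <- search_database(list(parse_denovo_string("WWWWWW", "cx")),
                           db1, min_matched = 6)
  out0 <- report_tables(list(), empty, parsimony_group(empty), db1,
                        counts = list(spectral_triplets = 0L,
                                      raw_files = 0L))
  expect_true(all(out0$summary_table$count == 0))
})
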