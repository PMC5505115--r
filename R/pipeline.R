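# End-to-end orchestration: simulate -> prm -> network -> assemble ->
# denovo -> map, with a frozen config, per-stage TSV artifacts and a
# summary mirroring the standard count categories.

#' Recompute a pairwise alignment at a fixed shift
#'
#' Runs the monotone-matching dynamic program of [align_pair()] at a
#' given shift (no shift search). Used when re-deriving matched peak
#' pairs from a persisted edge table.
#'
#' @param a,b `PRMSpectrum` objects.
#' @param shift Shift (Da) of b inside a's coordinate frame.
#' @param align_tol Mass tolerance (Da).
#' @return A `PairwiseAlignment` (possibly with zero matches).
#' @export
align_at_shift <- function(a, b, shift, align_tol = 0.3) {
  m <- .match_dp(.augment(a), .augment(b), shift, align_tol)
  structure(list(id_a = a$id, id_b = b$id, shift = shift,
                 matched_pairs = data.frame(i = m$ia, j = m$ib),
                 n_matches = m$n_real, score = m$score),
            class = "PairwiseAlignment")
}

#' Default pipeline configuration
#'
#' Every parameter of every stage with its default. The proteome /
#' acquisition block encodes the emulated experimental design: a
#' synthetic proteome fractionated at 10 kDa, four digests (trypsin
#' 4 h partial, trypsin 18 h, chymotrypsin 18 h, pepsin 18 h),
#' noiseless CID/HCD/ETD triples per eligible precursor in the m/z
#' 350-1800 survey window.
#'
#' @param seed Integer master seed (drives every stochastic step).
#' @param out_dir Run directory.
#' @param ... Named overrides of any top-level config entry.
#' @return A named list (class `PipelineConfig`).
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("metaspec_run_"),
                            ...) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = list(simulate = TRUE),
    input_mgf = NULL,          # named list group -> dir, when simulate = FALSE
    db_fasta = NULL,           # defaults to the simulated proteome
    proteome = list(n = 10L, len_range = c(60L, 200L)),
    fraction_cutoff = 10000,
    digests = list(len_min = 6L, len_max = 30L),
    noiseless = TRUE,
    acquisition = list(dda = FALSE, mz_range = c(350, 1800), charges = 2:3),
    precursor_tol = 0.01,
    prm = list(merge_tol = 0.3, min_modes = 3L),
    network = list(align_tol = 0.3, min_matches = 7L, min_frac = 0.8,
                   min_score = "auto"),
    assembly = list(frame_tol = 0.35, min_component_size = 2L),
    denovo = list(call_tol = 0.02),
    homology = list(gap_tol = 0.05, max_gap_residues = 6L, min_matched = 6L),
    contaminants = default_contaminants()
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "PipelineConfig")
}

.group_dir <- function(run_dir, group) file.path(run_dir, group)

.stage_prm <- function(run_dir, group, cfg) {
  gd <- .group_dir(run_dir, group)
  mgfs <- sort(list.files(gd, pattern = "\\.mgf$", full.names = TRUE))
  prms <- list()
  n_triples <- 0L
  for (f in mgfs) {
    spectra <- read_mgf(f)
    grouped <- group_triples(spectra, precursor_tol = cfg$precursor_tol)
    n_triples <- n_triples + length(grouped$triples)
    for (tr in grouped$triples) {
      p <- triple_to_prm(tr, merge_tol = cfg$prm$merge_tol)
      p <- sparsify_prm(p, min_modes = cfg$prm$min_modes)
      prms[[length(prms) + 1L]] <- p
    }
  }
  write_prm_archive(prms, file.path(gd, "prms.tsv"))
  list(prms = prms, n_triples = n_triples, n_raw = length(mgfs))
}

.stage_network <- function(run_dir, group, cfg) {
  gd <- .group_dir(run_dir, group)
  prms <- read_prm_archive(file.path(gd, "prms.tsv"))
  net <- build_network(prms, align_tol = cfg$network$align_tol,
                       min_matches = cfg$network$min_matches,
                       min_frac = cfg$network$min_frac,
                       min_score = cfg$network$min_score,
                       seed = cfg$seed)
  utils::write.table(net$edges, file.path(gd, "edges.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  comp <- data.frame(id = names(net$membership),
                     component = as.integer(net$membership))
  utils::write.table(comp, file.path(gd, "components.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  net
}

.stage_assemble <- function(run_dir, group, cfg) {
  gd <- .group_dir(run_dir, group)
  prms <- read_prm_archive(file.path(gd, "prms.tsv"))
  names(prms) <- vapply(prms, function(p) p$id, character(1))
  edges <- utils::read.delim(file.path(gd, "edges.tsv"),
                             stringsAsFactors = FALSE)
  alignments <- lapply(seq_len(nrow(edges)), function(k) {
    align_at_shift(prms[[edges$id_a[k]]], prms[[edges$id_b[k]]],
                   edges$shift[k], cfg$network$align_tol)
  })
  g <- igraph::graph_from_data_frame(
    edges[, c("id_a", "id_b")], directed = FALSE,
    vertices = data.frame(name = names(prms)))
  membership <- igraph::components(g)$membership[names(prms)]
  net <- list(membership = membership, alignments = alignments)
  mcs <- assemble_network(prms, net, frame_tol = cfg$assembly$frame_tol,
                          min_component_size = cfg$assembly$min_component_size,
                          id_prefix = paste0(group, ".contig"))
  rows <- lapply(mcs, function(m) {
    data.frame(contig_id = m$contig_id, n_spectra = m$n_spectra, M = m$M,
               mass = m$consensus$mass, score = m$consensus$score)
  })
  tab <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(contig_id = character(0), n_spectra = integer(0),
               M = numeric(0), mass = numeric(0), score = numeric(0))
  utils::write.table(tab, file.path(gd, "metacontigs.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  memb <- lapply(mcs, function(m) {
    data.frame(contig_id = m$contig_id, spectrum_id = m$member_ids)
  })
  mt <- if (length(memb) > 0) do.call(rbind, memb) else
    data.frame(contig_id = character(0), spectrum_id = character(0))
  utils::write.table(mt, file.path(gd, "contig_members.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  mcs
}

.stage_denovo <- function(run_dir, group, cfg) {
  gd <- .group_dir(run_dir, group)
  tab <- utils::read.delim(file.path(gd, "metacontigs.tsv"),
                           stringsAsFactors = FALSE)
  seqs <- list()
  for (cid in unique(tab$contig_id)) {
    d <- tab[tab$contig_id == cid, ]
    mc <- list(contig_id = cid,
               consensus = data.frame(mass = d$mass, score = d$score),
               M = d$M[1])
    seqs[[length(seqs) + 1L]] <-
      sequence_consensus(mc, call_tol = cfg$denovo$call_tol)
  }
  out <- data.frame(
    contig_id = vapply(seqs, function(s) s$contig_id, character(1)),
    denovo_string = vapply(seqs, format_denovo_string, character(1)),
    n_residues = vapply(seqs, n_residues, integer(1)),
    n_gaps = vapply(seqs, n_gaps, integer(1)),
    total_mass = vapply(seqs, denovo_mass, numeric(1)))
  if (nrow(out) == 0) {
    out <- data.frame(contig_id = character(0), denovo_string = character(0),
                      n_residues = integer(0), n_gaps = integer(0),
                      total_mass = numeric(0))
  }
  utils::write.table(out, file.path(gd, "sequences.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  seqs
}

.stage_map <- function(run_dir, group, cfg, db) {
  gd <- .group_dir(run_dir, group)
  tab <- utils::read.delim(file.path(gd, "sequences.tsv"),
                           stringsAsFactors = FALSE)
  seqs <- lapply(seq_len(nrow(tab)), function(k) {
    parse_denovo_string(tab$denovo_string[k], contig_id = tab$contig_id[k])
  })
  matches <- search_database(seqs, db,
                             gap_tol = cfg$homology$gap_tol,
                             max_gap_residues = cfg$homology$max_gap_residues,
                             min_matched = cfg$homology$min_matched)
  flt <- filter_contaminants(matches, cfg$contaminants)
  utils::write.table(flt$kept, file.path(gd, "matches.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  rep <- parsimony_group(flt$kept)
  ptab <- if (length(rep$selected) > 0) {
    data.frame(accession = rep$selected,
               n_contigs = vapply(rep$support[rep$selected], length,
                                  integer(1)))
  } else data.frame(accession = character(0), n_contigs = integer(0))
  utils::write.table(ptab, file.path(gd, "parsimony.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  list(seqs = seqs, matches = flt$kept, removed = flt$removed, report = rep)
}

#' Run the full pipeline
#'
#' Executes simulate, prm, network, assemble, denovo and map in order
#' for each input group (the two molecular-weight fractions when
#' simulating), persisting every intermediate as TSV/MGF/FASTA in the
#' run directory together with a frozen YAML copy of the resolved
#' configuration. The two groups are processed independently and merged
#' at the parsimony step. A rerun with the same configuration and seed
#' is bit-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the run directory, per-group
#'   artifacts, combined parsimony report and summary table.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  run_dir <- cfg$out_dir
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_frozen <- cfg
  cfg_frozen$out_dir <- NULL
  yaml::write_yaml(unclass(cfg_frozen), file.path(run_dir, "config.yaml"))
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))

  model <- fragmentation_model(noiseless = cfg$noiseless)
  if (isTRUE(cfg$stages$simulate)) {
    proteome <- generate_proteome(cfg$proteome$n, cfg$proteome$len_range,
                                  seed = cfg$seed)
    write_fasta(proteome, file.path(run_dir, "proteome.fasta"))
    fr <- fractionate(proteome, cfg$fraction_cutoff)
    groups <- list(above10k = fr$above, below10k = fr$below)
    groups <- groups[vapply(groups, nrow, integer(1)) > 0]
    gt_all <- list()
    for (gi in seq_along(groups)) {
      group <- names(groups)[gi]
      digests <- default_digests(cfg$digests$len_min, cfg$digests$len_max)
      pools <- digest_proteome(groups[[gi]], digests,
                               seed = cfg$seed + 17L * gi)
      acq <- simulate_acquisition(pools, model, seed = cfg$seed + 31L * gi,
                                  dda = cfg$acquisition$dda,
                                  mz_range = cfg$acquisition$mz_range,
                                  charges = cfg$acquisition$charges,
                                  out_dir = .group_dir(run_dir, group))
      gt_all[[group]] <- acq$ground_truth
      say("simulate[%s]: %d proteins, %d triples", group,
          nrow(groups[[gi]]), nrow(acq$ground_truth))
    }
  } else {
    if (is.null(cfg$input_mgf)) stop("stage 'simulate' is off but no input_mgf given")
    groups <- cfg$input_mgf
    for (group in names(groups)) {
      gd <- .group_dir(run_dir, group)
      dir.create(gd, recursive = TRUE, showWarnings = FALSE)
      file.copy(list.files(groups[[group]], pattern = "\\.mgf$",
                           full.names = TRUE), gd)
    }
    gt_all <- NULL
  }
  group_names <- names(groups)

  db <- if (!is.null(cfg$db_fasta)) read_fasta(cfg$db_fasta) else
    read_fasta(file.path(run_dir, "proteome.fasta"))

  res <- list()
  all_matches <- list()
  for (group in group_names) {
    p <- .stage_prm(run_dir, group, cfg)
    say("prm[%s]: %d triples -> %d merged PRM spectra", group,
        p$n_triples, length(p$prms))
    net <- .stage_network(run_dir, group, cfg)
    say("network[%s]: %d edges (min_score %.3f)", group,
        nrow(net$edges), net$min_score)
    mcs <- .stage_assemble(run_dir, group, cfg)
    say("assemble[%s]: %d meta-contigs", group, length(mcs))
    seqs <- .stage_denovo(run_dir, group, cfg)
    mapped <- .stage_map(run_dir, group, cfg, db)
    say("map[%s]: %d sequences, %d mapped, %d proteins", group,
        length(seqs), length(unique(mapped$matches$contig_id)),
        length(mapped$report$selected))
    all_matches[[group]] <- mapped$matches
    res[[group]] <- list(n_triples = p$n_triples, n_raw = p$n_raw,
                         prms = p$prms, network = net, meta_contigs = mcs,
                         seqs = mapped$seqs, matches = mapped$matches,
                         report = mapped$report)
  }
  combined <- parsimony_group(do.call(rbind, all_matches))
  ptab <- if (length(combined$selected) > 0) {
    data.frame(accession = combined$selected,
               n_contigs = vapply(combined$support[combined$selected],
                                  length, integer(1)))
  } else data.frame(accession = character(0), n_contigs = integer(0))
  utils::write.table(ptab, file.path(run_dir, "parsimony.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  writeLines(log, file.path(run_dir, "log.txt"))
  summary_table <- summarize_run(run_dir)
  invisible(list(run_dir = run_dir, groups = res, combined = combined,
                 ground_truth = gt_all, summary = summary_table))
}

#' Summarise a completed run
#'
#' Recounts the persisted artifacts of each input group and emits the
#' standard count categories — spectral triplets, contigs, de novo
#' sequences, homologous sequences, proteins, raw files — one column
#' per group plus a combined column (whose protein count comes from
#' the cross-group parsimony, so it may be smaller than the group
#' sum).
#'
#' @param run_dir A run directory produced by [run_pipeline()].
#' @return The summary data frame (also written to `summary.tsv`).
#' @export
summarize_run <- function(run_dir) {
  groups <- list.dirs(run_dir, recursive = FALSE, full.names = FALSE)
  groups <- groups[file.exists(file.path(run_dir, groups, "prms.tsv"))]
  if (length(groups) == 0) stop("incomplete run: no group artifacts under ", run_dir)
  needed <- c("prms.tsv", "metacontigs.tsv", "sequences.tsv", "matches.tsv",
              "parsimony.tsv")
  for (g in groups) {
    missing <- needed[!file.exists(file.path(run_dir, g, needed))]
    if (length(missing) > 0) {
      stop("incomplete run: group ", g, " missing ",
           paste(missing, collapse = ", "))
    }
  }
  if (!file.exists(file.path(run_dir, "parsimony.tsv"))) {
    stop("incomplete run: missing combined parsimony.tsv")
  }
  categories <- c("spectral_triplets", "contigs", "denovo_sequences",
                  "homologous_sequences", "proteins", "raw_files")
  out <- data.frame(category = categories)
  tot <- stats::setNames(rep(0L, length(categories)), categories)
  for (g in groups) {
    gd <- file.path(run_dir, g)
    prm <- utils::read.delim(file.path(gd, "prms.tsv"), stringsAsFactors = FALSE)
    mc <- utils::read.delim(file.path(gd, "metacontigs.tsv"), stringsAsFactors = FALSE)
    sq <- utils::read.delim(file.path(gd, "sequences.tsv"), stringsAsFactors = FALSE)
    mt <- utils::read.delim(file.path(gd, "matches.tsv"), stringsAsFactors = FALSE)
    pt <- utils::read.delim(file.path(gd, "parsimony.tsv"), stringsAsFactors = FALSE)
    counts <- c(length(unique(prm$id)),
                length(unique(mc$contig_id)),
                nrow(sq),
                length(unique(mt$contig_id)),
                nrow(pt),
                length(list.files(gd, pattern = "\\.mgf$")))
    out[[g]] <- counts
    tot <- tot + counts
  }
  ptab <- utils::read.delim(file.path(run_dir, "parsimony.tsv"),
                            stringsAsFactors = FALSE)
  tot[["proteins"]] <- nrow(ptab)
  out[["together"]] <- as.integer(tot)
  utils::write.table(out, file.path(run_dir, "summary.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  out
}

#' Ground-truth recovery metrics for a simulated run
#'
#' Joins a pipeline result against its simulation ground truth and
#' reports: the fraction of meta-contigs whose best database match is
#' their true source protein, residue-call accuracy (matched residue
#' elements of correctly mapped contigs over all residue elements
#' called), and whether the parsimony-selected accession set equals
#' the set of source proteins that received at least one meta-contig.
#'
#' @param result The list returned by [run_pipeline()] (a simulated
#'   run, so ground truth is available).
#' @return List with `n_meta_contigs`, `frac_mapped_to_source`,
#'   `residue_accuracy`, `parsimony_equals_truth`, `true_proteins`,
#'   `selected_proteins`.
#' @export
ground_truth_recovery <- function(result) {
  stopifnot(!is.null(result$ground_truth))
  n_mc <- 0L; n_correct <- 0L
  res_called <- 0L; res_matched <- 0L
  true_set <- character(0)
  for (group in names(result$groups)) {
    g <- result$groups[[group]]
    gt <- result$ground_truth[[group]]
    src <- stats::setNames(gt$accession, gt$triple_id)
    for (k in seq_along(g$meta_contigs)) {
      mc <- g$meta_contigs[[k]]
      n_mc <- n_mc + 1L
      member_src <- unique(src[sub("\\.(CID|HCD|ETD)$", "", mc$member_ids)])
      seq_k <- Filter(function(s) s$contig_id == mc$contig_id, g$seqs)[[1]]
      res_called <- res_called + n_residues(seq_k)
      best <- g$matches[g$matches$best & g$matches$contig_id == mc$contig_id, ]
      ok <- nrow(best) == 1 && length(member_src) == 1 &&
        best$accession == member_src
      if (ok) {
        n_correct <- n_correct + 1L
        res_matched <- res_matched + best$matched_residues
        true_set <- union(true_set, member_src)
      } else if (length(member_src) == 1) {
        true_set <- union(true_set, member_src)
      }
    }
  }
  selected <- result$combined$selected
  list(n_meta_contigs = n_mc,
       frac_mapped_to_source = if (n_mc > 0) n_correct / n_mc else NA_real_,
       residue_accuracy = if (res_called > 0) res_matched / res_called else NA_real_,
       parsimony_equals_truth = setequal(selected, true_set),
       true_proteins = sort(true_set),
       selected_proteins = sort(selected))
}
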