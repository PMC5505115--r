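# Gap-tolerant mapping of de novo sequences onto a protein database,
# contaminant filtering, and maximum-parsimony protein inference.

#' Align a gapped de novo sequence to one protein
#'
#' Dynamic program over (element index, protein position) with no
#' insertions or deletions: a residue element must match an identical
#' protein residue (I and L are equivalent); a gap element consumes any
#' protein substring of 1 to `max_gap_residues` residues whose
#' residue-mass sum lies within `gap_tol` of the gap mass. The score of
#' a placement is its count of matched residue elements; the
#' best-scoring (leftmost on ties) placement with at least
#' `min_matched` matched residues is returned.
#'
#' @param seq A `DeNovoSequence`.
#' @param protein One-row protein record (list or data frame row with
#'   `accession`, `sequence`).
#' @param gap_tol Gap mass tolerance (Da), default 0.05.
#' @param max_gap_residues Longest substring a gap may consume,
#'   default 6.
#' @param min_matched Minimum matched residue elements, default 6.
#' @return A `HomologyMatch` (fields `contig_id`, `accession`, `start`,
#'   `end` 0-based half-open, `matched_residues`, `gap_spans`, `score`)
#'   or `NULL`.
#' @export
align_denovo_to_protein <- function(seq, protein, gap_tol = 0.05,
                                    max_gap_residues = 6L,
                                    min_matched = 6L) {
  el <- seq$elements
  ne <- nrow(el)
  n_res <- sum(el$kind == "residue")
  if (n_res < min_matched) return(NULL)
  prot <- strsplit(protein$sequence, "", fixed = TRUE)[[1]]
  prot_il <- ifelse(prot == "L", "I", prot)
  np <- length(prot)
  pm <- c(0, cumsum(unname(residue_masses()[prot])))  # prefix sums, pm[i+1] = mass of prot[1..i]
  el_letter <- ifelse(el$letter == "L", "I", el$letter)
  # step(e, p): protein positions reachable after consuming element e
  # starting at 0-based position p. Memoised forward search per start.
  for (start in 0:(np - 1)) {
    # residues are forced; gaps branch over qualifying span lengths,
    # shortest first (depth-first with a stack)
    stack <- list(list(e = 1L, pos = start, spans = list()))
    found <- NULL
    while (length(stack) > 0) {
      st <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (st$e > ne) { found <- st; break }
      k <- st$e
      if (el$kind[k] == "residue") {
        p <- st$pos
        if (p < np && prot_il[p + 1L] == el_letter[k]) {
          stack[[length(stack) + 1L]] <-
            list(e = k + 1L, pos = p + 1L, spans = st$spans)
        }
      } else {
        # push longer spans first so shorter spans are explored first
        for (len in rev(seq_len(min(max_gap_residues, np - st$pos)))) {
          mass <- pm[st$pos + len + 1L] - pm[st$pos + 1L]
          if (abs(mass - el$mass[k]) <= gap_tol) {
            sp <- st$spans
            sp[[length(sp) + 1L]] <- c(gap = k, from = st$pos,
                                       to = st$pos + len)
            stack[[length(stack) + 1L]] <-
              list(e = k + 1L, pos = st$pos + len, spans = sp)
          }
        }
      }
    }
    if (!is.null(found)) {
      return(structure(list(
        contig_id = seq$contig_id,
        accession = protein$accession,
        start = start, end = found$pos,
        matched_residues = n_res,
        gap_spans = found$spans,
        score = n_res
      ), class = "HomologyMatch"))
    }
  }
  NULL
}

#' @export
print.HomologyMatch <- function(x, ...) {
  cat(sprintf("<HomologyMatch> %s -> %s [%d,%d), %d matched residues\n",
              x$contig_id, x$accession, x$start, x$end, x$matched_residues))
  invisible(x)
}

#' Search de novo sequences against a protein database
#'
#' Attempts every (sequence, protein) pair; all matches reaching
#' `min_matched` are retained, ordered by score descending then
#' accession ascending, with the best match per sequence flagged (ties
#' broken by accession order).
#'
#' @param seqs List of `DeNovoSequence` objects.
#' @param db Protein data frame (`accession`, `description`,
#'   `sequence`), non-empty.
#' @param gap_tol,max_gap_residues,min_matched As in
#'   [align_denovo_to_protein()].
#' @return Data frame with columns `contig_id`, `accession`, `start`,
#'   `end`, `matched_residues`, `score`, `best`; attribute `matches`
#'   holds the `HomologyMatch` objects.
#' @export
search_database <- function(seqs, db, gap_tol = 0.05,
                            max_gap_residues = 6L, min_matched = 6L) {
  if (nrow(db) == 0) stop("empty protein database")
  hits <- list()
  for (s in seqs) {
    for (p in seq_len(nrow(db))) {
      m <- align_denovo_to_protein(s, db[p, ], gap_tol, max_gap_residues,
                                   min_matched)
      if (!is.null(m)) hits[[length(hits) + 1L]] <- m
    }
  }
  if (length(hits) == 0) {
    out <- data.frame(contig_id = character(0), accession = character(0),
                      start = integer(0), end = integer(0),
                      matched_residues = integer(0), score = numeric(0),
                      best = logical(0))
    attr(out, "matches") <- list()
    return(out)
  }
  out <- do.call(rbind, lapply(hits, function(m) {
    data.frame(contig_id = m$contig_id, accession = m$accession,
               start = m$start, end = m$end,
               matched_residues = m$matched_residues, score = m$score,
               stringsAsFactors = FALSE)
  }))
  o <- order(-out$score, out$accession)
  out <- out[o, , drop = FALSE]
  hits <- hits[o]
  out$best <- FALSE
  for (cid in unique(out$contig_id)) {
    ix <- which(out$contig_id == cid)
    ix <- ix[order(-out$score[ix], out$accession[ix])]
    out$best[ix[1]] <- TRUE
  }
  rownames(out) <- NULL
  attr(out, "matches") <- hits
  out
}

#' Bundled contaminant accessions
#'
#' The proteases used during sample preparation plus common keratin
#' contaminants; matches whose best hit is on this list are excluded
#' from reporting.
#'
#' @return Character vector of accessions.
#' @export
default_contaminants <- function() {
  c("TRYP_PIG", "TRY1_BOVIN", "CTRA_BOVIN", "CTRB_BOVIN", "PEPA_PIG",
    "K1C9_HUMAN", "K1C10_HUMAN", "K2C1_HUMAN", "K22E_HUMAN", "ALBU_BOVIN")
}

#' Remove matches to contaminant proteins
#'
#' Sequences whose best match accession is on the contaminant list are
#' removed (all their matches) and counted.
#'
#' @param matches Match table from [search_database()].
#' @param contaminant_accessions Character vector; default
#'   [default_contaminants()].
#' @return List with `kept` and `removed` match tables.
#' @export
filter_contaminants <- function(matches,
                                contaminant_accessions = default_contaminants()) {
  if (nrow(matches) == 0 || length(contaminant_accessions) == 0) {
    return(list(kept = matches, removed = matches[0, , drop = FALSE]))
  }
  best <- matches[matches$best, , drop = FALSE]
  bad_ids <- best$contig_id[best$accession %in% contaminant_accessions]
  removed <- matches$contig_id %in% bad_ids
  list(kept = matches[!removed, , drop = FALSE],
       removed = matches[removed, , drop = FALSE])
}

#' Maximum-parsimony protein inference
#'
#' Greedy minimum set cover over the contig-to-protein incidence:
#' repeatedly select the accession covering the most not-yet-covered
#' contigs (ties broken toward more total matches, then accession
#' ascending) until every mapped contig is covered.
#'
#' @param matches Match table from [search_database()].
#' @return A `ParsimonyReport`: list with `selected` (accessions),
#'   `support` (named list of contig ids per selected accession) and
#'   `n_contigs`.
#' @export
parsimony_group <- function(matches) {
  if (nrow(matches) == 0) {
    return(structure(list(selected = character(0), support = list(),
                          n_contigs = 0L), class = "ParsimonyReport"))
  }
  cover <- split(matches$contig_id, matches$accession)
  cover <- lapply(cover, unique)
  total <- vapply(split(seq_len(nrow(matches)), matches$accession),
                  length, integer(1))
  uncovered <- unique(matches$contig_id)
  selected <- character(0)
  support <- list()
  while (length(uncovered) > 0) {
    gain <- vapply(cover, function(cs) length(intersect(cs, uncovered)),
                   integer(1))
    o <- order(-gain, -total[names(cover)], names(cover))
    pick <- names(cover)[o[1]]
    if (gain[pick] == 0) break
    selected <- c(selected, pick)
    support[[pick]] <- cover[[pick]]
    uncovered <- setdiff(uncovered, cover[[pick]])
  }
  structure(list(selected = selected, support = support,
                 n_contigs = length(unique(matches$contig_id))),
            class = "ParsimonyReport")
}

#' @export
print.ParsimonyReport <- function(x, ...) {
  cat(sprintf("<ParsimonyReport> %d proteins explain %d contigs\n",
              length(x$selected), x$n_contigs))
  invisible(x)
}

#' Write the per-contig and summary report tables
#'
#' The per-contig table has columns (`denovo_string`, `accession`,
#' `description`, `species`); the summary table reports the standard
#' count categories: spectral triplets, contigs, de novo sequences,
#' homologous sequences, parsimonious proteins, and raw files
#' processed.
#'
#' @param seqs List of `DeNovoSequence` objects.
#' @param matches Match table (contaminants already filtered).
#' @param report A `ParsimonyReport`.
#' @param db Protein database data frame (may carry a `species`
#'   column).
#' @param counts Named list with `spectral_triplets` and `raw_files`
#'   (the upstream counts the tables cannot recompute).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the two data frames (`contig_table`,
#'   `summary_table`); files `contigs.tsv` and `summary.tsv` written to
#'   `out_dir` when it is non-`NULL`.
#' @export
report_tables <- function(seqs, matches, report, db,
                          counts = list(spectral_triplets = NA_integer_,
                                        raw_files = NA_integer_),
                          out_dir = NULL) {
  species <- if ("species" %in% names(db)) db$species else
    rep(NA_character_, nrow(db))
  names(species) <- db$accession
  desc <- stats::setNames(db$description, db$accession)
  best <- matches[matches$best, , drop = FALSE]
  strings <- vapply(seqs, format_denovo_string, character(1))
  names(strings) <- vapply(seqs, function(s) s$contig_id, character(1))
  contig_table <- if (nrow(best) > 0) {
    data.frame(denovo_string = unname(strings[best$contig_id]),
               accession = best$accession,
               description = unname(desc[best$accession]),
               species = unname(species[best$accession]),
               stringsAsFactors = FALSE)
  } else {
    data.frame(denovo_string = character(0), accession = character(0),
               description = character(0), species = character(0))
  }
  summary_table <- data.frame(
    category = c("spectral_triplets", "contigs", "denovo_sequences",
                 "homologous_sequences", "proteins", "raw_files"),
    count = c(counts$spectral_triplets,
              length(seqs),
              length(seqs),
              length(unique(best$contig_id)),
              length(report$selected),
              counts$raw_files)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(contig_table, file.path(out_dir, "contigs.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(summary_table, file.path(out_dir, "summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(list(contig_table = contig_table, summary_table = summary_table))
}
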