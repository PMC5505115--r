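# Gapped de novo sequences: reading a meta-contig consensus PRM
# spectrum as residue letters and bracketed gap masses, the
# parser/formatter for the notation, and gap-mass decomposition.

.new_denovo <- function(contig_id, elements) {
  structure(list(contig_id = contig_id, elements = elements),
            class = "DeNovoSequence")
}

#' @export
print.DeNovoSequence <- function(x, ...) {
  cat(sprintf("<DeNovoSequence %s> %s\n", x$contig_id,
              format_denovo_string(x)))
  invisible(x)
}

#' Number of residue / gap elements
#' @param seq A `DeNovoSequence`.
#' @return Integer count.
#' @export
n_residues <- function(seq) sum(seq$elements$kind == "residue")

#' @rdname n_residues
#' @export
n_gaps <- function(seq) sum(seq$elements$kind == "gap")

#' Call a de novo sequence from a meta-contig consensus spectrum
#'
#' The boundary masses 0 and M are prepended/appended to the strictly
#' increasing consensus masses; each adjacent mass difference is
#' emitted as a residue letter when exactly one residue mass of the
#' calling table lies within `call_tol` of it, and as a bracketed gap
#' of that mass otherwise (zero or two or more qualifying residues).
#' Isoleucine and leucine share a mass; a difference matching
#' 113.08406 Da is emitted as 'I' by convention. At the default
#' `call_tol` of 0.02 Da — justified by score-weighted consensus
#' averaging across modes and spectra — lysine (128.09496) and
#' glutamine (128.05858) are distinguishable; looser tolerances turn
#' such differences into gaps.
#'
#' Per-element confidence is the smaller consensus score of the two
#' bounding masses (boundaries count as fully supported).
#'
#' @param mc A `MetaContig` (or any list with `consensus` data frame
#'   and total residue mass `M`).
#' @param call_tol Residue-calling tolerance (Da), default 0.02.
#' @param residue_table Named mass table, default [calling_table()].
#' @return A `DeNovoSequence`.
#' @export
sequence_consensus <- function(mc, call_tol = 0.02,
                               residue_table = calling_table()) {
  cons <- mc$consensus
  if (any(diff(cons$mass) <= 0)) stop("consensus masses must be strictly increasing")
  if (nrow(cons) > 0 && (cons$mass[1] <= 0 || cons$mass[nrow(cons)] >= mc$M)) {
    stop("consensus masses must lie strictly inside (0, M)")
  }
  masses <- c(0, cons$mass, mc$M)
  scores <- c(Inf, cons$score, Inf)
  deltas <- diff(masses)
  conf <- pmin(scores[-length(scores)], scores[-1])
  el <- lapply(seq_along(deltas), function(k) {
    d <- deltas[k]
    hit <- which(abs(residue_table - d) <= call_tol)
    if (length(hit) == 1) {
      data.frame(kind = "residue", letter = names(residue_table)[hit],
                 mass = unname(residue_table[hit]), label = NA_character_,
                 confidence = conf[k], stringsAsFactors = FALSE)
    } else {
      data.frame(kind = "gap", letter = NA_character_, mass = d,
                 label = NA_character_, confidence = conf[k],
                 stringsAsFactors = FALSE)
    }
  })
  .new_denovo(mc$contig_id %||% "consensus", do.call(rbind, el))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Parse a gapped de novo string
#'
#' Grammar: a sequence of residue letters (20-letter alphabet) and
#' bracketed decimal masses, e.g. `"[168.09]PDATIVY[128.106]"`.
#' Bracket contents must be a plain decimal number (1-6 decimals
#' accepted); the printed digits are preserved verbatim for
#' round-tripping. Unbalanced brackets, illegal letters and non-numeric
#' bracket contents raise a parse error naming the offending position.
#'
#' @param s Character scalar.
#' @param contig_id Identifier attached to the result.
#' @return A `DeNovoSequence`.
#' @export
#' @examples
#' parse_denovo_string("[168.09]PDATIVY[128.106]")
parse_denovo_string <- function(s, contig_id = "parsed") {
  stopifnot(is.character(s), length(s) == 1L)
  if (!nzchar(s)) stop("parse error at position 1: empty de novo string")
  rm_tab <- residue_masses()
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  els <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= length(chars) && chars[j] != "]") j <- j + 1L
      if (j > length(chars)) stop("parse error at position ", i,
                                  ": unbalanced '['")
      content <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      if (!grepl("^[0-9]+(\\.[0-9]{1,6})?$", content)) {
        stop("parse error at position ", i + 1L,
             ": non-numeric gap mass '", content, "'")
      }
      els[[length(els) + 1L]] <- data.frame(
        kind = "gap", letter = NA_character_, mass = as.numeric(content),
        label = content, confidence = NA_real_, stringsAsFactors = FALSE)
      i <- j + 1L
    } else if (ch == "]") {
      stop("parse error at position ", i, ": unbalanced ']'")
    } else if (ch %in% names(rm_tab)) {
      els[[length(els) + 1L]] <- data.frame(
        kind = "residue", letter = ch, mass = unname(rm_tab[ch]),
        label = NA_character_, confidence = NA_real_,
        stringsAsFactors = FALSE)
      i <- i + 1L
    } else {
      stop("parse error at position ", i, ": illegal letter '", ch, "'")
    }
  }
  .new_denovo(contig_id, do.call(rbind, els))
}

# 3 decimals with trailing zeros (and a trailing point) trimmed
.format_gap_mass <- function(m) {
  sub("\\.$", "", sub("0+$", "", sprintf("%.3f", m)))
}

#' Format a de novo sequence as a gapped string
#'
#' Residues print as letters; gaps as `[m]` with the mass printed to 3
#' decimals, trailing zeros trimmed. A gap parsed from text keeps its
#' printed digits verbatim, so `format(parse(s)) == s`.
#'
#' @param seq A `DeNovoSequence`.
#' @return Character scalar.
#' @export
#' @examples
#' format_denovo_string(parse_denovo_string("GVIIHE[291.835][227.31]GFY"))
format_denovo_string <- function(seq) {
  el <- seq$elements
  if (is.null(el) || nrow(el) == 0) return("")
  paste(vapply(seq_len(nrow(el)), function(k) {
    if (el$kind[k] == "residue") el$letter[k]
    else paste0("[", if (!is.na(el$label[k])) el$label[k]
                else .format_gap_mass(el$mass[k]), "]")
  }, character(1)), collapse = "")
}

#' Total mass of a de novo sequence's elements
#' @param seq A `DeNovoSequence`.
#' @return Sum of element masses (Da).
#' @export
denovo_mass <- function(seq) sum(seq$elements$mass)

#' Enumerate residue compositions of a gap mass
#'
#' Bounded depth-first enumeration over nondecreasing residue masses of
#' all multisets of at most `max_residues` residues whose summed mass
#' lies within `tol` of `mass`. I/L are represented by 'I' (one entry
#' per distinct residue mass).
#'
#' @param mass Gap mass (Da), > 0.
#' @param tol Mass tolerance (Da), default 0.01.
#' @param max_residues Multiset size bound, default 6.
#' @return List of character vectors (sorted residue letters), possibly
#'   empty; e.g. 114.043 yields `{N}` and `{G, G}`.
#' @export
#' @examples
#' gap_compositions(114.043, 0.01)
gap_compositions <- function(mass, tol = 0.01, max_residues = 6L) {
  stopifnot(mass > 0)
  tab <- sort(calling_table())
  letters <- names(tab)
  results <- list()
  rec <- function(target, i0, left, acc) {
    for (i in i0:length(tab)) {
      m <- tab[[i]]
      if (m > target + tol) break
      if (abs(target - m) <= tol) {
        results[[length(results) + 1L]] <<- sort(c(acc, letters[i]))
      }
      if (left > 1 && target - m > tab[[i]] - tol) {
        rec(target - m, i, left - 1L, c(acc, letters[i]))
      }
    }
  }
  rec(mass, 1L, as.integer(max_residues), character(0))
  unique(results)
}
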