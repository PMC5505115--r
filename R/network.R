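# Spectral networks: shifted pairwise alignment of merged PRM spectra
# and construction of the overlap graph.

# Augment a PRM spectrum with virtual boundary peaks at 0 and M
# (score 0). Virtual peaks take part in shift enumeration and in the
# monotone matching but contribute neither to the score nor to the
# reported matched pairs.
.augment <- function(prm) {
  list(mass = c(0, prm$peaks$mass, prm$M),
       score = c(0, prm$peaks$score, 0),
       real = c(FALSE, rep(TRUE, nrow(prm$peaks)), FALSE))
}

# Monotone matching of maximal score (then maximal number of real
# matched pairs) between two augmented peak lists under a fixed shift.
# O(n*m) dynamic program; weights are score_a + score_b for real-real
# pairs and 0 when a virtual peak is involved. Returns score, n real
# matches, and the real matched index pairs (1-based peak indices).
.match_dp <- function(a, b, shift, tol) {
  na <- length(a$mass); nb <- length(b$mass)
  S <- matrix(0, na + 1L, nb + 1L)        # best score
  N <- matrix(0L, na + 1L, nb + 1L)       # best real-match count at that score
  C <- matrix(0L, na + 1L, nb + 1L)       # choice: 1 skip a, 2 skip b, 3 match
  bm <- b$mass + shift
  for (i in seq_len(na)) {
    di <- abs(a$mass[i] - bm)
    for (j in seq_len(nb)) {
      s1 <- S[i, j + 1L]; n1 <- N[i, j + 1L]          # skip a[i]
      s2 <- S[i + 1L, j]; n2 <- N[i + 1L, j]          # skip b[j]
      best_s <- s1; best_n <- n1; ch <- 1L
      if (s2 > best_s || (s2 == best_s && n2 > best_n)) {
        best_s <- s2; best_n <- n2; ch <- 2L
      }
      if (di[j] <= tol) {
        real <- a$real[i] && b$real[j]
        w <- if (real) a$score[i] + b$score[j] else 0
        s3 <- S[i, j] + w
        n3 <- N[i, j] + (real && w != 0)
        if (s3 > best_s || (s3 == best_s && n3 > best_n)) {
          best_s <- s3; best_n <- n3; ch <- 3L
        }
      }
      S[i + 1L, j + 1L] <- best_s
      N[i + 1L, j + 1L] <- best_n
      C[i + 1L, j + 1L] <- ch
    }
  }
  # traceback for the real matched pairs
  i <- na; j <- nb
  pi <- integer(0); pj <- integer(0)
  while (i > 0 && j > 0) {
    ch <- C[i + 1L, j + 1L]
    if (ch == 3L) {
      if (a$real[i] && b$real[j]) { pi <- c(i, pi); pj <- c(j, pj) }
      i <- i - 1L; j <- j - 1L
    } else if (ch == 1L) i <- i - 1L else j <- j - 1L
  }
  list(score = S[na + 1L, nb + 1L], n_real = N[na + 1L, nb + 1L],
       ia = pi - 1L, ib = pj - 1L)   # drop the leading virtual index
}

#' Align two merged PRM spectra by mass shift
#'
#' Candidate shifts are all pairwise mass differences between the two
#' spectra (boundary masses 0 and M included virtually); candidates
#' supported by at least `min_matches` peak-pair differences within
#' `align_tol` are evaluated with a monotone-matching dynamic program
#' that maximises the alignment score (sum of `score_a + score_b` over
#' matched real pairs; matching a negative-scoring pair is never
#' forced). The best-scoring shift with at least `min_matches` matched
#' real pairs is returned, ties broken toward more matches, then the
#' smaller absolute shift.
#'
#' With `allow_offset = TRUE` the search additionally considers
#' alignments with one internal offset change (two shifts), supporting
#' the detection of a single unanticipated modification mass; such
#' alignments are annotated with `offset_shift`.
#'
#' In addition to the match-count and score thresholds, a candidate
#' shift must explain the bulk of the evidence inside its overlap
#' window: at least `min_frac` of the (positive) PRM score carried by
#' peaks of either spectrum lying strictly inside the overlap region
#' must belong to matched pairs. Alignments between spectra of truly
#' overlapping peptides are near-complete inside the overlap, whereas
#' coincidental alignments (exact compositional collisions between
#' residue-mass ladders) match only scattered peaks; the completeness
#' requirement separates the two where match counts alone cannot.
#'
#' @param a,b `PRMSpectrum` objects (non-empty).
#' @param align_tol Mass tolerance (Da), default 0.3.
#' @param min_matches Minimum matched real peak pairs, default 5.
#' @param min_frac Minimum matched fraction of in-overlap score,
#'   default 0.8.
#' @param allow_offset Search one internal offset change.
#' @return A `PairwiseAlignment` (fields `id_a`, `id_b`, `shift`,
#'   `matched_pairs`, `n_matches`, `score`, `frac_matched`, optional
#'   `offset_shift`) or `NULL` when no shift qualifies.
#' @export
align_pair <- function(a, b, align_tol = 0.3, min_matches = 5,
                       min_frac = 0.8, allow_offset = FALSE) {
  stopifnot(inherits(a, "PRMSpectrum"), inherits(b, "PRMSpectrum"),
            nrow(a$peaks) > 0, nrow(b$peaks) > 0)
  aa <- .augment(a); bb <- .augment(b)
  diffs <- as.vector(outer(aa$mass, bb$mass, "-"))
  real_d <- sort(as.vector(outer(a$peaks$mass, b$peaks$mass, "-")))
  cand <- unique(round(diffs, 6))
  support <- findInterval(cand + align_tol, real_d) -
    findInterval(cand - align_tol - 1e-12, real_d)
  cand_off <- cand[support >= 2]
  cand <- cand[support >= min_matches]
  if (length(cand) == 0 && !allow_offset) return(NULL)
  best <- NULL
  for (s in cand) {
    m <- .match_dp(aa, bb, s, align_tol)
    if (m$n_real < min_matches) next
    fr <- .overlap_fraction(a, b, s, m, align_tol)
    if (fr < min_frac) next
    if (is.null(best) ||
        m$score > best$score ||
        (m$score == best$score && m$n_real > best$n_matches) ||
        (m$score == best$score && m$n_real == best$n_matches &&
           abs(s) < abs(best$shift))) {
      best <- list(id_a = a$id, id_b = b$id, shift = s,
                   matched_pairs = data.frame(i = m$ia, j = m$ib),
                   n_matches = m$n_real, score = m$score,
                   frac_matched = fr)
    }
  }
  if (!is.null(best)) {
    # recentre the shift on the matched pairs: the raw candidate is one
    # peak-pair difference and may carry that pair's mass error; the
    # median over all matched pairs is robust to a displaced member
    best$shift <- stats::median(
      a$peaks$mass[best$matched_pairs$i] - b$peaks$mass[best$matched_pairs$j])
  }
  if (allow_offset) {
    off <- .align_with_offset(a, b, aa, bb, cand_off, align_tol, min_matches)
    if (!is.null(off) && (is.null(best) || off$score > best$score)) best <- off
  }
  if (is.null(best)) return(NULL)
  structure(best, class = "PairwiseAlignment")
}

# Matched fraction of the (positive) PRM score carried by real peaks
# strictly inside the overlap window of a shift. Boundary-adjacent
# peaks (within align_tol of either spectrum's terminus in the shared
# frame) are left out of the bookkeeping: they legitimately pair with
# the other spectrum's virtual boundary.
.overlap_fraction <- function(a, b, shift, m, align_tol) {
  lo <- max(0, shift); hi <- min(a$M, shift + b$M)
  wa <- pmax(a$peaks$score, 0); wb <- pmax(b$peaks$score, 0)
  in_a <- a$peaks$mass > lo + align_tol & a$peaks$mass < hi - align_tol
  bm <- b$peaks$mass + shift
  in_b <- bm > lo + align_tol & bm < hi - align_tol
  denom <- sum(wa[in_a]) + sum(wb[in_b])
  if (denom <= 0) return(1)
  num <- sum(wa[m$ia[in_a[m$ia]]]) + sum(wb[m$ib[in_b[m$ib]]])
  num / denom
}

# Two-phase alignment: shift s1 up to an internal breakpoint, s2 after
# it (one offset change of mass s2 - s1, e.g. a modification). Scores
# as in .match_dp; evaluated over candidate shift pairs with adequate
# support. Used for annotation only, never by assembly.
.align_with_offset <- function(a, b, aa, bb, cand, tol, min_matches) {
  if (length(cand) < 2) return(NULL)
  cand <- utils::head(cand, 24L)                     # bound the search
  best <- NULL
  for (s1 in cand) for (s2 in cand) {
    if (s2 == s1) next
    m1 <- .match_dp(aa, bb, s1, tol)
    m2 <- .match_dp(aa, bb, s2, tol)
    # combine: prefix matched under s1, suffix under s2 (split at the
    # best real breakpoint); a coarse but adequate two-shift search
    for (k in seq_len(length(m1$ia) + 1L) - 1L) {
      if (k == 0) next
      pre_i <- m1$ia[seq_len(k)]; pre_j <- m1$ib[seq_len(k)]
      post <- which(m2$ia > max(pre_i) & m2$ib > max(pre_j))
      n <- k + length(post)
      if (n < min_matches || length(post) == 0) next
      sc <- sum(a$peaks$score[c(pre_i, m2$ia[post])]) +
        sum(b$peaks$score[c(pre_j, m2$ib[post])])
      if (is.null(best) || sc > best$score) {
        best <- list(id_a = a$id, id_b = b$id, shift = s1,
                     offset_shift = s2,
                     matched_pairs = data.frame(
                       i = c(pre_i, m2$ia[post]), j = c(pre_j, m2$ib[post])),
                     n_matches = n, score = sc)
      }
    }
  }
  best
}

#' @export
print.PairwiseAlignment <- function(x, ...) {
  cat(sprintf("<PairwiseAlignment> %s ~ %s shift %.4f, %d matches, score %.3f\n",
              x$id_a, x$id_b, x$shift, x$n_matches, x$score))
  invisible(x)
}

#' Estimate a random-alignment score threshold from decoys
#'
#' Aligns shuffled-mass decoy versions of randomly drawn spectrum pairs
#' (peak masses redrawn uniformly inside (0, M), scores kept) and
#' returns twice the mean best decoy alignment score. Used as the
#' default `min_score` of [build_network()].
#'
#' @param prms List of `PRMSpectrum` objects.
#' @param align_tol,min_matches,min_frac As in [align_pair()].
#' @param n_pairs Number of decoy pairs to sample.
#' @param seed Integer seed.
#' @return Non-negative numeric threshold.
#' @export
decoy_min_score <- function(prms, align_tol = 0.3, min_matches = 5,
                            min_frac = 0.8, n_pairs = 50, seed = 1L) {
  if (length(prms) < 2) return(0)
  with_seed(seed, {
    shuffle <- function(p) {
      n <- nrow(p$peaks)
      prm_spectrum(p$id, p$M,
                   mass = sort(stats::runif(n, 1e-6, p$M - 1e-6)),
                   score = p$peaks$score, provenance = p$provenance)
    }
    scores <- vapply(seq_len(n_pairs), function(k) {
      ij <- sample(length(prms), 2)
      al <- align_pair(shuffle(prms[[ij[1]]]), shuffle(prms[[ij[2]]]),
                       align_tol, min_matches, min_frac)
      if (is.null(al)) 0 else al$score
    }, numeric(1))
    2 * mean(scores)
  })
}

#' Build the spectral network
#'
#' Attempts all unordered pairs of spectra; an edge is kept iff the
#' best alignment has at least `min_matches` matched pairs and a score
#' of at least `min_score`. All inputs become nodes (isolated nodes
#' allowed).
#'
#' @param prms List of `PRMSpectrum` objects with unique ids.
#' @param align_tol,min_matches,min_frac As in [align_pair()].
#' @param min_score Numeric threshold, or `"auto"` for the
#'   decoy-calibrated default ([decoy_min_score()]).
#' @param seed Seed for decoy calibration when `min_score = "auto"`.
#' @return A `SpectralNetwork`: list with `nodes` (ids), `edges` (data
#'   frame `id_a`, `id_b`, `shift`, `n_matches`, `score`), `alignments`
#'   (list of `PairwiseAlignment`), `graph` (igraph), `membership`
#'   (component id per node), and `min_score` used.
#' @export
build_network <- function(prms, align_tol = 0.3, min_matches = 5,
                          min_frac = 0.8, min_score = "auto", seed = 1L) {
  ids <- vapply(prms, function(p) p$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate PRM spectrum ids")
  if (identical(min_score, "auto")) {
    min_score <- decoy_min_score(prms, align_tol, min_matches, min_frac,
                                 seed = seed)
  }
  n <- length(prms)
  alignments <- list()
  if (n >= 2) {
    nonempty <- vapply(prms, function(p) nrow(p$peaks) > 0, logical(1))
    for (i in seq_len(n - 1)) {
      if (!nonempty[i]) next
      for (j in (i + 1):n) {
        if (!nonempty[j]) next
        al <- align_pair(prms[[i]], prms[[j]], align_tol, min_matches,
                         min_frac)
        if (!is.null(al) && al$score >= min_score) {
          alignments[[length(alignments) + 1L]] <- al
        }
      }
    }
  }
  edges <- if (length(alignments) > 0) {
    do.call(rbind, lapply(alignments, function(a) {
      data.frame(id_a = a$id_a, id_b = a$id_b, shift = a$shift,
                 n_matches = a$n_matches, score = a$score,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(id_a = character(0), id_b = character(0), shift = numeric(0),
               n_matches = integer(0), score = numeric(0))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("id_a", "id_b")], directed = FALSE,
    vertices = data.frame(name = ids))
  membership <- igraph::components(g)$membership[ids]
  structure(list(nodes = ids, edges = edges, alignments = alignments,
                 graph = g, membership = membership, min_score = min_score),
            class = "SpectralNetwork")
}

#' @export
print.SpectralNetwork <- function(x, ...) {
  cat(sprintf("<SpectralNetwork> %d nodes, %d edges, %d components\n",
              length(x$nodes), nrow(x$edges), length(unique(x$membership))))
  invisible(x)
}
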