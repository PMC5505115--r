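# Prefix-residue-mass (PRM) spectra: conversion of MS/MS spectra into
# scored cumulative prefix masses, and per-precursor merging of
# CID/HCD/ETD triples by adding scores of matching masses.

#' Construct a PRM spectrum
#'
#' A PRM spectrum holds hypothesised cumulative N-terminal residue
#' masses with log-odds scores. `M` is the total residue mass (neutral
#' precursor mass minus one water); the boundary masses 0 and `M` are
#' implicit and never stored, so all peak masses lie strictly inside
#' `(0, M)`.
#'
#' @param id Spectrum or triple identifier.
#' @param M Total residue mass (Da).
#' @param mass,score Numeric peak vectors.
#' @param modes Character vector of contributing modes per peak
#'   (comma-separated when several).
#' @param provenance Modes that contributed to the whole spectrum.
#' @return An object of class `PRMSpectrum` with a `peaks` data frame
#'   sorted strictly ascending by mass.
#' @export
prm_spectrum <- function(id, M, mass = numeric(0), score = numeric(0),
                         modes = rep(NA_character_, length(mass)),
                         provenance = unique(modes[!is.na(modes)])) {
  stopifnot(M > 0, length(mass) == length(score),
            all(mass > 0 & mass < M))
  o <- order(mass)
  structure(list(id = as.character(id), M = as.numeric(M),
                 peaks = data.frame(mass = mass[o], score = score[o],
                                    modes = modes[o],
                                    stringsAsFactors = FALSE),
                 provenance = provenance),
            class = "PRMSpectrum")
}

#' @export
print.PRMSpectrum <- function(x, ...) {
  cat(sprintf("<PRMSpectrum %s> M = %.4f Da, %d peaks [%s]\n",
              x$id, x$M, nrow(x$peaks),
              paste(x$provenance, collapse = "+")))
  invisible(x)
}

#' Ideal PRM spectrum of a known peptide
#'
#' The true prefix ladder of `peptide` with a constant score per peak;
#' a convenience for constructing ground-truth spectra.
#'
#' @param peptide Peptide sequence.
#' @param score Score assigned to every true prefix mass.
#' @param id Spectrum id (defaults to the peptide).
#' @return A `PRMSpectrum`.
#' @export
#' @examples
#' ideal_prm("GASP")
ideal_prm <- function(peptide, score = 1, id = peptide) {
  pm <- prefix_masses(peptide)
  prm_spectrum(id, M = sum(residue_vector(peptide)),
               mass = pm, score = rep(score, length(pm)))
}

#' PRM scoring model
#'
#' Log-odds scoring of PRM candidates: a peak of intensity rank `r`
#' interpreted through ion series `s` scores
#' `log(tier_likelihood(r) * prior(s) / noise_likelihood)`. Tiers are
#' intensity-rank bands (top 10 / top 25 / top 50 / rest) with
#' likelihood ratios 8/4/2/1; series priors are CID b = y = 0.4, HCD
#' b = y = 0.35 and a = 0.1, ETD c = z = 0.45; the noise likelihood
#' is 1. All values are overridable: the model is a declared monotone
#' intensity-likelihood default, not a fitted model.
#'
#' @param tier_bounds Upper rank bounds of the intensity tiers.
#' @param tier_lr Likelihood ratios, one per tier plus the rest band.
#' @param priors Named list per mode of named series-prior vectors.
#' @param noise Noise likelihood (> 0).
#' @return An object of class `ScoringModel`.
#' @export
scoring_model <- function(tier_bounds = c(10, 25, 50),
                          tier_lr = c(8, 4, 2, 1),
                          priors = list(CID = c(b = 0.4, y = 0.4),
                                        HCD = c(b = 0.35, y = 0.35, a = 0.1),
                                        ETD = c(c = 0.45, z = 0.45)),
                          noise = 1) {
  stopifnot(length(tier_lr) == length(tier_bounds) + 1, all(tier_lr > 0),
            noise > 0)
  structure(list(tier_bounds = tier_bounds, tier_lr = tier_lr,
                 priors = priors, noise = noise),
            class = "ScoringModel")
}

# Fragment-mass tolerance defaults per dissociation mode: ion-trap
# readout (CID, ETD) 0.4 Da; Orbitrap HCD readout 0.02 Da.
default_frag_tol <- function(mode) {
  switch(mode, CID = 0.4, ETD = 0.4, HCD = 0.02,
         stop("unknown mode: ", mode))
}

#' Convert an MS/MS spectrum to a PRM spectrum
#'
#' Every peak is interpreted through every ion series of the spectrum's
#' mode (fragment charge 1 assumed): the candidate neutral fragment is
#' `(mz - proton) - offset`; an N-terminal series yields the PRM mass
#' directly, a C-terminal series yields `M - candidate`. Candidates
#' outside `(0, M)` are discarded; each candidate scores
#' `log(tier_likelihood(intensity rank) * series_prior / noise)`.
#' Candidates within `frag_tol` of one another are merged keeping the
#' maximum score. Both terminal interpretations are always generated;
#' the resulting mirror ambiguity is resolved downstream by
#' corroboration across the triple and the network.
#'
#' @param s A `Spectrum` with known mode.
#' @param model A [scoring_model()].
#' @param frag_tol Fragment tolerance (Da); mode-specific default.
#' @param frag_model A [fragmentation_model()] supplying the ion series
#'   per mode.
#' @return A `PRMSpectrum`.
#' @export
spectrum_to_prm <- function(s, model = scoring_model(), frag_tol = NULL,
                            frag_model = fragmentation_model(TRUE)) {
  if (!s$mode %in% c("CID", "HCD", "ETD")) stop("unknown mode: ", s$mode)
  if (is.null(frag_tol)) frag_tol <- default_frag_tol(s$mode)
  M <- neutral_precursor_mass(s) - MASS[["water"]]
  pk <- s$peaks
  if (nrow(pk) == 0) {
    return(prm_spectrum(s$spectrum_id, M, provenance = s$mode))
  }
  rank <- rank(-pk$intensity, ties.method = "min")
  tier <- findInterval(rank, model$tier_bounds + 1L) + 1L
  lr <- model$tier_lr[tier]
  series <- frag_model[[s$mode]]$series
  priors <- model$priors[[s$mode]]
  cand_mass <- numeric(0); cand_score <- numeric(0)
  for (i in seq_len(nrow(series))) {
    pr <- priors[[series$series[i]]]
    if (is.null(pr)) next
    cand <- (pk$mz - MASS[["proton"]]) - series$offset[i]
    m <- if (series$terminus[i] == "N") cand else M - cand
    keep <- m > 0 & m < M
    cand_mass <- c(cand_mass, m[keep])
    cand_score <- c(cand_score, log(lr[keep] * pr / model$noise))
  }
  if (length(cand_mass) == 0) {
    return(prm_spectrum(s$spectrum_id, M, provenance = s$mode))
  }
  # merge candidates within frag_tol, keeping the best score per cluster
  o <- order(cand_mass)
  cand_mass <- cand_mass[o]; cand_score <- cand_score[o]
  cl <- cumsum(c(1L, diff(cand_mass) > frag_tol))
  best <- vapply(split(seq_along(cl), cl), function(ix) {
    ix[which.max(cand_score[ix])]
  }, integer(1))
  prm_spectrum(s$spectrum_id, M,
               mass = cand_mass[best], score = cand_score[best],
               modes = rep(s$mode, length(best)), provenance = s$mode)
}

#' Merge the three PRM spectra of one triple
#'
#' Single-linkage clustering of the pooled peaks by mass (a gap larger
#' than `merge_tol` splits clusters); each cluster becomes one peak
#' whose mass is the score-weighted mean of its strongest coherent
#' sub-population (members re-clustered at `fine_tol`; weights floored
#' at a small positive value since log-odds scores may be negative)
#' and whose score is the sum of all member scores, so total score is
#' conserved exactly. Taking the strongest sub-population rather than
#' the all-member mean keeps a chained near-collision candidate from
#' dragging a corroborated mass past the residue-calling tolerance. Per-peak provenance records which modes
#' contributed.
#'
#' @param prms List of three `PRMSpectrum` objects from one triple.
#' @param merge_tol Mass tolerance (Da), default 0.3.
#' @param fine_tol Sub-clustering precision (Da) for the robust
#'   cluster mass, default 0.02 (the high-resolution readout
#'   precision).
#' @param m_tol Maximum spread of the three `M` values (Da).
#' @param id Output id; defaults to the common triple stem.
#' @return A merged `PRMSpectrum` (provenance = contributing modes).
#' @export
merge_triple <- function(prms, merge_tol = 0.3, fine_tol = 0.02,
                         m_tol = 0.05, id = NULL) {
  stopifnot(length(prms) == 3)
  Ms <- vapply(prms, function(p) p$M, numeric(1))
  if (max(Ms) - min(Ms) > m_tol) {
    stop("PRM spectra disagree on total residue mass beyond tolerance")
  }
  if (is.null(id)) id <- sub("\\.(CID|HCD|ETD)$", "", prms[[1]]$id)
  M <- mean(Ms)
  pk <- do.call(rbind, lapply(prms, function(p) p$peaks))
  prov <- unique(unlist(lapply(prms, function(p) p$provenance)))
  if (nrow(pk) == 0) return(prm_spectrum(id, M, provenance = prov))
  pk <- pk[order(pk$mass), , drop = FALSE]
  cl <- cumsum(c(1L, diff(pk$mass) > merge_tol))
  w <- pmax(pk$score, 1e-9)
  agg <- lapply(split(seq_len(nrow(pk)), cl), function(ix) {
    # robust cluster mass: a single-linkage cluster can chain a clutter
    # candidate onto a corroborated mass (compositional near-collisions
    # sit a few hundredths of a Da away), so averaging all members can
    # drag the mass past the residue-calling tolerance. Sub-cluster at
    # fragment precision and take the strongest coherent sub-population
    # as the mass; the full cluster still contributes the score.
    fcl <- cumsum(c(1L, diff(pk$mass[ix]) > fine_tol))
    sub <- split(ix, fcl)
    best <- sub[[which.max(vapply(sub, function(jx) sum(w[jx]), numeric(1)))]]
    list(mass = sum(pk$mass[best] * w[best]) / sum(w[best]),
         score = sum(pk$score[ix]),
         modes = paste(sort(unique(unlist(strsplit(pk$modes[ix], ",")))),
                       collapse = ","))
  })
  mass <- vapply(agg, `[[`, numeric(1), "mass")
  # clamp weighted means into (0, M); cluster members are inside by invariant
  mass <- pmin(pmax(mass, 1e-9), M - 1e-9)
  prm_spectrum(id, M,
               mass = mass,
               score = vapply(agg, `[[`, numeric(1), "score"),
               modes = vapply(agg, `[[`, character(1), "modes"),
               provenance = prov)
}

#' Sparsify a merged PRM spectrum by corroboration
#'
#' Retains peaks corroborated by at least `min_modes` dissociation
#' modes and/or the `max_peaks` highest-scoring peaks. Rationale: a
#' genuine prefix mass is corroborated by N- and C-terminal ion series
#' of all three chemistries, whereas the N/C mirror image of a b/y pair
#' falls at the same spurious mass in CID and HCD but never in ETD
#' (c/z offsets shift it elsewhere), so cross-chemistry corroboration
#' separates true prefix masses from mirror-image artifacts before
#' network alignment.
#'
#' @param prm A `PRMSpectrum` (typically merged).
#' @param min_modes Minimum number of contributing modes per peak, or
#'   `NULL` to skip the filter.
#' @param max_peaks Keep at most this many peaks by score, or `NULL`.
#' @return A filtered `PRMSpectrum`.
#' @export
sparsify_prm <- function(prm, min_modes = NULL, max_peaks = NULL) {
  pk <- prm$peaks
  keep <- rep(TRUE, nrow(pk))
  if (!is.null(min_modes) && nrow(pk) > 0) {
    nm <- vapply(strsplit(pk$modes, ","), function(x) sum(!is.na(x)), integer(1))
    keep <- keep & nm >= min_modes
  }
  if (!is.null(max_peaks) && sum(keep) > max_peaks) {
    ix <- which(keep)
    drop <- ix[order(pk$score[ix], decreasing = TRUE)][-seq_len(max_peaks)]
    keep[drop] <- FALSE
  }
  prm_spectrum(prm$id, prm$M, mass = pk$mass[keep], score = pk$score[keep],
               modes = pk$modes[keep], provenance = prm$provenance)
}

#' Convert a spectrum triple to a merged PRM spectrum
#'
#' Convenience wrapper: [spectrum_to_prm()] on each member followed by
#' [merge_triple()].
#'
#' @param triple A `SpectrumTriple`.
#' @param model A [scoring_model()].
#' @param merge_tol Merge tolerance (Da).
#' @param frag_model A [fragmentation_model()].
#' @return A merged `PRMSpectrum` with the triple's id.
#' @export
triple_to_prm <- function(triple, model = scoring_model(), merge_tol = 0.3,
                          frag_model = fragmentation_model(TRUE)) {
  prms <- lapply(list(triple$cid, triple$hcd, triple$etd), spectrum_to_prm,
                 model = model, frag_model = frag_model)
  merge_triple(prms, merge_tol = merge_tol, m_tol = 1.0, id = triple$triple_id)
}

#' Write / read a PRM archive (TSV)
#'
#' Long-format archive: one row per peak with columns `id`, `M`,
#' `mass`, `score`, `modes`.
#'
#' @param prms List of `PRMSpectrum` objects.
#' @param path TSV path.
#' @return For the writer, `path` invisibly; for the reader, a list of
#'   `PRMSpectrum`.
#' @export
write_prm_archive <- function(prms, path) {
  rows <- lapply(prms, function(p) {
    if (nrow(p$peaks) == 0) {
      data.frame(id = p$id, M = p$M, mass = NA_real_, score = NA_real_,
                 modes = NA_character_, stringsAsFactors = FALSE)
    } else {
      data.frame(id = p$id, M = p$M, mass = p$peaks$mass,
                 score = p$peaks$score, modes = p$peaks$modes,
                 stringsAsFactors = FALSE)
    }
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_prm_archive
#' @param prov Provenance assigned to all spectra on read.
#' @export
read_prm_archive <- function(path, prov = c("CID", "HCD", "ETD")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(split(tab, factor(tab$id, levels = unique(tab$id))), function(d) {
    ok <- !is.na(d$mass)
    prm_spectrum(d$id[1], d$M[1], mass = d$mass[ok], score = d$score[ok],
                 modes = d$modes[ok], provenance = prov)
  })
}
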