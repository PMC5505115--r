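# Synthetic venom-proteomics acquisition: proteome generation, 10 kDa
# fractionation, multi-protease digestion, and CID/HCD/ETD triple
# simulation with ground truth.

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Protease cleavage rule
#'
#' C-terminal-side cleavage specificity: cut after any residue in
#' `cleave_after` unless the following residue is in `not_before`.
#'
#' @param name Enzyme name.
#' @param cleave_after Character vector of residues cut after.
#' @param not_before Character vector of residues blocking cleavage when
#'   they follow the site (e.g. proline).
#' @return An object of class `ProteaseRule`.
#' @export
protease_rule <- function(name, cleave_after, not_before = character(0)) {
  stopifnot(length(cleave_after) > 0)
  structure(list(name = name,
                 cleave_after = cleave_after,
                 not_before = not_before),
            class = "ProteaseRule")
}

#' Standard protease rules
#'
#' Trypsin cleaves after K/R not before P; chymotrypsin after F/W/Y not
#' before P; pepsin (low pH) after F/L/W/Y.
#'
#' @param name One of `"trypsin"`, `"chymotrypsin"`, `"pepsin"`.
#' @return A [protease_rule()].
#' @export
standard_protease <- function(name = c("trypsin", "chymotrypsin", "pepsin")) {
  name <- match.arg(name)
  switch(name,
    trypsin      = protease_rule("trypsin", c("K", "R"), "P"),
    chymotrypsin = protease_rule("chymotrypsin", c("F", "W", "Y"), "P"),
    pepsin       = protease_rule("pepsin", c("F", "L", "W", "Y")))
}

#' Digestion specification
#'
#' Couples a protease rule with a completeness model. In stochastic mode
#' each susceptible site is cut independently with probability
#' `p_cleave`, which models incubation time (a 4 h trypsin digest is
#' modelled as `p_cleave = 0.5` against 0.9 for 18 h digests: partial
#' digestion is the source of overlapping peptides). In deterministic
#' mode (`seed = NULL` in [digest()]) all products with at most
#' `max_missed` missed cleavages are enumerated.
#'
#' @param rule A [protease_rule()].
#' @param p_cleave Probability a susceptible site is cut, in `[0, 1]`.
#' @param max_missed Missed-cleavage bound for deterministic digestion.
#' @param len_min,len_max Retained product length bounds (residues);
#'   `len_min` must be at least 4.
#' @param name Digest label (defaults to the enzyme name).
#' @return An object of class `DigestSpec`.
#' @export
digest_spec <- function(rule, p_cleave = 0.9, max_missed = 2L,
                        len_min = 6L, len_max = 30L, name = rule$name) {
  stopifnot(inherits(rule, "ProteaseRule"),
            p_cleave >= 0, p_cleave <= 1, max_missed >= 0, len_min >= 4)
  structure(list(rule = rule, p_cleave = p_cleave,
                 max_missed = as.integer(max_missed),
                 len_min = as.integer(len_min), len_max = as.integer(len_max),
                 name = name),
            class = "DigestSpec")
}

#' The four-digest experimental design
#'
#' The digest set emulated by the simulator: trypsin 4 h (partial,
#' `p_cleave = 0.5`), trypsin 18 h, chymotrypsin 18 h, and pepsin 18 h
#' (each `p_cleave = 0.9`).
#'
#' @param len_min,len_max Product length bounds passed to every digest.
#' @return Named list of [digest_spec()] objects.
#' @export
default_digests <- function(len_min = 6L, len_max = 30L) {
  list(
    trypsin_4h   = digest_spec(standard_protease("trypsin"), p_cleave = 0.5,
                               len_min = len_min, len_max = len_max,
                               name = "trypsin_4h"),
    trypsin_18h  = digest_spec(standard_protease("trypsin"), p_cleave = 0.9,
                               len_min = len_min, len_max = len_max,
                               name = "trypsin_18h"),
    chymotrypsin_18h = digest_spec(standard_protease("chymotrypsin"),
                                   p_cleave = 0.9, len_min = len_min,
                                   len_max = len_max,
                                   name = "chymotrypsin_18h"),
    pepsin_18h   = digest_spec(standard_protease("pepsin"), p_cleave = 0.9,
                               len_min = len_min, len_max = len_max,
                               name = "pepsin_18h")
  )
}

#' Generate a synthetic proteome
#'
#' Draws `n` protein sequences i.i.d. from a residue frequency table
#' (uniform over the 20 letters by default), with lengths uniform in
#' `len_range`. Deterministic under `seed`. User-supplied sequences are
#' appended verbatim.
#'
#' @param n Number of random proteins (>= 1).
#' @param len_range Length bounds in residues, e.g. `c(60, 200)`.
#' @param seed Integer seed.
#' @param residue_freq Named probability vector over residue letters;
#'   default uniform.
#' @param extra_sequences Optional named character vector of sequences
#'   appended as additional records.
#' @return Data frame with columns `accession`, `description`,
#'   `sequence`.
#' @export
generate_proteome <- function(n, len_range = c(60, 200), seed = 1L,
                              residue_freq = NULL, extra_sequences = NULL) {
  stopifnot(n >= 1, length(len_range) == 2, len_range[1] >= 4)
  alphabet <- names(residue_masses())
  if (is.null(residue_freq)) {
    residue_freq <- stats::setNames(rep(1 / length(alphabet), length(alphabet)),
                                    alphabet)
  }
  stopifnot(all(names(residue_freq) %in% alphabet))
  seqs <- with_seed(seed, {
    lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
    vapply(lens, function(L) {
      paste(sample(names(residue_freq), L, replace = TRUE,
                   prob = residue_freq), collapse = "")
    }, character(1))
  })
  out <- data.frame(
    accession = sprintf("SYN%04d", seq_len(n)),
    description = "synthetic venom protein",
    sequence = seqs,
    stringsAsFactors = FALSE
  )
  if (!is.null(extra_sequences)) {
    out <- rbind(out, data.frame(
      accession = names(extra_sequences),
      description = "user-supplied sequence",
      sequence = unname(extra_sequences),
      stringsAsFactors = FALSE
    ))
  }
  out
}

#' Partition proteins at a molecular-weight cutoff
#'
#' Emulates ultrafiltration at a cutoff mass (10 kDa in the emulated
#' design). The mass proxy is the monoisotopic residue-mass sum plus one
#' water; proteins strictly above the cutoff go to `above`, the rest to
#' `below`.
#'
#' @param records Protein data frame (see [generate_proteome()]).
#' @param cutoff_da Cutoff mass (Da), > 0.
#' @return List with data frames `above` and `below`.
#' @export
fractionate <- function(records, cutoff_da = 10000) {
  stopifnot(cutoff_da > 0)
  if (nrow(records) == 0) return(list(above = records, below = records))
  masses <- vapply(records$sequence, peptide_mass, numeric(1))
  list(above = records[masses > cutoff_da, , drop = FALSE],
       below = records[masses <= cutoff_da, , drop = FALSE])
}

#' Digest a protein sequence in silico
#'
#' Candidate sites are positions `i` with residue `i` in `cleave_after`
#' and residue `i + 1` not in `not_before`. With a `seed`, each site is
#' cut independently with probability `p_cleave` (stochastic
#' completeness); with `seed = NULL`, all products with at most
#' `max_missed` missed cleavages are enumerated. Products are filtered
#' to the spec's length bounds. Start positions are 0-based.
#'
#' @param sequence Protein sequence (uppercase residue letters).
#' @param spec A [digest_spec()].
#' @param seed Integer seed for stochastic digestion, or `NULL` for
#'   deterministic enumeration.
#' @return Data frame with columns `peptide`, `start`, `n_missed`.
#' @export
digest <- function(sequence, spec, seed = NULL) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(res, names(residue_masses()))
  if (length(bad) > 0) stop("unknown residue letter(s): ",
                            paste(unique(bad), collapse = ", "))
  n <- length(res)
  sites <- which(res[-n] %in% spec$rule$cleave_after &
                   !(res[-1] %in% spec$rule$not_before))
  pieces <- function(cuts) {
    bounds <- c(0L, cuts, n)
    data.frame(start = bounds[-length(bounds)],
               end = bounds[-1])
  }
  if (!is.null(seed)) {
    cuts <- with_seed(seed, sites[stats::runif(length(sites)) < spec$p_cleave])
    prod <- pieces(cuts)
    prod$n_missed <- vapply(seq_len(nrow(prod)), function(i) {
      sum(sites > prod$start[i] & sites < prod$end[i])
    }, integer(1))
  } else {
    base <- pieces(sites)
    rows <- list()
    for (i in seq_len(nrow(base))) {
      for (j in i:min(nrow(base), i + spec$max_missed)) {
        rows[[length(rows) + 1L]] <- data.frame(
          start = base$start[i], end = base$end[j], n_missed = j - i)
      }
    }
    prod <- do.call(rbind, rows)
  }
  prod$peptide <- substr(rep(sequence, nrow(prod)), prod$start + 1L, prod$end)
  len <- prod$end - prod$start
  prod <- prod[len >= spec$len_min & len <= spec$len_max, , drop = FALSE]
  rownames(prod) <- NULL
  prod[, c("peptide", "start", "n_missed")]
}

# ---------------------------------------------------------------------------
# Fragmentation model

.SERIES_OFFSET <- c(b = 0.0, a = -27.99491, y = 18.010565,
                    c = 17.02655, z = 1.99184)
.SERIES_TERMINUS <- c(b = "N", a = "N", y = "C", c = "N", z = "C")

#' Per-mode fragmentation model
#'
#' Ion series tables, detection probabilities, mean relative
#' intensities, fragment m/z jitter, and noise-peak counts for each
#' dissociation mode. Defaults: CID produces b/y ions, HCD b/y/a, ETD
#' c/z-dot; neutral-fragment offsets are the standard monoisotopic
#' values (b 0, a -27.99491, y +18.010565, c +17.02655, z-dot +1.99184
#' Da). Fragment m/z jitter is 0.2 Da s.d. for the ion-trap readouts
#' (CID, ETD) and 0.01 Da for HCD.
#'
#' @param noiseless If `TRUE`, return the degenerate preset: detection
#'   probability 1, zero jitter, zero noise peaks, fixed intensities.
#' @return An object of class `FragmentationModel`: per mode a list with
#'   `series` data frame (`series`, `terminus`, `offset`, `detect`,
#'   `intensity`), `jitter_sd`, `noise_lambda`, `intensity_sdlog`.
#' @export
fragmentation_model <- function(noiseless = FALSE) {
  mk <- function(series, detect, intensity, jitter_sd, noise_lambda) {
    list(series = data.frame(series = series,
                             terminus = .SERIES_TERMINUS[series],
                             offset = unname(.SERIES_OFFSET[series]),
                             detect = if (noiseless) rep(1, length(series)) else detect,
                             intensity = intensity,
                             stringsAsFactors = FALSE),
         jitter_sd = if (noiseless) 0 else jitter_sd,
         noise_lambda = if (noiseless) 0 else noise_lambda,
         intensity_sdlog = if (noiseless) 0 else 0.4)
  }
  structure(list(
    CID = mk(c("b", "y"), c(0.80, 0.92), c(1.0, 1.0), 0.2, 8),
    HCD = mk(c("b", "y", "a"), c(0.85, 0.95, 0.35), c(1.0, 1.0, 0.3), 0.01, 8),
    ETD = mk(c("c", "z"), c(0.90, 0.85), c(1.0, 1.0), 0.2, 8)
  ), class = "FragmentationModel")
}

#' Theoretical fragment ions of a peptide
#'
#' For every ion series of the mode and every cut site `k` in
#' `1..n-1`: the N-terminal-series neutral fragment is the prefix
#' residue-mass sum plus the series offset, the C-terminal-series
#' fragment the suffix sum plus offset; singly protonated m/z is
#' neutral + proton. Cysteine carries the fixed carbamidomethyl mass.
#'
#' @param peptide Peptide sequence.
#' @param mode `"CID"`, `"HCD"` or `"ETD"`.
#' @param model A [fragmentation_model()].
#' @return Data frame sorted by `mz` with columns `mz`, `intensity`,
#'   `series`, `cut` (empty for a 1-residue peptide).
#' @export
#' @examples
#' theoretical_ions("AG", "CID")  # b1 at 72.04439, y1 at 76.03930
theoretical_ions <- function(peptide, mode, model = fragmentation_model(TRUE)) {
  mode <- match.arg(mode, c("CID", "HCD", "ETD"))
  rv <- residue_vector(peptide)
  n <- length(rv)
  empty <- data.frame(mz = numeric(0), intensity = numeric(0),
                      series = character(0), cut = integer(0))
  if (n < 2) return(empty)
  pre <- cumsum(rv)[-n]
  suf <- rev(cumsum(rev(rv)))[-1]   # suffix sums for cuts 1..n-1
  tab <- model[[mode]]$series
  out <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    neutral <- if (tab$terminus[i] == "N") pre + tab$offset[i]
               else suf + tab$offset[i]
    data.frame(mz = neutral + MASS[["proton"]],
               intensity = rep(tab$intensity[i], n - 1L),
               series = tab$series[i],
               cut = seq_len(n - 1L))
  }))
  out <- out[order(out$mz), ]
  rownames(out) <- NULL
  out
}

#' Simulate a CID/HCD/ETD spectrum triple for one peptide
#'
#' Per mode, each theoretical ion is retained with its series detection
#' probability, its m/z jittered with the mode's s.d., its intensity
#' multiplied by log-normal noise; uniform noise peaks are added
#' (Poisson count). The noiseless preset reproduces
#' [theoretical_ions()] exactly. Bit-reproducible under `seed`.
#'
#' @param peptide Peptide sequence.
#' @param charge Precursor charge (2 or 3).
#' @param model A [fragmentation_model()].
#' @param seed Integer seed (may be `NULL` for the noiseless preset).
#' @param triple_id Identifier stem; member spectra get `.CID` etc.
#' @param scan0 First scan number of the triple.
#' @return A `SpectrumTriple`.
#' @export
simulate_triple <- function(peptide, charge = 2L,
                            model = fragmentation_model(TRUE),
                            seed = NULL, triple_id = peptide, scan0 = 1L) {
  stopifnot(charge %in% 2:3)
  pm <- peptide_mass(peptide)
  precursor_mz <- (pm + charge * MASS[["proton"]]) / charge
  sim_mode <- function(mode, scan) {
    th <- theoretical_ions(peptide, mode, model)
    m <- model[[mode]]
    keep <- stats::runif(nrow(th)) < m$series$detect[match(th$series, m$series$series)]
    mz <- th$mz[keep] + stats::rnorm(sum(keep), 0, m$jitter_sd)
    int <- th$intensity[keep] * stats::rlnorm(sum(keep), 0, m$intensity_sdlog)
    n_noise <- if (m$noise_lambda > 0) stats::rpois(1, m$noise_lambda) else 0L
    if (n_noise > 0) {
      mz <- c(mz, stats::runif(n_noise, 100, pm))
      int <- c(int, 0.05 * stats::rlnorm(n_noise, 0, 1))
    }
    ok <- mz > 0
    spectrum(paste0(triple_id, ".", mode), precursor_mz, charge, mode,
             mz = mz[ok], intensity = int[ok], scan = scan)
  }
  build <- function() {
    spectrum_triple(sim_mode("CID", scan0),
                    sim_mode("HCD", scan0 + 1L),
                    sim_mode("ETD", scan0 + 2L),
                    triple_id = triple_id)
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Simulate acquisition of peptide pools
#'
#' Emulates the survey-scan eligibility window and, optionally,
#' top-3 data-dependent acquisition. Precursors whose m/z falls outside
#' `mz_range` at every charge in `charges` are dropped. With
#' `dda = FALSE` (default) each eligible peptide yields exactly one
#' triple at the lowest eligible charge. With `dda = TRUE`, peptides
#' elute as Gaussian profiles; per acquisition cycle the top 3 peptides
#' by instantaneous abundance are selected and then dynamically excluded
#' for `exclusion_s` seconds.
#'
#' @param pools Named list (one element per digest) of data frames with
#'   columns `peptide`, `accession`, `start` and optionally `abundance`.
#' @param model A [fragmentation_model()].
#' @param seed Integer seed.
#' @param dda Logical; run the DDA selection simulation.
#' @param mz_range MS1 survey window (Th), default `c(350, 1800)`.
#' @param charges Candidate precursor charges, default `2:3`.
#' @param exclusion_s Dynamic exclusion time (s), default 60.
#' @param cycle_s Acquisition cycle time (s), default 5.
#' @param gradient_s DDA gradient length (s), default 600.
#' @param out_dir If non-`NULL`, write one MGF per digest plus
#'   `ground_truth.tsv` there.
#' @return List with `spectra` (named list of per-digest `Spectrum`
#'   lists, triples flattened in scan order) and `ground_truth` (data
#'   frame: `peptide`, `accession`, `start`, `digest`, `charge`,
#'   `triple_id`).
#' @export
simulate_acquisition <- function(pools, model = fragmentation_model(TRUE),
                                 seed = 1L, dda = FALSE,
                                 mz_range = c(350, 1800), charges = 2:3,
                                 exclusion_s = 60, cycle_s = 5,
                                 gradient_s = 600, out_dir = NULL) {
  stopifnot(length(pools) > 0, !is.null(names(pools)))
  with_seed(seed, {
    gt <- list()
    spectra <- list()
    for (dg in names(pools)) {
      pool <- pools[[dg]]
      if (is.null(pool$abundance)) pool$abundance <- rep(1, nrow(pool))
      # precursor eligibility: lowest charge whose m/z is in the window
      z <- vapply(pool$peptide, function(p) {
        pm <- peptide_mass(p)
        mzs <- (pm + charges * MASS[["proton"]]) / charges
        ok <- which(mzs >= mz_range[1] & mzs <= mz_range[2])
        if (length(ok) == 0) NA_integer_ else charges[ok[1]]
      }, integer(1))
      pool <- pool[!is.na(z), , drop = FALSE]
      z <- z[!is.na(z)]
      sel <- if (dda && nrow(pool) > 0) {
        rt <- stats::runif(nrow(pool), 0.1 * gradient_s, 0.9 * gradient_s)
        peak_sd <- 15
        excluded_until <- rep(-Inf, nrow(pool))
        picks <- list()
        for (t in seq(0, gradient_s, by = cycle_s)) {
          signal <- pool$abundance * stats::dnorm(t, rt, peak_sd) * peak_sd
          cand <- which(signal > 1e-3 & t >= excluded_until)
          cand <- cand[order(signal[cand], decreasing = TRUE)]
          cand <- utils::head(cand, 3L)
          for (i in cand) {
            excluded_until[i] <- t + exclusion_s
            picks[[length(picks) + 1L]] <- i
          }
        }
        unlist(picks)
      } else seq_len(nrow(pool))
      dg_spectra <- list()
      scan <- 1L
      for (k in seq_along(sel)) {
        i <- sel[k]
        tid <- sprintf("%s|t%04d|%s", dg, k, pool$peptide[i])
        tr <- simulate_triple(pool$peptide[i], z[i], model, seed = NULL,
                              triple_id = tid, scan0 = scan)
        scan <- scan + 3L
        dg_spectra <- c(dg_spectra, list(tr$cid, tr$hcd, tr$etd))
        gt[[length(gt) + 1L]] <- data.frame(
          peptide = pool$peptide[i], accession = pool$accession[i],
          start = pool$start[i], digest = dg, charge = z[i],
          triple_id = tid, stringsAsFactors = FALSE)
      }
      spectra[[dg]] <- dg_spectra
    }
    ground_truth <- if (length(gt) > 0) do.call(rbind, gt) else
      data.frame(peptide = character(0), accession = character(0),
                 start = integer(0), digest = character(0),
                 charge = integer(0), triple_id = character(0))
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      for (dg in names(spectra)) {
        write_mgf(spectra[[dg]], file.path(out_dir, paste0(dg, ".mgf")))
      }
      utils::write.table(ground_truth,
                         file.path(out_dir, "ground_truth.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    list(spectra = spectra, ground_truth = ground_truth)
  })
}

#' Digest a proteome into per-digest peptide pools
#'
#' Applies each digest specification to every protein, with stochastic
#' site cutting seeded per (digest, protein) so the whole pool set is
#' reproducible from one seed.
#'
#' @param records Protein data frame.
#' @param digests Named list of [digest_spec()] (default
#'   [default_digests()]).
#' @param seed Integer seed; `NULL` for deterministic enumeration.
#' @return Named list of pool data frames (`peptide`, `accession`,
#'   `start`).
#' @export
digest_proteome <- function(records, digests = default_digests(), seed = 1L) {
  out <- list()
  for (d in seq_along(digests)) {
    rows <- list()
    for (p in seq_len(nrow(records))) {
      sd <- if (is.null(seed)) NULL else seed + 1000L * d + p
      pep <- digest(records$sequence[p], digests[[d]], seed = sd)
      if (nrow(pep) > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          peptide = pep$peptide, accession = records$accession[p],
          start = pep$start, stringsAsFactors = FALSE)
      }
    }
    pool <- if (length(rows) > 0) do.call(rbind, rows) else
      data.frame(peptide = character(0), accession = character(0),
                 start = integer(0))
    out[[names(digests)[d]]] <- pool
  }
  out
}
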