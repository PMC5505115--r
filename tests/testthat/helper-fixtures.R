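# Shared generators for test fixtures (everything built in code).

random_peptide <- function(len, alphabet = names(residue_masses())) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

random_spectrum <- function(id, n_peaks = 10, mode = "CID", charge = 2L,
                            scan = 1L) {
  mz <- sort(runif(n_peaks, 120, 1400))
  spectrum(id, precursor_mz = runif(1, 400, 900), precursor_charge = charge,
           mode = mode, mz = mz, intensity = rexp(n_peaks, 1 / 100),
           scan = scan)
}

random_prm <- function(id, n_peaks = 8, M = 600, positive = FALSE) {
  mass <- sort(runif(n_peaks, 1, M - 1))
  score <- if (positive) runif(n_peaks, 0.5, 3) else runif(n_peaks, -0.5, 3)
  prm_spectrum(id, M, mass = mass, score = score)
}

# A noiseless merged-and-sparsified PRM spectrum of a known peptide,
# produced through the full simulate -> convert -> merge path.
peptide_prm <- function(peptide, charge = 2L, min_modes = 3L) {
  tr <- simulate_triple(peptide, charge = charge,
                        model = fragmentation_model(noiseless = TRUE))
  sparsify_prm(triple_to_prm(tr), min_modes = min_modes)
}

corpus_path <- function() {
  p <- system.file("extdata", "denovo_strings.txt", package = "metaspec")
  if (nzchar(p)) p else file.path("..", "..", "inst", "extdata",
                                  "denovo_strings.txt")
}

# small helper: construct a glued-component object by hand
mk_glued <- function(masses, scores, chains, M = max(masses) + 100) {
  members <- vector("list", length(masses))
  for (s in seq_along(chains)) {
    for (k in seq_along(chains[[s]])) {
      v <- chains[[s]][k]
      members[[v]] <- rbind(members[[v]], data.frame(
        id = paste0("s", s), peak = k, frame_mass = masses[v],
        score = NA_real_, stringsAsFactors = FALSE))
    }
  }
  vertices <- lapply(seq_along(masses), function(v) {
    m <- members[[v]]
    if (is.null(m)) {
      m <- data.frame(id = paste0("solo", v), peak = 1L,
                      frame_mass = masses[v], score = NA_real_,
                      stringsAsFactors = FALSE)
    }
    list(members = m, consensus_mass = masses[v], total_score = scores[v])
  })
  list(vertices = vertices, offsets = NULL, anchor = "s1", M = M,
       ids = paste0("s", seq_along(chains)))
}

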