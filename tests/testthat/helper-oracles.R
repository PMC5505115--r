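# Independent brute-force oracles used to check the optimised
# implementations on small instances.

# All monotone matchings between two peak lists under a fixed shift,
# enumerated explicitly over the feasible pair set (no dynamic
# programming): returns the lexicographic best (score, n real pairs).
oracle_match <- function(mass_a, score_a, real_a, mass_b, score_b, real_b,
                         shift, tol) {
  feas <- which(outer(mass_a, mass_b + shift,
                      function(x, y) abs(x - y)) <= tol, arr.ind = TRUE)
  if (nrow(feas) == 0) return(c(score = 0, n_real = 0))
  feas <- feas[order(feas[, 1], feas[, 2]), , drop = FALSE]
  best <- c(score = 0, n_real = 0)
  rec <- function(k, last_i, last_j, sc, nr) {
    if (sc > best[["score"]] ||
        (sc == best[["score"]] && nr > best[["n_real"]])) {
      best <<- c(score = sc, n_real = nr)
    }
    if (k > nrow(feas)) return()
    for (t in k:nrow(feas)) {
      i <- feas[t, 1]; j <- feas[t, 2]
      if (i > last_i && j > last_j) {
        real <- real_a[i] && real_b[j]
        w <- if (real) score_a[i] + score_b[j] else 0
        rec(t + 1L, i, j, sc + w, nr + as.integer(real && w != 0))
      }
    }
  }
  rec(1L, 0L, 0L, 0, 0L)
  best
}

# Exhaustive shift-and-matching search over all pairwise differences
# (virtual boundary peaks at 0 and M included, score 0). Mirrors the
# align_pair contract with the overlap-completeness filter disabled.
oracle_align <- function(a, b, align_tol, min_matches) {
  mass_a <- c(0, a$peaks$mass, a$M); score_a <- c(0, a$peaks$score, 0)
  real_a <- c(FALSE, rep(TRUE, nrow(a$peaks)), FALSE)
  mass_b <- c(0, b$peaks$mass, b$M); score_b <- c(0, b$peaks$score, 0)
  real_b <- c(FALSE, rep(TRUE, nrow(b$peaks)), FALSE)
  cand <- unique(round(as.vector(outer(mass_a, mass_b, "-")), 6))
  best <- NULL
  for (s in cand) {
    m <- oracle_match(mass_a, score_a, real_a, mass_b, score_b, real_b,
                      s, align_tol)
    if (m[["n_real"]] < min_matches) next
    if (is.null(best) || m[["score"]] > best$score) {
      best <- list(shift = s, score = m[["score"]], n_real = m[["n_real"]])
    }
  }
  best
}

# Exhaustive enumeration of every directed path in a small DAG;
# returns the maximum total vertex score.
oracle_heaviest_path <- function(n, edges, vscore) {
  succ <- vector("list", n)
  for (e in edges) succ[[e[1]]] <- c(succ[[e[1]]], e[2])
  best <- -Inf
  walk <- function(v, acc) {
    acc <- acc + vscore[v]
    best <<- max(best, acc)
    for (w in succ[[v]]) walk(w, acc)
  }
  for (v in seq_len(n)) walk(v, 0)
  best
}

# Independent enumeration of residue multisets for a gap mass: loops
# over per-residue counts rather than a nondecreasing DFS.
oracle_gap_comps <- function(mass, tol, max_residues) {
  tab <- sort(metaspec::calling_table())
  out <- list()
  rec <- function(idx, left, remaining, acc) {
    if (remaining <= tol && remaining >= -tol && length(acc) > 0) {
      out[[length(out) + 1L]] <<- sort(acc)
    }
    if (idx > length(tab) || left == 0L || remaining < -tol) return()
    max_k <- min(left, floor((remaining + tol) / tab[[idx]]))
    for (k in 0:max_k) {
      rec(idx + 1L, left - k, remaining - k * tab[[idx]],
          c(acc, rep(names(tab)[idx], k)))
    }
  }
  rec(1L, as.integer(max_residues), mass, character(0))
  unique(out)
}

# Brute-force triple grouping: mirrors the documented scan-order greedy
# convention with explicit searches.
oracle_group_count <- function(spectra, tol) {
  scans <- vapply(spectra, function(s) s$scan, integer(1))
  spectra <- spectra[order(scans)]
  used <- logical(length(spectra))
  n <- 0L
  info <- function(s) c(s$precursor_mz, s$precursor_charge)
  for (i in seq_along(spectra)) {
    if (used[i] || spectra[[i]]$mode != "CID") next
    hcd <- 0L
    for (j in seq_along(spectra)) {
      if (j > i && !used[j] && spectra[[j]]$mode == "HCD" &&
          spectra[[j]]$precursor_charge == spectra[[i]]$precursor_charge &&
          abs(spectra[[j]]$precursor_mz - spectra[[i]]$precursor_mz) <= tol) {
        hcd <- j; break
      }
    }
    if (hcd == 0L) next
    etd <- 0L
    for (k in seq_along(spectra)) {
      if (k > hcd && !used[k] && spectra[[k]]$mode == "ETD" &&
          spectra[[k]]$precursor_charge == spectra[[i]]$precursor_charge &&
          abs(spectra[[k]]$precursor_mz - spectra[[i]]$precursor_mz) <= tol) {
        etd <- k; break
      }
    }
    if (etd == 0L) next
    used[c(i, hcd, etd)] <- TRUE
    n <- n + 1L
  }
  n
}
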