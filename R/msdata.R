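#' Construct an MS/MS spectrum
#'
#' A centroided tandem mass spectrum with an annotated fragmentation
#' mode. Peaks are stored as a two-column data frame (`mz`, `intensity`)
#' sorted ascending by m/z.
#'
#' @param spectrum_id Unique identifier (text).
#' @param precursor_mz Precursor m/z (Th).
#' @param precursor_charge Integer charge state, 1-5.
#' @param mode Fragmentation mode: one of `"CID"`, `"HCD"`, `"ETD"`.
#' @param mz,intensity Numeric peak vectors of equal length.
#' @param scan Positive integer scan number.
#' @param source_file Originating file (text, optional).
#' @param rt Retention time in seconds (optional).
#' @return An object of class `Spectrum`.
#' @export
spectrum <- function(spectrum_id, precursor_mz, precursor_charge, mode,
                     mz = numeric(0), intensity = numeric(0),
                     scan = 1L, source_file = NA_character_, rt = NA_real_) {
  mode <- match.arg(mode, c("CID", "HCD", "ETD"))
  stopifnot(length(mz) == length(intensity),
            all(mz > 0), all(intensity >= 0),
            precursor_charge %in% 1:5)
  o <- order(mz)
  s <- structure(list(
    spectrum_id = as.character(spectrum_id),
    source_file = source_file,
    scan = as.integer(scan),
    precursor_mz = as.numeric(precursor_mz),
    precursor_charge = as.integer(precursor_charge),
    mode = mode,
    rt = rt,
    peaks = data.frame(mz = mz[o], intensity = intensity[o])
  ), class = "Spectrum")
  if (neutral_precursor_mass(s) <= 0) {
    stop("non-positive neutral precursor mass for spectrum ", spectrum_id)
  }
  s
}

#' @export
print.Spectrum <- function(x, ...) {
  cat(sprintf("<Spectrum %s> %s scan %d, precursor %.4f (%d+), %d peaks\n",
              x$spectrum_id, x$mode, x$scan, x$precursor_mz,
              x$precursor_charge, nrow(x$peaks)))
  invisible(x)
}

#' Neutral precursor mass of a spectrum
#'
#' `precursor_mz * z - z * proton`.
#'
#' @param s A `Spectrum`.
#' @return Neutral mass (Da).
#' @export
neutral_precursor_mass <- function(s) {
  s$precursor_mz * s$precursor_charge - s$precursor_charge * MASS[["proton"]]
}

#' Construct a CID/HCD/ETD spectrum triple
#'
#' Three spectra acquired from the same precursor with the three
#' dissociation modes. All three must share the precursor charge and
#' agree on precursor m/z within `precursor_tol`.
#'
#' @param cid,hcd,etd `Spectrum` objects with the matching modes.
#' @param precursor_tol Maximum pairwise precursor m/z difference (Th).
#' @param triple_id Identifier; defaults to the CID spectrum id.
#' @return An object of class `SpectrumTriple`.
#' @export
spectrum_triple <- function(cid, hcd, etd, precursor_tol = 0.01,
                            triple_id = cid$spectrum_id) {
  stopifnot(cid$mode == "CID", hcd$mode == "HCD", etd$mode == "ETD")
  zs <- c(cid$precursor_charge, hcd$precursor_charge, etd$precursor_charge)
  if (length(unique(zs)) != 1L) stop("triple members differ in precursor charge")
  mzs <- c(cid$precursor_mz, hcd$precursor_mz, etd$precursor_mz)
  if (max(mzs) - min(mzs) > precursor_tol) {
    stop("triple members differ in precursor m/z beyond tolerance")
  }
  structure(list(triple_id = as.character(triple_id),
                 cid = cid, hcd = hcd, etd = etd),
            class = "SpectrumTriple")
}

#' @export
print.SpectrumTriple <- function(x, ...) {
  cat(sprintf("<SpectrumTriple %s> precursor %.4f (%d+)\n",
              x$triple_id, x$cid$precursor_mz, x$cid$precursor_charge))
  invisible(x)
}

# ---------------------------------------------------------------------------
# MGF input / output
#
# Mascot generic format with one extension: a per-spectrum FRAGMODE= header
# carrying the dissociation mode (MGF has no standard key for it). A
# "mode=XXX" token inside TITLE is also honoured.

#' Read an MGF file
#'
#' Parses a Mascot generic format file into a list of [spectrum()]
#' objects. The fragmentation mode is taken from a `FRAGMODE=` header
#' line, else from a `mode=` token in TITLE, else from `default_mode`.
#' `CHARGE` defaults to 2+ when absent (typical tryptic-like precursors);
#' blocks without `PEPMASS` are rejected with a warning. Peak lists are
#' returned sorted ascending by m/z; ids come from TITLE, else
#' `file:ordinal`.
#'
#' @param path MGF file path.
#' @param default_mode Mode used for blocks without explicit annotation,
#'   or `NULL` (a block with no mode then raises an error naming it).
#' @return List of `Spectrum` objects, in file order.
#' @export
read_mgf <- function(path, default_mode = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends)) stop("malformed MGF: unbalanced blocks in ", path)
  out <- vector("list", length(begins))
  kept <- 0L
  for (b in seq_along(begins)) {
    block <- lines[(begins[b] + 1L):(ends[b] - 1L)]
    hdr_idx <- grepl("=", block, fixed = TRUE) & !grepl("^[0-9.]", block)
    hdr <- block[hdr_idx]
    key <- toupper(sub("=.*", "", hdr))
    val <- sub("^[^=]*=", "", hdr)
    get <- function(k) if (k %in% key) val[match(k, key)] else NA_character_
    pep <- get("PEPMASS")
    if (is.na(pep)) {
      warning("MGF block ", b, " in ", basename(path),
              " has no PEPMASS; rejected")
      next
    }
    precursor_mz <- as.numeric(strsplit(trimws(pep), "[ \t]+")[[1]][1])
    ch <- get("CHARGE")
    charge <- if (is.na(ch)) 2L else as.integer(sub("[+-]$", "", trimws(ch)))
    title <- get("TITLE")
    mode <- get("FRAGMODE")
    if (is.na(mode) && !is.na(title) &&
        grepl("mode=", title, ignore.case = TRUE)) {
      mode <- sub(".*mode=([A-Za-z]+).*", "\\1", title, ignore.case = TRUE)
    }
    if (is.na(mode)) {
      if (is.null(default_mode)) {
        stop("MGF block ", b, " in ", basename(path),
             " has no fragmentation mode and no default was given")
      }
      mode <- default_mode
    }
    mode <- toupper(trimws(mode))
    scan <- get("SCANS")
    rt <- get("RTINSECONDS")
    peak_lines <- block[!hdr_idx & nzchar(trimws(block))]
    pk <- if (length(peak_lines) > 0) {
      m <- do.call(rbind, lapply(strsplit(trimws(peak_lines), "[ \t]+"),
                                 function(x) as.numeric(x[1:2])))
      m
    } else matrix(numeric(0), ncol = 2)
    kept <- kept + 1L
    out[[b]] <- spectrum(
      spectrum_id = if (!is.na(title)) title else paste0(basename(path), ":", b),
      precursor_mz = precursor_mz,
      precursor_charge = charge,
      mode = mode,
      mz = pk[, 1], intensity = pk[, 2],
      scan = if (!is.na(scan)) as.integer(scan) else kept,
      source_file = basename(path),
      rt = if (!is.na(rt)) as.numeric(rt) else NA_real_
    )
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Write spectra to an MGF file
#'
#' Writes m/z to 5 decimals and intensities to 3; the fragmentation mode
#' goes into a `FRAGMODE=` header line. `read_mgf(write_mgf(s))` is
#' lossless at that precision.
#'
#' @param spectra List of `Spectrum` objects (may be empty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (s in spectra) {
    hdr <- c("BEGIN IONS",
             paste0("TITLE=", s$spectrum_id),
             sprintf("PEPMASS=%.5f", s$precursor_mz),
             sprintf("CHARGE=%d+", s$precursor_charge),
             sprintf("SCANS=%d", s$scan),
             paste0("FRAGMODE=", s$mode))
    if (!is.na(s$rt)) hdr <- c(hdr, sprintf("RTINSECONDS=%.3f", s$rt))
    writeLines(hdr, con)
    if (nrow(s$peaks) > 0) {
      writeLines(sprintf("%.5f %.3f", s$peaks$mz, s$peaks$intensity), con)
    }
    writeLines("END IONS", con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# FASTA input / output (via Biostrings)

.ILLEGAL_RESIDUES <- c("B", "J", "O", "U", "X", "Z", "*")

#' Read a protein FASTA database
#'
#' Headers are parsed as `>accession description`. Sequences are
#' uppercased; records containing letters outside the 20-letter amino
#' acid alphabet (B, J, O, U, X, Z, *) are excluded, counted, and
#' reported via a message.
#'
#' @param path FASTA file path.
#' @return A data frame with columns `accession`, `description`,
#'   `sequence` and attribute `n_excluded`.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  accession <- sub("[ \t].*$", "", headers)
  description <- ifelse(grepl("[ \t]", headers),
                        sub("^[^ \t]+[ \t]+", "", headers), "")
  seqs <- toupper(as.character(aa))
  ok <- !grepl(paste0("[", gsub("\\*", "\\\\*", paste(.ILLEGAL_RESIDUES, collapse = "")), "]"),
               seqs) & nzchar(seqs)
  n_excluded <- sum(!ok)
  if (n_excluded > 0) {
    message(n_excluded, " FASTA record(s) with illegal residue letters excluded: ",
            paste(accession[!ok], collapse = ", "))
  }
  out <- data.frame(accession = accession[ok],
                    description = description[ok],
                    sequence = unname(seqs[ok]),
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Write a protein FASTA database
#'
#' Sequence lines are wrapped at 60 columns; `read_fasta(write_fasta(x))`
#' is the identity on (accession, description, sequence).
#'
#' @param records Data frame with columns `accession`, `description`,
#'   `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- ifelse(nzchar(records$description),
                      paste(records$accession, records$description),
                      records$accession)
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

# ---------------------------------------------------------------------------

#' Group spectra into CID/HCD/ETD triples
#'
#' Greedy grouping in scan order: each CID scan opens a candidate
#' triple; the next unused HCD scan with the same charge and a precursor
#' m/z within `precursor_tol`, followed by the next unused ETD scan
#' matching likewise, complete it. Each spectrum joins at most one
#' triple; everything else is returned as unpaired.
#'
#' @param spectra List of `Spectrum` objects carrying scan numbers and
#'   modes.
#' @param precursor_tol Precursor m/z tolerance (Th); default 0.01,
#'   appropriate for high-resolution MS1 precursor readout.
#' @return List with elements `triples` (list of `SpectrumTriple`) and
#'   `unpaired` (list of `Spectrum`).
#' @export
group_triples <- function(spectra, precursor_tol = 0.01) {
  if (length(spectra) == 0) return(list(triples = list(), unpaired = list()))
  scans <- vapply(spectra, function(s) s$scan, integer(1))
  ord <- order(scans)
  spectra <- spectra[ord]
  modes <- vapply(spectra, function(s) s$mode, character(1))
  mzs <- vapply(spectra, function(s) s$precursor_mz, numeric(1))
  zs <- vapply(spectra, function(s) s$precursor_charge, integer(1))
  used <- logical(length(spectra))
  triples <- list()
  for (i in seq_along(spectra)) {
    if (used[i] || modes[i] != "CID") next
    j <- which(!used & modes == "HCD" & seq_along(spectra) > i &
                 zs == zs[i] & abs(mzs - mzs[i]) <= precursor_tol)
    if (length(j) == 0) next
    j <- j[1]
    k <- which(!used & modes == "ETD" & seq_along(spectra) > j &
                 zs == zs[i] & abs(mzs - mzs[i]) <= precursor_tol)
    if (length(k) == 0) next
    k <- k[1]
    used[c(i, j, k)] <- TRUE
    triples[[length(triples) + 1L]] <-
      spectrum_triple(spectra[[i]], spectra[[j]], spectra[[k]],
                      precursor_tol = precursor_tol)
  }
  list(triples = triples, unpaired = spectra[!used])
}
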