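# Standard monoisotopic constants (Da), used throughout.
MASS <- c(
  proton          = 1.007276,
  water           = 18.010565,
  carbamidomethyl = 57.02146
)

#' Monoisotopic mass constants
#'
#' Standard monoisotopic constants used throughout the package:
#' `proton` (1.007276 Da), `water` (18.010565 Da), and
#' `carbamidomethyl` (+57.02146 Da, the fixed cysteine modification from
#' iodoacetamide alkylation).
#'
#' @return Named numeric vector.
#' @export
mass_constants <- function() MASS

# Unmodified monoisotopic residue masses, 20-letter alphabet.
.RESIDUE_MASS_PLAIN <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276,
  V =  99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' Residue masses with fixed cysteine carbamidomethylation
#'
#' Monoisotopic residue masses for the 20 amino acids. Cysteine carries
#' the fixed carbamidomethyl modification (+57.02146 Da) throughout the
#' package, reflecting iodoacetamide alkylation during sample
#' preparation; all theoretical and interpreted masses therefore use
#' C = 160.03065 Da.
#'
#' @param fixed_cys Add the carbamidomethyl mass to cysteine
#'   (default `TRUE`).
#' @return Named numeric vector of residue masses (Da).
#' @export
#' @examples
#' residue_masses()[["G"]]
residue_masses <- function(fixed_cys = TRUE) {
  m <- .RESIDUE_MASS_PLAIN
  if (fixed_cys) m[["C"]] <- m[["C"]] + MASS[["carbamidomethyl"]]
  m
}

#' Residue-calling table (I/L collapsed)
#'
#' The table used when translating mass differences into residue
#' letters. Isoleucine and leucine are isobaric (113.08406 Da); the
#' convention here is to report 'I', with the I/L equivalence restored
#' during database mapping. Lysine (128.09496) and glutamine
#' (128.05858) remain distinct entries: at the default consensus
#' calling tolerance of 0.02 Da they are distinguishable.
#'
#' @return Named numeric vector; one entry per distinct residue mass.
#' @export
calling_table <- function() {
  m <- residue_masses()
  m[names(m) != "L"]
}

#' Neutral peptide mass
#'
#' Sum of residue masses plus one water, with fixed
#' carbamidomethyl-cysteine.
#'
#' @param peptide Character scalar of residue letters.
#' @return Neutral monoisotopic mass (Da).
#' @export
#' @examples
#' peptide_mass("AG")
peptide_mass <- function(peptide) {
  sum(residue_vector(peptide)) + MASS[["water"]]
}

# Per-residue mass vector for a peptide; errors on unknown letters.
residue_vector <- function(peptide) {
  stopifnot(is.character(peptide), length(peptide) == 1L, nzchar(peptide))
  letters <- strsplit(peptide, "", fixed = TRUE)[[1]]
  m <- residue_masses()
  bad <- setdiff(letters, names(m))
  if (length(bad) > 0) {
    stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "))
  }
  unname(m[letters])
}

#' Cumulative prefix residue masses of a peptide
#'
#' The true prefix-residue-mass (PRM) ladder: cumulative sums of residue
#' masses at each internal cut site (the boundary masses 0 and the total
#' residue mass are excluded, matching the PRM spectrum convention).
#'
#' @param peptide Character scalar.
#' @return Numeric vector of length `nchar(peptide) - 1`.
#' @export
#' @examples
#' prefix_masses("GAS")
prefix_masses <- function(peptide) {
  cs <- cumsum(residue_vector(peptide))
  n <- length(cs)
  if (n < 2) return(numeric(0))
  cs[-n]
}
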