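# Shared constants: amino-acid alphabet, physicochemical groups, reference
# accessibilities, van der Waals radii, CDR ranges.

#' Standard amino-acid one-letter alphabet
#'
#' The 20 standard amino acids, alphabetical by one-letter code.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Physicochemical amino-acid groups
#'
#' Fixed partition of the 20 standard amino acids into 6 physicochemical
#' groups, obtained by hierarchical clustering of BLOSUM62 substitution
#' features. A designed substitution within the native residue's group counts
#' as a "similar" recovery; cysteine forms a singleton group.
#'
#' @format Named list of 6 character vectors whose union is the 20 standard
#'   amino acids.
#' @seealso [similarity_recovery()], [aa_group_of()]
#' @export
AA_GROUPS <- list(
  small    = c("A", "G", "S"),
  cysteine = c("C"),
  acidic   = c("D", "E", "P", "T"),
  polar    = c("Q", "N", "H", "R", "K"),
  aliphatic = c("I", "L", "M", "V"),
  aromatic = c("F", "Y", "W")
)

#' Group membership lookup for an amino acid
#'
#' @param aa Character vector of one-letter amino-acid codes.
#' @param groups Partition to use (default [AA_GROUPS]).
#' @return Integer vector of group indices (NA for letters outside the
#'   partition, e.g. 'X').
#' @export
aa_group_of <- function(aa, groups = AA_GROUPS) {
  idx <- rep(NA_integer_, length(aa))
  for (g in seq_along(groups)) {
    idx[aa %in% groups[[g]]] <- g
  }
  idx
}

#' Maximum accessible surface areas (theoretical), per residue
#'
#' Theoretical maximum accessible surface area of residue X in a Gly-X-Gly
#' tripeptide, in square Angstroms (Tien et al. 2013, theoretical column).
#' Used as the denominator of relative solvent accessibility (RSA).
#'
#' @format Named numeric vector over the 20 standard amino acids.
#' @export
MAX_ASA_TIEN <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167,
  E = 223, Q = 225, G = 104, H = 224, I = 197,
  L = 201, K = 236, M = 224, F = 240, P = 159,
  S = 155, T = 172, W = 264, Y = 263, V = 174
)

# Element-based van der Waals radii (Angstrom) for Shrake-Rupley SASA.
VDW_RADII <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, H = 1.2)
VDW_DEFAULT <- 1.8

#' Aho-numbering CDR ranges
#'
#' Inclusive Aho-number ranges delimiting the three complementarity-
#' determining regions of a TCR variable domain: CDR1 27-40, CDR2 58-70,
#' CDR3 106-139. Every other Aho number is framework (FR).
#'
#' @format Named list of length-2 integer vectors (inclusive bounds).
#' @seealso [assign_region()]
#' @export
AHO_CDR_RANGES <- list(
  CDR1 = c(27L, 40L),
  CDR2 = c(58L, 70L),
  CDR3 = c(106L, 139L)
)

# Chain roles recognised in a role map.
COMPLEX_ROLES <- c("tcr_alpha", "tcr_beta", "peptide", "mhc", "b2m", "other")
REQUIRED_ROLES <- c("tcr_alpha", "tcr_beta", "peptide", "mhc")

# Design scenarios (position-selection strategies).
DESIGN_SCENARIOS <- c("cdr3_interface", "cdr_interface", "cdr3_all",
                      "cdr_all", "full_variable")

# Map common 3-letter residue names to one-letter codes; anything else is 'X'.
AA_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLU = "E", GLN = "Q", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

AA_1TO3 <- structure(names(AA_3TO1), names = unname(AA_3TO1))
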