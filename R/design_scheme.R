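# CDR assignment from Aho numbers and design-position selection for the five
# design scenarios, including the pMHC-removal control.

#' Assign a CDR/framework region from an Aho number
#'
#' Inclusive ranges CDR1 27-40, CDR2 58-70, CDR3 106-139; everything else is
#' framework ("FR").
#'
#' @param aho_number Positive integer vector of Aho numbers.
#' @return Character vector over {"CDR1","CDR2","CDR3","FR"}.
#' @export
assign_region <- function(aho_number) {
  if (any(aho_number <= 0 | aho_number != as.integer(aho_number))) {
    stop("Aho numbers must be positive integers")
  }
  out <- rep("FR", length(aho_number))
  for (r in names(AHO_CDR_RANGES)) {
    rng <- AHO_CDR_RANGES[[r]]
    out[aho_number >= rng[1] & aho_number <= rng[2]] <- r
  }
  out
}

#' Select designable positions for a design scenario
#'
#' Implements the five position-selection strategies over the TCR variable
#' domains:
#' \describe{
#'   \item{cdr3_interface}{CDR3 residues (both chains) with at least one
#'     all-atom contact to the peptide or MHC.}
#'   \item{cdr_interface}{CDR1/2/3 residues in contact with peptide or MHC.}
#'   \item{cdr3_all}{every CDR3 residue.}
#'   \item{cdr_all}{every CDR1/2/3 residue.}
#'   \item{full_variable}{every Aho-mapped residue of both TCR chains.}
#' }
#' Positions are ordered TCR alpha first, then TCR beta, ascending residue
#' order within each chain. Residues with unknown letter 'X' are never
#' designable.
#'
#' @param structure A `complex_structure`.
#' @param aho_map data.frame chain/resnum/icode/aho covering both TCR
#'   chains (see [read_aho_map()]).
#' @param scenario One of `cdr3_interface`, `cdr_interface`, `cdr3_all`,
#'   `cdr_all`, `full_variable`.
#' @param contacts A `contact_set` of TCR vs peptide+MHC at the interface
#'   cutoff; required for the `*_interface` scenarios, ignored otherwise.
#'   If NULL it is computed at 5 Angstrom.
#' @return A `design_position_set`: data.frame with columns chain, resnum,
#'   icode, aho, region, native_aa, role, is_interface and attribute
#'   `scenario`.
#' @export
select_design_positions <- function(structure, aho_map, scenario,
                                    contacts = NULL) {
  scenario <- match.arg(scenario, DESIGN_SCENARIOS)
  validate_aho_map(aho_map, structure)
  res <- residue_table(structure)

  tcr_chains_a <- names(structure$role_map)[structure$role_map ==
                                              "tcr_alpha"]
  tcr_chains_b <- names(structure$role_map)[structure$role_map ==
                                              "tcr_beta"]
  aho_chains <- unique(aho_map$chain)
  if (!any(aho_chains %in% tcr_chains_a) ||
      !any(aho_chains %in% tcr_chains_b)) {
    stop("Aho map must cover both TCR chains")
  }

  need_contacts <- scenario %in% c("cdr3_interface", "cdr_interface")
  if (need_contacts && is.null(contacts)) {
    contacts <- compute_contacts(structure,
                                 roles_a = c("tcr_alpha", "tcr_beta"),
                                 roles_b = c("peptide", "mhc"))
  }

  res$key <- res_key(res$chain, res$resnum, res$icode)
  amap <- aho_map
  amap$key <- res_key(amap$chain, amap$resnum, amap$icode)
  res <- res[match(amap$key, res$key), , drop = FALSE]
  pos <- data.frame(
    chain = amap$chain, resnum = amap$resnum, icode = amap$icode,
    aho = amap$aho, region = assign_region(amap$aho),
    native_aa = res$aa, role = res$role, stringsAsFactors = FALSE
  )
  pos <- pos[pos$role %in% c("tcr_alpha", "tcr_beta"), , drop = FALSE]
  pos <- pos[pos$native_aa != "X", , drop = FALSE]

  if (need_contacts) {
    iface <- contact_residues_a(contacts)
    iface_key <- res_key(iface$chain, iface$resnum, iface$icode)
    pos$is_interface <- res_key(pos$chain, pos$resnum, pos$icode) %in%
      iface_key
  } else {
    pos$is_interface <- NA
  }

  keep <- switch(scenario,
    cdr3_interface = pos$region == "CDR3" & pos$is_interface,
    cdr_interface  = pos$region %in% c("CDR1", "CDR2", "CDR3") &
      pos$is_interface,
    cdr3_all       = pos$region == "CDR3",
    cdr_all        = pos$region %in% c("CDR1", "CDR2", "CDR3"),
    full_variable  = rep(TRUE, nrow(pos))
  )
  pos <- pos[keep, , drop = FALSE]
  if (nrow(pos) == 0) {
    stop("empty design-position selection for scenario ", scenario,
         " (degenerate complex?)")
  }
  pos <- pos[order(match(pos$role, c("tcr_alpha", "tcr_beta")),
                   pos$chain, pos$resnum, pos$icode), , drop = FALSE]
  rownames(pos) <- NULL
  attr(pos, "scenario") <- scenario
  class(pos) <- c("design_position_set", class(pos))
  pos
}

#' Remove the pMHC from a bound complex
#'
#' Returns the TCR-only structure (alpha and beta chains) with coordinates
#' unchanged, emulating interface design without the peptide-MHC context.
#' Previously selected design positions on the TCR chains remain valid.
#'
#' @param structure A `complex_structure` with peptide and mhc roles.
#' @return A `complex_structure` containing only the TCR chains.
#' @export
strip_pmhc <- function(structure) {
  roles <- structure$role_map
  if (!all(c("peptide", "mhc") %in% roles)) {
    stop("structure lacks peptide/mhc roles; nothing to strip")
  }
  keep_chains <- names(roles)[roles %in% c("tcr_alpha", "tcr_beta")]
  atoms <- structure$atoms[structure$atoms$chain %in% keep_chains, ,
                           drop = FALSE]
  complex_structure(atoms, roles[keep_chains], require_complete = FALSE)
}
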