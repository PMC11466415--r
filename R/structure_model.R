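# Domain types and readers: multi-chain complex structures with chain roles,
# Aho-number maps, designed-sequence sets, and alanine-scan ddG tables.
#
# A complex_structure stores one row per atom (bio3d-style flat table) plus a
# chain -> role map. Residue identity is (chain, resnum, icode) throughout;
# Aho numbering is never inferred internally, always supplied as input.

res_key <- function(chain, resnum, icode) {
  paste(chain, resnum, ifelse(is.na(icode) | icode == "", ".", icode),
        sep = "|")
}

#' Construct a TCR:pMHC complex structure
#'
#' Builds the atomic container used by all geometry and selection operations:
#' a flat per-atom table plus a chain-to-role map. Most users will obtain one
#' from [read_pdb_complex()] or [generate_toy_complex()] rather than calling
#' this directly.
#'
#' @param atoms data.frame with columns `chain`, `resnum` (integer), `icode`
#'   (character, `""` if absent), `aa` (one-letter code or `"X"`), `atom`
#'   (atom name), `element` (element symbol), `x`, `y`, `z` (Angstrom).
#' @param role_map Named character vector mapping chain identifiers to roles
#'   among `tcr_alpha`, `tcr_beta`, `peptide`, `mhc`, `b2m`, `other`.
#' @param require_complete If TRUE (default), require at least one chain for
#'   each of the four core roles (both TCR chains, peptide, MHC).
#' @return An object of class `complex_structure`.
#' @export
complex_structure <- function(atoms, role_map, require_complete = TRUE) {
  needed <- c("chain", "resnum", "icode", "aa", "atom", "element",
              "x", "y", "z")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atoms table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0) stop("structure has no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite atom coordinates")
  }
  if (any(atoms$element == "" | is.na(atoms$element))) {
    stop("every atom needs a non-empty element symbol")
  }
  bad_aa <- setdiff(unique(atoms$aa), c(AA_ALPHABET, "X"))
  if (length(bad_aa) > 0) {
    stop("invalid residue letters: ", paste(bad_aa, collapse = ", "))
  }
  if (is.null(names(role_map)) || any(names(role_map) == "")) {
    stop("role_map must be a named character vector (chain -> role)")
  }
  bad_roles <- setdiff(unname(role_map), COMPLEX_ROLES)
  if (length(bad_roles) > 0) {
    stop("unknown roles: ", paste(bad_roles, collapse = ", "))
  }
  absent <- setdiff(names(role_map), unique(atoms$chain))
  if (length(absent) > 0) {
    stop("role_map names chains absent from structure: ",
         paste(absent, collapse = ", "))
  }
  if (require_complete) {
    lacking <- setdiff(REQUIRED_ROLES, unname(role_map))
    if (length(lacking) > 0) {
      stop("complex lacks required roles: ", paste(lacking, collapse = ", "))
    }
  }
  unmapped <- setdiff(unique(atoms$chain), names(role_map))
  if (length(unmapped) > 0) {
    stop("chains without a role: ", paste(unmapped, collapse = ", "))
  }
  atoms$icode[is.na(atoms$icode)] <- ""
  # one aa letter per residue
  key <- res_key(atoms$chain, atoms$resnum, atoms$icode)
  if (any(tapply(atoms$aa, key, function(v) length(unique(v))) > 1)) {
    stop("inconsistent residue letters within a (chain, resnum, icode)")
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, role_map = role_map),
            class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  res <- residue_table(x)
  cat("complex_structure:", nrow(res), "residues,", nrow(x$atoms),
      "atoms\n")
  for (ch in names(x$role_map)) {
    cat(sprintf("  chain %s (%s): %d residues\n", ch, x$role_map[[ch]],
                sum(res$chain == ch)))
  }
  invisible(x)
}

#' Per-residue summary table of a complex structure
#'
#' @param structure A `complex_structure`.
#' @return data.frame with one row per residue, in file/atom order within
#'   each chain: `chain`, `resnum`, `icode`, `aa`, `role`, `n_atoms`.
#' @export
residue_table <- function(structure) {
  a <- structure$atoms
  key <- res_key(a$chain, a$resnum, a$icode)
  first <- !duplicated(key)
  out <- data.frame(
    chain = a$chain[first], resnum = a$resnum[first],
    icode = a$icode[first], aa = a$aa[first],
    role = unname(structure$role_map[a$chain[first]]),
    n_atoms = as.integer(table(factor(key, levels = key[first]))),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

pdb_field <- function(lines, from, to) {
  trimws(substr(lines, from, to))
}

element_from_name <- function(name) {
  # strip leading digits (e.g. "1HB"), take leading letters; two-letter
  # elements in PDBs of proteins are rare outside metals, so a single
  # leading letter is used unless the name starts in column 13 style
  stripped <- sub("^[0-9']+", "", name)
  first <- substr(stripped, 1, 1)
  toupper(first)
}

#' Read a TCR:pMHC complex from a PDB file
#'
#' Parses ATOM records (and HETATM records of standard residues, e.g.
#' selenomethionine-free chain breaks), excluding waters and non-polymer
#' heteroatoms. Alternate locations are resolved by keeping the blank or "A"
#' altloc. Hydrogens are retained when present. Nonstandard residue names
#' are kept with residue letter `"X"`.
#'
#' @param path PDB file path.
#' @param role_map Named character vector, chain id -> role (see
#'   [complex_structure()]).
#' @param require_complete Require all four core roles (default TRUE).
#' @return A `complex_structure`.
#' @export
read_pdb_complex <- function(path, role_map, require_complete = TRUE) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep <- trimws(rec) %in% c("ATOM", "HETATM")
  lines <- lines[keep]
  rec <- trimws(rec[keep])
  if (length(lines) == 0) stop("no ATOM/HETATM records in ", path)

  resname <- pdb_field(lines, 18, 20)
  # waters and non-polymer heteroatoms out; HETATM kept only for standard aa
  drop <- resname %in% c("HOH", "WAT", "DOD") |
    (rec == "HETATM" & !(resname %in% names(AA_3TO1)))
  lines <- lines[!drop]
  resname <- resname[!drop]
  if (length(lines) == 0) stop("no polymer atoms in ", path)

  altloc <- substr(lines, 17, 17)
  keep_alt <- altloc %in% c(" ", "", "A")
  lines <- lines[keep_alt]
  resname <- resname[keep_alt]

  element <- pdb_field(lines, 77, 78)
  name <- pdb_field(lines, 13, 16)
  no_el <- element == ""
  element[no_el] <- element_from_name(name[no_el])

  atoms <- data.frame(
    chain = substr(lines, 22, 22),
    resnum = as.integer(pdb_field(lines, 23, 26)),
    icode = trimws(substr(lines, 27, 27)),
    aa = unname(ifelse(resname %in% names(AA_3TO1),
                       AA_3TO1[resname], "X")),
    atom = name,
    element = element,
    x = as.numeric(pdb_field(lines, 31, 38)),
    y = as.numeric(pdb_field(lines, 39, 46)),
    z = as.numeric(pdb_field(lines, 47, 54)),
    stringsAsFactors = FALSE
  )
  complex_structure(atoms, role_map, require_complete = require_complete)
}

#' Write a complex structure to a PDB file
#'
#' @param structure A `complex_structure`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_pdb_complex <- function(structure, path) {
  a <- structure$atoms
  res3 <- ifelse(a$aa %in% names(AA_1TO3), AA_1TO3[a$aa], "UNK")
  name4 <- ifelse(nchar(a$atom) >= 4, substr(a$atom, 1, 4),
                  sprintf(" %-3s", a$atom))
  lines <- sprintf(
    "ATOM  %5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)) %% 100000, name4, res3, a$chain, a$resnum,
    ifelse(a$icode == "", " ", a$icode), a$x, a$y, a$z, 1, 0,
    a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a residue-to-Aho-number map
#'
#' Consumes the TSV produced by an external numbering tool (e.g. ANARCI run
#' outside this package): columns `chain`, `resnum`, `icode`, `aho`. Within
#' each chain Aho numbers must be strictly increasing in file order.
#'
#' @param path TSV path with header.
#' @return data.frame with columns chain, resnum, icode, aho.
#' @export
read_aho_map <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character")
  needed <- c("chain", "resnum", "icode", "aho")
  if (!all(needed %in% names(tab))) {
    stop("Aho map needs columns: ", paste(needed, collapse = ", "))
  }
  out <- data.frame(
    chain = tab$chain,
    resnum = as.integer(tab$resnum),
    icode = trimws(tab$icode),
    aho = as.integer(tab$aho),
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$aho)) || any(out$aho <= 0)) {
    stop("Aho numbers must be positive integers")
  }
  for (ch in unique(out$chain)) {
    v <- out$aho[out$chain == ch]
    if (any(diff(v) <= 0)) {
      stop("Aho numbers not strictly increasing in chain ", ch)
    }
  }
  out
}

#' Validate an Aho map against a structure
#'
#' Checks that every mapped residue exists in the structure.
#'
#' @param aho_map data.frame from [read_aho_map()] or equivalent.
#' @param structure A `complex_structure`.
#' @return Invisibly TRUE; errors otherwise.
#' @export
validate_aho_map <- function(aho_map, structure) {
  res <- residue_table(structure)
  have <- res_key(res$chain, res$resnum, res$icode)
  want <- res_key(aho_map$chain, aho_map$resnum, aho_map$icode)
  missing <- setdiff(want, have)
  if (length(missing) > 0) {
    stop("Aho map references residues absent from structure: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  invisible(TRUE)
}

#' Construct a design set
#'
#' Holds the native amino acids at the designable positions and the m
#' designed candidate strings aligned to them.
#'
#' @param native Single string of native amino acids over the positions.
#' @param designs Character vector of m designed strings, same length.
#' @param ids Optional design identifiers (default d1..dm).
#' @param positions Optional `design_position_set` the strings align to.
#' @return An object of class `design_set` with fields `native`, `designs`,
#'   `ids`, `n` (positions), `m` (designs), `positions`.
#' @export
design_set <- function(native, designs, ids = NULL, positions = NULL) {
  if (length(native) != 1 || nchar(native) == 0) {
    stop("native must be one non-empty string")
  }
  if (length(designs) < 1) stop("need at least one design (m >= 1)")
  n <- nchar(native)
  if (is.null(ids)) ids <- paste0("d", seq_along(designs))
  if (length(ids) != length(designs)) stop("ids/designs length mismatch")
  bad_len <- which(nchar(designs) != n)
  if (length(bad_len) > 0) {
    stop("design length mismatch (expected ", n, "): ",
         paste(ids[bad_len], collapse = ", "))
  }
  letters_used <- unique(strsplit(paste0(native, paste(designs,
                                                       collapse = "")),
                                  "")[[1]])
  bad <- setdiff(letters_used, AA_ALPHABET)
  if (length(bad) > 0) {
    stop("non-standard amino-acid letters: ", paste(bad, collapse = ", "))
  }
  if (!is.null(positions) && nrow(positions) != n) {
    stop("positions table does not match sequence length")
  }
  structure(list(native = native, designs = unname(designs),
                 ids = ids, n = n, m = length(designs),
                 positions = positions),
            class = "design_set")
}

#' @export
print.design_set <- function(x, ...) {
  cat("design_set: m =", x$m, "designs over n =", x$n, "positions\n")
  cat("native:", x$native, "\n")
  invisible(x)
}

#' Read designed sequences from FASTA or TSV
#'
#' Accepts either FASTA (records are the per-position strings) or a
#' two-column TSV `id`, `sequence` (no header required for TSV without one
#' named `id`). Every record must have exactly one letter per designable
#' position.
#'
#' @param path FASTA (`.fa`/`.fasta`/`.faa`) or TSV file.
#' @param positions A `design_position_set` defining length and native
#'   sequence.
#' @return A `design_set`.
#' @export
read_design_sets <- function(path, positions) {
  if (!file.exists(path)) stop("cannot read design file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty design file: ", path)
  if (startsWith(lines[[1]], ">")) {
    recs <- Biostrings::readAAStringSet(path)
    if (length(recs) == 0) stop("empty FASTA: ", path)
    ids <- sub("\\s.*$", "", names(recs))
    seqs <- as.character(recs)
  } else {
    parts <- strsplit(lines, "\t")
    if (identical(tolower(parts[[1]][1]), "id")) parts <- parts[-1]
    ids <- vapply(parts, `[`, character(1), 1)
    seqs <- toupper(trimws(vapply(parts, `[`, character(1), 2)))
  }
  native <- paste(positions$native_aa, collapse = "")
  design_set(native, seqs, ids = ids, positions = positions)
}

#' Read an alanine-scan ddG table
#'
#' Per-position free-energy changes for alanine substitution, computed by an
#' external alanine-scanning protocol and consumed here for hotspot
#' classification. Columns: `chain`, `resnum`, `icode`, `ddg` (kcal/mol).
#'
#' @param path TSV path with header.
#' @return data.frame keyed by (chain, resnum, icode) with numeric `ddg`.
#' @export
read_ddg_table <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character")
  needed <- c("chain", "resnum", "icode", "ddg")
  if (!all(needed %in% names(tab))) {
    stop("ddG table needs columns: ", paste(needed, collapse = ", "))
  }
  ddg <- suppressWarnings(as.numeric(tab$ddg))
  if (any(is.na(ddg) | !is.finite(ddg))) {
    bad <- which(is.na(ddg) | !is.finite(ddg))[1]
    stop("non-numeric ddG in row ", bad, " ('", tab$ddg[bad], "')")
  }
  out <- data.frame(
    chain = tab$chain, resnum = as.integer(tab$resnum),
    icode = trimws(tab$icode), ddg = ddg, stringsAsFactors = FALSE
  )
  key <- res_key(out$chain, out$resnum, out$icode)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, resnum, icode) in ddG table: ",
         key[duplicated(key)][1])
  }
  out
}
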