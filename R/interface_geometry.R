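# All-atom contact detection, Shrake-Rupley solvent accessibility, relative
# accessibility and burial classification.

role_atoms <- function(structure, roles) {
  chains <- names(structure$role_map)[structure$role_map %in% roles]
  structure$atoms[structure$atoms$chain %in% chains, , drop = FALSE]
}

#' All-atom residue contacts between two role groups
#'
#' A residue pair is in contact when the minimum Euclidean distance over all
#' inter-residue atom pairs is within the cutoff. The default 5 Angstrom
#' all-atom rule is the one used to define the TCR:pMHC interface; the
#' boundary is inclusive (d <= cutoff) by default.
#'
#' @param structure A `complex_structure`.
#' @param roles_a,roles_b Disjoint, non-empty sets of chain roles.
#' @param cutoff Distance threshold in Angstrom (default 5.0).
#' @param inclusive If TRUE (default) use d <= cutoff, else d < cutoff.
#' @return An object of class `contact_set`: data.frame `pairs` with columns
#'   `chain_a`, `resnum_a`, `icode_a`, `chain_b`, `resnum_b`, `icode_b`,
#'   `min_dist`, plus attributes `cutoff` and `inclusive`.
#' @export
compute_contacts <- function(structure, roles_a, roles_b, cutoff = 5.0,
                             inclusive = TRUE) {
  if (length(intersect(roles_a, roles_b)) > 0) {
    stop("role groups must be disjoint")
  }
  at_a <- role_atoms(structure, roles_a)
  at_b <- role_atoms(structure, roles_b)
  if (nrow(at_a) == 0) stop("no atoms for roles: ",
                            paste(roles_a, collapse = ", "))
  if (nrow(at_b) == 0) stop("no atoms for roles: ",
                            paste(roles_b, collapse = ", "))

  xa <- as.matrix(at_a[, c("x", "y", "z")])
  xb <- as.matrix(at_b[, c("x", "y", "z")])
  key_a <- res_key(at_a$chain, at_a$resnum, at_a$icode)
  key_b <- res_key(at_b$chain, at_b$resnum, at_b$icode)

  # squared distance matrix atoms_a x atoms_b, then min-aggregate by
  # residue pair
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  d2[d2 < 0] <- 0
  thr2 <- cutoff^2
  hit <- if (inclusive) which(d2 <= thr2, arr.ind = TRUE) else
    which(d2 < thr2, arr.ind = TRUE)

  if (nrow(hit) == 0) {
    pairs <- data.frame(chain_a = character(0), resnum_a = integer(0),
                        icode_a = character(0), chain_b = character(0),
                        resnum_b = integer(0), icode_b = character(0),
                        min_dist = numeric(0), stringsAsFactors = FALSE)
  } else {
    pk <- paste(key_a[hit[, 1]], key_b[hit[, 2]], sep = "~")
    mind <- tapply(sqrt(d2[hit]), pk, min)
    split_keys <- strsplit(names(mind), "~", fixed = TRUE)
    ka <- strsplit(vapply(split_keys, `[`, character(1), 1), "|",
                   fixed = TRUE)
    kb <- strsplit(vapply(split_keys, `[`, character(1), 2), "|",
                   fixed = TRUE)
    pairs <- data.frame(
      chain_a = vapply(ka, `[`, character(1), 1),
      resnum_a = as.integer(vapply(ka, `[`, character(1), 2)),
      icode_a = sub("^\\.$", "", vapply(ka, `[`, character(1), 3)),
      chain_b = vapply(kb, `[`, character(1), 1),
      resnum_b = as.integer(vapply(kb, `[`, character(1), 2)),
      icode_b = sub("^\\.$", "", vapply(kb, `[`, character(1), 3)),
      min_dist = unname(as.numeric(mind)),
      stringsAsFactors = FALSE
    )
    pairs <- pairs[order(pairs$chain_a, pairs$resnum_a, pairs$icode_a,
                         pairs$chain_b, pairs$resnum_b, pairs$icode_b), ]
    rownames(pairs) <- NULL
  }
  structure(list(pairs = pairs, cutoff = cutoff, inclusive = inclusive,
                 roles_a = roles_a, roles_b = roles_b),
            class = "contact_set")
}

#' @export
print.contact_set <- function(x, ...) {
  cat("contact_set:", nrow(x$pairs), "residue pairs at",
      if (x$inclusive) "d <=" else "d <", x$cutoff, "A\n")
  invisible(x)
}

#' Residues on the A side of a contact set
#'
#' @param contacts A `contact_set`.
#' @return data.frame of unique (chain, resnum, icode) on side A.
#' @export
contact_residues_a <- function(contacts) {
  p <- contacts$pairs
  out <- unique(data.frame(chain = p$chain_a, resnum = p$resnum_a,
                           icode = p$icode_a, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

fibonacci_sphere <- function(n) {
  # deterministic, near-uniform unit-sphere quadrature
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

atom_radii <- function(elements, strict = FALSE) {
  r <- unname(VDW_RADII[elements])
  unknown <- is.na(r)
  if (any(unknown)) {
    if (strict) {
      stop("unknown element(s): ",
           paste(unique(elements[unknown]), collapse = ", "))
    }
    warning("unknown element(s) ",
            paste(unique(elements[unknown]), collapse = ", "),
            "; using default vdW radius ", VDW_DEFAULT, " A")
    r[unknown] <- VDW_DEFAULT
  }
  r
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolling-probe SASA on a deterministic Fibonacci sphere lattice. Each
#' atom's extended sphere (vdW radius + probe) carries `n_sphere_points`
#' test points; a point is accessible when it lies outside every
#' neighbouring atom's extended sphere. Per-residue SASA is the sum over
#' member atoms.
#'
#' @param structure A `complex_structure`.
#' @param probe Probe radius, Angstrom (default 1.4, water).
#' @param n_sphere_points Test points per atom (default 960).
#' @param strict Error (rather than warn) on unknown elements.
#' @return List with `atom_sasa` (numeric per atom, file order) and
#'   `residue_sasa` (data.frame chain, resnum, icode, aa, sasa).
#' @export
shrake_rupley_sasa <- function(structure, probe = 1.4,
                               n_sphere_points = 960, strict = FALSE) {
  a <- structure$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- atom_radii(a$element, strict = strict) + probe
  n_at <- nrow(xyz)
  pts <- fibonacci_sphere(n_sphere_points)

  # neighbour lists via a coarse cell grid keep this O(n) in practice
  max_r <- max(rad)
  cell <- 2 * max_r
  ci <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cell)
  cell_id <- paste(ci[, 1], ci[, 2], ci[, 3])
  cell_members <- split(seq_len(n_at), cell_id)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))

  atom_sasa <- numeric(n_at)
  for (i in seq_len(n_at)) {
    neigh_cells <- paste(ci[i, 1] + offs[, 1], ci[i, 2] + offs[, 2],
                         ci[i, 3] + offs[, 3])
    cand <- unlist(cell_members[intersect(neigh_cells,
                                          names(cell_members))],
                   use.names = FALSE)
    cand <- cand[cand != i]
    if (length(cand) > 0) {
      dv <- xyz[cand, , drop = FALSE] -
        matrix(xyz[i, ], length(cand), 3, byrow = TRUE)
      d2 <- rowSums(dv^2)
      cand <- cand[d2 < (rad[i] + rad[cand])^2]
    }
    if (length(cand) == 0) {
      atom_sasa[i] <- 4 * pi * rad[i]^2
      next
    }
    sp <- pts * rad[i]
    sp <- sweep(sp, 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_sphere_points)
    for (j in cand) {
      if (!any(acc)) break
      dv <- sweep(sp[acc, , drop = FALSE], 2, xyz[j, ])
      acc[acc] <- rowSums(dv^2) > rad[j]^2
    }
    atom_sasa[i] <- 4 * pi * rad[i]^2 * sum(acc) / n_sphere_points
  }

  key <- res_key(a$chain, a$resnum, a$icode)
  first <- !duplicated(key)
  res_sasa <- as.numeric(tapply(atom_sasa, factor(key, levels = key[first]),
                                sum))
  residue_sasa <- data.frame(
    chain = a$chain[first], resnum = a$resnum[first],
    icode = a$icode[first], aa = a$aa[first], sasa = res_sasa,
    stringsAsFactors = FALSE
  )
  rownames(residue_sasa) <- NULL
  list(atom_sasa = atom_sasa, residue_sasa = residue_sasa)
}

#' Relative solvent accessibility
#'
#' RSA = SASA / max ASA of the residue type. The default reference is the
#' theoretical maximum accessibility table ([MAX_ASA_TIEN]); values may
#' slightly exceed 1 for extended conformations. Residues with unknown
#' letter 'X' get NA (excluded from burial statistics).
#'
#' @param sasa Numeric SASA values, square Angstrom.
#' @param aa One-letter residue codes, same length.
#' @param max_asa_table Named reference table (default [MAX_ASA_TIEN]).
#' @return Numeric RSA values (NA where no reference exists).
#' @export
relative_accessibility <- function(sasa, aa, max_asa_table = MAX_ASA_TIEN) {
  if (length(sasa) != length(aa)) stop("sasa/aa length mismatch")
  if (any(sasa < 0)) stop("negative SASA")
  ref <- unname(max_asa_table[aa])
  sasa / ref
}

#' Burial classification from RSA
#'
#' A position is buried when its relative solvent accessibility is strictly
#' below the threshold (default 0.2).
#'
#' @param rsa Numeric RSA values (NA allowed, returns NA).
#' @param threshold Burial threshold (default 0.2, strict `<`).
#' @return Logical vector.
#' @export
classify_buried <- function(rsa, threshold = 0.2) {
  if (any(rsa < 0, na.rm = TRUE)) stop("negative RSA")
  rsa < threshold
}

#' Per-residue burial annotation of a complex
#'
#' Computes SASA in the bound complex (all chains present, including b2m
#' when mapped), converts to RSA and classifies burial.
#'
#' @param structure A `complex_structure`.
#' @param probe,n_sphere_points Passed to [shrake_rupley_sasa()].
#' @param threshold Burial RSA threshold (default 0.2).
#' @param max_asa_table Reference accessibilities (default [MAX_ASA_TIEN]).
#' @return data.frame: chain, resnum, icode, aa, sasa, rsa, buried.
#' @export
annotate_burial <- function(structure, probe = 1.4, n_sphere_points = 960,
                            threshold = 0.2,
                            max_asa_table = MAX_ASA_TIEN) {
  s <- shrake_rupley_sasa(structure, probe = probe,
                          n_sphere_points = n_sphere_points)
  out <- s$residue_sasa
  out$rsa <- relative_accessibility(out$sasa, out$aa, max_asa_table)
  out$buried <- classify_buried(out$rsa, threshold)
  out
}
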