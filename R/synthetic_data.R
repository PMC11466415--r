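# Synthetic test-world generators: toy TCR:pMHC-like complexes with known
# interface contacts and burial classes, and designed-sequence sets with
# controlled match probability, same-group substitution probability and
# positional entropy; plus the random-dissimilar baseline.
#
# Toy geometry uses idealised 5-atom pseudo-residues (N, CA, C, O, CB); only
# distances and solvent accessibility matter to the pipeline under test.
# Interface residues are placed with min atom distance <= 4.5 A to the
# peptide and non-interface residues >= 7 A from peptide and MHC, keeping the
# ground truth robust to the 5.0 A contact boundary.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  force(expr)
}

# idealised atom offsets relative to CA
PSEUDO_ATOMS <- data.frame(
  atom = c("N", "CA", "C", "O", "CB"),
  element = c("N", "C", "C", "O", "C"),
  dx = c(-1.46, 0, 1.52, 2.32, 0.53),
  dy = c(0, 0, 0, 1.05, -0.77),
  dz = c(0, 0, 0, 0, 1.20),
  stringsAsFactors = FALSE
)

pseudo_residue <- function(chain, resnum, aa, cx, cy, cz) {
  data.frame(
    chain = chain, resnum = as.integer(resnum), icode = "", aa = aa,
    atom = PSEUDO_ATOMS$atom, element = PSEUDO_ATOMS$element,
    x = cx + PSEUDO_ATOMS$dx, y = cy + PSEUDO_ATOMS$dy,
    z = cz + PSEUDO_ATOMS$dz, stringsAsFactors = FALSE
  )
}

shell_residue <- function(chain, resnum, cx, cy, cz, radius = 5,
                          n_points = 256) {
  pts <- fibonacci_sphere(n_points) * radius
  data.frame(
    chain = chain, resnum = as.integer(resnum), icode = "", aa = "X",
    atom = paste0("S", seq_len(n_points) %% 100), element = "C",
    x = cx + pts[, 1], y = cy + pts[, 2], z = cz + pts[, 3],
    stringsAsFactors = FALSE
  )
}

#' Generate a toy TCR:pMHC-like complex with known ground truth
#'
#' Builds a four-role pseudo-complex (TCR alpha, TCR beta, peptide, MHC)
#' from idealised 5-atom residues. Designated CDR3 interface residues are
#' placed within 4.5 A (all-atom) of the peptide; non-interface residues at
#' least 7 A from peptide and MHC; designated buried residues are enclosed
#' in an occluding atom shell (an extra chain with role `other`) so that
#' their relative solvent accessibility in the full complex falls below
#' 0.2. Each TCR chain carries framework, CDR1, CDR2 and CDR3 residues with
#' consistent Aho numbers (CDR3 in 106-139). Fully deterministic per seed.
#'
#' @param n_cdr3_interface CDR3 residues in contact range of the peptide,
#'   split between the two TCR chains (default 10, emulating the typical
#'   size of a CDR3-interface design set).
#' @param n_cdr3_noninterface CDR3 residues out of contact range (default 6).
#' @param n_buried TCR framework residues to enclose below RSA 0.2
#'   (default 2).
#' @param peptide_length Peptide residues (default 9, a canonical MHC-I
#'   epitope length). Each TCR chain can host at most `peptide_length`
#'   interface residues.
#' @param seed Integer seed for the residue letters.
#' @return List: `structure` (a `complex_structure`), `aho_map`
#'   (data.frame chain/resnum/icode/aho), `ground_truth` (list with
#'   `interface` data.frame of the designated TCR interface residues and
#'   `burial` data.frame of Aho-mapped residues with expected `buried`
#'   flag).
#' @export
generate_toy_complex <- function(n_cdr3_interface = 10,
                                 n_cdr3_noninterface = 6,
                                 n_buried = 2, peptide_length = 9,
                                 seed = 1) {
  if (peptide_length < 1) stop("peptide_length must be >= 1")
  if (n_cdr3_interface < 0 || n_cdr3_noninterface < 0 || n_buried < 0) {
    stop("counts must be nonnegative")
  }
  n_ia <- ceiling(n_cdr3_interface / 2)
  n_ib <- n_cdr3_interface - n_ia
  if (n_ia > peptide_length) {
    stop("infeasible spec: at most ", peptide_length,
         " interface residues per TCR chain for this peptide length")
  }
  n_na <- ceiling(n_cdr3_noninterface / 2)
  n_nb <- n_cdr3_noninterface - n_na

  with_seed(seed, {
    raa <- function(n) sample(AA_ALPHABET, n, replace = TRUE)

    blocks <- list()
    # peptide along x at z = 0
    for (i in seq_len(peptide_length)) {
      blocks[[length(blocks) + 1]] <-
        pseudo_residue("P", i, raa(1), 3.8 * (i - 1), 0, 0)
    }
    # MHC platform well below the peptide
    for (i in 1:8) {
      blocks[[length(blocks) + 1]] <-
        pseudo_residue("M", i, raa(1), 3.8 * (i - 1), 0, -15)
    }

    build_tcr_chain <- function(chain, n_iface, n_noniface, iface_z,
                                noniface_y, n_fr = 3) {
      rows <- list()
      resnum <- 0
      aho_rows <- list()
      add <- function(aa, cx, cy, cz, aho) {
        resnum <<- resnum + 1
        rows[[length(rows) + 1]] <<-
          pseudo_residue(chain, resnum, aa, cx, cy, cz)
        aho_rows[[length(aho_rows) + 1]] <<-
          data.frame(chain = chain, resnum = resnum, icode = "",
                     aho = aho, stringsAsFactors = FALSE)
      }
      # framework, CDR1 and CDR2 residues far from the interface
      for (k in seq_len(n_fr)) {
        add(raa(1), 3.8 * (k - 1), noniface_y, 26, k)
      }
      add(raa(1), 3.8 * n_fr, noniface_y, 26, 28)        # CDR1
      add(raa(1), 3.8 * (n_fr + 1), noniface_y, 26, 30)  # CDR1
      add(raa(1), 3.8 * (n_fr + 2), noniface_y, 26, 60)  # CDR2
      add(raa(1), 3.8 * (n_fr + 3), noniface_y, 26, 62)  # CDR2
      # CDR3: interface residues stacked right against the peptide
      aho <- 106
      iface_res <- integer(0)
      for (k in seq_len(n_iface)) {
        add(raa(1), 3.8 * (k - 1), 0, iface_z, aho)
        iface_res <- c(iface_res, resnum)
        aho <- aho + 1
      }
      for (k in seq_len(n_noniface)) {
        add(raa(1), 3.8 * (k - 1), noniface_y, 20, aho)
        aho <- aho + 1
      }
      list(rows = rows, aho = do.call(rbind, aho_rows),
           iface_res = iface_res)
    }

    # alpha approaches the peptide from above, beta from below (between
    # peptide and MHC, still >= 7 A from the MHC platform)
    ca <- build_tcr_chain("A", n_ia, n_na, iface_z = 4.6,
                          noniface_y = 12)
    cb <- build_tcr_chain("B", n_ib, n_nb, iface_z = -4.6,
                          noniface_y = -12)
    blocks <- c(blocks, ca$rows, cb$rows)

    # buried framework-like residues wrapped in occluding shells, parked
    # far from everything on their own axis
    buried_keys <- character(0)
    if (n_buried > 0) {
      for (i in seq_len(n_buried)) {
        cx <- -30 - 14 * (i - 1)
        resnum <- 200 + i
        blocks[[length(blocks) + 1]] <-
          pseudo_residue("A", resnum, raa(1), cx, 0, 26)
        # shell centred on the residue's centroid
        cen <- colMeans(PSEUDO_ATOMS[, c("dx", "dy", "dz")]) +
          c(cx, 0, 26)
        blocks[[length(blocks) + 1]] <-
          shell_residue("S", i, cen[1], cen[2], cen[3])
        buried_keys <- c(buried_keys, res_key("A", resnum, ""))
      }
      ca$aho <- rbind(ca$aho,
                      data.frame(chain = "A", resnum = 200 + seq_len(n_buried),
                                 icode = "", aho = 200 + seq_len(n_buried),
                                 stringsAsFactors = FALSE))
    }

    atoms <- do.call(rbind, blocks)
    role_map <- c(A = "tcr_alpha", B = "tcr_beta", P = "peptide",
                  M = "mhc")
    if (n_buried > 0) role_map <- c(role_map, S = "other")
    st <- complex_structure(atoms, role_map)

    aho_map <- rbind(ca$aho, cb$aho)

    iface <- rbind(
      if (n_ia > 0) data.frame(chain = "A", resnum = ca$iface_res,
                               icode = "", stringsAsFactors = FALSE),
      if (n_ib > 0) data.frame(chain = "B", resnum = cb$iface_res,
                               icode = "", stringsAsFactors = FALSE)
    )
    if (is.null(iface)) {
      iface <- data.frame(chain = character(0), resnum = integer(0),
                          icode = character(0), stringsAsFactors = FALSE)
    }
    burial <- data.frame(
      chain = aho_map$chain, resnum = aho_map$resnum,
      icode = aho_map$icode,
      buried = res_key(aho_map$chain, aho_map$resnum, aho_map$icode) %in%
        buried_keys,
      stringsAsFactors = FALSE
    )
    list(structure = st, aho_map = aho_map,
         ground_truth = list(interface = iface, burial = burial))
  })
}

#' Generate a design set with controlled per-position statistics
#'
#' Per position, independently for each of the m designs: keep the native
#' amino acid with probability `p_match`; otherwise, with probability
#' `q_sim`, draw uniformly from the native's physicochemical group minus
#' the native (cysteine's singleton group falls through to a cross-group
#' draw); otherwise draw uniformly from the amino acids outside the
#' native's group. Expected sequence recovery is 100 p; expected similarity
#' recovery is 100 (p + (1-p) q) at non-cysteine positions.
#'
#' @param native Native amino-acid string over the designed positions.
#' @param p_match Probability a position keeps the native amino acid.
#' @param q_sim Probability a non-match stays within the native's group.
#' @param m Number of designs (default 10, the per-case design budget).
#' @param seed Integer seed.
#' @param groups Amino-acid partition (default [AA_GROUPS]).
#' @return A `design_set` of m designs.
#' @export
generate_design_set <- function(native, p_match = 0.5, q_sim = 0.5,
                                m = 10, seed = 1, groups = AA_GROUPS) {
  if (nchar(native) < 1) stop("native must be non-empty")
  if (p_match < 0 || p_match > 1 || q_sim < 0 || q_sim > 1) {
    stop("p_match and q_sim must be in [0, 1]")
  }
  nat <- seq_chars(native)
  n <- length(nat)
  gidx <- aa_group_of(nat, groups)
  if (any(is.na(gidx))) stop("native contains non-standard letters")

  with_seed(seed, {
    designs <- vapply(seq_len(m), function(i) {
      out <- nat
      u <- stats::runif(n)
      mutate <- u >= p_match
      for (j in which(mutate)) {
        same_group <- setdiff(groups[[gidx[j]]], nat[j])
        cross_group <- setdiff(AA_ALPHABET, groups[[gidx[j]]])
        pick_sim <- stats::runif(1) < q_sim && length(same_group) > 0
        pool <- if (pick_sim) same_group else cross_group
        out[j] <- pool[sample.int(length(pool), 1)]
      }
      paste(out, collapse = "")
    }, character(1))
    design_set(native, designs)
  })
}

#' Random-dissimilar baseline design set
#'
#' The null baseline: every designed position is replaced by a uniform draw
#' from the amino acids outside the native's physicochemical group,
#' excluding cysteine. By construction both sequence recovery and
#' similarity recovery against the native are 0.
#'
#' @param native Native amino-acid string over the designed positions.
#' @param m Number of baseline sequences (default 10).
#' @param seed Integer seed.
#' @param groups Amino-acid partition (default [AA_GROUPS]).
#' @return A `design_set` of m random-dissimilar sequences.
#' @export
random_dissimilar_baseline <- function(native, m = 10, seed = 1,
                                       groups = AA_GROUPS) {
  if (nchar(native) < 1) stop("native must be non-empty")
  nat <- seq_chars(native)
  gidx <- aa_group_of(nat, groups)
  if (any(is.na(gidx))) stop("native contains non-standard letters")
  pools <- lapply(gidx, function(g)
    setdiff(setdiff(AA_ALPHABET, groups[[g]]), "C"))

  with_seed(seed, {
    designs <- vapply(seq_len(m), function(i) {
      paste(vapply(pools, function(p) p[sample.int(length(p), 1)],
                   character(1)), collapse = "")
    }, character(1))
    design_set(native, designs)
  })
}

#' Write a toy complex to disk as standard files
#'
#' Emits `complex.pdb`, `aho.tsv`, `roles.json` and
#' `ground_truth.tsv` so the whole pipeline can be exercised from files
#' exactly as on real data.
#'
#' @param toy Output of [generate_toy_complex()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_toy_fixture <- function(toy, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    pdb = file.path(dir, "complex.pdb"),
    aho = file.path(dir, "aho.tsv"),
    roles = file.path(dir, "roles.json"),
    truth = file.path(dir, "ground_truth.tsv")
  )
  write_pdb_complex(toy$structure, paths[["pdb"]])
  utils::write.table(toy$aho_map, paths[["aho"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(toy$structure$role_map),
                       paths[["roles"]], auto_unbox = TRUE)
  truth <- toy$ground_truth$burial
  truth$interface <- res_key(truth$chain, truth$resnum, truth$icode) %in%
    res_key(toy$ground_truth$interface$chain,
            toy$ground_truth$interface$resnum,
            toy$ground_truth$interface$icode)
  utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
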