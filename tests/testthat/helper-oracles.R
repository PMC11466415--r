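# Independent brute-force oracles, coded without reference to the package
# implementations they check.

oracle_recovery <- function(native, designed) {
  x <- strsplit(native, "")[[1]]
  y <- strsplit(designed, "")[[1]]
  hits <- 0
  for (i in seq_along(x)) if (x[i] == y[i]) hits <- hits + 1
  100 * hits / length(x)
}

oracle_group_lookup <- local({
  g <- list(c("A", "G", "S"), "C", c("D", "E", "P", "T"),
            c("Q", "N", "H", "R", "K"), c("I", "L", "M", "V"),
            c("F", "Y", "W"))
  tab <- character(0)
  for (k in seq_along(g)) for (aa in g[[k]]) tab[aa] <- k
  tab
})

oracle_similarity <- function(native, designed) {
  x <- strsplit(native, "")[[1]]
  y <- strsplit(designed, "")[[1]]
  hits <- 0
  for (i in seq_along(x)) {
    if (oracle_group_lookup[x[i]] == oracle_group_lookup[y[i]]) {
      hits <- hits + 1
    }
  }
  100 * hits / length(x)
}

oracle_uniqueness <- function(designs) {
  u <- 0
  seen <- character(0)
  for (d in designs) {
    if (!(d %in% seen)) {
      u <- u + 1
      seen <- c(seen, d)
    }
  }
  100 * u / length(designs)
}

oracle_entropy <- function(designs) {
  L <- nchar(designs[1])
  h <- numeric(L)
  for (j in seq_len(L)) {
    col <- substr(designs, j, j)
    h_j <- 0
    for (aa in unique(col)) {
      p <- sum(col == aa) / length(col)
      h_j <- h_j - p * log(p, base = 2)
    }
    h[j] <- h_j
  }
  list(h = h, mse = sum(h) / L)
}

oracle_subset_recovery <- function(native, designed, mask) {
  x <- strsplit(native, "")[[1]][mask]
  y <- strsplit(designed, "")[[1]][mask]
  if (length(x) == 0) return(NA_real_)
  100 * sum(x == y) / length(x)
}

# exhaustive all-pairs residue contact oracle on a complex_structure
oracle_contacts <- function(structure, roles_a, roles_b, cutoff = 5) {
  a <- structure$atoms
  role_of <- structure$role_map[a$chain]
  ia <- which(role_of %in% roles_a)
  ib <- which(role_of %in% roles_b)
  pairs <- character(0)
  for (i in ia) {
    for (j in ib) {
      d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                  (a$z[i] - a$z[j])^2)
      if (d <= cutoff) {
        pairs <- c(pairs, paste(a$chain[i], a$resnum[i], a$icode[i],
                                a$chain[j], a$resnum[j], a$icode[j]))
      }
    }
  }
  sort(unique(pairs))
}

contact_pairs_str <- function(contacts) {
  p <- contacts$pairs
  sort(paste(p$chain_a, p$resnum_a, p$icode_a,
             p$chain_b, p$resnum_b, p$icode_b))
}

# random small structures for geometry oracle tests: point-atom residues
# scattered in a box, split over two role groups
random_point_structure <- function(n_res = 40, box = 18, seed = 1) {
  set.seed(seed)
  half <- floor(n_res / 2)
  atoms <- data.frame(
    chain = rep(c("A", "P"), c(half, n_res - half)),
    resnum = c(seq_len(half), seq_len(n_res - half)),
    icode = "", aa = sample(tcreval::AA_ALPHABET, n_res, replace = TRUE),
    atom = "CA", element = sample(c("C", "N", "O", "S"), n_res,
                                  replace = TRUE),
    x = runif(n_res, 0, box), y = runif(n_res, 0, box),
    z = runif(n_res, 0, box), stringsAsFactors = FALSE
  )
  # a couple of multi-atom residues so the all-atom rule is exercised
  extra <- atoms[1:3, ]
  extra$atom <- "CB"
  extra$x <- extra$x + runif(3, -1, 1)
  extra$y <- extra$y + runif(3, -1, 1)
  complex_structure(rbind(atoms, extra), c(A = "tcr_alpha", P = "peptide"),
                    require_complete = FALSE)
}

random_design_strings <- function(n, m, seed) {
  set.seed(seed)
  native <- paste(sample(tcreval::AA_ALPHABET, n, replace = TRUE),
                  collapse = "")
  designs <- vapply(seq_len(m), function(i) {
    paste(sample(tcreval::AA_ALPHABET, n, replace = TRUE), collapse = "")
  }, character(1))
  # inject some redundancy and some near-native designs
  if (m >= 4) {
    designs[2] <- designs[1]
    nat <- strsplit(native, "")[[1]]
    idx <- sample(n, max(1, floor(n / 2)))
    d <- nat
    d[idx] <- sample(tcreval::AA_ALPHABET, length(idx), replace = TRUE)
    designs[3] <- paste(d, collapse = "")
  }
  list(native = native, designs = designs)
}
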