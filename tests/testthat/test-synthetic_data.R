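# Synthetic generators: determinism, geometric ground-truth fidelity,
# design-set moments, random-dissimilar baseline.

test_that("same seed gives identical structures and design sets", {
  t1 <- generate_toy_complex(seed = 33)
  t2 <- generate_toy_complex(seed = 33)
  expect_identical(t1$structure$atoms, t2$structure$atoms)
  expect_identical(t1$aho_map, t2$aho_map)
  d1 <- generate_design_set("ACDKLM", m = 5, seed = 9)
  d2 <- generate_design_set("ACDKLM", m = 5, seed = 9)
  expect_identical(d1$designs, d2$designs)
  t3 <- generate_toy_complex(seed = 34)
  expect_false(identical(t1$structure$atoms$aa, t3$structure$atoms$aa))
})

test_that("interface ground truth is recovered by the contact module", {
  for (seed in 1:25) {
    spec <- list(n_iface = sample(2:12, 1), n_non = sample(0:8, 1))
    toy <- generate_toy_complex(n_cdr3_interface = spec$n_iface,
                                n_cdr3_noninterface = spec$n_non,
                                n_buried = 0, seed = seed)
    ct <- compute_contacts(toy$structure, c("tcr_alpha", "tcr_beta"),
                           c("peptide", "mhc"))
    got <- contact_residues_a(ct)
    gt <- toy$ground_truth$interface
    expect_setequal(paste(got$chain, got$resnum),
                    paste(gt$chain, gt$resnum))
    # margins: designated residues well inside, everything else well out
    expect_true(all(ct$pairs$min_dist <= 4.5))
  }
  expect_error(generate_toy_complex(n_cdr3_interface = 40,
                                    peptide_length = 9), "infeasible")
})

test_that("burial ground truth is recovered by the SASA module", {
  for (seed in c(1, 2)) {
    toy <- generate_toy_complex(n_buried = 2, seed = seed)
    burial <- annotate_burial(toy$structure, n_sphere_points = 480)
    bkey <- paste(burial$chain, burial$resnum, burial$icode)
    gt <- toy$ground_truth$burial
    got <- burial$buried[match(paste(gt$chain, gt$resnum, gt$icode), bkey)]
    expect_identical(got, gt$buried)
    # enclosed residues are buried by a wide margin
    expect_true(all(burial$rsa[match(
      paste(gt$chain[gt$buried], gt$resnum[gt$buried],
            gt$icode[gt$buried]), bkey)] < 0.05))
  }
})

test_that("design sets hit their analytic moments", {
  native <- "LKDEQRVTAY"  # no cysteine: similarity expectation is exact
  ds <- generate_design_set(native, p_match = 0.5, q_sim = 0.5, m = 500,
                            seed = 77)
  rec <- vapply(ds$designs, sequence_recovery, numeric(1),
                native = native)
  sim <- vapply(ds$designs, similarity_recovery, numeric(1),
                native = native)
  n_cells <- 500 * nchar(native)
  ci <- function(p) 100 * (p + c(-1, 1) * qnorm(0.995) *
                             sqrt(p * (1 - p) / n_cells))
  expect_gt(mean(rec), ci(0.5)[1])
  expect_lt(mean(rec), ci(0.5)[2])
  expect_gt(mean(sim), ci(0.75)[1])
  expect_lt(mean(sim), ci(0.75)[2])

  # degenerate settings
  all_native <- generate_design_set(native, p_match = 1, m = 20, seed = 1)
  expect_true(all(vapply(all_native$designs, sequence_recovery,
                         numeric(1), native = native) == 100))
  none <- generate_design_set(native, p_match = 0, q_sim = 0, m = 20,
                              seed = 1)
  expect_true(all(vapply(none$designs, similarity_recovery, numeric(1),
                         native = native) == 0))
})

test_that("cysteine singleton group falls through to cross-group draws", {
  ds <- generate_design_set("CCCCCCCCCC", p_match = 0, q_sim = 1, m = 50,
                            seed = 5)
  letters_used <- unique(unlist(strsplit(ds$designs, "")))
  expect_false("C" %in% letters_used)
})

test_that("plug-in entropy approaches its analytic value as m grows", {
  # p_match 0.5, q_sim 0 over native 'L': non-match uniform over the 16
  # amino acids outside {I,L,M,V}
  p <- c(0.5, rep(0.5 / 16, 16))
  h_true <- -sum(p * log2(p))
  ds <- generate_design_set(paste(rep("L", 8), collapse = ""),
                            p_match = 0.5, q_sim = 0, m = 2000, seed = 12)
  h_obs <- mean(positional_entropy(ds)$h)
  bias_bound <- (17 - 1) / (2 * 2000 * log(2))
  expect_lt(abs(h_obs - h_true), bias_bound + 0.05)
})

test_that("random-dissimilar baseline is always cross-group, cysteine-free", {
  native <- "ACDEFGHIKLMNPQRSTVWY"
  bs <- random_dissimilar_baseline(native, m = 30, seed = 3)
  for (d in bs$designs) {
    expect_equal(sequence_recovery(native, d), 0)
    expect_equal(similarity_recovery(native, d), 0)
    expect_false(grepl("C", d))
  }
  # native 'A' never maps to its own group
  firsts <- substr(bs$designs, 1, 1)
  expect_false(any(firsts %in% c("A", "G", "S", "C")))
})

test_that("designs with p_match > 0 dominate the dissimilar baseline", {
  native <- "LKDEQRVTAY"
  ds <- generate_design_set(native, p_match = 0.2, q_sim = 0.3, m = 100,
                            seed = 21)
  bs <- random_dissimilar_baseline(native, m = 100, seed = 22)
  mean_rec <- function(s) mean(vapply(s$designs, sequence_recovery,
                                      numeric(1), native = native))
  expect_gt(mean_rec(ds), mean_rec(bs))
  expect_equal(mean_rec(bs), 0)
})
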