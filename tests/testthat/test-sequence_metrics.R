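# Sequence-level metrics: endpoints, brute-force oracle equivalence,
# invariants.

test_that("recovery and similarity endpoints behave as defined", {
  expect_equal(sequence_recovery("ACDEFGHIKL", "ACDEFGHIKL"), 100)
  expect_equal(sequence_recovery("ACDEFGHIKL", "CDEFGHIKLM"), 0)
  expect_equal(sequence_recovery("ACD", "ACE"), 100 * 2 / 3)
  expect_error(sequence_recovery("ACD", "AC"), "length mismatch")

  expect_equal(similarity_recovery("A", "G"), 100)  # same group {A,G,S}
  expect_equal(similarity_recovery("A", "W"), 0)    # different groups
  expect_equal(similarity_recovery("AC", "GW"), 50)
})

test_that("uniqueness spans [100/m, 100]", {
  d10 <- paste0(AA_ALPHABET[1:10], "A")
  expect_equal(uniqueness(d10), 100)
  expect_equal(uniqueness(rep("AA", 10)), 10)
  expect_equal(uniqueness("AA"), 100)
})

test_that("positional entropy matches hand values and its bounds", {
  ep <- positional_entropy(rep("ACD", 5))
  expect_equal(ep$h, c(0, 0, 0))
  expect_equal(ep$mse, 0)
  ep2 <- positional_entropy(c("A", "V"))
  expect_equal(ep2$h, 1)
  ep3 <- positional_entropy(AA_ALPHABET)
  expect_equal(ep3$h, log2(20))
})

test_that("deduplication keeps first occurrences; raw set feeds uniqueness", {
  ds <- design_set("AAA", c("ACA", "ACA", "ADA"))
  dd <- deduplicate(ds)
  expect_equal(dd$designs, c("ACA", "ADA"))
  expect_equal(dd$ids, c("d1", "d3"))
  expect_equal(uniqueness(ds), 100 * 2 / 3)
  expect_equal(max_recovery(ds), 100 * 2 / 3)
})

test_that("every metric matches the brute-force oracle on random sets", {
  for (seed in 1:50) {
    n <- sample(1:12, 1)
    m <- sample(1:20, 1)
    rd <- random_design_strings(n, m, seed)
    ds <- design_set(rd$native, rd$designs)

    for (d in unique(rd$designs)) {
      expect_identical(sequence_recovery(rd$native, d),
                       oracle_recovery(rd$native, d))
      expect_identical(similarity_recovery(rd$native, d),
                       oracle_similarity(rd$native, d))
      mask <- runif(n) < 0.5
      expect_identical(subset_recovery(rd$native, d, mask),
                       oracle_subset_recovery(rd$native, d, mask))
    }
    expect_identical(uniqueness(ds), oracle_uniqueness(rd$designs))
    eo <- oracle_entropy(rd$designs)
    ep <- positional_entropy(ds)
    expect_equal(ep$h, eo$h)
    expect_equal(ep$mse, eo$mse)
    expect_identical(
      max_recovery(ds),
      max(vapply(rd$designs, oracle_recovery, numeric(1),
                 native = rd$native)))
  }
})

test_that("metrics are permutation-invariant and correctly ordered", {
  for (seed in 1:10) {
    rd <- random_design_strings(10, 12, seed + 100)
    ds <- design_set(rd$native, rd$designs)
    perm <- sample(length(rd$designs))
    dsp <- design_set(rd$native, rd$designs[perm])
    expect_equal(uniqueness(ds), uniqueness(dsp))
    expect_equal(positional_entropy(ds)$mse, positional_entropy(dsp)$mse)
    expect_equal(max_recovery(ds), max_recovery(dsp))
    for (d in rd$designs[1:3]) {
      rec <- sequence_recovery(rd$native, d)
      sim <- similarity_recovery(rd$native, d)
      expect_true(rec >= 0 && sim <= 100 && rec <= sim)
    }
  }
})

make_cases <- function() {
  # two tiny hand-checkable cases over CDR3 positions
  pos1 <- data.frame(chain = "A", resnum = 1:2, icode = "",
                     aho = c(106L, 107L), region = "CDR3",
                     native_aa = c("G", "G"), role = "tcr_alpha",
                     stringsAsFactors = FALSE)
  pos2 <- data.frame(chain = "A", resnum = 1:2, icode = "",
                     aho = c(106L, 108L), region = "CDR3",
                     native_aa = c("A", "K"), role = "tcr_alpha",
                     stringsAsFactors = FALSE)
  list(
    c1 = list(positions = pos1,
              designs = design_set("GG", c("GG", "GA", "GA"))),
    c2 = list(positions = pos2,
              designs = design_set("AK", c("AK", "WK")))
  )
}

test_that("per-position recovery pools by (role, aho) with sparse flagging", {
  res <- per_position_recovery(make_cases(), min_cases = 2)
  s <- res$summary
  # aho 106 designed in both cases: c1 dedup {GG, GA} -> 100%;
  # c2 {AK, WK} -> 50%; mean 75
  expect_equal(s$mean_recovery[s$aho == 106], 75)
  expect_equal(s$n_cases[s$aho == 106], 2)
  expect_false(s$excluded[s$aho == 106])
  # aho 107 only in c1 (dedup match 100, 50 -> wait: GG vs GG, GA)
  expect_equal(s$mean_recovery[s$aho == 107], 50)
  expect_true(s$excluded[s$aho == 107])
  # independent double-loop recomputation
  for (k in seq_len(nrow(res$per_case))) {
    row <- res$per_case[k, ]
    cs <- make_cases()[[row$case_id]]
    dd <- unique(cs$designs$designs)
    j <- which(cs$positions$aho == row$aho)
    nat <- substr(cs$designs$native, j, j)
    manual <- 100 * mean(vapply(dd, function(d)
      substr(d, j, j) == nat, logical(1)))
    expect_equal(row$recovery, manual)
  }
})

test_that("composition pools native and design cells; both sum to 100", {
  comp <- composition_frequencies(make_cases())
  expect_equal(sum(comp$native), 100, tolerance = 1e-9)
  expect_equal(sum(comp$designed), 100, tolerance = 1e-9)
  # native pool: G,G,A,K -> G 50%, A 25%, K 25%
  expect_equal(unname(comp$native["G"]), 50)
  expect_equal(unname(comp$native["A"]), 25)
  # design pool (dedup): GG, GA, AK, WK -> 8 cells: G3 A2 K2 W1
  expect_equal(unname(comp$designed["G"]), 100 * 3 / 8)
  expect_equal(unname(comp$designed["W"]), 100 * 1 / 8)

  single <- list(c1 = list(
    positions = make_cases()$c1$positions,
    designs = design_set("GG", c("GG"))))
  expect_equal(unname(composition_frequencies(single)$native["G"]), 100)
})

test_that("substitution matrix is a joint frequency over design cells", {
  subst <- substitution_matrix(make_cases())
  expect_equal(sum(subst), 100, tolerance = 1e-9)
  # cells: c1 dedup GG,GA: (G,G),(G,G),(G,G),(G,A); c2: (A,A),(K,K),(A,W),(K,K)
  expect_equal(subst["G", "G"], 100 * 3 / 8)
  expect_equal(subst["G", "A"], 100 * 1 / 8)
  expect_equal(subst["K", "K"], 100 * 2 / 8)
  expect_equal(subst["A", "W"], 100 * 1 / 8)

  ident <- list(c1 = list(positions = make_cases()$c1$positions,
                          designs = design_set("GG", c("GG"))))
  si <- substitution_matrix(ident)
  expect_equal(sum(diag(si)), 100)

  srow <- substitution_matrix(make_cases(), normalize = "row")
  expect_equal(unname(rowSums(srow, na.rm = TRUE)[c("G", "A", "K")]),
               c(100, 100, 100))
})

test_that("subset recovery restricts Eq-style matching to the mask", {
  expect_equal(subset_recovery("ACDE", "ACDE", rep(TRUE, 4)), 100)
  expect_equal(subset_recovery("ACDE", "AWWW", c(TRUE, FALSE, FALSE,
                                                 FALSE)), 100)
  expect_true(is.na(subset_recovery("ACDE", "ACDE", rep(FALSE, 4))))
  expect_equal(subset_recovery("ACDE", "ACWW", rep(TRUE, 4)),
               sequence_recovery("ACDE", "ACWW"))
})
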