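# Hotspot classification, bootstrap group test, rank-sum test,
# pMHC-removal summaries.

test_that("hotspot rule is strict on |ddG| > 0.5 kcal/mol", {
  expect_true(classify_hotspots(0.6))
  expect_true(classify_hotspots(-0.6))
  expect_false(classify_hotspots(0.5))
  expect_false(classify_hotspots(-0.5))
  tab <- data.frame(chain = "A", resnum = 1:3, icode = "",
                    ddg = c(0.6, -0.7, 0.2))
  expect_equal(classify_hotspots(tab)$hotspot, c(TRUE, TRUE, FALSE))
})

test_that("bootstrap p-value hits the estimator floor and the centre", {
  ref <- c(40, 45, 50, 55, 60, 42, 58, 48, 52, 46, 54, 44)
  # test mean far below every possible subsample mean -> floor
  b <- bootstrap_group_pvalue(ref, c(1, 2, 3), k = 6, n_boot = 1000,
                              seed = 1)
  expect_equal(b$p_two_tailed, 2 / 1001)
  expect_equal(b$observed_mean, 2)
  expect_length(b$null_means, 1000)
  # test group centred on the reference -> p near 1
  b2 <- bootstrap_group_pvalue(ref, ref, k = 6, n_boot = 1000, seed = 2)
  expect_gte(b2$p_two_tailed, 0.9)
})

test_that("bootstrap is seeded-reproducible and permutation-invariant", {
  ref <- seq(30, 70, length.out = 15)
  tst <- c(35, 40, 38)
  b1 <- bootstrap_group_pvalue(ref, tst, k = 6, n_boot = 500, seed = 42)
  b2 <- bootstrap_group_pvalue(ref, tst, k = 6, n_boot = 500, seed = 42)
  expect_identical(b1$null_means, b2$null_means)
  expect_identical(b1$p_two_tailed, b2$p_two_tailed)
  b3 <- bootstrap_group_pvalue(rev(ref), tst, k = 6, n_boot = 500,
                               seed = 42)
  expect_equal(sort(b3$null_means), sort(b1$null_means))

  expect_error(bootstrap_group_pvalue(1:5, 1, k = 6, seed = 1),
               "more reference values")
  # with-replacement mode lifts that restriction
  b4 <- bootstrap_group_pvalue(1:5, 1, k = 6, n_boot = 100, seed = 1,
                               replace = TRUE)
  expect_length(b4$null_means, 100)
})

test_that("the subsampling test is calibrated for large reference panels", {
  # with a large reference group the finite-population correction and the
  # reference-mean noise vanish, and the type-I error approaches alpha
  set.seed(19)
  rejections <- vapply(seq_len(1500), function(i) {
    ref <- rnorm(1000, 60, 10)
    tst <- rnorm(6, 60, 10)
    bootstrap_group_pvalue(ref, tst, k = 6, n_boot = 1000,
                           seed = i)$p_two_tailed < 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("moving the observed mean into the tail never increases p", {
  ref <- seq(30, 70, length.out = 20)
  obs <- seq(50, 20, by = -5)
  ps <- vapply(obs, function(o)
    bootstrap_group_pvalue(ref, o, k = 6, n_boot = 400,
                           seed = 7)$p_two_tailed, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("exact rank-sum branch equals the permutation oracle", {
  # separated groups: only the 2 most extreme of the 20 labelings
  rs <- rank_sum_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(rs$method, "exact")
  expect_equal(rs$p_value, 0.1)
  expect_equal(rs$statistic, 0)

  # identical groups (ties) -> symmetric, p = 1
  rs2 <- rank_sum_test(c(5, 6, 7), c(5, 6, 7))
  expect_equal(rs2$p_value, 1)

  # full agreement with the exhaustive permutation distribution
  set.seed(31)
  for (rep in 1:20) {
    na <- sample(2:5, 1)
    nb <- sample(2:5, 1)
    vals <- sample(seq_len(50), na + nb)  # distinct -> no ties
    a <- vals[seq_len(na)]
    b <- vals[-seq_len(na)]
    rs <- rank_sum_test(a, b)
    expect_equal(rs$method, "exact")
    # oracle: enumerate every labeling of the pooled values
    pool <- c(a, b)
    idx <- utils::combn(na + nb, na)
    u_all <- apply(idx, 2, function(ii) {
      ra <- rank(pool)[ii]
      sum(ra) - na * (na + 1) / 2
    })
    u_obs <- sum(rank(pool)[seq_len(na)]) - na * (na + 1) / 2
    p_oracle <- min(1, 2 * min(mean(u_all <= u_obs),
                               mean(u_all >= u_obs)))
    expect_equal(rs$p_value, p_oracle)
    # and the standard-library backend agrees on the exact branch
    expect_equal(rs$p_value,
                 stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("normal-approximation branch tracks the reference backend", {
  set.seed(17)
  a <- rnorm(30, 50, 10)
  b <- rnorm(25, 55, 10)
  rs <- rank_sum_test(a, b, exact_max = 8)
  expect_equal(rs$method, "normal")
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  expect_equal(rs$p_value, ref, tolerance = 1e-10)
})

test_that("context-removal summary computes deltas, means, correlation", {
  w <- c(a = 50, b = 60)
  wo <- c(b = 20, a = 30)
  s <- context_removal_summary(w, wo)
  expect_equal(s$per_case$delta, c(20, 40))
  expect_equal(s$mean_delta, 30)

  same <- context_removal_summary(w, w)
  expect_equal(same$per_case$delta, c(0, 0))

  s2 <- context_removal_summary(w, wo,
                                other_deltas = c(a = 20, b = 40))
  expect_equal(s2$pearson_r, 1)
  expect_error(context_removal_summary(w, c(a = 1, z = 2)),
               "case ids differ")
})
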