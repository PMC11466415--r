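# Hotspot classification from alanine-scan ddG, the subsampling bootstrap
# group-comparison test, Mann-Whitney rank tests, and with/without-pMHC
# comparison summaries.

#' Classify alanine-scan hotspots
#'
#' A residue is a hotspot when the absolute alanine-substitution free-energy
#' change exceeds the threshold: |ddG| > 0.5 kcal/mol by default (strict).
#'
#' @param ddg A data.frame from [read_ddg_table()] (columns chain, resnum,
#'   icode, ddg) or a bare numeric vector of ddG values.
#' @param threshold Hotspot threshold in kcal/mol (default 0.5).
#' @return The input with a logical `hotspot` column appended (or a logical
#'   vector for numeric input).
#' @export
classify_hotspots <- function(ddg, threshold = 0.5) {
  if (is.numeric(ddg)) return(abs(ddg) > threshold)
  ddg$hotspot <- abs(ddg$ddg) > threshold
  ddg
}

#' Subsampling bootstrap test for a small group against a reference group
#'
#' Tests whether the mean of a small test group (e.g. the per-case maximum
#' recoveries of the 6 MHC-II cases) is compatible with the reference group
#' (the MHC-I cases): a null distribution of means is built by repeatedly
#' subsampling k cases from the reference values (without replacement within
#' each draw, by default) and averaging; the observed test-group mean is
#' located in that distribution with an add-one empirical CDF and the
#' two-tailed p-value is twice the smaller tail, capped at 1.
#'
#' @param reference_values Numeric vector of per-case statistics (length >
#'   k in without-replacement mode).
#' @param test_group_values Numeric vector for the test group; its mean is
#'   the observed statistic.
#' @param k Subsample size per draw (default 6, the number of test cases).
#' @param n_boot Number of subsample draws (default 1000).
#' @param seed Integer seed; the test is reproducible given the seed.
#' @param replace Draw with replacement within each subsample (default
#'   FALSE).
#' @return List of class `bootstrap_result`: `observed_mean`, `null_means`,
#'   `p_two_tailed`, `k`, `n_boot`, `seed`, `replace`.
#' @export
bootstrap_group_pvalue <- function(reference_values, test_group_values,
                                   k = 6, n_boot = 1000, seed,
                                   replace = FALSE) {
  if (k < 1 || n_boot < 1) stop("k and n_boot must be >= 1")
  if (!replace && length(reference_values) <= k) {
    stop("need more reference values than k for without-replacement draws")
  }
  if (length(test_group_values) < 1) stop("empty test group")
  if (missing(seed)) stop("seed is required for reproducibility")
  # sort so the draw sequence is invariant to input permutation
  reference_values <- sort(reference_values)

  rng <- local({
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    if (replace) {
      idx <- matrix(sample.int(length(reference_values), k * n_boot,
                               replace = TRUE), nrow = k)
      colMeans(matrix(reference_values[idx], nrow = k))
    } else {
      vapply(seq_len(n_boot), function(i) {
        mean(reference_values[sample.int(length(reference_values), k)])
      }, numeric(1))
    }
  })
  obs <- mean(test_group_values)
  # symmetric add-one tails: never exactly 0, floor 2/(n_boot+1)
  lower <- (1 + sum(rng <= obs)) / (n_boot + 1)
  upper <- (1 + sum(rng >= obs)) / (n_boot + 1)
  p <- min(1, 2 * min(lower, upper))
  structure(list(observed_mean = obs, null_means = rng, p_two_tailed = p,
                 k = k, n_boot = n_boot, seed = seed, replace = replace),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "bootstrap_result: observed mean %.3f, p (two-tailed) = %.4f ",
    x$observed_mean, x$p_two_tailed))
  cat(sprintf("(k = %d, n_boot = %d, seed = %d, %s replacement)\n",
              x$k, x$n_boot, x$seed, if (x$replace) "with" else "without"))
  invisible(x)
}

#' Two-sided Mann-Whitney rank-sum test
#'
#' Exact enumeration of the U distribution when the smaller group has at
#' most `exact_max` observations and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @param exact_max Largest min-group size for the exact branch (default 8).
#' @return List: `statistic` (U of group_a), `p_value` (two-sided),
#'   `method` ("exact" or "normal").
#' @export
rank_sum_test <- function(group_a, group_b, exact_max = 8) {
  n1 <- length(group_a)
  n2 <- length(group_b)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  comb <- c(group_a, group_b)
  r <- rank(comb)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(comb) > 0

  if (!has_ties && min(n1, n2) <= exact_max) {
    # exact: U over all C(n1+n2, n1) equally likely rank assignments
    sets <- utils::combn(n1 + n2, n1)
    u_null <- colSums(matrix(seq_len(n1 + n2)[sets], nrow = n1)) -
      n1 * (n1 + 1) / 2
    p_le <- mean(u_null <= u)
    p_ge <- mean(u_null >= u)
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(statistic = u, p_value = p, method = "exact"))
  }

  n <- n1 + n2
  mu <- n1 * n2 / 2
  ties <- table(comb)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(statistic = u, p_value = 1,
                               method = "normal"))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = u, p_value = p, method = "normal")
}

#' Effect of pMHC removal on per-case maximum recovery
#'
#' Per-case difference between the maximum sequence recovery obtained with
#' the pMHC context and without it (with minus without), with group means;
#' optionally the Pearson correlation between this method's per-case deltas
#' and another method's.
#'
#' @param max_with Named numeric vector, case id -> maximum recovery (%)
#'   with pMHC.
#' @param max_without Named numeric vector over the same case ids, without
#'   pMHC.
#' @param other_deltas Optional named numeric vector of another method's
#'   deltas (same case ids) for the cross-method correlation.
#' @return List: `per_case` (data.frame case_id, with, without, delta),
#'   `mean_with`, `mean_without`, `mean_delta`, and `pearson_r` when
#'   `other_deltas` is given.
#' @export
context_removal_summary <- function(max_with, max_without,
                                    other_deltas = NULL) {
  if (is.null(names(max_with)) || is.null(names(max_without))) {
    stop("max_with/max_without must be named by case id")
  }
  if (!setequal(names(max_with), names(max_without))) {
    stop("case ids differ between with/without runs")
  }
  ids <- names(max_with)
  w <- max_with[ids]
  wo <- max_without[ids]
  delta <- w - wo
  out <- list(
    per_case = data.frame(case_id = ids, with = unname(w),
                          without = unname(wo), delta = unname(delta),
                          stringsAsFactors = FALSE),
    mean_with = mean(w), mean_without = mean(wo),
    mean_delta = mean(delta)
  )
  if (!is.null(other_deltas)) {
    if (!setequal(names(other_deltas), ids)) {
      stop("other_deltas case ids do not match")
    }
    out$pearson_r <- stats::cor(unname(delta),
                                unname(other_deltas[ids]))
  }
  out
}
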