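# Sequence-level design-quality metrics: native sequence recovery,
# physicochemical similarity, uniqueness, positional Shannon entropy,
# per-position / composition / substitution summaries, subset recoveries.
#
# Conventions: recovery-type statistics are computed on deduplicated design
# sets; uniqueness and entropy on the raw sets (they measure generation
# diversity, not design quality).

seq_chars <- function(s) strsplit(s, "")[[1]]

check_pair <- function(native, designed) {
  if (nchar(native) != nchar(designed)) {
    stop("native/designed length mismatch: ", nchar(native), " vs ",
         nchar(designed))
  }
  if (nchar(native) < 1) stop("empty sequences")
}

#' Native sequence recovery
#'
#' Percentage of designed positions whose amino acid equals the native one:
#' 100 * (1/n) * sum over positions of the match indicator. 100 means the
#' design is identical to the native sequence; 0 means no position is
#' recovered.
#'
#' @param native,designed Equal-length amino-acid strings.
#' @return Percentage in [0, 100].
#' @export
sequence_recovery <- function(native, designed) {
  check_pair(native, designed)
  x <- seq_chars(native)
  y <- seq_chars(designed)
  100 * sum(x == y) / length(x)
}

#' Physicochemical similarity recovery
#'
#' Percentage of positions where the designed amino acid falls in the same
#' physicochemical group as the native one (identity counts: it is trivially
#' same-group). Groups default to the 6-group BLOSUM62-derived partition
#' [AA_GROUPS].
#'
#' @param native,designed Equal-length amino-acid strings.
#' @param groups Partition of the 20 amino acids (default [AA_GROUPS]).
#' @return Percentage in [0, 100]; never below [sequence_recovery()].
#' @export
similarity_recovery <- function(native, designed, groups = AA_GROUPS) {
  check_pair(native, designed)
  gx <- aa_group_of(seq_chars(native), groups)
  gy <- aa_group_of(seq_chars(designed), groups)
  100 * sum(gx == gy) / length(gx)
}

#' Uniqueness of a design set
#'
#' Percentage of distinct sequences among the m generated designs:
#' 100 * u / m. Ranges from 100/m (all identical) to 100 (all distinct).
#' Computed on the raw, pre-deduplication set.
#'
#' @param designs Character vector of designed sequences, or a `design_set`.
#' @return Percentage in [100/m, 100].
#' @export
uniqueness <- function(designs) {
  if (inherits(designs, "design_set")) designs <- designs$designs
  if (length(designs) < 1) stop("need m >= 1 designs")
  100 * length(unique(designs)) / length(designs)
}

#' Positional Shannon entropy profile
#'
#' Per position j, amino-acid probabilities are estimated from observed
#' frequencies across the designs and the Shannon entropy
#' H_j = -sum p_i log2 p_i is computed (0 log 0 = 0), bounded by log2(20).
#' The mean over positions is the Mean Sequence Entropy (MSE).
#'
#' @param designs Character vector of equal-length sequences, or a
#'   `design_set` (raw set; entropy measures generation diversity).
#' @return List of class `entropy_profile`: `h` (bits per position), `mse`
#'   (mean, bits), `L` (number of positions).
#' @export
positional_entropy <- function(designs) {
  if (inherits(designs, "design_set")) designs <- designs$designs
  if (length(designs) < 1) stop("need m >= 1 designs")
  L <- nchar(designs[1])
  if (any(nchar(designs) != L)) stop("designs of unequal length")
  mat <- do.call(rbind, strsplit(designs, ""))
  h <- apply(mat, 2, function(col) {
    p <- table(col) / length(col)
    -sum(p * log2(p))
  })
  structure(list(h = unname(h), mse = mean(h), L = L),
            class = "entropy_profile")
}

#' @export
print.entropy_profile <- function(x, ...) {
  cat("entropy_profile: L =", x$L, "positions, MSE =",
      round(x$mse, 4), "bits\n")
  invisible(x)
}

#' Remove redundant designs
#'
#' Keeps the first occurrence of each distinct sequence, preserving order.
#' Applied before recovery/similarity statistics; uniqueness and entropy
#' use the raw set.
#'
#' @param design_set A `design_set`.
#' @return A `design_set` of the non-redundant designs.
#' @export
deduplicate <- function(design_set) {
  keep <- !duplicated(design_set$designs)
  design_set(design_set$native, design_set$designs[keep],
             ids = design_set$ids[keep], positions = design_set$positions)
}

#' Maximum sequence recovery of a design set
#'
#' The best native sequence recovery over the non-redundant designs of one
#' test case.
#'
#' @param design_set A `design_set`.
#' @return Percentage in [0, 100].
#' @export
max_recovery <- function(design_set) {
  dd <- deduplicate(design_set)
  max(vapply(dd$designs, sequence_recovery, numeric(1),
             native = dd$native))
}

#' Per-design metric table for one test case
#'
#' Recovery and similarity per non-redundant design, plus the raw-set
#' uniqueness and entropy.
#'
#' @param design_set A `design_set`.
#' @param groups Amino-acid partition for similarity (default [AA_GROUPS]).
#' @return List: `per_design` (data.frame id, recovery, similarity),
#'   `uniqueness`, `entropy` (an `entropy_profile`), `max_recovery`,
#'   `mean_recovery`, `mean_similarity`, `m_raw`, `m_unique`.
#' @export
case_metrics <- function(design_set, groups = AA_GROUPS) {
  dd <- deduplicate(design_set)
  rec <- vapply(dd$designs, sequence_recovery, numeric(1),
                native = dd$native)
  sim <- vapply(dd$designs, similarity_recovery, numeric(1),
                native = dd$native, groups = groups)
  list(
    per_design = data.frame(id = dd$ids, recovery = unname(rec),
                            similarity = unname(sim),
                            stringsAsFactors = FALSE),
    uniqueness = uniqueness(design_set),
    entropy = positional_entropy(design_set),
    max_recovery = max(rec),
    mean_recovery = mean(rec),
    mean_similarity = mean(sim),
    m_raw = design_set$m,
    m_unique = dd$m
  )
}

check_cases <- function(cases) {
  if (length(cases) < 1) stop("need at least one case")
  if (is.null(names(cases)) || any(names(cases) == "")) {
    stop("cases must be a named list (case id -> list(positions, designs))")
  }
  for (id in names(cases)) {
    cs <- cases[[id]]
    if (is.null(cs$positions) || is.null(cs$designs)) {
      stop("case ", id, " needs $positions and $designs")
    }
    if (nrow(cs$positions) != cs$designs$n) {
      stop("case ", id, ": positions/design length mismatch")
    }
  }
  invisible(TRUE)
}

#' Per-position sequence recovery across test cases
#'
#' For each case and designable position, the mean of the match indicator
#' over the case's non-redundant designs; pooled across cases by TCR chain
#' role and Aho number. Positions designed in fewer than `min_cases` cases
#' are flagged as excluded (sparse).
#'
#' @param cases Named list; each element `list(positions =
#'   design_position_set, designs = design_set)`.
#' @param min_cases Minimum cases per position (default 3).
#' @return List: `per_case` (long data.frame case_id, role, aho, recovery),
#'   `summary` (role, aho, mean_recovery, n_cases, excluded).
#' @export
per_position_recovery <- function(cases, min_cases = 3) {
  check_cases(cases)
  rows <- list()
  for (id in names(cases)) {
    cs <- cases[[id]]
    dd <- deduplicate(cs$designs)
    nat <- seq_chars(dd$native)
    mat <- do.call(rbind, strsplit(dd$designs, ""))
    pos_rec <- 100 * colMeans(mat == matrix(nat, nrow(mat), length(nat),
                                            byrow = TRUE))
    rows[[id]] <- data.frame(
      case_id = id, role = cs$positions$role, aho = cs$positions$aho,
      recovery = unname(pos_rec), stringsAsFactors = FALSE
    )
  }
  per_case <- do.call(rbind, rows)
  rownames(per_case) <- NULL
  key <- paste(per_case$role, per_case$aho)
  agg <- aggregate(per_case$recovery, by = list(key = key), FUN = mean)
  cnt <- aggregate(per_case$recovery, by = list(key = key), FUN = length)
  parts <- strsplit(agg$key, " ", fixed = TRUE)
  summary <- data.frame(
    role = vapply(parts, `[`, character(1), 1),
    aho = as.integer(vapply(parts, `[`, character(1), 2)),
    mean_recovery = agg$x,
    n_cases = cnt$x[match(agg$key, cnt$key)],
    stringsAsFactors = FALSE
  )
  summary$excluded <- summary$n_cases < min_cases
  summary <- summary[order(summary$role, summary$aho), ]
  rownames(summary) <- NULL
  list(per_case = per_case, summary = summary)
}

#' Amino-acid composition of native and designed positions
#'
#' Native frequencies pool the native amino acids of every designable
#' position across cases; design frequencies pool every (non-redundant
#' design x position) cell. Both distributions sum to 100.
#'
#' @param cases Named list as in [per_position_recovery()].
#' @return List of two named numeric vectors (`native`, `designed`),
#'   percentages over the 20 amino acids.
#' @export
composition_frequencies <- function(cases) {
  check_cases(cases)
  nat_all <- character(0)
  des_all <- character(0)
  for (cs in cases) {
    dd <- deduplicate(cs$designs)
    nat_all <- c(nat_all, seq_chars(dd$native))
    des_all <- c(des_all, unlist(strsplit(dd$designs, "")))
  }
  f <- function(v) {
    t <- table(factor(v, levels = AA_ALPHABET))
    100 * as.numeric(t) / length(v)
  }
  list(native = structure(f(nat_all), names = AA_ALPHABET),
       designed = structure(f(des_all), names = AA_ALPHABET))
}

#' Native-to-designed substitution frequency matrix
#'
#' Joint frequency of (native amino acid, designed amino acid) over all
#' (non-redundant design x position) cells, pooled across cases. With
#' `normalize = "global"` (default) the whole matrix sums to 100; with
#' `"row"` each native amino acid's row sums to 100 (rows with no mass are
#' NA).
#'
#' @param cases Named list as in [per_position_recovery()].
#' @param normalize `"global"` or `"row"`.
#' @return 20x20 numeric matrix, rows = native, columns = designed.
#' @export
substitution_matrix <- function(cases, normalize = c("global", "row")) {
  normalize <- match.arg(normalize)
  check_cases(cases)
  counts <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  for (cs in cases) {
    dd <- deduplicate(cs$designs)
    nat <- seq_chars(dd$native)
    for (d in dd$designs) {
      des <- seq_chars(d)
      for (k in seq_along(nat)) {
        counts[nat[k], des[k]] <- counts[nat[k], des[k]] + 1
      }
    }
  }
  if (normalize == "global") {
    100 * counts / sum(counts)
  } else {
    rs <- rowSums(counts)
    sweep(counts, 1, ifelse(rs > 0, rs, NA), "/") * 100
  }
}

#' Sequence recovery over a position subset
#'
#' Native sequence recovery restricted to masked positions (e.g. buried
#' positions or alanine-scan hotspots). An all-false mask has no defined
#' value and returns NA.
#'
#' @param native,designed Equal-length amino-acid strings.
#' @param mask Logical vector, one per position.
#' @return Percentage in [0, 100], or NA for an empty mask.
#' @export
subset_recovery <- function(native, designed, mask) {
  check_pair(native, designed)
  if (length(mask) != nchar(native)) stop("mask length mismatch")
  if (!any(mask)) return(NA_real_)
  x <- seq_chars(native)[mask]
  y <- seq_chars(designed)[mask]
  100 * sum(x == y) / length(x)
}
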