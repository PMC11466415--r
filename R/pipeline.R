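# End-to-end orchestration: load a run config, evaluate every test case
# (positions -> metrics -> annotations), write the MetricsReport tables and
# a reproducibility manifest.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load and validate a run configuration
#'
#' JSON config with fields:
#' \preformatted{
#' {
#'   "scenario": "cdr3_interface",
#'   "cases": [
#'     {"id": "case1", "pdb": "...", "roles": {"A": "tcr_alpha", ...},
#'      "aho": "aho.tsv", "designs": "designs.fasta",
#'      "ddg": "ddg.tsv"}          // ddg optional
#'   ],
#'   "options": {"cutoff": 5.0, "inclusive": true,
#'               "burial_threshold": 0.2, "hotspot_threshold": 0.5,
#'               "min_cases": 3, "n_sphere_points": 960,
#'               "annotate_burial": true},
#'   "output_dir": "out"
#' }
#' }
#' All referenced files must exist; thresholds must be positive.
#'
#' @param path JSON config path.
#' @return Validated config list.
#' @export
load_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  validate_run_config(cfg, base_dir = dirname(path))
}

validate_run_config <- function(cfg, base_dir = ".") {
  if (is.null(cfg$scenario)) stop("config lacks 'scenario'")
  cfg$scenario <- match.arg(cfg$scenario, DESIGN_SCENARIOS)
  if (length(cfg$cases) < 1) stop("config lists no cases")
  resolve <- function(p) {
    if (file.exists(p)) p else file.path(base_dir, p)
  }
  ids <- vapply(cfg$cases, function(cs) cs$id %||% "", character(1))
  if (any(ids == "")) stop("every case needs an 'id'")
  if (anyDuplicated(ids)) stop("duplicate case ids")
  for (i in seq_along(cfg$cases)) {
    cs <- cfg$cases[[i]]
    for (f in c("pdb", "aho", "designs")) {
      if (is.null(cs[[f]])) stop("case ", cs$id, " lacks '", f, "'")
      cfg$cases[[i]][[f]] <- resolve(cs[[f]])
      if (!file.exists(cfg$cases[[i]][[f]])) {
        stop("case ", cs$id, ": missing file ", cs[[f]])
      }
    }
    if (!is.null(cs$ddg)) {
      cfg$cases[[i]]$ddg <- resolve(cs$ddg)
      if (!file.exists(cfg$cases[[i]]$ddg)) {
        stop("case ", cs$id, ": missing ddg table ", cs$ddg)
      }
    }
    if (is.null(cs$roles)) stop("case ", cs$id, " lacks 'roles'")
  }
  opt <- cfg$options %||% list()
  opt$cutoff <- opt$cutoff %||% 5.0
  opt$inclusive <- opt$inclusive %||% TRUE
  opt$burial_threshold <- opt$burial_threshold %||% 0.2
  opt$hotspot_threshold <- opt$hotspot_threshold %||% 0.5
  opt$min_cases <- opt$min_cases %||% 3
  opt$n_sphere_points <- opt$n_sphere_points %||% 960
  opt$annotate_burial <- opt$annotate_burial %||% TRUE
  for (th in c("cutoff", "burial_threshold", "hotspot_threshold")) {
    if (opt[[th]] <= 0) stop("option ", th, " must be positive")
  }
  cfg$options <- opt
  cfg
}

round1 <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = 1)
  df
}

write_csv_out <- function(df, path) {
  utils::write.csv(round1(df), path, row.names = FALSE, quote = FALSE)
}

evaluate_one_case <- function(cs, scenario, opt, out_dir) {
  st <- read_pdb_complex(cs$pdb, unlist(cs$roles))
  aho <- read_aho_map(cs$aho)
  contacts <- compute_contacts(st, c("tcr_alpha", "tcr_beta"),
                               c("peptide", "mhc"),
                               cutoff = opt$cutoff,
                               inclusive = opt$inclusive)
  positions <- select_design_positions(st, aho, scenario,
                                       contacts = contacts)
  designs <- read_design_sets(cs$designs, positions)
  metrics <- case_metrics(designs)

  burial <- NULL
  if (isTRUE(opt$annotate_burial)) {
    burial <- annotate_burial(st, n_sphere_points = opt$n_sphere_points,
                              threshold = opt$burial_threshold)
  }
  hotspots <- if (!is.null(cs$ddg)) {
    classify_hotspots(read_ddg_table(cs$ddg),
                      threshold = opt$hotspot_threshold)
  } else NULL

  # subset recoveries over buried / hotspot designed positions
  dd <- deduplicate(designs)
  pos_key <- res_key(positions$chain, positions$resnum, positions$icode)
  subset_row <- function(mask, label) {
    vals <- vapply(dd$designs, subset_recovery, numeric(1),
                   native = dd$native, mask = mask)
    data.frame(id = dd$ids, subset = label, recovery = unname(vals),
               n_positions = sum(mask), stringsAsFactors = FALSE)
  }
  subsets <- list()
  if (!is.null(burial)) {
    bkey <- res_key(burial$chain, burial$resnum, burial$icode)
    bmask <- burial$buried[match(pos_key, bkey)]
    bmask[is.na(bmask)] <- FALSE
    subsets$buried <- subset_row(bmask, "buried")
  }
  if (!is.null(hotspots)) {
    hkey <- res_key(hotspots$chain, hotspots$resnum, hotspots$icode)
    hmask <- hotspots$hotspot[match(pos_key, hkey)]
    hmask[is.na(hmask)] <- FALSE
    subsets$hotspot <- subset_row(hmask, "hotspot")
  }

  case_dir <- file.path(out_dir, cs$id)
  dir.create(case_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(as.data.frame(positions),
                     file.path(case_dir, "positions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_csv_out(metrics$per_design,
                file.path(case_dir, "per_design_metrics.csv"))
  if (!is.null(burial)) {
    write_csv_out(burial, file.path(case_dir, "burial.csv"))
  }
  if (!is.null(hotspots)) {
    write_csv_out(hotspots, file.path(case_dir, "hotspots.csv"))
  }
  if (length(subsets) > 0) {
    write_csv_out(do.call(rbind, subsets),
                  file.path(case_dir, "subset_recovery.csv"))
  }

  list(positions = positions, designs = designs, metrics = metrics,
       burial = burial, hotspots = hotspots,
       subsets = if (length(subsets)) do.call(rbind, subsets) else NULL)
}

#' Run a full design-evaluation pipeline
#'
#' For each configured case: parse the structure, detect the TCR-pMHC
#' interface, select design positions for the scenario, load the designed
#' sequences and compute all per-case metrics and annotations; then the
#' cross-case aggregates (max recovery, per-position recovery, composition
#' and substitution tables, optional group tests). All tables are written
#' under the output directory plus a JSON manifest; the full report is
#' returned invisibly. A run is a pure function of its inputs, config and
#' seeds.
#'
#' @param config Config list (see [load_run_config()]) or path to a JSON
#'   config.
#' @param output_dir Output directory (overrides `config$output_dir`).
#' @param group_map Optional named character vector case id -> group label;
#'   when exactly two groups are present the bootstrap group test
#'   (reference = larger group) and the rank-sum test are run on the
#'   per-case maximum recoveries.
#' @param bootstrap Options for the group test:
#'   `list(k = 6, n_boot = 1000, seed = 1, replace = FALSE)`.
#' @return Invisibly, a `metrics_report` list: `cases`, `max_recovery`,
#'   `per_position`, `composition`, `substitution`, `tests`.
#' @export
run_evaluation <- function(config, output_dir = NULL, group_map = NULL,
                           bootstrap = list(k = 6, n_boot = 1000,
                                            seed = 1, replace = FALSE)) {
  if (is.character(config)) config <- load_run_config(config)
  else config <- validate_run_config(config)
  out_dir <- output_dir %||% config$output_dir %||% stop(
    "no output directory configured")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  opt <- config$options

  case_results <- list()
  for (cs in config$cases) {
    case_results[[cs$id]] <- tryCatch(
      evaluate_one_case(cs, config$scenario, opt, out_dir),
      error = function(e) stop("case ", cs$id, ": ", conditionMessage(e),
                               call. = FALSE)
    )
  }

  cases <- lapply(case_results, function(r)
    list(positions = r$positions, designs = r$designs))

  maxrec <- data.frame(
    case_id = names(case_results),
    max_recovery = vapply(case_results, function(r)
      r$metrics$max_recovery, numeric(1)),
    mean_recovery = vapply(case_results, function(r)
      r$metrics$mean_recovery, numeric(1)),
    mean_similarity = vapply(case_results, function(r)
      r$metrics$mean_similarity, numeric(1)),
    uniqueness = vapply(case_results, function(r)
      r$metrics$uniqueness, numeric(1)),
    mse = vapply(case_results, function(r)
      r$metrics$entropy$mse, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(maxrec) <- NULL
  write_csv_out(maxrec, file.path(out_dir, "case_summary.csv"))

  per_pos <- per_position_recovery(cases, min_cases = opt$min_cases)
  write_csv_out(per_pos$summary,
                file.path(out_dir, "per_position_recovery.csv"))
  comp <- composition_frequencies(cases)
  comp_df <- data.frame(aa = AA_ALPHABET, native = comp$native,
                        designed = comp$designed,
                        stringsAsFactors = FALSE)
  rownames(comp_df) <- NULL
  write_csv_out(comp_df, file.path(out_dir, "composition.csv"))
  subst <- substitution_matrix(cases)
  write_csv_out(cbind(data.frame(native = rownames(subst)),
                      as.data.frame(round(subst, 4))),
                file.path(out_dir, "substitution_matrix.csv"))

  tests <- NULL
  if (!is.null(group_map)) {
    missing_ids <- setdiff(maxrec$case_id, names(group_map))
    if (length(missing_ids) > 0) {
      stop("group_map lacks cases: ", paste(missing_ids, collapse = ", "))
    }
    g <- group_map[maxrec$case_id]
    labs <- sort(unique(unname(g)))
    if (length(labs) == 2) {
      v1 <- maxrec$max_recovery[g == labs[1]]
      v2 <- maxrec$max_recovery[g == labs[2]]
      ref_first <- length(v1) >= length(v2)
      boot <- bootstrap_group_pvalue(
        reference_values = if (ref_first) v1 else v2,
        test_group_values = if (ref_first) v2 else v1,
        k = bootstrap$k %||% 6, n_boot = bootstrap$n_boot %||% 1000,
        seed = bootstrap$seed %||% 1,
        replace = bootstrap$replace %||% FALSE)
      rs <- rank_sum_test(v1, v2)
      tests <- list(bootstrap = boot, rank_sum = rs,
                    reference_group = labs[if (ref_first) 1 else 2])
      jsonlite::write_json(
        list(bootstrap = list(observed_mean = boot$observed_mean,
                              p_two_tailed = boot$p_two_tailed,
                              k = boot$k, n_boot = boot$n_boot,
                              seed = boot$seed, replace = boot$replace,
                              reference_group = tests$reference_group),
             rank_sum = rs),
        file.path(out_dir, "group_tests.json"), auto_unbox = TRUE,
        digits = NA)
    }
  }

  manifest <- list(
    package = "tcreval",
    version = as.character(utils::packageVersion("tcreval")),
    scenario = config$scenario,
    options = opt,
    n_cases = length(config$cases),
    case_ids = names(case_results),
    bootstrap = if (!is.null(tests)) bootstrap else NULL
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  report <- list(cases = case_results, max_recovery = maxrec,
                 per_position = per_pos, composition = comp,
                 substitution = subst, tests = tests,
                 output_dir = out_dir)
  class(report) <- "metrics_report"
  invisible(report)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("metrics_report:", length(x$cases), "cases ->", x$output_dir, "\n")
  print(round1(x$max_recovery))
  invisible(x)
}

#' Compare paired runs with and without the pMHC context
#'
#' Given two `metrics_report`s over the same case ids (one evaluated on the
#' bound complex, one with the pMHC removed), computes the per-case drop in
#' maximum sequence recovery and writes the comparison table.
#'
#' @param run_with_pmhc,run_without_pmhc `metrics_report` objects from
#'   [run_evaluation()].
#' @param output_path Optional CSV path for the per-case table.
#' @param other_deltas Optional named deltas of another method for the
#'   cross-method Pearson correlation.
#' @return A [context_removal_summary()] list.
#' @export
compare_runs <- function(run_with_pmhc, run_without_pmhc,
                         output_path = NULL, other_deltas = NULL) {
  w <- run_with_pmhc$max_recovery
  wo <- run_without_pmhc$max_recovery
  if (!setequal(w$case_id, wo$case_id)) {
    stop("runs cover different case ids")
  }
  res <- context_removal_summary(
    structure(w$max_recovery, names = w$case_id),
    structure(wo$max_recovery, names = wo$case_id),
    other_deltas = other_deltas
  )
  if (!is.null(output_path)) {
    write_csv_out(res$per_case, output_path)
  }
  res
}
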