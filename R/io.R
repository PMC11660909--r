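# Formats and orchestration: tidy CSV readers/writers for cohorts and a
# seeded end-to-end pipeline producing an artifact manifest.

#' Read a long-format cohort CSV
#'
#' Expects the header `patient_id, month, mmse, cdrsb, faq`; empty cells
#' are missing values. Months are validated against the declared grid,
#' scores against their valid ranges, and duplicated (patient, month)
#' rows are rejected — all errors name the offending CSV line numbers.
#'
#' @param path CSV file path.
#' @param visit_grid months the cohort is declared on.
#' @param truth_path optional CSV `patient_id, true_label` with generator
#'   ground truth.
#' @return a `longitudinal_cohort`.
#' @export
read_long_cohort <- function(path, visit_grid = seq(0, 36, by = 6),
                             truth_path = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(), month = readr::col_double(),
    mmse = readr::col_double(), cdrsb = readr::col_double(),
    faq = readr::col_double()
  ))
  expected <- c("patient_id", "month", "mmse", "cdrsb", "faq")
  if (!identical(names(df), expected)) {
    stopf("malformed header: expected columns %s", paste(expected, collapse = ", "))
  }
  lineno <- seq_len(nrow(df)) + 1L  # header is line 1
  bad_month <- which(!df$month %in% visit_grid)
  if (length(bad_month) > 0) {
    stopf("month outside the declared visit grid at line(s) %s",
          paste(head(lineno[bad_month], 5), collapse = ", "))
  }
  info <- score_info()
  for (d in seq_len(nrow(info))) {
    v <- df[[info$score[d]]]
    bad <- which(!is.na(v) & (v < info$min[d] | v > info$max[d]))
    if (length(bad) > 0) {
      stopf("%s outside [%g, %g] at line(s) %s", info$score[d], info$min[d],
            info$max[d], paste(head(lineno[bad], 5), collapse = ", "))
    }
  }
  key <- paste(df$patient_id, df$month)
  dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
  if (length(dup) > 0) {
    stopf("duplicated (patient, month) rows at line(s) %s",
          paste(lineno[dup], collapse = ", "))
  }
  truth <- if (!is.null(truth_path)) {
    readr::read_csv(truth_path, col_types = readr::cols(
      patient_id = readr::col_character(),
      true_label = readr::col_character()
    ))
  } else {
    tibble::tibble(patient_id = unique(df$patient_id),
                   true_label = NA_character_)
  }
  new_longitudinal_cohort(tibble::as_tibble(df), truth,
                          as.numeric(visit_grid))
}

#' Write cohort artifacts as CSV
#'
#' Writes `cohort_long.csv` (empty cell = missing), `truth.csv` and, when
#' supplied, `baseline.csv` into `dir`.
#'
#' @param cohort a `longitudinal_cohort`.
#' @param dir output directory (created if absent).
#' @param baseline optional baseline feature table.
#' @return invisibly, the paths written.
#' @export
write_cohort_csv <- function(cohort, dir, baseline = NULL) {
  stopifnot(inherits(cohort, "longitudinal_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(long = file.path(dir, "cohort_long.csv"),
             truth = file.path(dir, "truth.csv"))
  readr::write_csv(cohort$visits, paths["long"], na = "")
  readr::write_csv(cohort$truth, paths["truth"], na = "")
  if (!is.null(baseline)) {
    paths["baseline"] <- file.path(dir, "baseline.csv")
    readr::write_csv(baseline, paths["baseline"], na = "")
  }
  invisible(paths)
}

#' Pipeline configuration
#'
#' Stage settings for [run_pipeline()]. The defaults run a desk-scale
#' end-to-end analysis (small cohort, reduced epochs and CV budget).
#'
#' @param out_dir output directory for stage artifacts.
#' @param seed global seed; every stage derives its seed from it.
#' @param cohort a [cohort_config()] (its seed is overridden by `seed`).
#' @param k number of subgroups, or `"auto"` to run [select_k()].
#' @param k_range candidates for `"auto"` selection.
#' @param cluster a [training_config()]; the full defaults keep fits
#'   reliable, reduce epochs for quick demos.
#' @param repeats consensus repeats.
#' @param ps_splits prediction-strength splits and null draws for
#'   `"auto"` selection.
#' @param cv a [cv_config()].
#' @param thresholds enrichment threshold grid.
#' @param effect an [effect_spec()].
#' @param power a [power_spec()].
#' @param costs a [cost_params()].
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            cohort = cohort_config(n_patients = 200),
                            k = 2, k_range = 2:3,
                            cluster = training_config(),
                            repeats = 10, ps_splits = 10,
                            cv = cv_config(outer_folds = 4, inner_folds = 3,
                                           repeats = 2, search_budget = 5),
                            thresholds = seq(0.5, 0.9, by = 0.05),
                            effect = effect_spec(), power = power_spec(),
                            costs = cost_params()) {
  stopifnot(is.character(out_dir), length(out_dir) == 1)
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), cohort = cohort,
         k = k, k_range = k_range, cluster = cluster, repeats = repeats,
         ps_splits = ps_splits, cv = cv, thresholds = thresholds,
         effect = effect, power = power, costs = costs),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' simulate -> cluster (consensus over repeats, optional k selection) ->
#' characterize -> classify (nested CV + final model) -> enrich ->
#' economics. Every artifact is written under `config$out_dir` and listed
#' in `manifest.json` together with the global seed.
#'
#' @param config a [pipeline_config()].
#' @return the manifest (named list of artifact paths), invisibly
#'   alongside the in-memory stage results in attribute `"results"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  ccfg <- config$cohort; ccfg$seed <- config$seed
  sim <- stage("simulate", simulate_cohort(ccfg))
  paths <- write_cohort_csv(sim$cohort, config$out_dir, sim$baseline)
  manifest$cohort <- unname(paths)

  tensor <- as_trajectory_tensor(sim$cohort)
  tcfg <- config$cluster; tcfg$seed <- config$seed + 100L
  k <- config$k
  if (identical(k, "auto")) {
    sel <- stage("select_k", select_k(tensor, config$k_range, tcfg,
                                      n_splits = config$ps_splits,
                                      n_null = config$ps_splits,
                                      seed = config$seed + 200L))
    if (is.na(sel$k)) stopf("no cluster structure detected")
    k <- sel$k
    manifest$k_selection <- file.path(config$out_dir, "k_selection.csv")
    readr::write_csv(sel$table, manifest$k_selection)
  }
  clus <- stage("cluster", consensus_cluster(tensor, k, tcfg,
                                             repeats = config$repeats))
  assign_tab <- tibble::tibble(
    patient_id = clus$assignment$patient_id,
    label = clus$assignment$label,
    semantic_label = clus$assignment$semantic_label,
    p_fast = clus$assignment$responsibilities[
      , which(clus$assignment$semantic == "fast")[1]]
  )
  manifest$assignments <- file.path(config$out_dir, "assignments.csv")
  readr::write_csv(assign_tab, manifest$assignments)

  char <- stage("characterize", characterize(sim$baseline, clus$assignment))
  manifest$characterization <- file.path(config$out_dir, "table1.csv")
  readr::write_csv(char, manifest$characterization)

  labels <- as.integer(clus$assignment$semantic_label == "fast")
  cvcfg <- config$cv; cvcfg$seed <- config$seed + 300L
  cvrep <- stage("classify", nested_cv(sim$baseline, labels, cvcfg))
  manifest$cv_report <- file.path(config$out_dir, "cv_report.json")
  jsonlite::write_json(
    list(auc_roc_mean = cvrep$auc_roc_mean, auc_roc_sd = cvrep$auc_roc_sd,
         auc_pr_mean = cvrep$auc_pr_mean, auc_pr_sd = cvrep$auc_pr_sd,
         prevalence = cvrep$prevalence, seed = cvcfg$seed),
    manifest$cv_report, auto_unbox = TRUE, digits = NA)

  n_retrain <- 10
  pmat <- stage("predict", vapply(seq_len(n_retrain), function(r) {
    m <- train_final(sim$baseline, labels, seed = config$seed + 400L + r)
    predict_proba(m, sim$baseline)
  }, numeric(nrow(sim$baseline))))

  enr <- stage("enrich", enrichment_curve(pmat, labels, config$thresholds))
  red <- stage("enrich", reduction_curve(sim$cohort, pmat, config$thresholds,
                                         config$effect, config$power))
  manifest$enrichment <- file.path(config$out_dir, "enrichment.csv")
  readr::write_csv(dplyr::left_join(enr, red, by = "tau"),
                   manifest$enrichment)

  arms <- clarity_ad_arms()
  econ <- stage("economics", build_cost_report(arms$conventional,
                                               arms$enriched, config$costs))
  manifest$cost_report <- file.path(config$out_dir, "table2.csv")
  readr::write_csv(econ$table, manifest$cost_report)

  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  manifest$manifest <- manifest_path
  results <- list(sim = sim, assignment = clus$assignment, char = char,
                  cv = cvrep, enrichment = enr, reduction = red,
                  economics = econ)
  out <- manifest
  attr(out, "results") <- results
  invisible(out)
}
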