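#' Cohort median row of per-patient classification metrics
#'
#' Columnwise sample median across patients (mean of the two central order
#' statistics for an even cohort), rounded to two decimals — the convention
#' used for the cohort summary rows of the report tables.
#'
#' @param reports Tibble with one row per patient and numeric metric columns
#'   (e.g. `sn`, `sp`, `accuracy`, `gmean`); non-numeric columns are dropped.
#' @param digits Decimal places for rounding (default 2).
#' @return One-row tibble of medians.
#' @export
cohort_medians <- function(reports, digits = 2) {
  med <- cohort_median(reports)
  dplyr::mutate(med, dplyr::across(dplyr::everything(), ~ round(.x, digits)))
}

#' Expected intervention counts from sensitivity and specificity
#'
#' Translates a model's sensitivity/specificity into the expected confusion
#' counts over a set of nights, nearest-integer rounded: how many
#' hypoglycemic nights would be caught (TP), missed (FN), and how many alarm
#' nights would be false (FP).
#'
#' @param sn,sp Sensitivity and specificity in percent.
#' @param n_pos,n_neg Numbers of hypoglycemic and non-hypoglycemic nights.
#' @return One-row tibble `tp`, `fn`, `fp`, `tn`.
#' @examples
#' expected_intervention_counts(79.90, 91.37, 20, 35)  # TP 16, FN 4, FP 3
#' @export
expected_intervention_counts <- function(sn, sp, n_pos, n_neg) {
  if (any(c(sn, sp) < 0) || any(c(sn, sp) > 100) || n_pos < 0 || n_neg < 0) {
    abort("Rates must lie in [0, 100] and counts be nonnegative.",
          class = "nhpred_validation_error")
  }
  tp <- round(sn * n_pos / 100)
  fp <- round((100 - sp) * n_neg / 100)
  tibble::tibble(tp = tp, fn = n_pos - tp, fp = fp, tn = n_neg - fp)
}

#' Accuracy implied by sensitivity, specificity and class counts
#'
#' The count-weighted mean `(sn * n_pos + sp * n_neg) / (n_pos + n_neg)`,
#' rounded to two decimals; useful as a consistency check on reported
#' accuracy columns.
#'
#' @inheritParams expected_intervention_counts
#' @return Accuracy in percent.
#' @examples
#' accuracy_from_rates(100, 99.73, 3, 11)  # 99.79
#' @export
accuracy_from_rates <- function(sn, sp, n_pos, n_neg) {
  if (n_pos + n_neg == 0) {
    abort("At least one instance is required.",
          class = "nhpred_validation_error")
  }
  round((sn * n_pos + sp * n_neg) / (n_pos + n_neg), 2)
}

#' Load a cohort of simulation configurations from a YAML file
#'
#' The file holds one entry per patient under a top-level `patients` key;
#' every field of [sim_config()] with a scalar value can be set (others keep
#' their defaults):
#'
#' ```yaml
#' patients:
#'   P01: { n_days: 40, seed: 11 }
#'   P02: { n_days: 40, seed: 12, basal_overdose: 1.6 }
#' ```
#'
#' @param path Path to the YAML file.
#' @return Named list of [sim_config()]s, usable as the `patients` argument
#'   of [run_pipeline()].
#' @export
load_sim_configs <- function(path) {
  spec <- yaml::read_yaml(path)
  if (is.null(spec$patients) || length(spec$patients) == 0) {
    abort("Config file must define at least one entry under `patients`.",
          class = "nhpred_config_error")
  }
  lapply(spec$patients, function(fields) do.call(sim_config, as.list(fields)))
}

#' Run the full pipeline for a synthetic cohort
#'
#' Chains every stage end-to-end: simulate each patient's raw streams, write
#' and re-read the CSV exports, preprocess to the 5-min grid, build labeled
#' night instances, run the exhaustive feature-group search under repeated
#' stratified cross-validation, and write deterministic report files. Given
#' the same configuration and seeds the output files are byte-identical
#' across runs.
#'
#' @param patients Named list of [sim_config()]s, one per patient id; or a
#'   path to a YAML cohort file (see [load_sim_configs()]); or an integer n
#'   to simulate n patients at default settings with seeds derived from
#'   `seed`.
#' @param out_dir Output directory.
#' @param cv A [cv_config()].
#' @param params [physio_params()].
#' @param groups Optional group-id subset for the search (see
#'   [exhaustive_search()]).
#' @param seed Base seed used when `patients` is an integer.
#' @return Invisibly, a list with `instances`, `summary`, `glucometrics`,
#'   `best_models` tibbles and the written file paths.
#' @export
run_pipeline <- function(patients = 2L, out_dir, cv = cv_config(repetitions = 5L),
                         params = physio_params(), groups = NULL, seed = 1L) {
  if (is.character(patients) && length(patients) == 1) {
    patients <- load_sim_configs(patients)
  }
  if (is.numeric(patients) && length(patients) == 1) {
    n <- as.integer(patients)
    patients <- setNames(
      lapply(seq_len(n), function(i) sim_config(seed = seed + 1000L * i)),
      sprintf("P%02d", seq_len(n))
    )
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  all_instances <- list()
  gluco_rows <- list()
  best_rows <- list()
  for (pid in names(patients)) {
    raw <- simulate_patient(patients[[pid]])
    raw_dir <- file.path(out_dir, "raw", pid)
    write_raw_exports(raw, raw_dir)
    raw2 <- read_raw_dataset(raw_dir)
    prep <- preprocess_patient(raw2)
    gluco_rows[[pid]] <- dplyr::bind_cols(tibble::tibble(patient_id = pid),
                                          summarize_trace(prep$trace))
    inst <- build_dataset(prep, patient_id = pid, params = params)
    all_instances[[pid]] <- inst
    search <- exhaustive_search(inst, cv = cv, groups = groups)
    top <- search$results[1, ]
    best_rows[[pid]] <- tibble::tibble(
      patient_id = pid, classifier = cv$classifier,
      mask = top$mask, n_features = top$n_features,
      sn = round(top$sn, 2), sp = round(top$sp, 2),
      accuracy = round(top$accuracy, 2), gmean = round(top$gmean, 2)
    )
  }
  instances <- dplyr::bind_rows(all_instances)
  summary <- summarize_instances(instances)
  glucometrics <- dplyr::bind_rows(gluco_rows)
  best_models <- dplyr::bind_rows(best_rows)

  inst_out <- dplyr::mutate(instances,
                            night_date = as.character(.data$night_date),
                            sleep_onset = fmt_timestamp(.data$sleep_onset))
  paths <- c(
    instances = file.path(out_dir, "instances.csv"),
    summary = file.path(out_dir, "instance_summary.csv"),
    glucometrics = file.path(out_dir, "glucometrics.csv"),
    best_models = file.path(out_dir, "best_models.csv"),
    catalog = file.path(out_dir, "feature_catalog.json")
  )
  readr::write_csv(inst_out, paths[["instances"]])
  readr::write_csv(summary, paths[["summary"]])
  readr::write_csv(dplyr::mutate(glucometrics,
                                 dplyr::across(dplyr::where(is.numeric),
                                               ~ round(.x, 2))),
                   paths[["glucometrics"]])
  readr::write_csv(best_models, paths[["best_models"]])
  jsonlite::write_json(feature_catalog(), paths[["catalog"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(instances = instances, summary = summary,
                 glucometrics = glucometrics, best_models = best_models,
                 paths = paths))
}
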