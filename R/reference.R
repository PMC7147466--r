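#' Reference cohort tables
#'
#' Published per-patient results from a ten-patient reference cohort of
#' adults with type 1 diabetes on multiple daily injections, monitored for
#' 12 weeks under free-living conditions. These tables are shipped as plain
#' CSV so in-report arithmetic (cohort medians, Gmean/accuracy identities,
#' expected-intervention counts) can be recomputed and checked without the
#' raw cohort data, which was never deposited.
#'
#' @return `reference_glucometrics()`: per-patient CGM glucometrics
#'   (mg/dL and percent columns as in [summarize_trace()]).
#'   `reference_instance_counts()`: per-patient night-instance totals and
#'   class counts. `reference_model_results()`: best-subset sensitivity,
#'   specificity, accuracy and Gmean per patient and classifier
#'   (`mlp` / `svm`), averaged over 100 repetitions.
#' @name reference_cohort
NULL

read_reference <- function(file) {
  path <- system.file("extdata", file, package = "nhpred", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname reference_cohort
#' @export
reference_glucometrics <- function() read_reference("reference_glucometrics.csv")

#' @rdname reference_cohort
#' @export
reference_instance_counts <- function() read_reference("reference_instance_counts.csv")

#' @rdname reference_cohort
#' @export
reference_model_results <- function() read_reference("reference_model_results.csv")
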