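#' Per-patient CGM summary statistics
#'
#' Computes the standard glucometrics panel over the non-missing readings of
#' a glucose trace: mean, SD, coefficient of variation, and time in the
#' consensus glycemic ranges. Range conventions: 70-180 is inclusive on both
#' ends, `<70` and `<54` are strict, `>180` and `>250` are strict, so
#' boundary readings fall in the lower category.
#'
#' @param trace A `glucose_trace` (see [resample_to_grid()]); any tibble
#'   with `glucose_mgdl` and `provenance` columns works.
#' @param include_imputed Count imputed readings as well as measured ones
#'   (default TRUE).
#' @return A one-row tibble: `mean_cgm`, `std_cgm`, `cv_pct`, `pct_70_180`,
#'   `pct_below_70`, `pct_below_54`, `pct_above_180`, `pct_above_250`
#'   (percentages of non-missing readings).
#' @export
summarize_trace <- function(trace, include_imputed = TRUE) {
  keep <- if (include_imputed) {
    trace$provenance != "missing"
  } else {
    trace$provenance == "measured"
  }
  g <- trace$glucose_mgdl[keep]
  g <- g[!is.na(g)]
  if (length(g) == 0) {
    abort("Cannot summarize a trace with no usable readings.",
          class = "nhpred_insufficient_data")
  }
  m <- mean(g)
  s <- if (length(g) > 1) sd(g) else 0
  pct <- function(cond) 100 * sum(cond) / length(g)
  tibble::tibble(
    mean_cgm = m,
    std_cgm = s,
    cv_pct = 100 * s / m,
    pct_70_180 = pct(g >= 70 & g <= 180),
    pct_below_70 = pct(g < 70),
    pct_below_54 = pct(g < 54),
    pct_above_180 = pct(g > 180),
    pct_above_250 = pct(g > 250)
  )
}

#' Columnwise cohort median of glucometrics rows
#'
#' Sample median of every numeric column across patients; for an even number
#' of patients the mean of the two central order statistics is used.
#'
#' @param rows Tibble of per-patient glucometrics rows (non-numeric columns,
#'   e.g. a patient id, are dropped).
#' @return A one-row tibble of columnwise medians.
#' @export
cohort_median <- function(rows) {
  if (nrow(rows) == 0) {
    abort("Cannot take the median of an empty cohort.",
          class = "nhpred_validation_error")
  }
  num <- rows[vapply(rows, is.numeric, logical(1))]
  dplyr::summarise(num, dplyr::across(dplyr::everything(),
                                      ~ median(.x, na.rm = TRUE)))
}
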