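#' The 29-feature catalog
#'
#' Ordered definitions of the 29 hand-crafted pre-sleep features, partitioned
#' into 11 named groups. Twenty-five features derive from the CGM signal,
#' one from insulin on board, one from carbohydrate on board and two from
#' physical activity (activity on board and calories burned), all computed
#' over the 6 h before sleep onset.
#'
#' @return A tibble with columns `index` (1-29), `name`, `group_id` (1-11),
#'   `group` and `units`.
#' @export
feature_catalog <- function() {
  tibble::tribble(
    ~index, ~name,              ~group_id, ~group,          ~units,
    1L,  "glucose_at_onset",    1L, "endpoint",      "mg/dL",
    2L,  "mean_last_30min",     1L, "endpoint",      "mg/dL",
    3L,  "mean_glucose",        2L, "central",       "mg/dL",
    4L,  "median_glucose",      2L, "central",       "mg/dL",
    5L,  "mean_last_60min",     2L, "central",       "mg/dL",
    6L,  "sd_glucose",          3L, "dispersion",    "mg/dL",
    7L,  "cv_glucose",          3L, "dispersion",    "%",
    8L,  "iqr_glucose",         3L, "dispersion",    "mg/dL",
    9L,  "min_glucose",         4L, "extremes",      "mg/dL",
    10L, "max_glucose",         4L, "extremes",      "mg/dL",
    11L, "range_glucose",       4L, "extremes",      "mg/dL",
    12L, "slope",               5L, "rates",         "mg/dL/h",
    13L, "mean_abs_rate",       5L, "rates",         "mg/dL/h",
    14L, "max_fall_rate",       5L, "rates",         "mg/dL/h",
    15L, "max_rise_rate",       5L, "rates",         "mg/dL/h",
    16L, "pct_below_70",        6L, "time_in_range", "%",
    17L, "pct_70_180",          6L, "time_in_range", "%",
    18L, "pct_above_180",       6L, "time_in_range", "%",
    19L, "pct_above_250",       6L, "time_in_range", "%",
    20L, "lbgi",                7L, "risk",          "risk units",
    21L, "hbgi",                7L, "risk",          "risk units",
    22L, "auc_below_70",        7L, "risk",          "mg/dL.min",
    23L, "hypo_episodes",       8L, "hypo_history",  "count",
    24L, "min_since_hypo",      8L, "hypo_history",  "min",
    25L, "any_hypo",            8L, "hypo_history",  "0/1",
    26L, "iob_onset",           9L, "iob",           "U",
    27L, "cob_onset",          10L, "cob",           "g",
    28L, "aob_onset",          11L, "activity",      "step-equivalents",
    29L, "calories_burned",    11L, "activity",      "kcal"
  )
}

#' Select one sleep onset per calendar night
#'
#' The retained onset is the start of the first sleep period of duration at
#' least 3 h beginning between 20:00 and 04:00; a night with no such period
#' yields no instance. A period starting after midnight belongs to the
#' previous calendar night.
#'
#' @param sleep Sleep-period tibble (`start`, `end`), non-overlapping.
#' @return Tibble `night_date`, `onset`.
#' @export
select_nights <- function(sleep) {
  if (nrow(sleep) == 0) {
    return(tibble::tibble(night_date = as.Date(character()),
                          onset = as.POSIXct(character(), tz = "UTC")))
  }
  dur_min <- as.numeric(sleep$end - sleep$start, units = "mins")
  clock_min <- as.numeric(sleep$start -
                            lubridate::floor_date(sleep$start, "day"),
                          units = "mins")
  ok <- dur_min >= 180 & (clock_min >= 20 * 60 | clock_min <= 4 * 60)
  cand <- sleep[ok, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(tibble::tibble(night_date = as.Date(character()),
                          onset = as.POSIXct(character(), tz = "UTC")))
  }
  out <- tibble::tibble(
    night_date = as.Date(cand$start - 12 * 3600, tz = "UTC"),
    onset = cand$start
  )
  out <- out[order(out$onset), , drop = FALSE]
  out[!duplicated(out$night_date), , drop = FALSE]
}

# Grid index of the point nearest to `when` (half-way rounds later).
grid_index <- function(grid, when) {
  floor(as.numeric(when - grid[1], units = "mins") / GRID_STEP_MIN + 0.5) + 1L
}

# Symmetrized blood-glucose risk transform underlying LBGI/HBGI.
risk_transform <- function(g) 1.509 * (log(g)^1.084 - 5.381)

#' Extract the 29 pre-sleep features for one night
#'
#' Features are computed over the half-open window `(onset - 360 min, onset]`
#' on the 5-min grid (the onset reading belongs to the feature side). The
#' window must have at least `coverage_min` non-missing glucose points.
#'
#' @param trace Imputed `glucose_trace`.
#' @param onset Sleep-onset timestamp (snapped to the nearest grid point).
#' @param iob,cob,aob Physiological effect series on the trace grid (see
#'   [iob_profile()], [cob_profile()], [aob_profile()]).
#' @param activity Gridded activity tibble from [align_activity()].
#' @param coverage_min Minimum non-missing fraction of the 72-point window
#'   (default 0.8).
#' @return Named numeric vector of length 29, in [feature_catalog()] order.
#' @export
extract_features <- function(trace, onset, iob, cob, aob, activity,
                             coverage_min = 0.8) {
  oi <- grid_index(trace$timestamp, onset)
  w <- seq(oi - 71L, oi)
  if (w[1] < 1 || oi > nrow(trace)) {
    abort("Pre-sleep window falls outside the trace.",
          class = "nhpred_coverage_error")
  }
  g_all <- trace$glucose_mgdl[w]
  miss <- trace$provenance[w] == "missing"
  if (mean(!miss) < coverage_min) {
    abort("Pre-sleep window coverage below threshold.",
          class = "nhpred_coverage_error")
  }
  ok <- !miss & !is.na(g_all)
  g <- g_all[ok]
  t_min <- (seq_along(w) - length(w)) * GRID_STEP_MIN  # minutes before onset
  tg <- t_min[ok]

  last_k <- function(minutes) {
    v <- g[tg > -minutes]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  rates <- if (length(g) > 1) diff(g) / (diff(tg) / 60) else numeric(0)
  fg <- risk_transform(g)
  pct <- function(cond) 100 * sum(cond) / length(g)

  deficit <- pmax(0, 70 - g)
  auc70 <- if (length(g) > 1) {
    sum((deficit[-1] + deficit[-length(deficit)]) / 2 * diff(tg))
  } else 0

  hypo_t <- tg[g < 70]
  episodes <- if (length(hypo_t) == 0) 0L else 1L + sum(diff(hypo_t) > 15)
  min_since <- if (length(hypo_t) == 0) 360 else min(360, -max(hypo_t))

  m <- mean(g)
  s <- if (length(g) > 1) sd(g) else 0
  slope <- if (length(g) > 1) {
    th <- tg / 60
    sum((th - mean(th)) * (g - m)) / sum((th - mean(th))^2)
  } else 0

  x <- c(
    glucose_at_onset = g[length(g)],
    mean_last_30min = last_k(30),
    mean_glucose = m,
    median_glucose = median(g),
    mean_last_60min = last_k(60),
    sd_glucose = s,
    cv_glucose = 100 * s / m,
    iqr_glucose = unname(quantile(g, 0.75) - quantile(g, 0.25)),
    min_glucose = min(g),
    max_glucose = max(g),
    range_glucose = max(g) - min(g),
    slope = slope,
    mean_abs_rate = if (length(rates) > 0) mean(abs(rates)) else 0,
    max_fall_rate = max(c(0, -rates)),
    max_rise_rate = max(c(0, rates)),
    pct_below_70 = pct(g < 70),
    pct_70_180 = pct(g >= 70 & g <= 180),
    pct_above_180 = pct(g > 180),
    pct_above_250 = pct(g > 250),
    lbgi = mean(10 * fg^2 * (fg < 0)),
    hbgi = mean(10 * fg^2 * (fg > 0)),
    auc_below_70 = auc70,
    hypo_episodes = as.numeric(episodes),
    min_since_hypo = min_since,
    any_hypo = as.numeric(length(hypo_t) > 0),
    iob_onset = iob[oi],
    cob_onset = cob[oi],
    aob_onset = aob[oi],
    calories_burned = sum(activity$calories[w])
  )
  if (any(!is.finite(x))) {
    abort("Non-finite feature value encountered.",
          class = "nhpred_validation_error")
  }
  x
}

#' Label one night for nocturnal hypoglycemia
#'
#' The label window is the half-open 6 h `[onset, onset + 360 min)`. The
#' night is Class 1 if any non-missing reading in the window is below
#' 70 mg/dL (3.9 mmol/L), else Class 0. By default imputed readings count
#' towards the label (they are bounded by their measured anchors).
#'
#' @inheritParams extract_features
#' @param include_imputed Whether imputed readings may trigger the label.
#' @return Integer 0/1.
#' @export
label_night <- function(trace, onset, coverage_min = 0.8,
                        include_imputed = TRUE) {
  oi <- grid_index(trace$timestamp, onset)
  w <- seq(oi, oi + 71L)
  if (oi < 1 || w[72] > nrow(trace)) {
    abort("Label window falls outside the trace.",
          class = "nhpred_coverage_error")
  }
  prov <- trace$provenance[w]
  usable <- if (include_imputed) prov != "missing" else prov == "measured"
  if (mean(prov != "missing") < coverage_min) {
    abort("Label window coverage below threshold.",
          class = "nhpred_coverage_error")
  }
  g <- trace$glucose_mgdl[w][usable]
  as.integer(any(g < 70, na.rm = TRUE))
}

window_coverage <- function(trace, idx) {
  idx <- idx[idx >= 1 & idx <= nrow(trace)]
  if (length(idx) == 0) return(0)
  sum(trace$provenance[idx] != "missing") / 72
}

#' Build the labeled night-instance dataset for one patient
#'
#' Converts preprocessed streams into one instance per retained night: the
#' 29 pre-sleep features plus the nocturnal-hypoglycemia label. Nights whose
#' pre-sleep or label window has less than `coverage_min` non-missing CGM
#' coverage are discarded with a message.
#'
#' @param prep Output of [preprocess_patient()].
#' @param patient_id Identifier stored with each instance.
#' @param params [physio_params()] for the on-board models.
#' @param coverage_min Minimum window coverage (default 0.8).
#' @param label_include_imputed Whether imputed readings may trigger labels.
#' @return Tibble with `patient_id`, `night_date`, `sleep_onset`, feature
#'   columns `f1`..`f29`, `label`, `coverage_pre`, `coverage_post`.
#' @export
build_dataset <- function(prep, patient_id = "P01", params = physio_params(),
                          coverage_min = 0.8, label_include_imputed = TRUE) {
  trace <- prep$trace
  grid <- trace$timestamp
  ev <- prep$events
  iob <- iob_profile(ev[ev$kind == "rapid_insulin", ], grid, params)
  cob <- cob_profile(ev[ev$kind == "meal", ], grid, params)
  aob <- aob_profile(prep$activity$steps, grid, params)
  nights <- select_nights(prep$sleep)
  rows <- vector("list", nrow(nights))
  n_discard <- 0L
  for (i in seq_len(nrow(nights))) {
    oi <- grid_index(grid, nights$onset[i])
    cov_pre <- window_coverage(trace, seq(oi - 71L, oi))
    cov_post <- window_coverage(trace, seq(oi, oi + 71L))
    if (oi - 71L < 1 || oi + 71L > nrow(trace) ||
        cov_pre < coverage_min || cov_post < coverage_min) {
      n_discard <- n_discard + 1L
      next
    }
    x <- extract_features(trace, nights$onset[i], iob, cob, aob,
                          prep$activity, coverage_min)
    y <- label_night(trace, nights$onset[i], coverage_min,
                     label_include_imputed)
    row <- tibble::tibble(patient_id = patient_id,
                          night_date = nights$night_date[i],
                          sleep_onset = nights$onset[i])
    feat <- tibble::as_tibble(as.list(setNames(x, paste0("f", 1:29))))
    rows[[i]] <- dplyr::bind_cols(row, feat,
                                  tibble::tibble(label = y,
                                                 coverage_pre = cov_pre,
                                                 coverage_post = cov_post))
  }
  if (n_discard > 0) {
    message(sprintf("%s: discarded %d night(s) with window coverage < %.2f.",
                    patient_id, n_discard, coverage_min))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    warn(sprintf("%s: no retained nights; dataset is empty.", patient_id))
  }
  out
}

#' Per-patient instance class counts
#'
#' Summarises an instance table into per-patient totals and class
#' distribution, with the percentage convention `"24 (23%)"` (count followed
#' by the integer-rounded share of all instances).
#'
#' @param instances Instance tibble from [build_dataset()] (any number of
#'   patients).
#' @return Tibble `patient_id`, `total`, `class1`, `class0`,
#'   `class1_display`, `class0_display`.
#' @export
summarize_instances <- function(instances) {
  dplyr::summarise(
    dplyr::group_by(instances, .data$patient_id),
    total = dplyr::n(),
    class1 = sum(.data$label == 1L),
    class0 = sum(.data$label == 0L),
    class1_display = format_count_pct(class1, total),
    class0_display = format_count_pct(class0, total),
    .groups = "drop"
  )
}

#' Count-with-percentage display used in instance summaries
#' @param n Count in the class.
#' @param total Total instance count.
#' @return String like `"24 (23%)"`.
#' @export
format_count_pct <- function(n, total) {
  sprintf("%d (%d%%)", n, round(100 * n / total))
}
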