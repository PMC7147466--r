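#' Resample irregular CGM records onto the 5-min analysis grid
#'
#' Builds a day-aligned grid of 5-min-spaced timestamps (288 points per day)
#' and assigns each grid point the nearest raw record within +/- 2.5 min.
#' When two records are equidistant from a grid point the earlier record
#' wins. Grid points with no record in reach are marked `missing`.
#'
#' @param records Tibble of raw CGM records (`timestamp`, `glucose_mgdl`),
#'   time-sorted.
#' @param grid_origin Start of the grid; defaults to midnight of the first
#'   record's day. The grid spans whole days covering all records.
#' @param n_days Number of days on the grid; defaults to the smallest whole
#'   number of days covering the records.
#' @return A `glucose_trace` tibble: `timestamp` (5-min grid),
#'   `glucose_mgdl` (NA where missing) and `provenance`
#'   (`"measured"` / `"imputed"` / `"missing"`).
#' @export
resample_to_grid <- function(records, grid_origin = NULL, n_days = NULL) {
  if (nrow(records) == 0) {
    out <- tibble::tibble(timestamp = as.POSIXct(character(), tz = "UTC"),
                          glucose_mgdl = numeric(), provenance = character())
    return(structure(out, class = c("glucose_trace", class(out))))
  }
  if (is.null(grid_origin)) {
    grid_origin <- lubridate::floor_date(min(records$timestamp), "day")
  }
  offset_min <- as.numeric(records$timestamp - grid_origin, units = "mins")
  if (any(offset_min < -2.5)) {
    abort("Records precede the grid origin.", class = "nhpred_validation_error")
  }
  if (is.null(n_days)) {
    n_days <- max(1L, ceiling((max(offset_min) + 1e-9) / 1440))
  }
  n <- as.integer(n_days) * 288L
  grid <- grid_origin + (seq_len(n) - 1L) * GRID_STEP_SEC

  # Nearest grid index for each record; half-way records go to the later point.
  idx <- floor(offset_min / GRID_STEP_MIN + 0.5) + 1L
  dist <- abs(offset_min - (idx - 1L) * GRID_STEP_MIN)
  keep <- idx >= 1L & idx <= n
  cand <- tibble::tibble(idx = idx[keep], dist = dist[keep],
                         ord = which(keep),
                         glucose = records$glucose_mgdl[keep])
  # per grid point: minimum distance, ties broken by earlier record
  cand <- cand[order(cand$idx, cand$dist, cand$ord), , drop = FALSE]
  cand <- cand[!duplicated(cand$idx), , drop = FALSE]

  glucose <- rep(NA_real_, n)
  glucose[cand$idx] <- cand$glucose
  out <- tibble::tibble(
    timestamp = grid,
    glucose_mgdl = glucose,
    provenance = ifelse(is.na(glucose), "missing", "measured")
  )
  structure(out, class = c("glucose_trace", class(out)))
}

#' Impute short CGM gaps by linear interpolation
#'
#' Every interior run of missing grid points whose gap — measured between its
#' two bounding measured points — is at most 120 min (i.e. at most 23 missing
#' 5-min points) is filled by linear interpolation between those bounds and
#' flagged `imputed`. Longer gaps and leading/trailing runs (which lack an
#' anchor) are left missing.
#'
#' @param trace A `glucose_trace` from [resample_to_grid()].
#' @param max_gap_min Largest imputable gap in minutes (default 120).
#' @return The trace with short gaps filled.
#' @export
impute_gaps <- function(trace, max_gap_min = 120) {
  miss <- trace$provenance == "missing"
  if (!any(miss) || nrow(trace) == 0) return(trace)
  max_run <- floor(max_gap_min / GRID_STEP_MIN) - 1L  # 120 min -> 23 points
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  meas_idx <- which(!miss)
  for (j in which(r$values)) {
    s <- starts[j]; e <- ends[j]
    if (s == 1L || e == nrow(trace)) next            # edge run: no anchor
    if (r$lengths[j] > max_run) next                 # gap exceeds the bound
    x0 <- s - 1L; x1 <- e + 1L
    fill <- approx(x = c(x0, x1),
                   y = trace$glucose_mgdl[c(x0, x1)],
                   xout = s:e)$y
    trace$glucose_mgdl[s:e] <- fill
    trace$provenance[s:e] <- "imputed"
  }
  trace
}

#' Aggregate per-minute activity onto the 5-min grid
#'
#' Steps and calories are summed within each 5-min bin `[t, t + 5 min)`;
#' heart rate is averaged. Bins without any activity row get 0 steps and
#' calories and a missing heart rate.
#'
#' @param activity Per-minute activity tibble (`timestamp`, `steps`,
#'   `heart_rate`, `calories`).
#' @param grid POSIXct vector of 5-min grid timestamps.
#' @return Tibble `timestamp`, `steps`, `heart_rate`, `calories` on the grid.
#' @export
align_activity <- function(activity, grid) {
  n <- length(grid)
  steps <- numeric(n); calories <- numeric(n)
  hr_sum <- numeric(n); hr_n <- numeric(n)
  if (nrow(activity) > 0) {
    bin <- floor(as.numeric(activity$timestamp - grid[1], units = "mins") /
                   GRID_STEP_MIN) + 1L
    keep <- bin >= 1L & bin <= n
    bin <- bin[keep]
    add_to <- function(vec, values) {
      agg <- tapply(values, bin, sum, na.rm = TRUE)
      vec[as.integer(names(agg))] <- vec[as.integer(names(agg))] + agg
      vec
    }
    if (length(bin) > 0) {
      steps <- add_to(steps, activity$steps[keep])
      calories <- add_to(calories, activity$calories[keep])
      hr <- activity$heart_rate[keep]
      hr_sum <- add_to(hr_sum, ifelse(is.na(hr), 0, hr))
      hr_n <- add_to(hr_n, as.numeric(!is.na(hr)))
    }
  }
  tibble::tibble(
    timestamp = grid,
    steps = steps,
    heart_rate = ifelse(hr_n > 0, hr_sum / hr_n, NA_real_),
    calories = calories
  )
}

#' Preprocess one patient's raw streams
#'
#' Runs the full data-preparation stage: resample CGM to the 5-min grid,
#' impute gaps of at most 120 min, and align the activity stream to the same
#' grid.
#'
#' @param raw A `raw_dataset` (from [simulate_patient()] or
#'   [read_raw_dataset()]).
#' @param grid_origin,n_days Passed to [resample_to_grid()].
#' @return A list with `trace` (imputed `glucose_trace`), `activity`
#'   (gridded activity), `events` and `sleep` (carried through).
#' @export
preprocess_patient <- function(raw, grid_origin = NULL, n_days = NULL) {
  trace <- impute_gaps(resample_to_grid(raw$cgm, grid_origin, n_days))
  list(
    trace = trace,
    activity = align_activity(raw$activity, trace$timestamp),
    events = raw$events,
    sleep = raw$sleep
  )
}
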