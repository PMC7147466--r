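#' Simulate free-living data streams for one synthetic T1D patient
#'
#' Generates the four raw streams the pipeline consumes — CGM interstitial
#' glucose at 15-min cadence, an event log of rapid/long insulin doses, meal
#' carbohydrate estimates and SMBG fingersticks, per-minute activity
#' (steps, heart rate, calories) and nightly sleep periods — for `n_days` of
#' free-living monitoring.
#'
#' Glucose follows a minimal linear-response model on a 5-min step: each step
#' adds the carbohydrate appearance of recent meals, subtracts the insulin
#' action of recent rapid boluses and the accumulated activity effect,
#' subtracts a nocturnal drift (`basal_overdose`) while asleep, relaxes
#' towards a basal level, and receives AR(1) noise. It is a device to plant
#' learnable pre-sleep structure (insulin on board and afternoon activity
#' predict nocturnal hypoglycemia), not a physiological simulator.
#'
#' @param config A [sim_config()].
#' @return A `raw_dataset` list with tibbles `cgm` (`timestamp`,
#'   `glucose_mgdl`), `events` (`timestamp`, `kind`, `value`), `activity`
#'   (`timestamp`, `steps`, `heart_rate`, `calories`) and `sleep` (`start`,
#'   `end`). The attribute `"truth"` holds per-night ground-truth
#'   hypoglycemia labels computed from the pre-dropout CGM samples.
#' @examples
#' raw <- simulate_patient(sim_config(n_days = 3, seed = 7))
#' nrow(raw$sleep)
#' @export
simulate_patient <- function(config = sim_config()) {
  validate_sim_config(config)
  local_seed(config$seed, {
    origin <- as.POSIXct("2019-01-01 00:00:00", tz = "UTC")
    n <- config$n_days * 288L
    grid <- origin + (seq_len(n) - 1L) * GRID_STEP_SEC
    day_start <- origin + (seq_len(config$n_days) - 1L) * 86400

    ## --- meals and rapid boluses ---------------------------------------
    meals <- purrr::pmap_dfr(config$meal_schedule, function(time, jitter_min,
                                                           ch_mean, ch_sd) {
      jit <- round(runif(config$n_days, -jitter_min, jitter_min))
      ch <- round(pmax(5, rnorm(config$n_days, ch_mean, ch_sd)), 1)
      tibble::tibble(
        timestamp = day_start + (clock_to_min(time) + jit) * 60,
        ch = ch
      )
    })
    meals <- dplyr::arrange(meals, .data$timestamp)
    dose_err <- rnorm(nrow(meals), 0, config$dose_noise_sd)
    boluses <- tibble::tibble(
      timestamp = meals$timestamp + 60,  # logged one minute after the meal
      units = round(pmax(0.5, meals$ch / 10 * config$insulin_ratio *
                           (1 + dose_err)), 1)
    )
    long_doses <- tibble::tibble(
      timestamp = day_start + (22 * 60) * 60 + 30,
      units = 20
    )

    ## --- activity -------------------------------------------------------
    minute_ts <- origin + (seq_len(config$n_days * 1440L) - 1L) * 60
    steps_min <- rpois(length(minute_ts), 0.8)
    minute_of_day <- (as.numeric(minute_ts - origin, units = "mins")) %% 1440
    steps_min[minute_of_day < 7 * 60 | minute_of_day >= 22 * 60] <- 0L
    for (j in seq_len(nrow(config$activity))) {
      slot <- config$activity[j, ]
      happens <- runif(config$n_days) < slot$prob
      dur <- round(pmax(10, rnorm(config$n_days, slot$duration_mean,
                                  slot$duration_sd)))
      w0 <- clock_to_min(slot$window_start)
      w1 <- clock_to_min(slot$window_end)
      start_min <- round(runif(config$n_days, w0, w1))
      for (d in which(happens)) {
        idx0 <- (d - 1L) * 1440L + start_min[d] + 1L
        idx <- idx0:min(idx0 + dur[d] - 1L, length(steps_min))
        steps_min[idx] <- steps_min[idx] + rpois(length(idx), slot$steps_per_min)
      }
    }
    heart_rate <- round(68 + 0.25 * steps_min + rnorm(length(minute_ts), 0, 3), 1)
    calories <- round(pmax(0, 1.15 + 0.0045 * steps_min +
                             rnorm(length(minute_ts), 0, 0.05)), 2)
    activity <- tibble::tibble(timestamp = minute_ts, steps = steps_min,
                               heart_rate = heart_rate, calories = calories)

    ## --- sleep periods --------------------------------------------------
    onset_min <- clock_to_min(config$sleep_onset$time) +
      round(runif(config$n_days, -config$sleep_onset$jitter_min,
                  config$sleep_onset$jitter_min))
    sleep_len <- round(pmax(240, rnorm(config$n_days,
                                       config$sleep_onset$duration_min,
                                       config$sleep_onset$duration_sd)))
    sleep <- tibble::tibble(
      start = day_start + onset_min * 60,
      end = day_start + (onset_min + sleep_len) * 60
    )

    ## --- glucose dynamics on the 5-min grid -----------------------------
    innov <- rnorm(n, 0, config$noise_sd)
    noise <- as.numeric(stats::filter(innov, config$ar_coef,
                                      method = "recursive"))
    events <- tibble::tibble(
      timestamp = c(meals$timestamp, boluses$timestamp, long_doses$timestamp),
      kind = rep(c("meal", "rapid_insulin", "long_insulin"),
                 c(nrow(meals), nrow(boluses), nrow(long_doses))),
      value = c(meals$ch, boluses$units, long_doses$units)
    )
    glucose <- simulate_glucose(grid, events, steps_min, minute_ts, sleep,
                                config, noise = noise)

    ## --- SMBG fingersticks ----------------------------------------------
    smbg_clock <- c("07:50", "12:50", "19:50")
    smbg <- purrr::map_dfr(smbg_clock, function(ct) {
      ts <- day_start + clock_to_min(ct) * 60 + 30
      gi <- pmin(pmax(round(as.numeric(ts - origin, units = "mins") / 5) + 1L, 1L), n)
      tibble::tibble(timestamp = ts,
                     value = round(pmin(600, pmax(
                       20, glucose[gi] + rnorm(length(ts), 0, 8)))))
    })
    events <- dplyr::arrange(
      dplyr::bind_rows(events, tibble::tibble(timestamp = smbg$timestamp,
                                              kind = "smbg",
                                              value = smbg$value)),
      .data$timestamp, .data$kind)

    ## --- CGM emission at 15-min cadence with dropout gaps ---------------
    cgm_idx <- seq(1L, n, by = 3L)
    cgm_full <- tibble::tibble(
      timestamp = grid[cgm_idx],
      glucose_mgdl = round(pmin(400, pmax(40, glucose[cgm_idx])), 1)
    )
    n_gaps <- rpois(config$n_days, config$sensor_dropout$rate_per_day)
    gap_day <- rep(seq_len(config$n_days), n_gaps)
    gap_start <- day_start[gap_day] + round(runif(sum(n_gaps), 0, 1439)) * 60
    gap_len <- round(rlnorm(sum(n_gaps), config$sensor_dropout$meanlog,
                            config$sensor_dropout$sdlog))
    drop <- rep(FALSE, nrow(cgm_full))
    for (g in seq_along(gap_start)) {
      drop <- drop | (cgm_full$timestamp >= gap_start[g] &
                        cgm_full$timestamp < gap_start[g] + gap_len[g] * 60)
    }
    cgm <- cgm_full[!drop, ]

    ## --- ground-truth night labels (pre-dropout samples) ----------------
    truth <- purrr::map_dfr(seq_len(nrow(sleep)), function(i) {
      w <- cgm_full$timestamp >= sleep$start[i] &
        cgm_full$timestamp < sleep$start[i] + 360 * 60
      tibble::tibble(onset = sleep$start[i],
                     nh_truth = as.integer(any(cgm_full$glucose_mgdl[w] < 70)))
    })

    out <- structure(
      list(cgm = cgm, events = events, activity = activity, sleep = sleep),
      class = "raw_dataset"
    )
    attr(out, "truth") <- truth
    out
  })
}

#' Glucose response of the synthetic generator
#'
#' Deterministic core of [simulate_patient()]: given an event log, per-minute
#' steps, sleep periods and a noise series, returns the (unclamped) glucose
#' trajectory on the 5-min grid. Exposed so counterfactuals can be computed
#' at equal noise — e.g. the effect of one extra bolus.
#'
#' @param grid POSIXct 5-min grid.
#' @param events Event tibble (`timestamp`, `kind`, `value`); only `meal` and
#'   `rapid_insulin` rows drive the dynamics.
#' @param steps_min Integer per-minute step counts aligned with `minute_ts`.
#' @param minute_ts POSIXct per-minute timestamps for `steps_min`.
#' @param sleep Sleep-period tibble (`start`, `end`).
#' @param config A [sim_config()].
#' @param noise Numeric noise series on the grid (default all zero).
#' @return Numeric glucose (mg/dL) at each grid point.
#' @export
simulate_glucose <- function(grid, events, steps_min, minute_ts, sleep,
                             config = sim_config(), noise = NULL) {
  n <- length(grid)
  if (is.null(noise)) noise <- numeric(n)
  dyn <- config$dynamics
  meals <- events[events$kind == "meal", ]
  doses <- events[events$kind == "rapid_insulin", ]
  ra <- appearance_series(grid, meals$timestamp, meals$value,
                          config$physio$tau_ch)
  ia <- appearance_series(grid, doses$timestamp, doses$value,
                          config$physio$tau_ins)
  bins <- floor(as.numeric(minute_ts - grid[1], units = "mins") / 5) + 1
  keep <- bins >= 1 & bins <= n
  steps5 <- numeric(n)
  if (any(keep)) {
    agg <- tapply(steps_min[keep], bins[keep], sum)
    steps5[as.integer(names(agg))] <- agg
  }
  aa <- as.numeric(stats::filter(steps5, exp(-GRID_STEP_MIN / config$physio$tau_act),
                                 method = "recursive"))
  night <- rep(0, n)
  for (i in seq_len(nrow(sleep))) {
    night[grid >= sleep$start[i] & grid < sleep$end[i]] <- 1
  }
  u <- dyn$reversion * dyn$basal_glucose + dyn$k_meal * ra - dyn$k_ins * ia -
    dyn$k_act * aa - config$basal_overdose * night + noise
  as.numeric(stats::filter(u, 1 - dyn$reversion, method = "recursive",
                           init = dyn$basal_glucose))
}

# Fraction of an impulse still "on board" after s minutes
# (two-compartment equal-time-constant response).
onboard_remaining <- function(s, tau) {
  ifelse(s < 0, 1, exp(-s / tau) * (1 + s / tau))
}

# Per-step appearance of past impulses on the grid: amount entering the
# system during (t_i - 5 min, t_i], summed over events.
appearance_series <- function(grid, times, amounts, tau) {
  out <- numeric(length(grid))
  if (length(times) == 0) return(out)
  for (j in seq_along(times)) {
    s1 <- as.numeric(grid - times[j], units = "mins")
    out <- out + amounts[j] * (onboard_remaining(s1 - GRID_STEP_MIN, tau) -
                                 onboard_remaining(s1, tau))
  }
  out
}

#' Write a raw dataset to the four stream CSV files
#'
#' Exports `cgm.csv` (`timestamp,glucose_mgdl`), `events.csv`
#' (`timestamp,kind,value`), `activity.csv`
#' (`timestamp,steps,heart_rate,calories`) and `sleep.csv` (`start,end`)
#' with ISO-8601 timestamps, the dialects consumed by [read_cgm_csv()] and
#' friends. The export round-trips losslessly through the readers.
#'
#' @param data A `raw_dataset` (see [simulate_patient()]).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the four file paths.
#' @export
write_raw_exports <- function(data, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create directory '%s'.", dir),
                   class = "nhpred_io_error")
  }
  paths <- file.path(dir, c("cgm.csv", "events.csv", "activity.csv", "sleep.csv"))
  readr::write_csv(dplyr::mutate(data$cgm, timestamp = fmt_timestamp(.data$timestamp)),
                   paths[1])
  readr::write_csv(dplyr::mutate(data$events, timestamp = fmt_timestamp(.data$timestamp)),
                   paths[2])
  readr::write_csv(dplyr::mutate(data$activity, timestamp = fmt_timestamp(.data$timestamp)),
                   paths[3])
  readr::write_csv(dplyr::mutate(data$sleep, start = fmt_timestamp(.data$start),
                                 end = fmt_timestamp(.data$end)),
                   paths[4])
  invisible(paths)
}

#' An empty raw dataset (headers only when exported)
#' @return A `raw_dataset` whose four streams have zero rows.
#' @export
empty_raw_dataset <- function() {
  structure(list(
    cgm = tibble::tibble(timestamp = as.POSIXct(character(), tz = "UTC"),
                         glucose_mgdl = numeric()),
    events = tibble::tibble(timestamp = as.POSIXct(character(), tz = "UTC"),
                            kind = character(), value = numeric()),
    activity = tibble::tibble(timestamp = as.POSIXct(character(), tz = "UTC"),
                              steps = integer(), heart_rate = numeric(),
                              calories = numeric()),
    sleep = tibble::tibble(start = as.POSIXct(character(), tz = "UTC"),
                           end = as.POSIXct(character(), tz = "UTC"))
  ), class = "raw_dataset")
}
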