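#' Insulin-on-board (IOB) profile
#'
#' Residual subcutaneous insulin from past rapid-acting boluses, evaluated on
#' the analysis grid. Each dose of `U` units contributes
#' `U * exp(-t/tau_ins) * (1 + t/tau_ins)` for elapsed time `t >= 0` (a
#' two-compartment impulse response with equal time constants); doses
#' superpose additively. Long-acting doses are excluded by construction: pass
#' only `rapid_insulin` events.
#'
#' @param doses Tibble of rapid-insulin events (`timestamp`, `value` in U),
#'   time-sorted.
#' @param grid POSIXct vector of grid timestamps.
#' @param params A [physio_params()].
#' @return Numeric IOB series (U) on the grid.
#' @export
iob_profile <- function(doses, grid, params = physio_params()) {
  onboard_series(doses, grid, params$tau_ins, "dose")
}

#' Carbohydrate-on-board (COB) profile
#'
#' Carbohydrate consumed but not yet appeared in plasma, with the same
#' impulse-response form as [iob_profile()] and time constant `tau_ch`. The
#' series is bounded above by the cumulative ingested carbohydrate.
#'
#' @param meals Tibble of meal events (`timestamp`, `value` in g CH),
#'   time-sorted.
#' @inheritParams iob_profile
#' @return Numeric COB series (g) on the grid.
#' @export
cob_profile <- function(meals, grid, params = physio_params()) {
  onboard_series(meals, grid, params$tau_ch, "meal carbohydrate")
}

onboard_series <- function(events, grid, tau, what) {
  out <- numeric(length(grid))
  if (is.null(events) || nrow(events) == 0) return(out)
  if (any(events$value < 0)) {
    abort(sprintf("Negative %s amounts are not allowed.", what),
          class = "nhpred_validation_error")
  }
  for (j in seq_len(nrow(events))) {
    s <- as.numeric(grid - events$timestamp[j], units = "mins")
    active <- s >= 0
    out[active] <- out[active] +
      events$value[j] * exp(-s[active] / tau) * (1 + s[active] / tau)
  }
  out
}

#' Activity-on-board (AOB) profile
#'
#' Accumulated effect of physical activity: a first-order leaky accumulation
#' of per-bin step counts, `AOB(t) = sum_{k <= t} steps(k) *
#' exp(-(t - k)/tau_act)`, so a bin's own steps count in full and decay
#' exponentially afterwards.
#'
#' @param steps Nonnegative step counts per 5-min grid bin.
#' @param grid POSIXct grid (used only for a length check).
#' @inheritParams iob_profile
#' @return Numeric AOB series (step-equivalents) on the grid.
#' @export
aob_profile <- function(steps, grid = NULL, params = physio_params()) {
  if (any(steps < 0)) {
    abort("Step counts must be nonnegative.", class = "nhpred_validation_error")
  }
  if (!is.null(grid) && length(grid) != length(steps)) {
    abort("`steps` and `grid` must have equal length.",
          class = "nhpred_validation_error")
  }
  as.numeric(stats::filter(steps, exp(-GRID_STEP_MIN / params$tau_act),
                           method = "recursive"))
}
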