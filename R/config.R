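#' Simulation configuration for a synthetic free-living patient
#'
#' Bundles every generative parameter of the synthetic type-1-diabetes data
#' generator: monitoring duration, meal/insulin schedule, physical activity,
#' sleep timing, CGM sensor dropout and glucose dynamics. Defaults describe a
#' 12-week (84-day) free-living monitoring period on multiple daily
#' injections, with nocturnal hypoglycemia on roughly one third of nights.
#'
#' @param n_days Integer number of monitored days (default 84, i.e. 12 weeks).
#' @param meal_schedule Data frame with one row per daily meal and columns
#'   `time` ("HH:MM" clock-time mean), `jitter_min` (uniform timing jitter,
#'   minutes), `ch_mean`, `ch_sd` (carbohydrate grams).
#' @param insulin_ratio Rapid-acting insulin dose in units per 10 g of
#'   carbohydrate (default 1).
#' @param dose_noise_sd Relative (fractional) dosing error of each rapid bolus.
#' @param basal_overdose Nonnegative nocturnal glucose drift, mg/dL per 5-min
#'   step, applied while asleep; the knob controlling nocturnal-hypoglycemia
#'   prevalence. The default is calibrated so that about one third of nights
#'   are labeled hypoglycemic.
#' @param activity Data frame with one row per daily activity slot and columns
#'   `window_start`, `window_end` ("HH:MM"), `duration_mean`, `duration_sd`
#'   (minutes), `steps_per_min`, `prob` (probability the session happens).
#' @param sleep_onset List with `time` ("HH:MM" mean bedtime), `jitter_min`,
#'   `duration_min` (mean sleep length, minutes) and `duration_sd`.
#' @param sensor_dropout List with `rate_per_day` (expected CGM gaps per day)
#'   and `meanlog`, `sdlog` of the log-normal gap-length distribution
#'   (minutes).
#' @param noise_sd Standard deviation (mg/dL) of the AR(1) innovation added to
#'   each 5-min glucose step.
#' @param ar_coef AR(1) coefficient of the glucose noise process, in [0, 1).
#' @param seed Integer seed; identical configurations with identical seeds
#'   produce byte-identical exports.
#' @param dynamics List of glucose-dynamics constants: `basal_glucose`
#'   (mg/dL), `reversion` (fraction of the gap to basal closed per 5-min
#'   step), `k_meal` (mg/dL per g of appearing carbohydrate), `k_ins` (mg/dL
#'   per U of acting insulin), `k_act` (mg/dL per unit of activity-on-board).
#' @param physio [physio_params()] used to shape meal/insulin/activity
#'   response curves inside the generator.
#'
#' @return A validated `sim_config` list.
#' @seealso [simulate_patient()]
#' @export
sim_config <- function(n_days = 84L,
                       meal_schedule = default_meal_schedule(),
                       insulin_ratio = 1.0,
                       dose_noise_sd = 0.25,
                       basal_overdose = 1.25,
                       activity = default_activity_schedule(),
                       sleep_onset = list(time = "23:20", jitter_min = 35,
                                          duration_min = 480, duration_sd = 30),
                       sensor_dropout = list(rate_per_day = 0.5,
                                             meanlog = log(40), sdlog = 0.6),
                       noise_sd = 1.2,
                       ar_coef = 0.8,
                       seed = 1L,
                       dynamics = list(basal_glucose = 145, reversion = 0.03,
                                       k_meal = 2.0, k_ins = 20, k_act = 5e-04),
                       physio = physio_params()) {
  cfg <- structure(
    list(n_days = as.integer(n_days), meal_schedule = tibble::as_tibble(meal_schedule),
         insulin_ratio = insulin_ratio, dose_noise_sd = dose_noise_sd,
         basal_overdose = basal_overdose, activity = tibble::as_tibble(activity),
         sleep_onset = sleep_onset, sensor_dropout = sensor_dropout,
         noise_sd = noise_sd, ar_coef = ar_coef, seed = as.integer(seed),
         dynamics = dynamics, physio = physio),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @export
default_meal_schedule <- function() {
  tibble::tibble(
    time = c("08:00", "13:30", "21:00"),
    jitter_min = c(30, 30, 40),
    ch_mean = c(45, 70, 60),
    ch_sd = c(10, 15, 15)
  )
}

#' @rdname sim_config
#' @export
default_activity_schedule <- function() {
  tibble::tibble(
    window_start = "18:30", window_end = "20:30",
    duration_mean = 40, duration_sd = 10,
    steps_per_min = 90, prob = 0.6
  )
}

validate_sim_config <- function(cfg) {
  chk_nonneg <- function(value, field) {
    if (!is.numeric(value) || length(value) == 0 || any(!is.finite(value)) ||
        any(value < 0)) {
      abort(sprintf("Invalid sim_config: `%s` must be finite and nonnegative.",
                    field),
            class = "nhpred_config_error")
    }
  }
  if (cfg$n_days < 1) {
    abort("Invalid sim_config: `n_days` must be >= 1.",
          class = "nhpred_config_error")
  }
  chk_nonneg(cfg$insulin_ratio, "insulin_ratio")
  chk_nonneg(cfg$dose_noise_sd, "dose_noise_sd")
  chk_nonneg(cfg$basal_overdose, "basal_overdose")
  chk_nonneg(cfg$noise_sd, "noise_sd")
  chk_nonneg(cfg$sensor_dropout$rate_per_day, "sensor_dropout$rate_per_day")
  chk_nonneg(cfg$sensor_dropout$sdlog, "sensor_dropout$sdlog")
  chk_nonneg(cfg$meal_schedule$jitter_min, "meal_schedule$jitter_min")
  chk_nonneg(cfg$meal_schedule$ch_mean, "meal_schedule$ch_mean")
  chk_nonneg(cfg$meal_schedule$ch_sd, "meal_schedule$ch_sd")
  if (!is.numeric(cfg$ar_coef) || cfg$ar_coef < 0 || cfg$ar_coef >= 1) {
    abort("Invalid sim_config: `ar_coef` must lie in [0, 1).",
          class = "nhpred_config_error")
  }
  invisible(cfg)
}

#' Physiological on-board model parameters
#'
#' Time constants (minutes) of the insulin-on-board (IOB),
#' carbohydrate-on-board (COB) and activity-on-board (AOB) effect curves.
#' IOB/COB use a two-compartment equal-time-constant impulse response,
#' `D * exp(-t/tau) * (1 + t/tau)`; AOB is a first-order leaky accumulator of
#' step counts with decay `exp(-dt/tau_act)`.
#'
#' @param tau_ins Insulin action time constant, minutes (default 75).
#' @param tau_ch Carbohydrate absorption time constant, minutes (default 40).
#' @param tau_act Activity effect time constant, minutes (default 120).
#' @return A `physio_params` list.
#' @export
physio_params <- function(tau_ins = 75, tau_ch = 40, tau_act = 120) {
  if (any(c(tau_ins, tau_ch, tau_act) <= 0)) {
    abort("All physiological time constants must be > 0.",
          class = "nhpred_config_error")
  }
  structure(list(tau_ins = tau_ins, tau_ch = tau_ch, tau_act = tau_act),
            class = "physio_params")
}

#' Cross-validation configuration
#'
#' @param k Number of folds (default 5). When a patient's minority class has
#'   fewer than `k` members the evaluator reduces `k` to that count.
#' @param repetitions Number of repeated cross-validation runs whose pooled
#'   confusion metrics are averaged (default 100).
#' @param base_seed Integer; repetition `r` uses seed `base_seed + r`.
#' @param classifier `"svm"` (RBF kernel, C = 1, balanced class weights) or
#'   `"mlp"` (single hidden layer of `hidden` logistic units).
#' @param hidden Hidden layer size for the MLP (default 8).
#' @param maxit Maximum MLP training epochs (default 500).
#' @return A `cv_config` list.
#' @export
cv_config <- function(k = 5L, repetitions = 100L, base_seed = 20201L,
                      classifier = c("svm", "mlp"), hidden = 8L, maxit = 500L) {
  classifier <- match.arg(classifier)
  if (k < 2) abort("`k` must be >= 2.", class = "nhpred_config_error")
  if (repetitions < 1) abort("`repetitions` must be >= 1.",
                             class = "nhpred_config_error")
  structure(list(k = as.integer(k), repetitions = as.integer(repetitions),
                 base_seed = as.integer(base_seed), classifier = classifier,
                 hidden = as.integer(hidden), maxit = as.integer(maxit)),
            class = "cv_config")
}
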