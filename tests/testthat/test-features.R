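test_that("the feature catalog has 29 features in 11 groups with the stated mix", {
  cat29 <- feature_catalog()
  expect_equal(nrow(cat29), 29)
  expect_equal(sort(unique(cat29$group_id)), 1:11)
  expect_equal(sum(table(cat29$group_id)), 29)
  expect_equal(sum(cat29$group == "iob"), 1)
  expect_equal(sum(cat29$group == "cob"), 1)
  expect_equal(sum(cat29$group == "activity"), 2)
  expect_equal(sum(!cat29$group %in% c("iob", "cob", "activity")), 25)
})

test_that("night selection applies the >=3h / 20:00-04:00 first-period rule", {
  none <- select_nights(tibble::tibble(start = as.POSIXct(character(), tz = "UTC"),
                                       end = as.POSIXct(character(), tz = "UTC")))
  expect_equal(nrow(none), 0)

  single <- tibble::tibble(
    start = as.POSIXct("2019-01-01 23:10:00", tz = "UTC"),
    end = as.POSIXct("2019-01-02 07:00:00", tz = "UTC"))
  expect_equal(select_nights(single)$onset, single$start)

  nap_then_sleep <- tibble::tibble(
    start = as.POSIXct(c("2019-01-01 22:00:00", "2019-01-01 23:30:00"),
                       tz = "UTC"),
    end = as.POSIXct(c("2019-01-01 22:40:00", "2019-01-02 07:00:00"),
                     tz = "UTC"))
  out <- select_nights(nap_then_sleep)
  expect_equal(nrow(out), 1)
  expect_equal(out$onset, nap_then_sleep$start[2])  # 40-min nap skipped

  # after-midnight onset belongs to the previous calendar night
  late <- tibble::tibble(
    start = as.POSIXct("2019-01-02 01:30:00", tz = "UTC"),
    end = as.POSIXct("2019-01-02 08:30:00", tz = "UTC"))
  expect_equal(select_nights(late)$night_date, as.Date("2019-01-01"))

  # daytime sleep yields no instance
  daytime <- tibble::tibble(
    start = as.POSIXct("2019-01-01 13:00:00", tz = "UTC"),
    end = as.POSIXct("2019-01-01 17:00:00", tz = "UTC"))
  expect_equal(nrow(select_nights(daytime)), 0)
})

constant_fixture <- function(value = 100, n = 288) {
  trace <- make_trace(rep(value, n))
  list(trace = trace,
       iob = rep(0, n), cob = rep(0, n), aob = rep(0, n),
       activity = make_activity_grid(n),
       onset = trace$timestamp[144])
}

test_that("a constant hypo-free window yields the documented feature vector", {
  fx <- constant_fixture()
  x <- extract_features(fx$trace, fx$onset, fx$iob, fx$cob, fx$aob,
                        fx$activity)
  expect_length(x, 29)
  expect_true(all(is.finite(x)))
  expect_equal(unname(x[c("glucose_at_onset", "mean_glucose", "min_glucose",
                          "max_glucose")]), rep(100, 4))
  expect_equal(unname(x[c("sd_glucose", "cv_glucose", "slope",
                          "mean_abs_rate", "max_fall_rate",
                          "max_rise_rate")]), rep(0, 6))
  expect_equal(unname(x[c("pct_below_70", "pct_70_180", "pct_above_180",
                          "pct_above_250")]), c(0, 100, 0, 0))
  expect_equal(unname(x[c("iob_onset", "cob_onset", "aob_onset")]), rep(0, 3))
  expect_equal(unname(x[c("hypo_episodes", "min_since_hypo", "any_hypo")]),
               c(0, 360, 0))
  expect_equal(names(x), feature_catalog()$name)
})

test_that("each feature matches an independent brute-force recomputation", {
  n <- 288
  trace <- random_trace(n, seed = 101, p_missing = 0.08)
  onset <- trace$timestamp[200]
  grid <- trace$timestamp
  doses <- tibble::tibble(timestamp = grid[c(50, 150)], value = c(4, 7))
  meals <- tibble::tibble(timestamp = grid[c(48, 148)], value = c(50, 70))
  steps <- withr::with_seed(55, rpois(n, 15))
  act <- make_activity_grid(n, steps = steps,
                            calories = withr::with_seed(56, runif(n, 5, 9)))
  iob <- iob_profile(doses, grid)
  cob <- cob_profile(meals, grid)
  aob <- aob_profile(steps, grid)
  x <- extract_features(trace, onset, iob, cob, aob, act)

  sel <- grid > onset - 360 * 60 & grid <= onset
  ok <- sel & trace$provenance != "missing"
  g <- trace$glucose_mgdl[ok]
  tmin <- as.numeric(grid[ok] - onset, units = "mins")

  expect_equal(unname(x["glucose_at_onset"]), g[length(g)])
  expect_equal(unname(x["mean_last_30min"]), mean(g[tmin > -30]))
  expect_equal(unname(x["mean_glucose"]), mean(g))
  expect_equal(unname(x["median_glucose"]), median(g))
  expect_equal(unname(x["mean_last_60min"]), mean(g[tmin > -60]))
  expect_equal(unname(x["sd_glucose"]), sd(g))
  expect_equal(unname(x["cv_glucose"]), 100 * sd(g) / mean(g))
  expect_equal(unname(x["iqr_glucose"]),
               unname(quantile(g, .75) - quantile(g, .25)))
  expect_equal(unname(x["min_glucose"]), min(g))
  expect_equal(unname(x["max_glucose"]), max(g))
  expect_equal(unname(x["range_glucose"]), diff(range(g)))
  fit <- lm(g ~ I(tmin / 60))
  expect_equal(unname(x["slope"]), unname(coef(fit)[2]), tolerance = 1e-9)
  rates <- diff(g) / (diff(tmin) / 60)
  expect_equal(unname(x["mean_abs_rate"]), mean(abs(rates)))
  expect_equal(unname(x["max_fall_rate"]), max(c(0, -rates)))
  expect_equal(unname(x["max_rise_rate"]), max(c(0, rates)))
  expect_equal(unname(x["pct_below_70"]), 100 * mean(g < 70))
  expect_equal(unname(x["pct_70_180"]), 100 * mean(g >= 70 & g <= 180))
  expect_equal(unname(x["pct_above_180"]), 100 * mean(g > 180))
  expect_equal(unname(x["pct_above_250"]), 100 * mean(g > 250))
  f <- 1.509 * (log(g)^1.084 - 5.381)
  expect_equal(unname(x["lbgi"]), mean(10 * f^2 * (f < 0)))
  expect_equal(unname(x["hbgi"]), mean(10 * f^2 * (f > 0)))
  d <- pmax(0, 70 - g)
  expect_equal(unname(x["auc_below_70"]),
               sum((d[-1] + d[-length(d)]) / 2 * diff(tmin)))
  hypo_t <- tmin[g < 70]
  eps <- if (length(hypo_t) == 0) 0 else 1 + sum(diff(hypo_t) > 15)
  expect_equal(unname(x["hypo_episodes"]), eps)
  expect_equal(unname(x["min_since_hypo"]),
               if (length(hypo_t) == 0) 360 else min(360, -max(hypo_t)))
  expect_equal(unname(x["any_hypo"]), as.numeric(length(hypo_t) > 0))
  oi <- which(grid == onset)
  s_d <- as.numeric(onset - doses$timestamp, units = "mins")
  expect_equal(unname(x["iob_onset"]),
               sum(doses$value * exp(-s_d / 75) * (1 + s_d / 75)))
  s_m <- as.numeric(onset - meals$timestamp, units = "mins")
  expect_equal(unname(x["cob_onset"]),
               sum(meals$value * exp(-s_m / 40) * (1 + s_m / 40)))
  expect_equal(unname(x["aob_onset"]),
               sum(steps[1:oi] * exp(-5 * (oi - (1:oi)) / 120)),
               tolerance = 1e-9)
  expect_equal(unname(x["calories_burned"]), sum(act$calories[sel]))
})

test_that("feature extraction is invariant to shifting all streams by a day", {
  n <- 288
  trace <- random_trace(n, seed = 77, p_missing = 0.05)
  onset <- trace$timestamp[180]
  doses <- tibble::tibble(timestamp = trace$timestamp[60], value = 5)
  steps <- withr::with_seed(78, rpois(n, 10))
  act <- make_activity_grid(n, steps = steps, calories = 2)
  x1 <- extract_features(trace, onset, iob_profile(doses, trace$timestamp),
                         rep(0, n), aob_profile(steps), act)
  shift <- 86400
  trace2 <- trace; trace2$timestamp <- trace$timestamp + shift
  doses2 <- doses; doses2$timestamp <- doses$timestamp + shift
  act2 <- act; act2$timestamp <- act$timestamp + shift
  x2 <- extract_features(trace2, onset + shift,
                         iob_profile(doses2, trace2$timestamp),
                         rep(0, n), aob_profile(steps), act2)
  expect_equal(x1, x2)
})

test_that("night labels follow the 70 mg/dL threshold on the 6-h window", {
  base <- make_trace(rep(120, 288))
  onset <- base$timestamp[100]
  expect_equal(label_night(base, onset), 0L)

  one_low <- base
  one_low$glucose_mgdl[100 + 36] <- 69   # onset + 3 h
  expect_equal(label_night(one_low, onset), 1L)

  outside <- base
  outside$glucose_mgdl[100 + 73] <- 69   # onset + 365 min, outside the window
  expect_equal(label_night(outside, onset), 0L)

  # half-open window: reading exactly at onset + 360 min does not count
  edge <- base
  edge$glucose_mgdl[100 + 72] <- 69
  expect_equal(label_night(edge, onset), 0L)

  # monotone: lowering an in-window reading never flips 1 -> 0
  lower <- one_low
  lower$glucose_mgdl[130] <- 55
  expect_equal(label_night(lower, onset), 1L)

  # coverage below threshold discards the night
  sparse <- base
  sparse$provenance[101:160] <- "missing"
  sparse$glucose_mgdl[101:160] <- NA
  expect_error(label_night(sparse, onset), class = "nhpred_coverage_error")
})

test_that("build_dataset retains covered nights and reports class counts", {
  raw <- simulate_patient(sim_config(n_days = 15, seed = 41))
  prep <- preprocess_patient(raw)
  inst <- suppressMessages(build_dataset(prep, "P99"))
  expect_true(all(paste0("f", 1:29) %in% names(inst)))
  expect_true(all(inst$label %in% 0:1))
  expect_true(all(inst$coverage_pre >= 0.8 & inst$coverage_post >= 0.8))
  expect_lte(nrow(inst), 15)
  smry <- summarize_instances(inst)
  expect_equal(smry$total, nrow(inst))
  expect_equal(smry$class1 + smry$class0, smry$total)
  # percentage convention and rounding-consistency of the display strings
  expect_equal(format_count_pct(24, 104), "24 (23%)")
  pcts <- as.integer(sub(".*\\((\\d+)%\\)", "\\1",
                         c(smry$class1_display, smry$class0_display)))
  expect_lte(abs(sum(pcts) - 100), 1)
})
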