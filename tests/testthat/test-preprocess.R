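test_that("a full day of 1-min records resamples to 288 complete grid points", {
  records <- tibble::tibble(
    timestamp = ORIGIN + (0:1439) * 60,
    glucose_mgdl = 100 + sin((0:1439) / 100) * 30
  )
  trace <- resample_to_grid(records)
  expect_equal(nrow(trace), 288)
  expect_true(all(trace$provenance == "measured"))
})

test_that("resampling is the identity (and idempotent) on gridded records", {
  g <- withr::with_seed(1, runif(288, 80, 200))
  records <- tibble::tibble(timestamp = make_grid(288), glucose_mgdl = g)
  trace <- resample_to_grid(records)
  expect_equal(trace$glucose_mgdl, g)
  expect_true(all(trace$provenance == "measured"))
  again <- resample_to_grid(trace[, c("timestamp", "glucose_mgdl")])
  expect_equal(again$glucose_mgdl, trace$glucose_mgdl)
})

test_that("records map to the nearest grid point", {
  records <- tibble::tibble(timestamp = ORIGIN + 3 * 60, glucose_mgdl = 123)
  trace <- resample_to_grid(records, grid_origin = ORIGIN)
  expect_equal(trace$glucose_mgdl[2], 123)  # 00:03 -> 00:05 point
  expect_true(is.na(trace$glucose_mgdl[1]))
  expect_equal(nrow(trace), 288)            # day-aligned grid
  # empty input is not an error
  none <- tibble::tibble(timestamp = as.POSIXct(character(), tz = "UTC"),
                         glucose_mgdl = numeric())
  expect_equal(nrow(resample_to_grid(none)), 0)
})

test_that("gap imputation is linear, bounded to 120 min, and anchor-convex", {
  # 10-min run between 100 and 130 -> 110, 120
  g <- c(100, NA, NA, 130, 120)
  out <- impute_gaps(make_trace(g))
  expect_equal(out$glucose_mgdl, c(100, 110, 120, 130, 120))
  expect_equal(out$provenance, c("measured", "imputed", "imputed", "measured",
                                 "measured"))
  # 125-min run (25 points) remains missing
  g2 <- c(100, rep(NA, 25), 130)
  out2 <- impute_gaps(make_trace(g2))
  expect_true(all(is.na(out2$glucose_mgdl[2:26])))
  # 120-min bound: 23 missing points (bounding distance exactly 120) imputed
  g3 <- c(100, rep(NA, 23), 130)
  out3 <- impute_gaps(make_trace(g3))
  expect_false(any(is.na(out3$glucose_mgdl)))
  # identity with no missing points
  g4 <- withr::with_seed(2, runif(50, 80, 200))
  expect_equal(impute_gaps(make_trace(g4)), make_trace(g4))
  # leading/trailing runs untouched
  g5 <- c(NA, NA, 100, NA, 120, NA)
  out5 <- impute_gaps(make_trace(g5))
  expect_true(all(is.na(out5$glucose_mgdl[c(1, 2, 6)])))
  expect_equal(out5$glucose_mgdl[4], 110)
})

test_that("imputation conserves measured points and matches a linear oracle", {
  for (seed in 1:10) {
    trace <- random_trace(200, seed, p_missing = 0.25)
    out <- impute_gaps(trace)
    expect_equal(sum(out$provenance == "measured"),
                 sum(trace$provenance == "measured"))
    # oracle: approx() over measured points, restricted to short interior runs
    meas <- which(trace$provenance == "measured")
    imp <- which(out$provenance == "imputed")
    if (length(imp) > 0) {
      oracle <- approx(meas, trace$glucose_mgdl[meas], xout = imp)$y
      expect_equal(out$glucose_mgdl[imp], oracle, tolerance = 1e-12)
      # convex hull of the two anchors
      for (i in imp) {
        lo <- max(meas[meas < i]); hi <- min(meas[meas > i])
        anchors <- trace$glucose_mgdl[c(lo, hi)]
        expect_true(out$glucose_mgdl[i] >= min(anchors) - 1e-12 &&
                      out$glucose_mgdl[i] <= max(anchors) + 1e-12)
      }
    }
    # no imputed run longer than 23 points
    r <- rle(out$provenance == "imputed")
    expect_true(all(r$lengths[r$values] <= 23))
  }
})

test_that("activity aligns to 5-min bins by sum (steps, calories) and mean (HR)", {
  grid <- make_grid(12)
  act <- tibble::tibble(
    timestamp = ORIGIN + (0:4) * 60,  # five minutes inside bin 1
    steps = rep(20L, 5), heart_rate = c(80, 82, NA, 84, 86),
    calories = rep(1.5, 5)
  )
  out <- align_activity(act, grid)
  expect_equal(out$steps[1], 100)
  expect_equal(out$calories[1], 7.5)
  expect_equal(out$heart_rate[1], mean(c(80, 82, 84, 86)))
  expect_equal(out$steps[2:12], rep(0, 11))
  expect_true(all(is.na(out$heart_rate[2:12])))
  # empty activity -> all-zero steps grid
  empty <- align_activity(make_activity_grid(0)[0, ], grid)
  expect_equal(empty$steps, rep(0, 12))
})

test_that("activity binning matches brute-force re-aggregation", {
  grid <- make_grid(50)
  act <- withr::with_seed(9, tibble::tibble(
    timestamp = ORIGIN + sort(sample(0:(50 * 5 - 1), 150, replace = FALSE)) * 60,
    steps = rpois(150, 10),
    heart_rate = ifelse(runif(150) < 0.2, NA, rnorm(150, 75, 8)),
    calories = runif(150, 1, 3)
  ))
  out <- align_activity(act, grid)
  for (k in seq_len(50)) {
    inbin <- act$timestamp >= grid[k] & act$timestamp < grid[k] + 300
    expect_equal(out$steps[k], sum(act$steps[inbin]))
    expect_equal(out$calories[k], sum(act$calories[inbin]), tolerance = 1e-12)
    hr <- act$heart_rate[inbin]
    if (any(!is.na(hr))) {
      expect_equal(out$heart_rate[k], mean(hr, na.rm = TRUE), tolerance = 1e-12)
    } else {
      expect_true(is.na(out$heart_rate[k]))
    }
  }
})
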