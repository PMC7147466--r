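# Shared fixture builders for the test suite.

ORIGIN <- as.POSIXct("2019-01-01 00:00:00", tz = "UTC")

make_grid <- function(n, origin = ORIGIN) origin + (seq_len(n) - 1L) * 300L

# A glucose trace directly on the 5-min grid.
make_trace <- function(glucose, origin = ORIGIN,
                       provenance = ifelse(is.na(glucose), "missing", "measured")) {
  tibble::tibble(
    timestamp = make_grid(length(glucose), origin),
    glucose_mgdl = glucose,
    provenance = provenance
  )
}

# Gridded activity with given per-bin calories/steps.
make_activity_grid <- function(n, steps = 0, calories = 0, origin = ORIGIN) {
  tibble::tibble(timestamp = make_grid(n, origin),
                 steps = rep_len(steps, n),
                 heart_rate = NA_real_,
                 calories = rep_len(calories, n))
}

empty_events <- function() {
  tibble::tibble(timestamp = as.POSIXct(character(), tz = "UTC"),
                 kind = character(), value = numeric())
}

# Random-walk trace with optional missing runs; used by property tests.
random_trace <- function(n, seed, p_missing = 0.1) {
  withr::with_seed(seed, {
    g <- 140 + cumsum(rnorm(n, 0, 4))
    g <- pmin(400, pmax(40, g))
    miss <- runif(n) < p_missing
    g[miss] <- NA
    make_trace(g)
  })
}
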