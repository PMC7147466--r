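#' Read raw stream CSV files
#'
#' Readers for the four vendor-neutral stream dialects: CGM
#' (`timestamp,glucose_mgdl`), event log (`timestamp,kind,value`), per-minute
#' activity (`timestamp,steps,heart_rate,calories`) and sleep periods
#' (`start,end`). Timestamps are timezone-naive ISO-8601 local times; glucose
#' is stored in mg/dL throughout.
#'
#' Malformed rows (unparseable timestamps or values, out-of-range values,
#' unknown event kinds) are skipped with a message; the number of skipped
#' rows is attached as attribute `"skipped"`. Duplicate timestamps are
#' deduplicated keeping the first occurrence, with a warning.
#'
#' @param path Path to the CSV file.
#' @return `read_cgm_csv()`: a tibble `timestamp`, `glucose_mgdl`, sorted by
#'   time. `read_events_csv()`: a tibble `timestamp`, `kind`, `value` with
#'   `kind` one of `rapid_insulin`, `long_insulin`, `meal`, `smbg`.
#'   `read_activity_csv()`: a per-minute tibble `timestamp`, `steps`,
#'   `heart_rate`, `calories`. `read_sleep_csv()`: a tibble `start`, `end`
#'   of validated non-overlapping sleep periods.
#' @name raw_readers
NULL

read_stream_csv <- function(path, required_cols) {
  if (!file.exists(path)) {
    abort(sprintf("File '%s' does not exist.", path), class = "nhpred_io_error")
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  missing_cols <- setdiff(required_cols, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("File '%s' is missing required column(s): %s.", path,
                  paste(missing_cols, collapse = ", ")),
          class = "nhpred_format_error")
  }
  df
}

# Drop rows with any NA in `cols`, message the 1-based data line numbers.
drop_malformed <- function(df, cols, path) {
  bad <- rep(FALSE, nrow(df))
  for (cl in cols) bad <- bad | is.na(df[[cl]])
  if (any(bad)) {
    message(sprintf("%s: skipped %d malformed row(s) at line(s) %s.",
                    basename(path), sum(bad),
                    paste(which(bad) + 1L, collapse = ", ")))
  }
  out <- df[!bad, , drop = FALSE]
  attr(out, "skipped") <- sum(bad)
  out
}

dedupe_sorted <- function(df, time_col, path) {
  ord <- order(df[[time_col]])
  df <- df[ord, , drop = FALSE]
  dup <- duplicated(df[[time_col]])
  if (any(dup)) {
    warn(sprintf("%s: %d duplicate timestamp(s) removed (kept first).",
                 basename(path), sum(dup)))
    skipped <- attr(df, "skipped")
    df <- df[!dup, , drop = FALSE]
    attr(df, "skipped") <- skipped
  }
  df
}

#' @rdname raw_readers
#' @export
read_cgm_csv <- function(path) {
  raw <- read_stream_csv(path, c("timestamp", "glucose_mgdl"))
  df <- tibble::tibble(timestamp = parse_timestamp(raw$timestamp),
                       glucose_mgdl = suppressWarnings(as.numeric(raw$glucose_mgdl)))
  df <- drop_malformed(df, c("timestamp", "glucose_mgdl"), path)
  df <- dedupe_sorted(df, "timestamp", path)
  df
}

#' @rdname raw_readers
#' @export
read_events_csv <- function(path) {
  raw <- read_stream_csv(path, c("timestamp", "kind", "value"))
  kinds <- c("rapid_insulin", "long_insulin", "meal", "smbg")
  df <- tibble::tibble(timestamp = parse_timestamp(raw$timestamp),
                       kind = ifelse(raw$kind %in% kinds, raw$kind, NA_character_),
                       value = suppressWarnings(as.numeric(raw$value)))
  ok_value <- !is.na(df$value) & !is.na(df$kind) &
    ((df$kind == "smbg" & df$value >= 20 & df$value <= 600) |
       (df$kind != "smbg" & df$value > 0))
  df$value[!ok_value] <- NA_real_
  df <- drop_malformed(df, c("timestamp", "kind", "value"), path)
  skipped <- attr(df, "skipped")
  ord <- order(df$timestamp, df$kind)
  df <- df[ord, , drop = FALSE]
  attr(df, "skipped") <- skipped
  df
}

#' @rdname raw_readers
#' @export
read_activity_csv <- function(path) {
  raw <- read_stream_csv(path, c("timestamp", "steps", "heart_rate", "calories"))
  df <- tibble::tibble(timestamp = parse_timestamp(raw$timestamp),
                       steps = suppressWarnings(as.integer(raw$steps)),
                       heart_rate = suppressWarnings(as.numeric(raw$heart_rate)),
                       calories = suppressWarnings(as.numeric(raw$calories)))
  df$steps[!is.na(df$steps) & df$steps < 0] <- NA_integer_
  df$calories[!is.na(df$calories) & df$calories < 0] <- NA_real_
  # heart_rate may be missing; only timestamp/steps/calories disqualify a row
  df <- drop_malformed(df, c("timestamp", "steps", "calories"), path)
  df <- dedupe_sorted(df, "timestamp", path)
  df
}

#' @rdname raw_readers
#' @export
read_sleep_csv <- function(path) {
  raw <- read_stream_csv(path, c("start", "end"))
  df <- tibble::tibble(start = parse_timestamp(raw$start),
                       end = parse_timestamp(raw$end))
  df <- drop_malformed(df, c("start", "end"), path)
  bad_dur <- df$end <= df$start
  if (any(bad_dur)) {
    abort(sprintf("%s: sleep period(s) with end <= start at row(s) %s.",
                  basename(path), paste(which(bad_dur), collapse = ", ")),
          class = "nhpred_format_error")
  }
  skipped <- attr(df, "skipped")
  df <- df[order(df$start), , drop = FALSE]
  if (nrow(df) > 1) {
    overlap <- which(df$start[-1] < df$end[-nrow(df)])
    if (length(overlap) > 0) {
      abort(sprintf("%s: overlapping sleep periods at rows %d and %d.",
                    basename(path), overlap[1], overlap[1] + 1L),
            class = "nhpred_validation_error")
    }
  }
  attr(df, "skipped") <- skipped
  df
}

#' Read all four streams of one patient directory
#'
#' @param dir Directory containing `cgm.csv`, `events.csv`, `activity.csv`
#'   and `sleep.csv`.
#' @return A `raw_dataset` list (see [simulate_patient()]).
#' @export
read_raw_dataset <- function(dir) {
  structure(list(
    cgm = read_cgm_csv(file.path(dir, "cgm.csv")),
    events = read_events_csv(file.path(dir, "events.csv")),
    activity = read_activity_csv(file.path(dir, "activity.csv")),
    sleep = read_sleep_csv(file.path(dir, "sleep.csv"))
  ), class = "raw_dataset")
}
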