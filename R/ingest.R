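# Event ingestion and binning into 16:00-anchored daily count vectors.
#
# Only event START times are used; durations are discarded.  An event at
# local time T belongs to the day window [16:00 d, 16:00 d+1) that contains
# it, and to bin floor(minutes_since_window_start(T) / bin_minutes).

#' Read smartphone event logs
#'
#' Reads a delimited text file (comma or tab, autodetected from the header
#' line) of timestamped events, one row per event.  The default column
#' mapping matches deposited screen-event datasets: a user identifier and a
#' Unix timestamp in seconds.  Rows whose timestamp cannot be parsed as a
#' number are skipped; their count is reported in the `"skipped"` attribute
#' and via a warning.
#'
#' @param path Path to the file.
#' @param user_col,time_col,type_col Column names for the user identifier,
#'   Unix timestamp, and (optionally) event type.  `type_col = NULL` (the
#'   default) ignores event types.
#' @param delim Field delimiter; `NULL` autodetects `","` vs `"\t"`.
#' @return A tibble with columns `user_id` (character), `timestamp` (numeric
#'   Unix seconds) and, when requested, `event_type`, sorted by user and
#'   time.  Attribute `"skipped"` holds the number of rejected rows.
#' @export
read_events <- function(path, user_col = "user_id", time_col = "timestamp",
                        type_col = NULL, delim = NULL) {
  stopifnot(file.exists(path))
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  if (nrow(raw) == 0L) {
    warning("no event rows in ", path)
    out <- tibble::tibble(user_id = character(), timestamp = numeric())
    attr(out, "skipped") <- 0L
    return(out)
  }
  needed <- c(user_col, time_col, type_col)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  ts <- suppressWarnings(as.numeric(raw[[time_col]]))
  skipped <- sum(is.na(ts))
  if (skipped > 0L) {
    warning(skipped, " row(s) with unparseable timestamps skipped")
  }
  out <- tibble::tibble(
    user_id = as.character(raw[[user_col]]),
    timestamp = ts
  )
  if (!is.null(type_col)) out$event_type <- as.character(raw[[type_col]])
  out <- dplyr::arrange(out[!is.na(ts), , drop = FALSE],
                        .data$user_id, .data$timestamp)
  attr(out, "skipped") <- skipped
  out
}

# Map Unix timestamps to (window day, bin index) in local civil time.
event_day_bin <- function(timestamp, window_start_hour = 16,
                          bin_minutes = 15, tz = "UTC") {
  tp <- as.POSIXct(timestamp, origin = "1970-01-01", tz = tz)
  shifted <- as.POSIXlt(tp - window_start_hour * 3600, tz = tz)
  secs <- shifted$hour * 3600 + shifted$min * 60 + shifted$sec
  list(day = as.Date(shifted), bin = as.integer(secs %/% (bin_minutes * 60)))
}

#' Construct a binned-counts object
#'
#' Low-level constructor for the per-user day-by-bin event count matrix.
#' Most users will call [bin_events()] instead.
#'
#' @param user_id User identifier.
#' @param day_labels `Date` vector: the calendar date on which each window
#'   opens at `window_start_hour`.
#' @param counts Integer matrix, `length(day_labels)` rows by
#'   `24 * 60 / bin_minutes` columns, of non-negative event counts.
#' @param bin_minutes Bin width in minutes (default 15, giving 96 bins/day).
#' @param window_start_hour Hour at which day windows open (default 16).
#' @param tz Timezone used for binning.
#' @return An object of class `binned_counts`.
#' @export
binned_counts <- function(user_id, day_labels, counts, bin_minutes = 15,
                          window_start_hour = 16, tz = "UTC") {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  n <- as.integer(24 * 60 / bin_minutes)
  stopifnot(
    24 * 60 %% bin_minutes == 0,
    ncol(counts) == n,
    nrow(counts) == length(day_labels),
    all(counts >= 0)
  )
  day_labels <- as.Date(day_labels)
  dimnames(counts) <- list(format(day_labels, "%Y-%m-%d"),
                           sprintf("bin_%03d", seq_len(n) - 1L))
  structure(
    list(user_id = as.character(user_id), day_labels = day_labels,
         counts = counts, n = n, bin_minutes = bin_minutes,
         window_start_hour = window_start_hour, tz = tz),
    class = "binned_counts"
  )
}

#' Bin one user's events into daily count vectors
#'
#' Divides time into 24-hour windows opening at 16:00 local time (so that a
#' typical night lies mid-window) and counts the events starting in each
#' 15-minute bin.  Windows are half-open `[16:00 d, 16:00 d+1)`; all windows
#' between the user's first and last event are kept, including all-zero days.
#'
#' @param events Tibble with columns `user_id` and `timestamp` (Unix
#'   seconds), for a single user; see [bin_events_by_user()] for many.
#' @param window_start_hour Hour of day at which windows open.
#' @param bin_minutes Bin width in minutes; must divide `24 * 60`.
#' @param tz Timezone in which civil local time is computed.
#' @return A [binned_counts()] object.
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   user_id = "u1",
#'   timestamp = as.numeric(as.POSIXct("2013-11-04 23:07:00", tz = "UTC"))
#' )
#' bc <- bin_events(ev)
#' which(bc$counts[1, ] > 0) - 1L # bin 28
bin_events <- function(events, window_start_hour = 16, bin_minutes = 15,
                       tz = "UTC") {
  stopifnot(nrow(events) > 0L, 24 * 60 %% bin_minutes == 0)
  uid <- unique(events$user_id)
  if (length(uid) != 1L) {
    stop("bin_events() expects a single user; use bin_events_by_user()")
  }
  db <- event_day_bin(events$timestamp, window_start_hour, bin_minutes, tz)
  days <- seq(min(db$day), max(db$day), by = "day")
  n <- as.integer(24 * 60 / bin_minutes)
  counts <- matrix(0L, nrow = length(days), ncol = n)
  idx_day <- match(db$day, days)
  for (k in seq_along(idx_day)) {
    counts[idx_day[k], db$bin[k] + 1L] <- counts[idx_day[k], db$bin[k] + 1L] + 1L
  }
  binned_counts(uid, days, counts, bin_minutes, window_start_hour, tz)
}

#' Bin events for every user in a log
#'
#' @inheritParams bin_events
#' @param events Tibble of events for any number of users.
#' @return A named list of [binned_counts()] objects, one per user.
#' @export
bin_events_by_user <- function(events, window_start_hour = 16,
                               bin_minutes = 15, tz = "UTC") {
  split(events, events$user_id) |>
    purrr::map(bin_events, window_start_hour = window_start_hour,
               bin_minutes = bin_minutes, tz = tz)
}

#' @export
print.binned_counts <- function(x, ...) {
  cat("<binned_counts> user", x$user_id, "-", nrow(x$counts), "days x",
      x$n, "bins of", x$bin_minutes, "min, windows from",
      format(x$day_labels[1]), sprintf("%02d:00", x$window_start_hour),
      paste0("(", sum(x$counts), " events)"), "\n")
  invisible(x)
}

#' @export
as.matrix.binned_counts <- function(x, ...) x$counts

#' @export
dim.binned_counts <- function(x) dim(x$counts)

#' Tidy a binned-counts object into long form
#'
#' @param x A [binned_counts()] object.
#' @param ... Unused.
#' @return A tibble with columns `user_id`, `day`, `bin`, `count`.
#' @export
tidy.binned_counts <- function(x, ...) {
  tibble::tibble(
    user_id = x$user_id,
    day = rep(x$day_labels, each = x$n),
    bin = rep(seq_len(x$n) - 1L, times = nrow(x$counts)),
    count = as.integer(t(x$counts))
  )
}

#' Serialize binned counts to CSV or JSON
#'
#' CSV layout: one row per day (first column `day`, ISO-8601), then columns
#' `bin_000` .. `bin_095`.
#'
#' @param x A [binned_counts()] object.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_binned_counts <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- tibble::as_tibble(x$counts)
    df <- dplyr::bind_cols(tibble::tibble(day = format(x$day_labels)), df)
    readr::write_csv(df, path)
  } else {
    jsonlite::write_json(
      list(user_id = x$user_id, day_labels = format(x$day_labels),
           bin_minutes = x$bin_minutes,
           window_start_hour = x$window_start_hour, tz = x$tz,
           counts = unname(apply(x$counts, 1, as.integer, simplify = FALSE))),
      path, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read binned counts written by [write_binned_counts()]
#'
#' @param path File path (CSV or JSON, detected from the extension).
#' @param user_id User identifier to attach when reading CSV.
#' @inheritParams bin_events
#' @return A [binned_counts()] object.
#' @export
read_binned_counts <- function(path, user_id = "user", bin_minutes = 15,
                               window_start_hour = 16, tz = "UTC") {
  if (grepl("\\.json$", path)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    cm <- obj$counts
    if (is.list(cm)) cm <- do.call(rbind, cm)
    return(binned_counts(obj$user_id, as.Date(obj$day_labels), cm,
                         obj$bin_minutes, obj$window_start_hour, obj$tz))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  binned_counts(user_id, as.Date(df$day),
                as.matrix(df[, -1, drop = FALSE]),
                bin_minutes, window_start_hour, tz)
}

#' Filter users by minimum daily event volume
#'
#' Retains users with enough phone interaction for switchpoint inference.
#' Under the default `rule = "mean"`, a user is kept when their mean number
#' of events per day window over their span (or `date_range`) is at least
#' `min_per_day`; `rule = "every"` requires every window to reach the
#' minimum.
#'
#' @param events Events tibble (`user_id`, `timestamp`), any number of users.
#' @param min_per_day Minimum events per day (boundary inclusive).
#' @param rule `"mean"` (default) or `"every"`.
#' @param date_range Optional `Date` vector of length 2 restricting the
#'   windows considered (inclusive window-start dates).
#' @inheritParams bin_events
#' @return The events tibble restricted to retained users.
#' @export
filter_users_min_daily_events <- function(events, min_per_day = 10,
                                          rule = c("mean", "every"),
                                          date_range = NULL,
                                          window_start_hour = 16,
                                          bin_minutes = 15, tz = "UTC") {
  rule <- match.arg(rule)
  if (nrow(events) == 0L) return(events)
  db <- event_day_bin(events$timestamp, window_start_hour, bin_minutes, tz)
  df <- tibble::tibble(user_id = events$user_id, day = db$day)
  if (!is.null(date_range)) {
    df <- dplyr::filter(df, .data$day >= date_range[1],
                        .data$day <= date_range[2])
  }
  keep <- df |>
    dplyr::group_by(.data$user_id) |>
    dplyr::summarise(
      n_events = dplyr::n(),
      span_days = as.numeric(max(.data$day) - min(.data$day)) + 1,
      min_daily = min(table(factor(.data$day,
                                   levels = as.character(seq(min(.data$day),
                                                             max(.data$day),
                                                             by = "day"))))),
      .groups = "drop"
    ) |>
    dplyr::filter(if (rule == "mean") .data$n_events / .data$span_days >=
                    min_per_day else .data$min_daily >= min_per_day)
  dplyr::filter(events, .data$user_id %in% keep$user_id)
}

#' Read sleep-tracker ground truth logs
#'
#' Expects delimited text at (up to) one-minute cadence with a user id, a
#' Unix timestamp, and an asleep/awake state coded as `sleep`/`awake`,
#' `asleep`/`awake`, or `1`/`0`.
#'
#' @inheritParams read_events
#' @param state_col Name of the state column.
#' @return Tibble with columns `user_id`, `timestamp`, `asleep` (logical).
#' @export
read_sleep_truth <- function(path, user_col = "user_id",
                             time_col = "timestamp", state_col = "state",
                             delim = NULL) {
  raw <- read_events(path, user_col = user_col, time_col = time_col,
                     type_col = state_col, delim = delim)
  if (nrow(raw) == 0L) {
    return(tibble::tibble(user_id = character(), timestamp = numeric(),
                          asleep = logical()))
  }
  state <- tolower(raw$event_type)
  asleep <- state %in% c("sleep", "asleep", "1", "true")
  awake <- state %in% c("awake", "wake", "0", "false")
  if (any(!asleep & !awake)) {
    stop("unrecognized sleep state value(s): ",
         paste(unique(state[!asleep & !awake]), collapse = ", "))
  }
  tibble::tibble(user_id = raw$user_id, timestamp = raw$timestamp,
                 asleep = asleep)
}

#' Filter tracker users by tracked-sleep quality
#'
#' Keeps users whose ground-truth stream shows at least `min_sleep_hours` of
#' tracked sleep in every tracked day window and whose tracked days form a
#' contiguous span of between `min_days` and `max_days` windows.
#'
#' @param truth Ground-truth tibble from [read_sleep_truth()].
#' @param min_sleep_hours Minimum tracked sleep per day window, in hours.
#' @param min_days,max_days Inclusive bounds on the contiguous tracked span.
#' @inheritParams bin_events
#' @return The truth tibble restricted to retained users.
#' @export
filter_users_tracked_sleep <- function(truth, min_sleep_hours = 3,
                                       min_days = 14, max_days = 28,
                                       window_start_hour = 16, tz = "UTC") {
  if (nrow(truth) == 0L) return(truth)
  db <- event_day_bin(truth$timestamp, window_start_hour, 15, tz)
  df <- tibble::tibble(user_id = truth$user_id, day = db$day,
                       asleep = truth$asleep)
  keep <- df |>
    dplyr::group_by(.data$user_id) |>
    dplyr::summarise(
      n_days = dplyr::n_distinct(.data$day),
      span = as.numeric(max(.data$day) - min(.data$day)) + 1,
      min_sleep_min = min(tapply(.data$asleep, .data$day, sum)),
      .groups = "drop"
    ) |>
    dplyr::filter(
      .data$n_days == .data$span,           # contiguously tracked
      .data$span >= min_days, .data$span <= max_days,
      .data$min_sleep_min >= min_sleep_hours * 60
    )
  dplyr::filter(truth, .data$user_id %in% keep$user_id)
}
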