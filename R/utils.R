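# Clock/bin conversions for 16:00-anchored day windows.

#' Convert a bin index to clock time
#'
#' Day windows start at `window_start_hour` (16:00 by default), so bin 0 is
#' 16:00, bin 32 is midnight and bin 60 is 07:00 with 15-minute bins.
#'
#' @param bin Bin index (may be fractional).
#' @param window_start_hour Hour of day at which the window opens.
#' @param bin_minutes Bin width in minutes.
#' @return Clock time in fractional hours of day, in `[0, 24)`.
#' @export
#' @examples
#' bin_to_clock(32) # midnight
#' bin_to_clock(60) # 07:00
bin_to_clock <- function(bin, window_start_hour = 16, bin_minutes = 15) {
  (window_start_hour + bin * bin_minutes / 60) %% 24
}

#' Convert a clock time to a bin index
#'
#' @param clock Clock time: `"HH:MM"` string or fractional hours of day.
#' @inheritParams bin_to_clock
#' @return Fractional bin index in `[0, 24 * 60 / bin_minutes)`.
#' @export
#' @examples
#' clock_to_bin("23:00") # 28
clock_to_bin <- function(clock, window_start_hour = 16, bin_minutes = 15) {
  hours <- parse_clock(clock)
  ((hours - window_start_hour) %% 24) * 60 / bin_minutes
}

parse_clock <- function(clock) {
  if (is.character(clock)) {
    parts <- strsplit(clock, ":", fixed = TRUE)
    vapply(parts, function(p) {
      as.numeric(p[1]) + as.numeric(p[2]) / 60 +
        if (length(p) > 2) as.numeric(p[3]) / 3600 else 0
    }, numeric(1))
  } else {
    as.numeric(clock)
  }
}

#' Format fractional hours as HH:MM
#'
#' @param hours Fractional hours of day (wrapped into `[0, 24)`).
#' @return Character vector like `"23:38"`.
#' @export
format_clock <- function(hours) {
  hours <- hours %% 24
  h <- floor(hours)
  m <- round((hours - h) * 60)
  h <- ifelse(m == 60, (h + 1) %% 24, h)
  m <- ifelse(m == 60, 0, m)
  sprintf("%02d:%02d", as.integer(h), as.integer(m))
}

# Format a duration in hours as "Hh MMm" (used in summary tables).
format_duration <- function(hours) {
  h <- floor(hours)
  m <- round((hours - h) * 60)
  h <- ifelse(m == 60, h + 1, h)
  m <- ifelse(m == 60, 0, m)
  sprintf("%dh %02dm", as.integer(h), as.integer(m))
}

logsumexp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
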