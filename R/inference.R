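# From posterior traces to sleep matrices, P_sleep curves, duration and
# mid-sleep summaries, and cohort aggregates.

#' Infer the per-day sleep matrix from a fitted model
#'
#' The point estimate of each day's sleep interval is the posterior mean of
#' `t_sleep_i` and `t_awake_i`; bin `t` is marked asleep (`Z = 1`) when
#' `mean(t_sleep_i) <= t < mean(t_awake_i)` (the same half-open rule as the
#' likelihood, applied to the possibly non-integer means).  A probabilistic
#' matrix — the per-bin posterior probability of being asleep, from paired
#' samples — is also computed for visualization.  Pooled variants broadcast
#' their single switchpoint pair to every day.
#'
#' @param fit A `sleep_fit`.
#' @return A `sleep_estimate`: list with `day_tbl` (per-day posterior means
#'   and central 50%/95% credible intervals, in bins and clock hours), the
#'   binary matrix `Z`, the probability matrix `prob` (both `m x n`), and
#'   the source `counts`.
#' @export
infer_sleep_matrix <- function(fit) {
  spec <- fit$spec
  m <- spec$m; n <- spec$n
  ts <- fit_par_matrix(fit, "t_sleep", broadcast = TRUE)
  ta <- fit_par_matrix(fit, "t_awake", broadcast = TRUE)
  ws <- fit$counts$window_start_hour
  bm <- spec$bin_minutes

  qs <- function(mat, p) apply(mat, 2, quantile, probs = p, names = FALSE)
  day_tbl <- tibble::tibble(
    day = fit$counts$day_labels,
    mean_sleep_bin = colMeans(ts),
    mean_wake_bin = colMeans(ta),
    sleep_lo50 = qs(ts, 0.25), sleep_hi50 = qs(ts, 0.75),
    sleep_lo95 = qs(ts, 0.025), sleep_hi95 = qs(ts, 0.975),
    wake_lo50 = qs(ta, 0.25), wake_hi50 = qs(ta, 0.75),
    wake_lo95 = qs(ta, 0.025), wake_hi95 = qs(ta, 0.975)
  )
  day_tbl$sleep_clock <- bin_to_clock(day_tbl$mean_sleep_bin, ws, bm)
  day_tbl$wake_clock <- bin_to_clock(day_tbl$mean_wake_bin, ws, bm)

  bins <- seq_len(n) - 1L
  Z <- matrix(0L, m, n, dimnames = dimnames(fit$counts$counts))
  prob <- matrix(0, m, n, dimnames = dimnames(fit$counts$counts))
  for (i in seq_len(m)) {
    Z[i, ] <- as.integer(day_tbl$mean_sleep_bin[i] <= bins &
                           bins < day_tbl$mean_wake_bin[i])
    prob[i, ] <- vapply(bins, function(t) mean(ts[, i] <= t & t < ta[, i]),
                        numeric(1))
  }
  structure(list(day_tbl = day_tbl, Z = Z, prob = prob,
                 counts = fit$counts, spec = spec),
            class = "sleep_estimate")
}

#' @export
print.sleep_estimate <- function(x, ...) {
  cat("<sleep_estimate>", nrow(x$Z), "days; mean sleep",
      format_clock(mean(x$day_tbl$sleep_clock)), "- wake",
      format_clock(mean(x$day_tbl$wake_clock)), "\n")
  invisible(x)
}

#' Tidy a sleep estimate (per-day table)
#'
#' @param x A `sleep_estimate`.
#' @param ... Unused.
#' @return The per-day tibble of posterior means and credible intervals.
#' @export
tidy.sleep_estimate <- function(x, ...) x$day_tbl

#' Posterior sleep-probability curve
#'
#' `P_sleep(t)`, the posterior probability that the user is asleep at bin
#' `t`.  The default `"paired"` estimator is the fraction of posterior
#' samples with `t_sleep <= t < t_awake` (sleep onset passed, wake not yet).
#' The `"cdf"` estimator is `F_tsleep(t) - F_tawake(t)`, the difference of
#' the empirical distribution functions of the two switchpoints; the two
#' agree when no sample has `t_awake <= t < t_sleep`.
#'
#' @param fit A `sleep_fit`.
#' @param day Day index (1-based), or `NULL` to pool samples across days.
#' @param estimator `"paired"` (default) or `"cdf"`.
#' @return Tibble with columns `bin`, `clock` (hours), `p_sleep`.
#' @export
p_sleep_curve <- function(fit, day = NULL, estimator = c("paired", "cdf")) {
  estimator <- match.arg(estimator)
  ts <- fit_par_matrix(fit, "t_sleep", broadcast = TRUE)
  ta <- fit_par_matrix(fit, "t_awake", broadcast = TRUE)
  if (!is.null(day)) {
    stopifnot(day >= 1, day <= ncol(ts))
    ts <- ts[, day, drop = FALSE]
    ta <- ta[, day, drop = FALSE]
  }
  tsv <- as.numeric(ts); tav <- as.numeric(ta)
  bins <- seq_len(fit$spec$n) - 1L
  p <- if (estimator == "paired") {
    vapply(bins, function(t) mean(tsv <= t & t < tav), numeric(1))
  } else {
    vapply(bins, function(t) mean(tsv <= t) - mean(tav <= t), numeric(1))
  }
  tibble::tibble(
    bin = bins,
    clock = bin_to_clock(bins, fit$counts$window_start_hour,
                         fit$spec$bin_minutes),
    p_sleep = p
  )
}

#' Posterior sleep duration and mid-sleep time
#'
#' Computed per trace sample and per day: duration is
#' `(t_awake - t_sleep) * bin_minutes` and mid-sleep is the clock time of
#' `t_sleep + duration / 2`.  Samples with `t_awake < t_sleep` (negative
#' duration) are excluded from the summaries; their fraction is reported.
#'
#' @param fit A `sleep_fit`.
#' @return A `sleep_summary`: list with `samples` (tibble `day`,
#'   `duration_h`, `midsleep_bin`, `midsleep_clock`), `negative_fraction`,
#'   and a one-row `summary` tibble of means and SDs.
#' @export
derive_duration_midsleep <- function(fit) {
  ts <- fit_par_matrix(fit, "t_sleep", broadcast = TRUE)
  ta <- fit_par_matrix(fit, "t_awake", broadcast = TRUE)
  bm <- fit$spec$bin_minutes
  ws <- fit$counts$window_start_hour
  m <- ncol(ts)
  df <- tibble::tibble(
    day = rep(fit$counts$day_labels, each = nrow(ts)),
    duration_h = as.numeric(ta - ts) * bm / 60,
    midsleep_bin = as.numeric(ts + (ta - ts) / 2)
  )
  neg <- df$duration_h < 0
  negative_fraction <- mean(neg)
  if (negative_fraction > 0) {
    message(signif(100 * negative_fraction, 3),
            "% of samples have t_awake < t_sleep; excluded from summaries")
  }
  df <- df[!neg, , drop = FALSE]
  df$midsleep_clock <- bin_to_clock(df$midsleep_bin, ws, bm)
  summary <- tibble::tibble(
    mean_duration_h = mean(df$duration_h),
    sd_duration_h = sd(df$duration_h),
    mean_midsleep_clock = bin_to_clock(mean(df$midsleep_bin), ws, bm),
    sd_midsleep_h = sd(df$midsleep_bin) * bm / 60
  )
  structure(list(samples = df, negative_fraction = negative_fraction,
                 summary = summary, bin_minutes = bm,
                 window_start_hour = ws),
            class = "sleep_summary")
}

#' @export
print.sleep_summary <- function(x, ...) {
  cat("<sleep_summary> mean duration",
      format_duration(x$summary$mean_duration_h), "; mid-sleep",
      format_clock(x$summary$mean_midsleep_clock), "\n")
  invisible(x)
}

#' @export
glance.sleep_summary <- function(x, ...) x$summary

# locale-independent weekday labels (ISO: Monday = 1)
weekday_name <- function(d) {
  c("Monday", "Tuesday", "Wednesday", "Thursday", "Friday", "Saturday",
    "Sunday")[as.integer(format(as.Date(d), "%u"))]
}

# Per-day posterior samples of one user as a long tibble with equal-user
# weights attached.
user_time_samples <- function(fit, user_id = NULL) {
  ts <- fit_par_matrix(fit, "t_sleep", broadcast = TRUE)
  ta <- fit_par_matrix(fit, "t_awake", broadcast = TRUE)
  tibble::tibble(
    user_id = user_id %||% fit$counts$user_id,
    day = rep(fit$counts$day_labels, each = nrow(ts)),
    t_sleep = as.numeric(ts),
    t_awake = as.numeric(ta),
    weight = 1 / length(ts)
  )
}

#' Aggregate sleep schedules across a cohort
#'
#' Pools posterior switchpoint samples across users with equal per-user
#' weight (regardless of trace length or day count) and summarizes sleep
#' time, wake time, and duration, optionally grouped by the weekday on
#' which each day window *starts* (so a Friday-night sleep belongs to
#' Friday).  Statistics are computed on the window-anchored bin scale —
#' where a night is a contiguous stretch — then converted to clock time.
#'
#' @param fits A list of `sleep_fit` objects (one per user), optionally
#'   named by user id.
#' @param group_by `"none"` (default) or `"weekday"`.
#' @return A `cohort_summary`: list with `samples` (pooled weighted
#'   samples) and `summary` (per-group means/SDs of sleep time, wake time,
#'   duration; clock times as fractional hours plus formatted strings).
#' @export
aggregate_cohort <- function(fits, group_by = c("none", "weekday")) {
  group_by <- match.arg(group_by)
  if (inherits(fits, "sleep_fit")) fits <- list(fits)
  ids <- names(fits) %||% vapply(fits, function(f) f$counts$user_id,
                                 character(1))
  samples <- purrr::map2(fits, ids, user_time_samples) |>
    purrr::list_rbind()
  ws <- fits[[1]]$counts$window_start_hour
  bm <- fits[[1]]$spec$bin_minutes
  samples$duration_h <- (samples$t_awake - samples$t_sleep) * bm / 60
  samples$group <- if (group_by == "weekday") {
    weekday_name(samples$day)
  } else "all"
  if (group_by == "weekday") {
    # renormalize weights so each user still counts equally within a group
    samples <- samples |>
      dplyr::group_by(.data$user_id, .data$group) |>
      dplyr::mutate(weight = 1 / dplyr::n()) |>
      dplyr::ungroup()
  }
  wsd <- function(x, w) {
    mu <- weighted.mean(x, w)
    sqrt(weighted.mean((x - mu)^2, w))
  }
  summary <- samples |>
    dplyr::filter(.data$duration_h >= 0) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      mean_sleep_bin = weighted.mean(.data$t_sleep, .data$weight),
      sd_sleep_h = wsd(.data$t_sleep, .data$weight) * bm / 60,
      mean_wake_bin = weighted.mean(.data$t_awake, .data$weight),
      sd_wake_h = wsd(.data$t_awake, .data$weight) * bm / 60,
      mean_duration_h = weighted.mean(.data$duration_h, .data$weight),
      sd_duration_h = wsd(.data$duration_h, .data$weight),
      n_users = dplyr::n_distinct(.data$user_id),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mean_sleep_clock = bin_to_clock(.data$mean_sleep_bin, ws, bm),
      mean_wake_clock = bin_to_clock(.data$mean_wake_bin, ws, bm),
      sleep_time = format_clock(.data$mean_sleep_clock),
      wake_time = format_clock(.data$mean_wake_clock),
      duration = format_duration(.data$mean_duration_h)
    )
  if (group_by == "weekday") {
    lv <- c("Monday", "Tuesday", "Wednesday", "Thursday", "Friday",
            "Saturday", "Sunday")
    summary <- dplyr::arrange(summary, match(.data$group, lv))
  }
  structure(list(samples = samples, summary = summary, group_by = group_by,
                 window_start_hour = ws, bin_minutes = bm),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> grouped by", x$group_by, "\n")
  print(dplyr::select(x$summary, "group", "sleep_time", "wake_time",
                      "duration", "n_users"))
  invisible(x)
}

#' Cohort summary table
#'
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @return The per-group summary tibble.
#' @export
glance.cohort_summary <- function(x, ...) x$summary

#' @export
tidy.cohort_summary <- function(x, ...) x$summary
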