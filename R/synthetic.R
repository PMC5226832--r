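# Synthetic event streams and ground truth drawn from the generative model:
# two Poisson rates switched by per-day sleep/wake switchpoints.

#' Define a synthetic user scenario
#'
#' Holds the per-day truth (switchpoints in bins, awake rates) and the
#' perturbations applied on top of the generative model: night checks (an
#' event injected inside the sleep interval, *not* drawn from the model, to
#' probe robustness), a weekday shift of the sleep schedule, and missing
#' days with no recorded events.
#'
#' @param m_days Number of day windows.
#' @param t_sleep,t_awake True switchpoints in bins (scalar or length
#'   `m_days`); defaults put sleep at midnight (bin 32) and wake at 07:00
#'   (bin 60) in the 16:00-anchored day.
#' @param lambda_awake True awake rate(s), events/bin (scalar or length
#'   `m_days`).
#' @param lambda_sleep True sleep rate, events/bin.
#' @param night_check_prob Probability per night that check events are
#'   injected.
#' @param night_check_events Number of injected events on such nights.
#' @param weekday_shift `NULL`, or `list(weekday = "Friday", hours = 2)`:
#'   shifts that weekday's switchpoints by the given hours (window-start
#'   weekday, so Friday night belongs to Friday).
#' @param missing_day_prob Probability that a day records no events at all.
#' @param start_date Date of the first window's 16:00 start.
#' @param n Bins per day.
#' @param bin_minutes,window_start_hour,tz Grid definition.
#' @return A `sleep_scenario` object.
#' @export
sleep_scenario <- function(m_days = 21, t_sleep = 32, t_awake = 60,
                           lambda_awake = 5, lambda_sleep = 1e-4,
                           night_check_prob = 0, night_check_events = 1,
                           weekday_shift = NULL, missing_day_prob = 0,
                           start_date = as.Date("2013-11-04"),
                           n = 96L, bin_minutes = 15, window_start_hour = 16,
                           tz = "UTC") {
  t_sleep <- rep_len(t_sleep, m_days)
  t_awake <- rep_len(t_awake, m_days)
  lambda_awake <- rep_len(lambda_awake, m_days)
  stopifnot(
    all(lambda_awake > 0), lambda_sleep > 0,
    all(t_sleep >= 0 & t_sleep <= n), all(t_awake >= 0 & t_awake <= n),
    night_check_prob >= 0, night_check_prob <= 1,
    missing_day_prob >= 0, missing_day_prob <= 1
  )
  days <- seq(as.Date(start_date), by = "day", length.out = m_days)
  if (!is.null(weekday_shift)) {
    hit <- weekday_name(days) == weekday_shift$weekday
    shift_bins <- weekday_shift$hours * 60 / bin_minutes
    t_sleep[hit] <- pmin(pmax(t_sleep[hit] + shift_bins, 0), n)
    t_awake[hit] <- pmin(pmax(t_awake[hit] + shift_bins, 0), n)
  }
  structure(
    list(m_days = m_days, t_sleep = t_sleep, t_awake = t_awake,
         lambda_awake = lambda_awake, lambda_sleep = lambda_sleep,
         night_check_prob = night_check_prob,
         night_check_events = night_check_events,
         missing_day_prob = missing_day_prob,
         day_labels = days, n = as.integer(n), bin_minutes = bin_minutes,
         window_start_hour = window_start_hour, tz = tz),
    class = "sleep_scenario"
  )
}

#' Simulate one user's event stream from the generative model
#'
#' Per day and bin, the event count is Poisson with rate `lambda_sleep`
#' inside the true sleep interval and `lambda_awake_i` outside; each event
#' receives a timestamp uniform within its bin.  Night-check events (when
#' enabled) are added to a uniformly chosen sleep bin without altering the
#' ground truth.  Fully deterministic given `seed`.
#'
#' @param scenario A [sleep_scenario()].
#' @param user_id User identifier for the outputs.
#' @param seed Integer seed.
#' @return List with `events` (tibble `user_id`, `timestamp`), `counts`
#'   ([binned_counts()]), `truth` (`ground_truth` matrix, fully observed),
#'   and `truth_tbl` (per-day true parameters and perturbation record).
#' @export
simulate_user <- function(scenario, user_id = "user01", seed = 1) {
  sc <- scenario
  set.seed(seed %% 2147483647L)
  n <- sc$n; m <- sc$m_days
  bins <- seq_len(n) - 1L
  counts <- matrix(0L, m, n)
  Z <- matrix(0L, m, n)
  night_checked <- rep(FALSE, m)
  missing <- rep(FALSE, m)
  for (i in seq_len(m)) {
    rates <- rate_at(bins, sc$t_sleep[i], sc$t_awake[i], sc$lambda_sleep,
                     sc$lambda_awake[i])
    counts[i, ] <- rpois(n, rates)
    Z[i, ] <- as.integer(sc$t_sleep[i] <= bins & bins < sc$t_awake[i])
    sleep_bins <- bins[Z[i, ] == 1L]
    if (length(sleep_bins) > 0 && sc$night_check_prob > 0 &&
        runif(1) < sc$night_check_prob) {
      night_checked[i] <- TRUE
      hit <- sample(sleep_bins, sc$night_check_events, replace = TRUE)
      for (b in hit) counts[i, b + 1L] <- counts[i, b + 1L] + 1L
    }
    if (sc$missing_day_prob > 0 && runif(1) < sc$missing_day_prob) {
      missing[i] <- TRUE
      counts[i, ] <- 0L
    }
  }
  bc <- binned_counts(user_id, sc$day_labels, counts, sc$bin_minutes,
                      sc$window_start_hour, sc$tz)
  # timestamps uniform within each bin
  win_start <- as.numeric(as.POSIXct(
    paste(format(sc$day_labels), sprintf("%02d:00:00", sc$window_start_hour)),
    tz = sc$tz))
  ts_list <- vector("list", m)
  for (i in seq_len(m)) {
    k <- counts[i, ]
    if (sum(k) == 0L) next
    b <- rep(bins, k)
    ts_list[[i]] <- win_start[i] + b * sc$bin_minutes * 60 +
      runif(sum(k), 0, sc$bin_minutes * 60)
  }
  events <- tibble::tibble(user_id = user_id,
                           timestamp = sort(unlist(ts_list)))
  truth <- structure(
    list(Z = Z, observed = matrix(TRUE, m, n), user_id = user_id,
         day_labels = sc$day_labels, n = n, bin_minutes = sc$bin_minutes,
         window_start_hour = sc$window_start_hour),
    class = "ground_truth")
  truth_tbl <- tibble::tibble(
    user_id = user_id, day = sc$day_labels,
    t_sleep = sc$t_sleep, t_awake = sc$t_awake,
    lambda_awake = sc$lambda_awake, lambda_sleep = sc$lambda_sleep,
    night_checked = night_checked, missing = missing
  )
  list(events = events, counts = bc, truth = truth, truth_tbl = truth_tbl,
       scenario = sc, user_id = user_id, seed = seed)
}

#' Simulate a cohort of users with hierarchical variation
#'
#' Per-user schedules are drawn in the spirit of the fully hierarchical
#' model: each user gets a characteristic sleep/wake center (Normal around
#' midnight and 07:00), per-day switchpoints scatter around those centers
#' and are rounded to whole bins, and per-day awake rates are Gamma around
#' a user-level mean with a floor of `rate_floor` events/bin.  User `u`
#' uses seed `seed + u - 1`, so a cohort is reproducible user by user.
#'
#' @param n_users Number of users.
#' @param m_days Days per user.
#' @param seed Base integer seed; user `u` uses `seed + u - 1`.
#' @param sleep_center_bin,wake_center_bin Population centers (bins).
#' @param user_center_sd Between-user SD of the centers (bins).
#' @param day_sd Within-user, between-day SD of switchpoints (bins).
#' @param rate_range Range of the uniform draw of user mean awake rates
#'   (events/bin).
#' @param rate_shape Gamma shape of per-day rates around the user mean.
#' @param rate_floor Lower bound applied to per-day awake rates.
#' @param lambda_sleep Shared true sleep rate.
#' @param night_check_prob,night_check_events,weekday_shift,missing_day_prob
#'   Perturbations, as in [sleep_scenario()].
#' @param start_date First window date.
#' @return List with `users` (named list of [simulate_user()] bundles) and
#'   `truth_tbl` (all users' per-day truth).
#' @export
simulate_cohort <- function(n_users = 20, m_days = 14, seed = 0,
                            sleep_center_bin = 32, wake_center_bin = 60,
                            user_center_sd = 3, day_sd = 1.5,
                            rate_range = c(4, 7), rate_shape = 50,
                            rate_floor = 3, lambda_sleep = 1e-4,
                            night_check_prob = 0, night_check_events = 1,
                            weekday_shift = NULL, missing_day_prob = 0,
                            start_date = as.Date("2013-11-04")) {
  users <- vector("list", n_users)
  ids <- sprintf("user%02d", seq_len(n_users))
  for (u in seq_len(n_users)) {
    user_seed <- seed + u - 1L
    set.seed(user_seed %% 2147483647L)
    mu_ts <- rnorm(1, sleep_center_bin, user_center_sd)
    mu_ta <- rnorm(1, wake_center_bin, user_center_sd)
    user_rate <- runif(1, rate_range[1], rate_range[2])
    ts_i <- pmin(pmax(round(rnorm(m_days, mu_ts, day_sd)), 0), 96)
    ta_i <- pmin(pmax(round(rnorm(m_days, mu_ta, day_sd)), 0), 96)
    la_i <- pmax(rgamma(m_days, shape = rate_shape,
                        rate = rate_shape / user_rate), rate_floor)
    sc <- sleep_scenario(
      m_days = m_days, t_sleep = ts_i, t_awake = ta_i,
      lambda_awake = la_i, lambda_sleep = lambda_sleep,
      night_check_prob = night_check_prob,
      night_check_events = night_check_events,
      weekday_shift = weekday_shift, missing_day_prob = missing_day_prob,
      start_date = start_date
    )
    # separate seed stream for the counts so truth and noise are independent
    users[[u]] <- simulate_user(sc, ids[u], seed = user_seed + 500000L)
  }
  names(users) <- ids
  truth_tbl <- purrr::list_rbind(purrr::map(users, "truth_tbl"))
  list(users = users, truth_tbl = truth_tbl, seed = seed)
}
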