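test_that("a degenerate trace yields the exact sleep interval", {
  fit <- fake_pooled_fit(t_sleep = rep(28, 10), t_awake = rep(60, 10))
  est <- infer_sleep_matrix(fit)
  expect_true(all(est$Z[, 29:60 - 0] == rep(c(1), 32)))
  expect_equal(unname(which(est$Z[1, ] == 1L) - 1L), 28:59)
  expect_identical(est$Z[1, ], est$Z[2, ])  # pooled broadcast: row-constant
  expect_equal(est$prob, matrix(as.numeric(est$Z), nrow(est$Z), ncol(est$Z),
                                dimnames = dimnames(est$prob)))
})

test_that("non-integer posterior means use the half-open rule", {
  # mean t_sleep 28.4: first fully-sleeping bin is 29
  fit <- fake_pooled_fit(t_sleep = c(28, 28.8), t_awake = c(60, 60))
  est <- infer_sleep_matrix(fit)
  expect_equal(min(which(est$Z[1, ] == 1L)) - 1L, 29L)
  # brute-force per-bin check of the same convention
  bins <- 0:95
  expect_equal(est$Z[1, ], as.integer(28.4 <= bins & bins < 60),
               ignore_attr = TRUE)
})

test_that("p_sleep_curve matches a brute-force sample average", {
  u <- simulate_user(sleep_scenario(m_days = 4), seed = 8)
  fit <- fit_sleep_model(u$counts, "independent-pooled", n_samples = 400,
                         burn_in = 300, chains = 1, seed = 6)
  day <- 2
  pc <- p_sleep_curve(fit, day = day)
  ts <- fit$samples[, sprintf("t_sleep[%d]", day)]
  ta <- fit$samples[, sprintf("t_awake[%d]", day)]
  brute <- vapply(0:95, function(t) mean(ts <= t & t < ta), numeric(1))
  expect_equal(pc$p_sleep, brute)
  expect_true(all(pc$p_sleep >= 0 & pc$p_sleep <= 1))
  # below every sampled onset the curve is zero
  expect_equal(pc$p_sleep[pc$bin < min(ts)], rep(0, sum(pc$bin < min(ts))))
})

test_that("degenerate p_sleep_curve is an indicator and estimators agree", {
  fit <- fake_pooled_fit(t_sleep = rep(28, 5), t_awake = rep(60, 5))
  paired <- p_sleep_curve(fit, estimator = "paired")
  cdf <- p_sleep_curve(fit, estimator = "cdf")
  expect_equal(paired$p_sleep, as.numeric(28 <= 0:95 & 0:95 < 60))
  expect_equal(paired$p_sleep, cdf$p_sleep)
})

test_that("duration and mid-sleep arithmetic from the trace", {
  fit <- fake_pooled_fit(t_sleep = rep(28, 5), t_awake = rep(60, 5))
  dm <- derive_duration_midsleep(fit)
  expect_equal(unique(dm$samples$duration_h), 8)
  expect_equal(unique(dm$samples$midsleep_bin), 44)
  expect_equal(format_clock(unique(dm$samples$midsleep_clock)), "03:00")
  expect_equal(dm$summary$sd_duration_h, 0)
  expect_equal(dm$negative_fraction, 0)
})

test_that("negative-duration samples are excluded and reported", {
  fit <- fake_pooled_fit(t_sleep = c(28, 70), t_awake = c(60, 50))
  expect_message(dm <- derive_duration_midsleep(fit), "excluded")
  expect_equal(dm$negative_fraction, 0.5)
  expect_equal(dm$summary$mean_duration_h, 8)
})

test_that("mean duration equals the trace-sample average duration", {
  u <- simulate_user(sleep_scenario(m_days = 3), seed = 10)
  fit <- fit_sleep_model(u$counts, "independent-independent",
                         n_samples = 400, burn_in = 300, chains = 1,
                         seed = 12)
  dm <- derive_duration_midsleep(fit)
  ts <- fit$samples[, grepl("^t_sleep", colnames(fit$samples))]
  ta <- fit$samples[, grepl("^t_awake", colnames(fit$samples))]
  brute <- (as.numeric(ta) - as.numeric(ts)) * 15 / 60
  expect_equal(dm$summary$mean_duration_h, mean(brute[brute >= 0]))
})

test_that("P_sleep integrates to the mean sleep duration (integer trace)", {
  u <- simulate_user(sleep_scenario(m_days = 5), seed = 13)
  fit <- fit_sleep_model(u$counts, "independent-pooled", n_samples = 500,
                         burn_in = 300, chains = 1, seed = 14)
  pc <- p_sleep_curve(fit)  # pooled over days
  dm <- derive_duration_midsleep(fit)
  expect_equal(sum(pc$p_sleep) * 15 / 60, dm$summary$mean_duration_h,
               tolerance = 1e-10)
})

test_that("clock conversion round-trips integer bins", {
  bins <- 0:95
  expect_equal(clock_to_bin(bin_to_clock(bins)), bins)
  expect_equal(bin_to_clock(32), 0)   # midnight
  expect_equal(clock_to_bin("23:00"), 28)
})

test_that("cohort aggregation averages users with equal weight", {
  # two users with degenerate schedules: 23:00-07:00 and 01:00-09:00
  f1 <- fake_pooled_fit(t_sleep = rep(28, 10), t_awake = rep(60, 10))
  f2 <- fake_pooled_fit(t_sleep = rep(36, 4), t_awake = rep(68, 4))
  agg <- aggregate_cohort(list(u1 = f1, u2 = f2))
  expect_equal(agg$summary$mean_sleep_bin, 32)   # midnight
  expect_equal(agg$summary$sleep_time, "00:00")
  expect_equal(agg$summary$wake_time, "08:00")
  expect_equal(agg$summary$mean_duration_h, 8)
  # a single user's cohort equals that user's own summary
  solo <- aggregate_cohort(list(u1 = f1))
  expect_equal(solo$summary$mean_sleep_bin, 28)
  expect_equal(solo$summary$n_users, 1L)
})

test_that("an injected Friday shift shows up in the weekday aggregate", {
  cohort <- simulate_cohort(n_users = 20, m_days = 14, seed = 3,
                            weekday_shift = list(weekday = "Friday",
                                                 hours = 2))
  # the truth table records the shift exactly
  tt <- cohort$truth_tbl
  tt$wd <- format(tt$day, "%u")
  base_mean <- mean(tt$t_sleep[tt$wd %in% c("1", "2", "3", "4")])
  fri_mean <- mean(tt$t_sleep[tt$wd == "5"])
  expect_equal(fri_mean - base_mean, 8, tolerance = 1.5)
  # and is recovered from fitted posteriors
  fits <- purrr::map(cohort$users, function(u)
    fit_sleep_model(u$counts, "hyper-hyper", n_samples = 600,
                    burn_in = 500, chains = 1, seed = u$seed))
  agg <- aggregate_cohort(fits, group_by = "weekday")
  s <- agg$summary
  base_fit <- mean(s$mean_sleep_bin[s$group %in%
                                      c("Monday", "Tuesday", "Wednesday",
                                        "Thursday")])
  expect_equal(s$mean_sleep_bin[s$group == "Friday"] - base_fit, 8,
               tolerance = 2)
  expect_equal(nrow(s), 7)
})
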