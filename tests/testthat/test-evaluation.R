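test_that("ground-truth binning marks a bin asleep on any asleep minute", {
  grid <- make_counts(matrix(0L, 1, 96))
  base <- posix("2013-11-04 16:00:00")
  mk <- function(mins_asleep, mins_awake) {
    tibble::tibble(
      user_id = "u",
      timestamp = base + c(mins_asleep, mins_awake) * 60,
      asleep = rep(c(TRUE, FALSE), c(length(mins_asleep), length(mins_awake)))
    )
  }
  # bin 0 covers 16:00-16:15: one asleep minute among 15 -> asleep
  suppressMessages({
    gt <- bin_ground_truth(mk(7, c(0:6, 8:14)), grid)
    expect_equal(gt$Z[1, 1], 1L)
    # all 15 awake -> awake but observed
    gt2 <- bin_ground_truth(mk(integer(0), 0:14), grid)
    expect_equal(gt2$Z[1, 1], 0L)
    expect_true(gt2$observed[1, 1])
    # all 15 asleep -> asleep
    gt3 <- bin_ground_truth(mk(0:14, integer(0)), grid)
    expect_equal(gt3$Z[1, 1], 1L)
  })
  # uncovered bins are flagged missing
  expect_message(gt4 <- bin_ground_truth(mk(7, integer(0)), grid),
                 "no tracker coverage")
  expect_false(gt4$observed[1, 2])
})

test_that("score_sleep computes the confusion-matrix metrics", {
  z <- matrix(0L, 1, 96)
  perfect <- score_sleep(z + 1L, z + 1L)
  expect_equal(perfect[, c("accuracy", "precision", "recall", "f1")],
               tibble::tibble(accuracy = 1, precision = 1, recall = 1,
                              f1 = 1))
  truth <- z; truth[1, 10:12] <- 1L           # 3 positives
  pred <- z; pred[1, 11:13] <- 1L             # TP=2, FP=1, FN=1, TN=92
  s <- score_sleep(pred, truth)
  expect_equal(s$precision, 2 / 3)
  expect_equal(s$recall, 2 / 3)
  expect_equal(s$f1, 2 / 3)
  expect_equal(s$accuracy, 94 / 96)
})

test_that("zero-denominator metrics return flagged zeros", {
  z <- matrix(0L, 1, 96)
  truth <- z; truth[1, 30:60] <- 1L
  s <- score_sleep(z, truth)   # predicts all awake
  expect_equal(s$recall, 0)
  expect_equal(s$precision, 0)
  expect_true(s$flag_precision)
  expect_equal(s$f1, 0)
  expect_true(s$flag_f1)
  expect_error(score_sleep(matrix(0L, 2, 96), truth), "shape")
})

test_that("scoring is invariant to relabeling days in both matrices", {
  set.seed(31)
  pred <- matrix(rbinom(5 * 96, 1, 0.3), 5, 96)
  truth <- matrix(rbinom(5 * 96, 1, 0.3), 5, 96)
  perm <- sample(5)
  expect_equal(score_sleep(pred, truth),
               score_sleep(pred[perm, ], truth[perm, ]))
})

test_that("concatenated users reproduce pooled confusion-matrix metrics", {
  set.seed(32)
  preds <- purrr::map(1:3, ~ matrix(rbinom(2 * 96, 1, 0.4), 2, 96))
  truths <- purrr::map(1:3, ~ matrix(rbinom(2 * 96, 1, 0.4), 2, 96))
  pooled <- score_sleep(do.call(rbind, preds), do.call(rbind, truths))
  per_user <- purrr::map2(preds, truths, score_sleep) |> purrr::list_rbind()
  tp <- sum(per_user$tp); fp <- sum(per_user$fp); fn <- sum(per_user$fn)
  expect_equal(pooled$precision, tp / (tp + fp))
  expect_equal(pooled$recall, tp / (tp + fn))
  expect_equal(pooled$accuracy,
               (tp + sum(per_user$tn)) / sum(per_user$n_scored))
})

test_that("rule baseline finds the overnight gap at bin resolution", {
  # events every 10 min until 23:02, silence until 06:48, events after
  base <- posix("2013-11-04 16:00:00")
  times <- c(seq(base, base + 7 * 3600 + 120, by = 600),
             seq(base + 14.8 * 3600, base + 23.9 * 3600, by = 600))
  ev <- tibble::tibble(user_id = "u", timestamp = sort(times))
  rb <- rule_based_sleep(ev)
  asleep <- which(rb$Z[1, ] == 1L) - 1L
  # zero-count bins from 23:15 (bin 29) through 06:45-07:00 (bin 59 starts
  # 06:45; the 06:48 event makes bin 59 non-zero) -> 29..58
  expect_equal(range(asleep), c(29, 58))
  expect_false(rb$flagged[1])
})

test_that("rule baseline enforces the onset window and flags empty days", {
  base <- posix("2013-11-04 16:00:00")
  # a 25-bin evening gap starting 17:15 (before 22:00, ineligible) and a
  # 24-bin overnight gap starting 00:00 (eligible): the shorter one wins
  ev_times <- c(seq(base, base + 3600, by = 900),            # 16:00-17:00
                base + 7.5 * 3600, base + 7.75 * 3600,       # 23:30, 23:45
                seq(base + 14 * 3600, base + 23.9 * 3600, by = 900))
  ev <- tibble::tibble(user_id = "u", timestamp = ev_times)
  rb <- rule_based_sleep(ev)
  asleep <- which(rb$Z[1, ] == 1L) - 1L
  expect_equal(range(asleep), c(32, 55))
  # a window with no events at all is all-awake and flagged
  two_day <- make_counts(rbind(matrix(1L, 1, 96), matrix(0L, 1, 96)))
  rb2 <- rule_based_sleep(two_day)
  expect_true(rb2$flagged[2])
  expect_equal(sum(rb2$Z[2, ]), 0L)
})

test_that("rule baseline matches Bayesian truth recovery on clean data", {
  u <- simulate_user(sleep_scenario(m_days = 10, t_sleep = 30, t_awake = 59,
                                    lambda_awake = 6), seed = 2)
  rb <- rule_based_sleep(u$counts)
  expect_gt(score_sleep(rb$Z, u$truth$Z)$accuracy, 0.9)
})
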