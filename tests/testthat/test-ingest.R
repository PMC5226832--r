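test_that("read_events partitions users, sorts, and reports skipped rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("user_id,timestamp",
               "u1,1383580800", "u2,1383580900", "u1,1383580700",
               "u2,1383580600", "u1,1383580750", "u1,abc"), f)
  expect_warning(ev <- read_events(f), "skipped")
  expect_equal(attr(ev, "skipped"), 1L)
  expect_equal(nrow(ev), 5L)
  expect_equal(sort(unique(ev$user_id)), c("u1", "u2"))
  for (u in c("u1", "u2")) {
    expect_false(is.unsorted(ev$timestamp[ev$user_id == u]))
  }
  expect_equal(sum(ev$user_id == "u1"), 3L)
})

test_that("read_events errors on missing columns and warns on empty files", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("who,when", "u1,1"), f)
  expect_error(read_events(f), "missing mandatory column")
  writeLines("user_id,timestamp", f)
  expect_warning(ev <- read_events(f), "no event rows")
  expect_equal(nrow(ev), 0L)
})

test_that("read_events autodetects tab-delimited logs", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("user_id\ttimestamp", "u1\t1383580800"), f)
  ev <- read_events(f)
  expect_equal(ev$timestamp, 1383580800)
})

test_that("bin_events maps local times onto the 16:00-anchored grid", {
  ev <- tibble::tibble(
    user_id = "u",
    timestamp = posix(c("2013-11-04 16:00:00",  # day d, bin 0
                        "2013-11-04 15:59:59",  # previous window, bin 95
                        "2013-11-04 23:07:00",  # bin 28
                        "2013-11-04 23:12:00")) # bin 28 again
  )
  bc <- bin_events(ev)
  expect_equal(format(bc$day_labels), c("2013-11-03", "2013-11-04"))
  expect_equal(bc$counts[1, 96], 1L)
  expect_equal(bc$counts[2, 1], 1L)
  expect_equal(bc$counts[2, 29], 2L)
  expect_equal(sum(bc$counts), 4L)
})

test_that("binning preserves counts, keeps zero days, and ignores order", {
  for (seed in 1:3) {
    set.seed(seed)
    base <- posix("2013-11-01 16:00:00")
    stamps <- sort(base + runif(200, 0, 10 * 86400))
    stamps <- stamps[as.Date(as.POSIXct(stamps, origin = "1970-01-01",
                                        tz = "UTC")) !=
                       as.Date("2013-11-05")]  # carve out a quiet day
    ev <- tibble::tibble(user_id = "u", timestamp = stamps)
    bc <- bin_events(ev)
    expect_equal(sum(bc$counts), length(stamps))
    expect_equal(diff(range(as.numeric(bc$day_labels))) + 1,
                 nrow(bc$counts))  # contiguous span incl. all-zero days
    shuffled <- ev[sample(nrow(ev)), ]
    expect_identical(bin_events(shuffled)$counts, bc$counts)
  }
})

test_that("minimum-daily-events filter is inclusive at the boundary", {
  base <- posix("2013-11-01 16:00:00")
  # exactly 10/day over a 30-day span vs 9/day
  mk <- function(uid, per_day) tibble::tibble(
    user_id = uid,
    timestamp = rep(base + (0:29) * 86400 + 3600, each = per_day) +
      rep(seq_len(per_day) * 60, times = 30))
  ev <- dplyr::bind_rows(mk("at_ten", 10), mk("at_nine", 9))
  kept <- filter_users_min_daily_events(ev, min_per_day = 10)
  expect_setequal(unique(kept$user_id), "at_ten")
  expect_equal(nrow(filter_users_min_daily_events(ev[0, ])), 0L)
})

test_that("mean vs every-day filter rules differ on a single quiet day", {
  base <- posix("2013-11-01 16:00:00")
  # 20 events/day for 9 days, 2 events on the last: mean 18.2, min 2
  ts <- c(rep(base + (0:8) * 86400, each = 20) + seq_len(20) * 60,
          base + 9 * 86400 + c(60, 120))
  ev <- tibble::tibble(user_id = "u", timestamp = ts)
  expect_equal(nrow(filter_users_min_daily_events(ev, 10, rule = "mean")),
               nrow(ev))
  expect_equal(nrow(filter_users_min_daily_events(ev, 10, rule = "every")), 0L)
})

test_that("tracked-sleep filter enforces per-day minimum and span bounds", {
  base <- posix("2013-11-01 20:00:00")
  mk_truth <- function(uid, n_days, hours_asleep, skip_day = NULL) {
    purrr::map(seq_len(n_days), function(d) {
      if (!is.null(skip_day) && d == skip_day) return(NULL)
      mins <- seq(0, hours_asleep * 60 - 1)
      tibble::tibble(user_id = uid,
                     timestamp = base + (d - 1) * 86400 + mins * 60,
                     asleep = TRUE)
    }) |> purrr::list_rbind()
  }
  truth <- dplyr::bind_rows(
    mk_truth("ok21", 21, 6),          # retained
    mk_truth("short_sleep", 21, 2),   # < 3 h/day
    mk_truth("too_long", 40, 6),      # span > 28
    mk_truth("too_short", 5, 6),      # span < 14
    mk_truth("gappy", 21, 6, skip_day = 10)  # not contiguous
  )
  kept <- filter_users_tracked_sleep(truth)
  expect_setequal(unique(kept$user_id), "ok21")
})

test_that("binned counts survive a CSV and JSON round trip", {
  set.seed(4)
  bc <- make_counts(matrix(rpois(3 * 96, 2), 3, 96))
  f <- withr::local_tempfile(fileext = ".csv")
  write_binned_counts(bc, f)
  back <- read_binned_counts(f, user_id = "u")
  expect_identical(back$counts, bc$counts)
  expect_equal(back$day_labels, bc$day_labels)
  fj <- withr::local_tempfile(fileext = ".json")
  write_binned_counts(bc, fj, format = "json")
  backj <- read_binned_counts(fj)
  expect_equal(unname(backj$counts), unname(bc$counts))
})
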