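# Scoring inferred sleep against tracker ground truth, and the rule-based
# longest-gap baseline.

#' Bin tracker ground truth onto the day/bin grid
#'
#' A bin is marked asleep (`Z = 1`) when at least one asleep record falls in
#' it, awake (`Z = 0`) when only awake records fall in it, and *missing*
#' (excluded from scoring) when the tracker has no record in the bin at all.
#'
#' @param truth Ground-truth tibble for one user (`user_id`, `timestamp`,
#'   `asleep`), e.g. from [read_sleep_truth()].
#' @param grid A [binned_counts()] object defining the day windows and bin
#'   grid to align to (its counts are not used).
#' @return A `ground_truth` object: binary matrix `Z`, logical `observed`
#'   mask, and the grid metadata.
#' @export
bin_ground_truth <- function(truth, grid) {
  stopifnot(inherits(grid, "binned_counts"))
  uid <- unique(truth$user_id)
  if (length(uid) > 1L) stop("bin_ground_truth() expects a single user")
  db <- event_day_bin(truth$timestamp, grid$window_start_hour,
                      grid$bin_minutes, grid$tz)
  m <- nrow(grid$counts); n <- grid$n
  Z <- matrix(0L, m, n, dimnames = dimnames(grid$counts))
  observed <- matrix(FALSE, m, n, dimnames = dimnames(grid$counts))
  idx_day <- match(db$day, grid$day_labels)
  inside <- !is.na(idx_day)
  for (k in which(inside)) {
    i <- idx_day[k]; j <- db$bin[k] + 1L
    observed[i, j] <- TRUE
    if (truth$asleep[k]) Z[i, j] <- 1L
  }
  n_missing <- sum(!observed)
  if (n_missing > 0) {
    message(n_missing, " of ", m * n,
            " bins have no tracker coverage; excluded from scoring")
  }
  structure(list(Z = Z, observed = observed, user_id = uid,
                 day_labels = grid$day_labels, n = n,
                 bin_minutes = grid$bin_minutes,
                 window_start_hour = grid$window_start_hour),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> user", x$user_id, "-", nrow(x$Z), "days,",
      round(100 * mean(x$observed), 1), "% bins observed,",
      round(100 * sum(x$Z) / max(sum(x$observed), 1), 1), "% asleep\n")
  invisible(x)
}

as_sleep_matrix <- function(x) {
  if (inherits(x, "sleep_estimate")) return(x$Z)
  if (inherits(x, c("ground_truth", "rule_sleep"))) return(x$Z)
  as.matrix(x)
}

#' Score an inferred sleep matrix against ground truth
#'
#' Binary classification with sleep bins as positives:
#' `accuracy = correct / total`, `precision = TP / predicted positives`,
#' `recall = TP / actual positives`, `F1 = 2PR / (P + R)`.  Bins without
#' tracker coverage (per the truth's `observed` mask) are excluded.  A
#' zero-denominator metric is reported as 0 with its flag column set, so
#' degenerate users do not poison cohort histograms.
#'
#' @param pred A `sleep_estimate`, `rule_sleep`, or binary matrix.
#' @param truth A `ground_truth` or binary matrix of the same shape.
#' @return One-row tibble with `accuracy`, `precision`, `recall`, `f1`, the
#'   confusion counts, `n_scored`, `n_excluded`, and
#'   `flag_precision`/`flag_recall`/`flag_f1`.
#' @export
score_sleep <- function(pred, truth) {
  zp <- as_sleep_matrix(pred)
  zt <- as_sleep_matrix(truth)
  if (!all(dim(zp) == dim(zt))) {
    stop("prediction and truth matrices must have the same shape")
  }
  observed <- if (inherits(truth, "ground_truth")) truth$observed else
    matrix(TRUE, nrow(zt), ncol(zt))
  p <- zp[observed] > 0
  a <- zt[observed] > 0
  tp <- sum(p & a); fp <- sum(p & !a); fn <- sum(!p & a); tn <- sum(!p & !a)
  total <- tp + fp + fn + tn
  safe_div <- function(num, den) if (den > 0) num / den else 0
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  tibble::tibble(
    accuracy = safe_div(tp + tn, total),
    precision = precision, recall = recall, f1 = f1,
    tp = tp, fp = fp, fn = fn, tn = tn,
    n_scored = total, n_excluded = sum(!observed),
    flag_precision = (tp + fp) == 0,
    flag_recall = (tp + fn) == 0,
    flag_f1 = (precision + recall) == 0
  )
}

#' Rule-based longest-gap sleep baseline
#'
#' A non-Bayesian reference: per day window, the longest run of event-free
#' bins whose start lies within the allowed onset window (22:00 to 07:00 by
#' default, half-open) is marked as sleep.  Gaps are measured at bin
#' resolution on event start times only (no durations).  Days with no
#' qualifying gap are left all-awake and flagged.
#'
#' @param x An events tibble for one user, or a [binned_counts()] object.
#' @param onset_earliest,onset_latest Clock bounds (`"HH:MM"` or fractional
#'   hours) on where a sleep gap may start.
#' @inheritParams bin_events
#' @return A `rule_sleep` object: binary matrix `Z`, logical `flagged` (per
#'   day, `TRUE` when no qualifying gap existed), and grid metadata.
#' @export
rule_based_sleep <- function(x, onset_earliest = "22:00",
                             onset_latest = "07:00",
                             window_start_hour = 16, bin_minutes = 15,
                             tz = "UTC") {
  bc <- if (inherits(x, "binned_counts")) x else
    bin_events(x, window_start_hour, bin_minutes, tz)
  n <- bc$n
  lo_bin <- clock_to_bin(onset_earliest, bc$window_start_hour, bc$bin_minutes)
  hi_bin <- clock_to_bin(onset_latest, bc$window_start_hour, bc$bin_minutes)
  m <- nrow(bc$counts)
  Z <- matrix(0L, m, n, dimnames = dimnames(bc$counts))
  flagged <- rep(FALSE, m)
  for (i in seq_len(m)) {
    zero <- bc$counts[i, ] == 0L
    r <- rle(zero)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cand <- which(r$values & (starts - 1L) >= lo_bin & (starts - 1L) < hi_bin)
    if (length(cand) == 0L) {
      flagged[i] <- TRUE
      next
    }
    best <- cand[which.max(r$lengths[cand])]   # ties: earliest start
    Z[i, starts[best]:ends[best]] <- 1L
  }
  structure(list(Z = Z, flagged = flagged, user_id = bc$user_id,
                 day_labels = bc$day_labels, n = n,
                 bin_minutes = bc$bin_minutes,
                 window_start_hour = bc$window_start_hour),
            class = "rule_sleep")
}

#' @export
print.rule_sleep <- function(x, ...) {
  cat("<rule_sleep> user", x$user_id, "-", nrow(x$Z), "days,",
      sum(x$flagged), "flagged all-awake\n")
  invisible(x)
}
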