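# Run orchestration: simulate / fit / evaluate / aggregate stages operating
# on a config list and an output directory.  Every stage writes the resolved
# config (with md5 content hashes of its file inputs) next to its outputs,
# so a run can be reproduced from its artifacts.

ss_log <- function(stage, ..., quiet = getOption("screensleep.quiet", FALSE)) {
  if (!quiet) message("[", stage, "] ", paste(..., collapse = " "))
}

#' Read a run configuration file
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON config file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

write_resolved_config <- function(config, out_dir, inputs = character()) {
  inputs <- inputs[file.exists(inputs)]
  config$input_md5 <- as.list(tools::md5sum(inputs))
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Simulate a synthetic cohort to disk
#'
#' Writes `events.csv` in the standard ingest dialect (`user_id`,
#' `timestamp`), per-bin ground truth `truth_bins.csv` (`user_id`, `day`,
#' `bin`, `asleep`), the per-day truth table, and the resolved config.
#'
#' @param config Named list of [simulate_cohort()] arguments (unknown
#'   entries are ignored); `seed` defaults to 0.
#' @param out_dir Output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  args <- config[intersect(names(config), names(formals(simulate_cohort)))]
  cohort <- do.call(simulate_cohort, args)
  events <- purrr::list_rbind(purrr::map(cohort$users, "events"))
  readr::write_csv(events, file.path(out_dir, "events.csv"))
  truth_bins <- purrr::list_rbind(purrr::map(cohort$users, function(u) {
    z <- u$truth$Z
    tibble::tibble(
      user_id = u$user_id,
      day = rep(format(u$truth$day_labels), each = ncol(z)),
      bin = rep(seq_len(ncol(z)) - 1L, times = nrow(z)),
      asleep = as.integer(t(z))
    )
  }))
  readr::write_csv(truth_bins, file.path(out_dir, "truth_bins.csv"))
  readr::write_csv(cohort$truth_tbl, file.path(out_dir, "truth_params.csv"))
  write_resolved_config(config, out_dir)
  ss_log("simulate", length(cohort$users), "users written to", out_dir)
  invisible(out_dir)
}

fit_seed <- function(seed, u_idx, v_idx) {
  (seed + 7919L * u_idx + 101L * v_idx) %% 2147483647L
}

#' Fit model variants to every user in an event log
#'
#' Reads events, applies the minimum-daily-events filter, bins each user,
#' fits the requested variants by MCMC, and persists one trace directory
#' per (user, variant) under `out_dir/traces/`.  Users with a completed
#' trace are skipped, so interrupted runs resume.  A DIC comparison report
#' (`report.csv`) and cohort ranking (`cohort_ranks.csv`) are written when
#' at least two variants are fitted.
#'
#' @param config Named list: `events` (path), optional `user_col`/`time_col`,
#'   `tz`, `min_per_day`, `filter_rule`, `variants` (default all five),
#'   `n_samples`, `burn_in`, `chains`, `seed`.
#' @param out_dir Output directory.
#' @return Tibble of per-user, per-variant DIC results, invisibly.
#' @export
run_fit <- function(config, out_dir) {
  dir.create(file.path(out_dir, "traces"), recursive = TRUE,
             showWarnings = FALSE)
  if (is.null(config$events) || !file.exists(config$events)) {
    stop("config$events must name a readable event log; run the simulate ",
         "stage or point it at your data")
  }
  events <- read_events(config$events,
                        user_col = config$user_col %||% "user_id",
                        time_col = config$time_col %||% "timestamp")
  tz <- config$tz %||% "UTC"
  events <- filter_users_min_daily_events(
    events, min_per_day = config$min_per_day %||% 10,
    rule = config$filter_rule %||% "mean", tz = tz)
  if (nrow(events) == 0L) stop("no users left after filtering")
  counts_by_user <- bin_events_by_user(events, tz = tz)
  variants <- config$variants %||% VARIANTS
  seed <- config$seed %||% 1L
  rows <- list()
  for (u_idx in seq_along(counts_by_user)) {
    uid <- names(counts_by_user)[u_idx]
    for (v_idx in seq_along(variants)) {
      v <- variants[v_idx]
      tdir <- file.path(out_dir, "traces", uid, v)
      meta_path <- file.path(tdir, "meta.json")
      if (file.exists(meta_path) &&
          identical(jsonlite::read_json(meta_path)$status, "done")) {
        ss_log("fit", uid, v, "already fitted; skipping")
        fit <- read_trace(tdir)
      } else {
        t0 <- Sys.time()
        fit <- tryCatch(
          fit_sleep_model(counts_by_user[[uid]], variant = v,
                          n_samples = config$n_samples %||% 5000,
                          burn_in = config$burn_in %||% 2000,
                          chains = config$chains %||% 2,
                          seed = fit_seed(seed, u_idx, v_idx)),
          error = function(e) {
            ss_log("fit", uid, v, "FAILED:", conditionMessage(e))
            NULL
          })
        if (is.null(fit)) next
        write_trace(fit, tdir)
        ss_log("fit", uid, v, sprintf("done in %.1fs",
                                      as.numeric(Sys.time() - t0, "secs")))
      }
      rows[[length(rows) + 1L]] <-
        dplyr::bind_cols(tibble::tibble(user_id = uid), compute_dic(fit))
    }
  }
  report <- purrr::list_rbind(rows)
  readr::write_csv(report, file.path(out_dir, "report.csv"))
  if (length(unique(report$variant)) >= 2) {
    comparison <- rank_models(report)
    readr::write_csv(tidy(comparison),
                     file.path(out_dir, "report_ranked.csv"))
    readr::write_csv(glance(comparison),
                     file.path(out_dir, "cohort_ranks.csv"))
  }
  write_resolved_config(config, out_dir, inputs = config$events)
  invisible(report)
}

# Rebuild a ground_truth object for one user from the per-bin truth table.
truth_from_bins <- function(truth_bins, grid) {
  df <- truth_bins[truth_bins$user_id == grid$user_id, , drop = FALSE]
  m <- nrow(grid$counts); n <- grid$n
  Z <- matrix(0L, m, n, dimnames = dimnames(grid$counts))
  observed <- matrix(FALSE, m, n, dimnames = dimnames(grid$counts))
  i <- match(as.Date(df$day), grid$day_labels)
  ok <- !is.na(i)
  observed[cbind(i[ok], df$bin[ok] + 1L)] <- TRUE
  Z[cbind(i[ok], df$bin[ok] + 1L)] <- as.integer(df$asleep[ok])
  structure(list(Z = Z, observed = observed, user_id = grid$user_id,
                 day_labels = grid$day_labels, n = n,
                 bin_minutes = grid$bin_minutes,
                 window_start_hour = grid$window_start_hour),
            class = "ground_truth")
}

#' Score fitted traces against ground truth
#'
#' Loads the persisted traces of one variant, infers each user's sleep
#' matrix, and scores it against the ground truth (per-bin `truth_bins.csv`
#' from the simulate stage, or a per-minute tracker log).  Optionally also
#' scores the rule-based baseline from the raw events.
#'
#' @param config Named list: `variant` (default `"hyper-hyper"`),
#'   `truth_bins` or `truth` (+ reader columns), `baseline` (logical),
#'   `events` (required for the baseline), `tz`.
#' @param out_dir The run directory written by [run_fit()].
#' @return Tibble of per-user, per-method metrics, invisibly; also written
#'   to `metrics.csv` and summarized in `metrics_cohort.json`.
#' @export
run_evaluate <- function(config, out_dir) {
  trace_root <- file.path(out_dir, "traces")
  if (!dir.exists(trace_root)) {
    stop("no traces under ", out_dir, "; run the fit stage (run_fit) first")
  }
  variant <- config$variant %||% "hyper-hyper"
  tz <- config$tz %||% "UTC"
  truth_bins <- NULL
  truth_minutes <- NULL
  if (!is.null(config$truth_bins)) {
    truth_bins <- readr::read_csv(config$truth_bins, show_col_types = FALSE,
                                  progress = FALSE)
  } else if (!is.null(config$truth)) {
    truth_minutes <- read_sleep_truth(config$truth)
  } else {
    stop("evaluation requires ground truth: set config$truth_bins or ",
         "config$truth")
  }
  baseline <- isTRUE(config$baseline)
  events <- NULL
  if (baseline) {
    if (is.null(config$events)) {
      stop("the rule baseline needs config$events (raw event log)")
    }
    events <- read_events(config$events)
  }
  users <- list.dirs(trace_root, recursive = FALSE, full.names = FALSE)
  rows <- list()
  for (uid in users) {
    tdir <- file.path(trace_root, uid, variant)
    if (!file.exists(file.path(tdir, "meta.json"))) {
      stop("no ", variant, " trace for user ", uid,
           "; run the fit stage (run_fit) with this variant")
    }
    fit <- read_trace(tdir)
    truth <- if (!is.null(truth_bins)) truth_from_bins(truth_bins, fit$counts)
             else bin_ground_truth(
               truth_minutes[truth_minutes$user_id == uid, ], fit$counts)
    est <- infer_sleep_matrix(fit)
    rows[[length(rows) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(user_id = uid, method = "bayes"),
      score_sleep(est, truth))
    if (baseline) {
      rb <- rule_based_sleep(events[events$user_id == uid, ], tz = tz)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(user_id = uid, method = "rule"),
        score_sleep(rb$Z[match(format(fit$counts$day_labels),
                               format(rb$day_labels)), , drop = FALSE],
                    truth))
    }
    ss_log("evaluate", uid, "scored")
  }
  metrics <- purrr::list_rbind(rows)
  readr::write_csv(metrics, file.path(out_dir, "metrics.csv"))
  cohort <- metrics |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(dplyr::across(c("accuracy", "precision", "recall", "f1"),
                                   mean), .groups = "drop")
  jsonlite::write_json(cohort, file.path(out_dir, "metrics_cohort.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(metrics)
}

#' Aggregate fitted traces into cohort sleep schedules
#'
#' @param config Named list: `variant` (default `"hyper-hyper"`),
#'   `group_by` (`"none"` or `"weekday"`), `plots` (logical; write PNG
#'   figures).
#' @param out_dir The run directory written by [run_fit()].
#' @return The `cohort_summary`, invisibly; its table is written to
#'   `cohort_summary.csv` (plus `cohort_weekday.csv` when grouped).
#' @export
run_aggregate <- function(config, out_dir) {
  trace_root <- file.path(out_dir, "traces")
  if (!dir.exists(trace_root)) {
    stop("no traces under ", out_dir, "; run the fit stage (run_fit) first")
  }
  variant <- config$variant %||% "hyper-hyper"
  group_by <- config$group_by %||% "none"
  users <- list.dirs(trace_root, recursive = FALSE, full.names = FALSE)
  fits <- purrr::map(users, function(uid)
    read_trace(file.path(trace_root, uid, variant)))
  names(fits) <- users
  agg <- aggregate_cohort(fits, group_by = group_by)
  fname <- if (group_by == "weekday") "cohort_weekday.csv" else
    "cohort_summary.csv"
  readr::write_csv(agg$summary, file.path(out_dir, fname))
  if (isTRUE(config$plots)) {
    ggplot2::ggsave(file.path(out_dir, paste0("cohort_", group_by, ".png")),
                    autoplot(agg), width = 8,
                    height = if (group_by == "weekday") 8 else 4, dpi = 150)
  }
  ss_log("aggregate", length(fits), "users aggregated by", group_by)
  invisible(agg)
}
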