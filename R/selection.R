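# Deviance information criterion and cross-variant ranking.

#' Deviance information criterion of a fitted model
#'
#' `DIC = Dbar + pD` with deviance `D = -2 * log-likelihood` (Poisson
#' likelihood only, priors excluded; for hierarchical variants the deviance
#' is conditional on the day-level parameters, i.e. the focus is the day
#' level).  `Dbar` is the mean deviance over retained samples and
#' `pD = Dbar - D(theta_hat)` where `theta_hat` takes the posterior mean for
#' continuous parameters and the rounded posterior median for discrete
#' switchpoints.  Negative `pD` (a known DIC pathology on multimodal
#' posteriors) is flagged, not failed.
#'
#' @param fit A `sleep_fit`.
#' @return One-row tibble: `variant`, `dic`, `p_d`, `d_bar`, `d_hat`,
#'   `mean_logp`, `p_d_negative`.
#' @export
compute_dic <- function(fit) {
  stopifnot(nrow(fit$samples) > 0)
  spec <- fit$spec
  cm <- fit$counts$counts
  ls <- fit$samples[, "lambda_sleep"]
  la <- fit_par_matrix(fit, "lambda_awake")
  ts <- fit_par_matrix(fit, "t_sleep")
  ta <- fit_par_matrix(fit, "t_awake")
  ll <- cpp_loglik_trace(cm, ls, la, ts, ta)
  d_bar <- mean(-2 * ll)

  discrete <- variant_code(spec$variant) <= 3
  point_t <- function(mat) {
    if (discrete) round(apply(mat, 2, median)) else colMeans(mat)
  }
  ll_hat <- cpp_loglik_trace(
    cm,
    mean(ls),
    matrix(colMeans(la), nrow = 1),
    matrix(point_t(ts), nrow = 1, ncol = ncol(ts)),
    matrix(point_t(ta), nrow = 1, ncol = ncol(ta))
  )
  d_hat <- -2 * ll_hat
  p_d <- d_bar - d_hat
  tibble::tibble(
    variant = spec$variant,
    dic = d_bar + p_d,
    p_d = p_d,
    d_bar = d_bar,
    d_hat = d_hat,
    mean_logp = mean(fit$logp),
    p_d_negative = p_d < 0
  )
}

#' Rank model variants across users by DIC
#'
#' Per user, variants are ranked by DIC (rank 1 = lowest); ties break toward
#' the simpler variant (fewer parameters).  Relative DIC is each variant's
#' DIC divided by the user's pooled-pooled DIC, so pooled-pooled is 1 by
#' construction.
#'
#' @param dic_tbl Tibble with columns `user_id`, `variant`, `dic` (and
#'   optionally `mean_logp`), one row per fitted user-variant pair.
#' @return A `model_comparison`: list with `per_user` (adds `rank`,
#'   `rel_dic`) and `cohort` (per-variant median/mean/sd rank, `p_best`,
#'   mean/sd relative DIC).
#' @export
rank_models <- function(dic_tbl) {
  stopifnot(all(c("user_id", "variant", "dic") %in% names(dic_tbl)))
  per_user <- dic_tbl |>
    dplyr::group_by(.data$user_id) |>
    dplyr::mutate(
      rank = order(order(.data$dic, variant_complexity(.data$variant))),
      rel_dic = .data$dic /
        .data$dic[match("pooled-pooled", .data$variant)]
    ) |>
    dplyr::ungroup()
  if (anyNA(per_user$rel_dic)) {
    message("pooled-pooled fit missing for some users; rel_dic is NA there")
  }
  cohort <- per_user |>
    dplyr::group_by(variant = factor(.data$variant, levels = VARIANTS)) |>
    dplyr::summarise(
      median_rank = median(.data$rank),
      mean_rank = mean(.data$rank),
      sd_rank = sd(.data$rank),
      p_best = mean(.data$rank == 1),
      mean_rel_dic = mean(.data$rel_dic),
      sd_rel_dic = sd(.data$rel_dic),
      n_users = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$median_rank, .data$mean_rank) |>
    dplyr::mutate(variant = as.character(.data$variant))
  structure(list(per_user = per_user, cohort = cohort),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>", dplyr::n_distinct(x$per_user$user_id),
      "users,", dplyr::n_distinct(x$per_user$variant), "variants\n")
  print(x$cohort)
  invisible(x)
}

#' Tidy a model comparison (per-user table)
#'
#' @param x A `model_comparison`.
#' @param ... Unused.
#' @return The per-user tibble (`user_id`, `variant`, `dic`, `rank`,
#'   `rel_dic`, ...).
#' @export
tidy.model_comparison <- function(x, ...) x$per_user

#' Summarize a model comparison at cohort level
#'
#' @param x A `model_comparison`.
#' @param ... Unused.
#' @return The cohort tibble (median/mean rank, `p_best`, relative DIC).
#' @export
glance.model_comparison <- function(x, ...) x$cohort
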