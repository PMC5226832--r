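# Generative model: Poisson event counts with switchpoint-controlled rate,
# and the five prior structures over rates and switchpoints.

VARIANTS <- c("pooled-pooled", "independent-pooled",
              "independent-independent", "independent-hyper", "hyper-hyper")

variant_code <- function(variant) {
  match(match.arg(variant, VARIANTS), VARIANTS) - 1L
}

# complexity order used for DIC tie-breaking (simplest first)
variant_complexity <- function(variant) match(variant, VARIANTS)

#' Specify a sleep switchpoint model
#'
#' Each day window holds `n` count bins; event counts in bin `t` are Poisson
#' with rate `lambda_sleep` when `t_sleep <= t < t_awake` and `lambda_awake`
#' otherwise.  The five variants differ in how rates and switchpoints are
#' shared across days:
#'
#' * `pooled-pooled`: one `lambda_awake`, one `(t_sleep, t_awake)` pair.
#' * `independent-pooled`: per-day switchpoints, one `lambda_awake`.
#' * `independent-independent`: per-day switchpoints and rates.
#' * `independent-hyper`: per-day rates share Gamma(`alpha_lambda`,
#'   `beta_lambda`) hyperpriors, `alpha_lambda, beta_lambda ~ Exponential(1)`.
#' * `hyper-hyper`: additionally the per-day switchpoints are Normal around
#'   user-level centers with shared precision `tau_t ~ Gamma(alpha_t,
#'   beta_t)`.
#'
#' Priors: `lambda_sleep ~ Exponential(1e4)` (rate parameterization, prior
#' mean 1e-4 events/bin); `lambda_awake ~ Gamma(2.5, 1)` (shape/rate, mean
#' and variance 2.5) in the non-hyper variants; discrete switchpoints are
#' uniform on the integers `{0, ..., n}`; hyper-hyper switchpoint centers
#' default to `8 * n / 24` (midnight in a 16:00-anchored day) and
#' `15 * n / 24` (07:00).  `tau_t` is a precision.
#'
#' @param variant One of the five variant names.
#' @param m Number of days.
#' @param n Bins per day (96 for 15-minute bins).
#' @param bin_minutes Bin width in minutes.
#' @param sleep_rate_prior_rate Exponential rate of the `lambda_sleep` prior.
#' @param awake_gamma_shape,awake_gamma_rate Gamma prior on `lambda_awake`
#'   for the non-hyper variants.
#' @param hyper_exp_rate Exponential rate shared by all hyperparameter
#'   priors.
#' @param tsleep_center_hours,tawake_center_hours Centers of the hyper-hyper
#'   switchpoint priors, in hours after the window start; converted to bins
#'   as `hours * n / 24`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(variant = VARIANTS, m, n = 96L, bin_minutes = 15,
                       sleep_rate_prior_rate = 1e4,
                       awake_gamma_shape = 2.5, awake_gamma_rate = 1,
                       hyper_exp_rate = 1,
                       tsleep_center_hours = 8, tawake_center_hours = 15) {
  variant <- match.arg(variant)
  stopifnot(m >= 1, n >= 1, sleep_rate_prior_rate > 0, awake_gamma_shape > 0,
            awake_gamma_rate > 0, hyper_exp_rate > 0)
  structure(
    list(variant = variant, m = as.integer(m), n = as.integer(n),
         bin_minutes = bin_minutes,
         sleep_rate_prior_rate = sleep_rate_prior_rate,
         awake_gamma_shape = awake_gamma_shape,
         awake_gamma_rate = awake_gamma_rate,
         hyper_exp_rate = hyper_exp_rate,
         tsleep_center_hours = tsleep_center_hours,
         tawake_center_hours = tawake_center_hours),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$variant, "-", x$m, "days x", x$n, "bins\n")
  invisible(x)
}

spec_consts <- function(spec) {
  list(sleep_rate_prior_rate = spec$sleep_rate_prior_rate,
       awake_gamma_shape = spec$awake_gamma_shape,
       awake_gamma_rate = spec$awake_gamma_rate,
       hyper_exp_rate = spec$hyper_exp_rate,
       tsleep_center_bin = spec$tsleep_center_hours * spec$n / 24,
       tawake_center_bin = spec$tawake_center_hours * spec$n / 24)
}

# expected parameter vector lengths per variant
spec_shapes <- function(spec) {
  v <- variant_code(spec$variant)
  list(
    lambda_awake = if (v >= 2) spec$m else 1L,
    times = if (v >= 1) spec$m else 1L,
    hyper_rates = v >= 3,
    hyper_times = v == 4
  )
}

#' Serialize / restore a model spec
#'
#' @param spec A [model_spec()].
#' @return `as_spec_config()` returns a plain named list; `spec_from_config()`
#'   rebuilds the `model_spec` from such a list (e.g. parsed from YAML/JSON).
#' @export
as_spec_config <- function(spec) unclass(spec)

#' @rdname as_spec_config
#' @param config Named list as produced by `as_spec_config()`.
#' @export
spec_from_config <- function(config) {
  do.call(model_spec, config[intersect(names(config),
                                       names(formals(model_spec)))])
}

#' Poisson rate at a time bin under the switchpoint rule
#'
#' Returns `lambda_sleep` where `t_sleep <= t < t_awake` and `lambda_awake`
#' elsewhere.  When `t_sleep >= t_awake` the sleep interval is empty and
#' every bin is awake.  All arguments recycle.
#'
#' @param t Bin index (integer, `0 <= t < n`).
#' @param t_sleep,t_awake Switchpoints in bins (may be non-integer).
#' @param lambda_sleep,lambda_awake Poisson rates, events/bin.
#' @return Numeric vector of rates.
#' @export
#' @examples
#' rate_at(50, 30, 60, 1e-4, 2.5) # asleep
#' rate_at(60, 30, 60, 1e-4, 2.5) # awake (half-open right boundary)
rate_at <- function(t, t_sleep, t_awake, lambda_sleep, lambda_awake) {
  ifelse(t_sleep <= t & t < t_awake, lambda_sleep, lambda_awake)
}

#' Poisson log probability mass
#'
#' `k log(lambda) - lambda - log(k!)`, evaluated stably through the
#' log-gamma function.
#'
#' @param k Non-negative integer count(s).
#' @param lam Poisson rate(s), strictly positive.
#' @return Log probability.
#' @export
poisson_log_pmf <- function(k, lam) {
  if (any(lam <= 0)) stop("Poisson rate must be > 0")
  if (any(k < 0) || any(k != floor(k))) stop("counts must be non-negative integers")
  stats::dpois(k, lam, log = TRUE)
}

# Assemble a full parameter list with defaults for unused entries so the
# C++ evaluator always receives every slot.
normalize_params <- function(spec, params) {
  sh <- spec_shapes(spec)
  need <- c("lambda_sleep", "lambda_awake", "t_sleep", "t_awake")
  if (sh$hyper_rates) need <- c(need, "alpha_lambda", "beta_lambda")
  if (sh$hyper_times) need <- c(need, "alpha_t", "beta_t", "tau_t")
  missing <- setdiff(need, names(params))
  if (length(missing) > 0L) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  }
  chk_len <- function(name, len) {
    if (length(params[[name]]) != len) {
      stop(name, " must have length ", len, " for variant ", spec$variant)
    }
  }
  chk_len("lambda_sleep", 1L)
  chk_len("lambda_awake", sh$lambda_awake)
  chk_len("t_sleep", sh$times)
  chk_len("t_awake", sh$times)
  list(
    lambda_sleep = as.numeric(params$lambda_sleep),
    lambda_awake = as.numeric(params$lambda_awake),
    t_sleep = as.numeric(params$t_sleep),
    t_awake = as.numeric(params$t_awake),
    alpha_lambda = as.numeric(params$alpha_lambda %||% 1),
    beta_lambda = as.numeric(params$beta_lambda %||% 1),
    alpha_t = as.numeric(params$alpha_t %||% 1),
    beta_t = as.numeric(params$beta_t %||% 1),
    tau_t = as.numeric(params$tau_t %||% 1)
  )
}

#' Log joint density of parameters and counts
#'
#' Sum of all prior log densities for the variant plus the Poisson log
#' likelihood of every (day, bin) count under the switchpoint rule.
#' Parameters outside the support (non-positive rates, switchpoints outside
#' `[0, n]`) give `-Inf` rather than an error; shape mismatches are errors.
#'
#' @param spec A [model_spec()].
#' @param params Named list: `lambda_sleep` (scalar), `lambda_awake` (scalar
#'   or length-`m`), `t_sleep`/`t_awake` (scalar or length-`m`), plus
#'   `alpha_lambda`/`beta_lambda` (hyper variants) and
#'   `alpha_t`/`beta_t`/`tau_t` (hyper-hyper).
#' @param counts A [binned_counts()] object or an `m x n` count matrix.
#' @return Log density (scalar), `-Inf` outside the support.
#' @export
log_joint <- function(spec, params, counts) {
  cm <- if (inherits(counts, "binned_counts")) counts$counts else
    as.matrix(counts)
  storage.mode(cm) <- "integer"
  if (nrow(cm) != spec$m || ncol(cm) != spec$n) {
    stop("counts must be ", spec$m, " x ", spec$n, " for this spec")
  }
  p <- normalize_params(spec, params)
  cpp_log_joint(cm, variant_code(spec$variant), spec_consts(spec),
                p$lambda_sleep, p$lambda_awake, p$t_sleep, p$t_awake,
                p$alpha_lambda, p$beta_lambda, p$alpha_t, p$beta_t, p$tau_t)
}
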