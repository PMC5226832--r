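# MCMC fitting (Metropolis-within-Gibbs), the exact-enumeration posterior
# oracle for the pooled model, trace diagnostics, and trace persistence.

trace_colnames <- function(spec) {
  sh <- spec_shapes(spec)
  la <- if (sh$lambda_awake > 1) sprintf("lambda_awake[%d]", seq_len(spec$m))
        else "lambda_awake"
  ts <- if (sh$times > 1) sprintf("t_sleep[%d]", seq_len(spec$m)) else "t_sleep"
  ta <- if (sh$times > 1) sprintf("t_awake[%d]", seq_len(spec$m)) else "t_awake"
  c("lambda_sleep", la, ts, ta,
    if (sh$hyper_rates) c("alpha_lambda", "beta_lambda"),
    if (sh$hyper_times) c("alpha_t", "beta_t", "tau_t"))
}

default_init <- function(spec, overdisperse = FALSE) {
  cst <- spec_consts(spec)
  sh <- spec_shapes(spec)
  discrete <- !sh$hyper_times
  ts0 <- rep(cst$tsleep_center_bin, sh$times)
  ta0 <- rep(cst$tawake_center_bin, sh$times)
  ls0 <- 1 / spec$sleep_rate_prior_rate
  la0 <- rep(spec$awake_gamma_shape / spec$awake_gamma_rate, sh$lambda_awake)
  hy <- 1
  if (overdisperse) {
    jit <- if (discrete) sample(-8:8, sh$times, replace = TRUE) * 1.0
           else rnorm(sh$times, 0, 4)
    ts0 <- pmin(pmax(ts0 + jit, 0), spec$n)
    jit <- if (discrete) sample(-8:8, sh$times, replace = TRUE) * 1.0
           else rnorm(sh$times, 0, 4)
    ta0 <- pmin(pmax(ta0 + jit, 0), spec$n)
    ls0 <- ls0 * exp(rnorm(1, 0, 1))
    la0 <- la0 * exp(rnorm(sh$lambda_awake, 0, 0.5))
    hy <- exp(rnorm(1, 0, 0.5))
  }
  list(lambda_sleep = ls0, lambda_awake = la0, t_sleep = ts0, t_awake = ta0,
       alpha_lambda = hy, beta_lambda = hy, alpha_t = hy, beta_t = hy,
       tau_t = hy)
}

#' Fit a sleep switchpoint model by MCMC
#'
#' Metropolis-within-Gibbs sampling: discrete switchpoints move by bounded
#' integer random walks with occasional uniform restarts (so any bin in
#' `{0, ..., n}` is reachable), positive parameters by log-scale Gaussian
#' random walks whose step sizes adapt toward 44% acceptance during
#' burn-in, and the hyper-hyper continuous switchpoints by a Gaussian walk.
#' Chains run sequentially from deterministic per-chain seeds
#' (`seed + 100003 * (chain - 1)`); chains beyond the first start from
#' overdispersed initial values.  The same seed and inputs reproduce the
#' trace exactly.
#'
#' @param counts A [binned_counts()] object or `m x n` count matrix.
#' @param variant Model variant (see [model_spec()]).
#' @param n_samples Retained samples per chain.
#' @param burn_in Discarded tuning iterations per chain.
#' @param chains Number of chains.
#' @param seed Master integer seed.
#' @param spec Optional [model_spec()] (overrides `variant`).
#' @param fixed Optional named list clamping `t_sleep`/`t_awake` at given
#'   values (scalar or per-day); used for conjugacy checks.
#' @param init Optional initial values (named list as in
#'   [log_joint()] `params`); defaults to prior centers.
#' @return A `sleep_fit` object: matrix `samples` (rows = retained samples
#'   across chains, named columns), per-sample log joint `logp`, `chain`
#'   ids, the `spec`, the `counts`, and sampler metadata.
#' @export
fit_sleep_model <- function(counts, variant = "hyper-hyper",
                            n_samples = 5000, burn_in = 2000, chains = 2,
                            seed = 1, spec = NULL, fixed = list(),
                            init = NULL) {
  if (!inherits(counts, "binned_counts")) {
    counts <- binned_counts("user",
                            seq(as.Date("2000-01-01"), by = "day",
                                length.out = nrow(as.matrix(counts))),
                            as.matrix(counts),
                            bin_minutes = 24 * 60 / ncol(as.matrix(counts)))
  }
  cm <- counts$counts
  if (is.null(spec)) {
    spec <- model_spec(variant, m = nrow(cm), n = ncol(cm),
                       bin_minutes = counts$bin_minutes)
  }
  stopifnot(n_samples >= 1, nrow(cm) == spec$m, ncol(cm) == spec$n)
  vc <- variant_code(spec$variant)
  cst <- spec_consts(spec)

  all_samples <- vector("list", chains)
  all_logp <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed((seed + 100003 * (ch - 1)) %% 2147483647L)
    ini <- NULL
    for (try in 1:20) {
      cand <- init %||% default_init(spec, overdisperse = (ch > 1 || try > 1))
      lp0 <- log_joint(spec, cand, counts)
      if (is.finite(lp0)) { ini <- cand; break }
    }
    if (is.null(ini)) stop("could not find a finite-density initialization")
    res <- cpp_sample(cm, vc, cst, as.integer(n_samples),
                      as.integer(burn_in), normalize_params(spec, ini), fixed)
    all_samples[[ch]] <- res$samples
    all_logp[[ch]] <- res$logp
  }
  samples <- do.call(rbind, all_samples)
  colnames(samples) <- trace_colnames(spec)
  structure(
    list(samples = samples, logp = unlist(all_logp),
         chain = rep(seq_len(chains), each = n_samples),
         spec = spec, counts = counts, seed = seed, chains = chains,
         n_samples = as.integer(n_samples), burn_in = as.integer(burn_in),
         fixed = fixed),
    class = "sleep_fit"
  )
}

#' @export
print.sleep_fit <- function(x, ...) {
  cat("<sleep_fit>", x$spec$variant, "- user", x$counts$user_id, "-",
      nrow(x$samples), "samples (", x$chains, "chains ),",
      "mean logp", round(mean(x$logp), 1), "\n")
  invisible(x)
}

# Extract the sample matrix for one parameter family, broadcasting pooled
# parameters across days when broadcast = TRUE.
fit_par_matrix <- function(fit, par, broadcast = FALSE) {
  cn <- colnames(fit$samples)
  cols <- cn == par | startsWith(cn, paste0(par, "["))
  mat <- fit$samples[, cols, drop = FALSE]
  if (broadcast && ncol(mat) == 1L && fit$spec$m > 1L) {
    mat <- mat[, rep(1L, fit$spec$m), drop = FALSE]
  }
  mat
}

#' Recompute the log joint density along a trace
#'
#' Per-sample log joint recomputed from the stored parameter values: prior
#' terms are evaluated in R (`dexp`/`dgamma`/`dnorm`) and added to the
#' Poisson likelihood.  Matches the sampler's stored `logp` to numerical
#' tolerance, providing a self-consistency check on the trace.
#'
#' @param fit A `sleep_fit`.
#' @return Numeric vector, one log density per retained sample.
#' @export
trace_logp <- function(fit) {
  spec <- fit$spec
  sh <- spec_shapes(spec)
  cst <- spec_consts(spec)
  ls <- fit$samples[, "lambda_sleep"]
  la <- fit_par_matrix(fit, "lambda_awake")
  ts <- fit_par_matrix(fit, "t_sleep")
  ta <- fit_par_matrix(fit, "t_awake")
  ll <- cpp_loglik_trace(fit$counts$counts, ls, la, ts, ta)

  lp <- stats::dexp(ls, rate = spec$sleep_rate_prior_rate, log = TRUE)
  if (sh$hyper_rates) {
    al <- fit$samples[, "alpha_lambda"]
    bl <- fit$samples[, "beta_lambda"]
    lp <- lp + stats::dexp(al, spec$hyper_exp_rate, log = TRUE) +
      stats::dexp(bl, spec$hyper_exp_rate, log = TRUE)
    for (j in seq_len(ncol(la))) {
      lp <- lp + stats::dgamma(la[, j], shape = al, rate = bl, log = TRUE)
    }
  } else {
    for (j in seq_len(ncol(la))) {
      lp <- lp + stats::dgamma(la[, j], shape = spec$awake_gamma_shape,
                               rate = spec$awake_gamma_rate, log = TRUE)
    }
  }
  if (sh$hyper_times) {
    at <- fit$samples[, "alpha_t"]
    bt <- fit$samples[, "beta_t"]
    tau <- fit$samples[, "tau_t"]
    lp <- lp + stats::dexp(at, spec$hyper_exp_rate, log = TRUE) +
      stats::dexp(bt, spec$hyper_exp_rate, log = TRUE) +
      stats::dgamma(tau, shape = at, rate = bt, log = TRUE)
    for (j in seq_len(ncol(ts))) {
      lp <- lp + stats::dnorm(ts[, j], cst$tsleep_center_bin,
                              1 / sqrt(tau), log = TRUE) +
        stats::dnorm(ta[, j], cst$tawake_center_bin, 1 / sqrt(tau),
                     log = TRUE)
    }
  } else {
    lp <- lp - (ncol(ts) + ncol(ta)) * log(spec$n + 1)
  }
  as.numeric(lp + ll)
}

#' Exact switchpoint posterior by grid enumeration (pooled model only)
#'
#' Enumerates the full `(n+1) x (n+1)` grid of `(t_sleep, t_awake)` values
#' for the pooled-pooled model.  With `lambda = NULL` (default) the two
#' rates are integrated out analytically through Gamma-Poisson conjugacy
#' (the Exponential sleep-rate prior is Gamma(1, rate)); otherwise the
#' likelihood is evaluated at the fixed `c(lambda_sleep, lambda_awake)`
#' pair.  Serves as an independent oracle for the MCMC sampler.
#'
#' @param counts A [binned_counts()] object or count matrix.
#' @param lambda `NULL`, or fixed rates `c(lambda_sleep, lambda_awake)`.
#' @param spec Optional pooled-pooled [model_spec()] supplying prior
#'   constants; hierarchical variants are rejected.
#' @return A `switchpoint_posterior`: list with `prob`, an `(n+1) x (n+1)`
#'   matrix (rows `t_sleep`, columns `t_awake`) summing to 1.
#' @export
exact_switchpoint_posterior <- function(counts, lambda = NULL, spec = NULL) {
  cm <- if (inherits(counts, "binned_counts")) counts$counts else
    as.matrix(counts)
  m <- nrow(cm); n <- ncol(cm)
  if (is.null(spec)) spec <- model_spec("pooled-pooled", m = m, n = n)
  if (spec$variant != "pooled-pooled") {
    stop("exact enumeration supports only the pooled-pooled variant")
  }
  P <- c(0, cumsum(colSums(cm)))
  Ktot <- sum(cm)
  ts_g <- rep(0:n, times = n + 1)
  ta_g <- rep(0:n, each = n + 1)
  hi <- pmin(ta_g - 1, n - 1)
  len <- pmax(hi - ts_g + 1, 0)
  Ks <- ifelse(len > 0, P[pmax(hi, 0) + 2] - P[pmin(ts_g, n - 1) + 1], 0)
  Ns <- m * len
  Ka <- Ktot - Ks
  Na <- m * n - Ns
  if (is.null(lambda)) {
    a_s <- 1; b_s <- spec$sleep_rate_prior_rate
    a_a <- spec$awake_gamma_shape; b_a <- spec$awake_gamma_rate
    logw <- lgamma(a_s + Ks) - (a_s + Ks) * log(b_s + Ns) +
      lgamma(a_a + Ka) - (a_a + Ka) * log(b_a + Na)
  } else {
    stopifnot(length(lambda) == 2, all(lambda > 0))
    logw <- Ks * log(lambda[1]) - Ns * lambda[1] +
      Ka * log(lambda[2]) - Na * lambda[2]
  }
  prob <- exp(logw - logsumexp(logw))
  prob <- prob / sum(prob)
  mat <- matrix(prob, nrow = n + 1, ncol = n + 1,
                dimnames = list(t_sleep = 0:n, t_awake = 0:n))
  structure(list(prob = mat, n = n, m = m), class = "switchpoint_posterior")
}

#' @export
print.switchpoint_posterior <- function(x, ...) {
  top <- which(x$prob == max(x$prob), arr.ind = TRUE)[1, ]
  cat("<switchpoint_posterior>", x$n + 1, "x", x$n + 1, "grid; mode (t_sleep,",
      "t_awake) = (", top[1] - 1, ",", top[2] - 1, ") with prob",
      signif(max(x$prob), 3), "\n")
  invisible(x)
}

#' Tidy an enumerated switchpoint posterior
#'
#' @param x A `switchpoint_posterior`.
#' @param ... Unused.
#' @return Tibble with columns `t_sleep`, `t_awake`, `prob`.
#' @export
tidy.switchpoint_posterior <- function(x, ...) {
  tibble::tibble(
    t_sleep = rep(0:x$n, times = x$n + 1),
    t_awake = rep(0:x$n, each = x$n + 1),
    prob = as.numeric(x$prob)
  )
}

#' Split-half R-hat convergence diagnostic
#'
#' Gelman-Rubin potential scale reduction factor with each chain split in
#' half, computed for the continuous parameters of a fit.
#'
#' @param fit A `sleep_fit`.
#' @return Tibble with columns `parameter`, `rhat`.
#' @export
rhat <- function(fit) {
  cn <- colnames(fit$samples)
  discrete <- variant_code(fit$spec$variant) <= 3
  keep <- if (discrete) !grepl("^t_(sleep|awake)", cn) else rep(TRUE, length(cn))
  half <- fit$n_samples %/% 2
  split_id <- interaction(fit$chain,
                          rep(rep(1:2, each = half, length.out = fit$n_samples),
                              fit$chains))
  vals <- vapply(which(keep), function(j) {
    x <- fit$samples[, j]
    groups <- split(x, split_id)
    groups <- groups[lengths(groups) > 1]
    nn <- min(lengths(groups))
    groups <- lapply(groups, function(g) g[seq_len(nn)])
    means <- vapply(groups, mean, numeric(1))
    vars <- vapply(groups, stats::var, numeric(1))
    W <- mean(vars)
    B <- nn * stats::var(means)
    if (W <= 0) return(1)
    sqrt(((nn - 1) / nn * W + B / nn) / W)
  }, numeric(1))
  tibble::tibble(parameter = cn[keep], rhat = vals)
}

#' Persist a fitted trace to a directory
#'
#' Writes `samples.csv` (one column per parameter plus `chain`), `logp.csv`,
#' `counts.csv`, and `meta.json` (variant, seed, sampler settings, day
#' labels) — enough to resume downstream stages without refitting.
#'
#' @param fit A `sleep_fit`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trace <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- tibble::as_tibble(fit$samples)
  df$chain <- fit$chain
  readr::write_csv(df, file.path(dir, "samples.csv"))
  readr::write_csv(tibble::tibble(logp = fit$logp),
                   file.path(dir, "logp.csv"))
  write_binned_counts(fit$counts, file.path(dir, "counts.csv"))
  meta <- list(
    user_id = fit$counts$user_id,
    day_labels = format(fit$counts$day_labels),
    tz = fit$counts$tz,
    window_start_hour = fit$counts$window_start_hour,
    spec = as_spec_config(fit$spec),
    seed = fit$seed, chains = fit$chains,
    n_samples = fit$n_samples, burn_in = fit$burn_in,
    status = "done"
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Reload a trace written by [write_trace()]
#'
#' @param dir Directory containing the persisted trace.
#' @return A `sleep_fit`.
#' @export
read_trace <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  df <- readr::read_csv(file.path(dir, "samples.csv"),
                        show_col_types = FALSE, progress = FALSE)
  logp <- readr::read_csv(file.path(dir, "logp.csv"),
                          show_col_types = FALSE, progress = FALSE)$logp
  spec <- spec_from_config(meta$spec)
  counts <- read_binned_counts(file.path(dir, "counts.csv"),
                               user_id = meta$user_id,
                               bin_minutes = spec$bin_minutes,
                               window_start_hour = meta$window_start_hour,
                               tz = meta$tz)
  chain <- df$chain
  samples <- as.matrix(df[, setdiff(names(df), "chain"), drop = FALSE])
  structure(
    list(samples = samples, logp = logp, chain = chain, spec = spec,
         counts = counts, seed = meta$seed, chains = meta$chains,
         n_samples = meta$n_samples, burn_in = meta$burn_in, fixed = list()),
    class = "sleep_fit"
  )
}
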