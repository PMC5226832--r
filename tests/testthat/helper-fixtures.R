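# Shared fixtures: hand-built counts, events, degenerate fits, and an
# independent brute-force log-joint oracle coded term by term in R.

posix <- function(x, tz = "UTC") as.numeric(as.POSIXct(x, tz = tz))

# counts object from a plain matrix
make_counts <- function(mat, user_id = "u", start = as.Date("2013-11-04")) {
  mat <- as.matrix(mat)
  binned_counts(user_id,
                seq(start, by = "day", length.out = nrow(mat)),
                mat, bin_minutes = 24 * 60 / ncol(mat))
}

# a sleep_fit with hand-specified posterior samples (pooled layout)
fake_pooled_fit <- function(t_sleep, t_awake, lambda_sleep = 1e-4,
                            lambda_awake = 5, counts = NULL, m = 3) {
  if (is.null(counts)) counts <- make_counts(matrix(0L, m, 96))
  S <- max(length(t_sleep), length(t_awake))
  samples <- cbind(
    lambda_sleep = rep_len(lambda_sleep, S),
    lambda_awake = rep_len(lambda_awake, S),
    t_sleep = rep_len(t_sleep, S),
    t_awake = rep_len(t_awake, S)
  )
  spec <- model_spec("pooled-pooled", m = nrow(counts$counts),
                     n = ncol(counts$counts))
  structure(
    list(samples = samples, logp = rep(0, S), chain = rep(1L, S),
         spec = spec, counts = counts, seed = 1L, chains = 1L,
         n_samples = S, burn_in = 0L, fixed = list()),
    class = "sleep_fit")
}

# term-by-term log joint, independent of the package's evaluator
oracle_log_joint <- function(spec, params, counts_mat) {
  n <- spec$n
  m <- spec$m
  v <- spec$variant
  la <- rep_len(params$lambda_awake, m)
  ts <- rep_len(params$t_sleep, m)
  ta <- rep_len(params$t_awake, m)
  ls <- params$lambda_sleep
  lp <- dexp(ls, rate = spec$sleep_rate_prior_rate, log = TRUE)
  if (v %in% c("independent-hyper", "hyper-hyper")) {
    lp <- lp + dexp(params$alpha_lambda, spec$hyper_exp_rate, log = TRUE) +
      dexp(params$beta_lambda, spec$hyper_exp_rate, log = TRUE) +
      sum(dgamma(la, shape = params$alpha_lambda,
                 rate = params$beta_lambda, log = TRUE))
  } else {
    n_la <- if (v == "independent-independent") m else 1
    lp <- lp + sum(dgamma(rep_len(params$lambda_awake, n_la),
                          shape = spec$awake_gamma_shape,
                          rate = spec$awake_gamma_rate, log = TRUE))
  }
  if (v == "hyper-hyper") {
    tau <- params$tau_t
    lp <- lp + dexp(params$alpha_t, spec$hyper_exp_rate, log = TRUE) +
      dexp(params$beta_t, spec$hyper_exp_rate, log = TRUE) +
      dgamma(tau, shape = params$alpha_t, rate = params$beta_t, log = TRUE) +
      sum(dnorm(ts, spec$tsleep_center_hours * n / 24, 1 / sqrt(tau),
                log = TRUE)) +
      sum(dnorm(ta, spec$tawake_center_hours * n / 24, 1 / sqrt(tau),
                log = TRUE))
  } else {
    n_t <- if (v == "pooled-pooled") 1 else m
    lp <- lp - 2 * n_t * log(n + 1)
  }
  for (i in seq_len(m)) {
    for (t in 0:(n - 1)) {
      lam <- if (ts[i] <= t && t < ta[i]) ls else la[i]
      lp <- lp + dpois(counts_mat[i, t + 1], lam, log = TRUE)
    }
  }
  lp
}

# batch-means Monte Carlo standard error (accounts for autocorrelation)
mcmc_se <- function(x, n_batches = 20) {
  nb <- floor(length(x) / n_batches)
  bm <- vapply(seq_len(n_batches),
               function(b) mean(x[((b - 1) * nb + 1):(b * nb)]), numeric(1))
  sd(bm) / sqrt(n_batches)
}
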