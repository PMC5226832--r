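test_that("rate_at follows the half-open switchpoint rule", {
  expect_equal(rate_at(50, 30, 60, 1e-4, 2.5), 1e-4)
  expect_equal(rate_at(60, 30, 60, 1e-4, 2.5), 2.5)   # t = t_awake is awake
  expect_equal(rate_at(30, 30, 60, 1e-4, 2.5), 1e-4)  # t = t_sleep is asleep
  # empty sleep interval when t_sleep >= t_awake
  expect_true(all(rate_at(0:95, 60, 30, 1e-4, 2.5) == 2.5))
  # vectorized over bins
  r <- rate_at(0:95, 28, 60, 1e-4, 5)
  expect_equal(sum(r == 1e-4), 32)
})

test_that("poisson_log_pmf matches direct evaluation and guards its domain", {
  expect_equal(poisson_log_pmf(0, 2.5), -2.5)
  expect_equal(poisson_log_pmf(1, 1.0), -1.0)
  expect_equal(poisson_log_pmf(3, 2.5), log(2.5^3 * exp(-2.5) / 6))
  expect_error(poisson_log_pmf(1, 0), "rate")
  expect_error(poisson_log_pmf(-1, 1), "non-negative")
})

test_that("poisson pmf sums to one over the support", {
  for (lam in c(0.1, 1, 5, 10)) {
    total <- sum(exp(poisson_log_pmf(0:200, lam)))
    expect_lt(abs(total - 1), 1e-9)
  }
})

test_that("log_joint equals an independent term-by-term summation", {
  set.seed(11)
  m <- 3; n <- 96
  cm <- matrix(rpois(m * n, 2), m, n)
  counts <- make_counts(cm)
  params_for <- function(variant) {
    per_day <- variant != "pooled-pooled"
    list(
      lambda_sleep = 2e-4,
      lambda_awake = if (variant %in% c("independent-independent",
                                        "independent-hyper", "hyper-hyper"))
        c(2.1, 5.3, 3.3) else 2.6,
      t_sleep = if (per_day) c(30, 28, 33) else 31,
      t_awake = if (per_day) c(58, 61, 60) else 59,
      alpha_lambda = 1.7, beta_lambda = 0.6,
      alpha_t = 1.2, beta_t = 0.9, tau_t = 0.25
    )
  }
  for (v in c("pooled-pooled", "independent-pooled",
              "independent-independent", "independent-hyper",
              "hyper-hyper")) {
    spec <- model_spec(v, m = m, n = n)
    p <- params_for(v)
    expect_equal(log_joint(spec, p, counts),
                 oracle_log_joint(spec, p, cm),
                 tolerance = 1e-10, label = v)
  }
})

test_that("log_joint returns -Inf outside the support, errors on bad shapes", {
  counts <- make_counts(matrix(1L, 2, 96))
  spec <- model_spec("pooled-pooled", m = 2)
  base <- list(lambda_sleep = 1e-4, lambda_awake = 2, t_sleep = 30,
               t_awake = 60)
  expect_true(is.finite(log_joint(spec, base, counts)))
  expect_identical(log_joint(spec, modifyList(base, list(lambda_awake = -1)),
                             counts), -Inf)
  expect_identical(log_joint(spec, modifyList(base, list(t_sleep = 97)),
                             counts), -Inf)
  expect_error(log_joint(spec, modifyList(base, list(t_sleep = c(1, 2))),
                         counts), "length")
  expect_error(log_joint(model_spec("pooled-pooled", m = 5), base, counts),
               "counts")
})

test_that("matched day-level parameters leave only prior terms different", {
  # hyper-hyper and independent-independent share the Poisson likelihood
  # when their per-day values coincide
  set.seed(12)
  m <- 4
  cm <- matrix(rpois(m * 96, 3), m, 96)
  counts <- make_counts(cm)
  shared <- list(lambda_sleep = 1e-4, lambda_awake = c(3, 4, 5, 6),
                 t_sleep = c(30, 31, 29, 32), t_awake = c(58, 60, 61, 59))
  hh <- c(shared, list(alpha_lambda = 2, beta_lambda = 0.5,
                       alpha_t = 1, beta_t = 1, tau_t = 0.3))
  spec_ii <- model_spec("independent-independent", m = m)
  spec_hh <- model_spec("hyper-hyper", m = m)
  lik <- function(spec, p) {
    # subtracting the all-zero-data evaluation isolates count-dependent terms
    log_joint(spec, p, counts) -
      log_joint(spec, p, make_counts(matrix(0L, m, 96)))
  }
  expect_equal(lik(spec_ii, shared), lik(spec_hh, hh), tolerance = 1e-8)
})

test_that("clamped-switchpoint log-joint differences match Gamma conjugacy", {
  set.seed(13)
  cm <- matrix(rpois(2 * 96, 4), 2, 96)
  cm[, 29:60] <- 0L
  counts <- make_counts(cm)
  spec <- model_spec("pooled-pooled", m = 2)
  ts <- 28; ta <- 60
  Ka <- sum(cm[, -(29:60)])
  Na <- 2 * (96 - 32)
  post_shape <- spec$awake_gamma_shape + Ka
  post_rate <- spec$awake_gamma_rate + Na
  p1 <- list(lambda_sleep = 1e-4, lambda_awake = 3.8, t_sleep = ts,
             t_awake = ta)
  p2 <- modifyList(p1, list(lambda_awake = 4.6))
  lhs <- log_joint(spec, p1, counts) - log_joint(spec, p2, counts)
  rhs <- dgamma(3.8, post_shape, post_rate, log = TRUE) -
    dgamma(4.6, post_shape, post_rate, log = TRUE)
  expect_equal(lhs, rhs, tolerance = 1e-8)
})

test_that("model specs round-trip through plain config lists", {
  spec <- model_spec("independent-hyper", m = 7, tsleep_center_hours = 7)
  back <- spec_from_config(as_spec_config(spec))
  expect_equal(back, spec)
})
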