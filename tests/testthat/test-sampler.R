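test_that("identical seeds and inputs reproduce the trace exactly", {
  u <- simulate_user(sleep_scenario(m_days = 4), seed = 2)
  f1 <- fit_sleep_model(u$counts, "independent-hyper", n_samples = 200,
                        burn_in = 100, chains = 2, seed = 7)
  f2 <- fit_sleep_model(u$counts, "independent-hyper", n_samples = 200,
                        burn_in = 100, chains = 2, seed = 7)
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$logp, f2$logp)
  f3 <- fit_sleep_model(u$counts, "independent-hyper", n_samples = 200,
                        burn_in = 100, chains = 2, seed = 8)
  expect_false(identical(f1$samples, f3$samples))
})

test_that("exact enumeration is normalized and spreads under flat counts", {
  flat <- make_counts(matrix(2L, 2, 96))
  ex <- exact_switchpoint_posterior(flat)
  expect_lt(abs(sum(ex$prob) - 1), 1e-12)
  expect_lt(max(ex$prob), 0.5)
  td <- tidy(ex)
  expect_equal(nrow(td), 97 * 97)
  expect_lt(abs(sum(td$prob) - 1), 1e-12)
})

test_that("enumeration mode recovers a clean switchpoint pair", {
  set.seed(21)
  cm <- t(replicate(2, {
    x <- rpois(96, 5)
    x[29:60] <- 0L
    x
  }))
  ex <- exact_switchpoint_posterior(make_counts(cm), lambda = c(1e-4, 5))
  am <- which(ex$prob == max(ex$prob), arr.ind = TRUE)
  expect_equal(unname(am[1, ]) - 1L, c(28L, 60L))
  expect_error(
    exact_switchpoint_posterior(make_counts(cm),
                                spec = model_spec("hyper-hyper", m = 2)),
    "pooled-pooled")
})

test_that("MCMC switchpoint marginals agree with exact enumeration", {
  u <- simulate_user(sleep_scenario(m_days = 2, t_sleep = 28, t_awake = 60,
                                    lambda_awake = 5), seed = 42)
  fit <- fit_sleep_model(u$counts, "pooled-pooled", n_samples = 5000,
                         burn_in = 1000, chains = 2, seed = 3)
  ex <- exact_switchpoint_posterior(u$counts)
  emp <- table(factor(fit$samples[, "t_sleep"], levels = 0:96),
               factor(fit$samples[, "t_awake"], levels = 0:96)) /
    nrow(fit$samples)
  tv <- 0.5 * sum(abs(emp - ex$prob))
  expect_lt(tv, 0.05)
})

test_that("pooled fit recovers strongly separated switchpoints within a bin", {
  u <- simulate_user(sleep_scenario(m_days = 14, t_sleep = 28, t_awake = 60,
                                    lambda_awake = 5), seed = 1)
  fit <- fit_sleep_model(u$counts, "pooled-pooled", n_samples = 2000,
                         burn_in = 1000, chains = 2, seed = 1)
  expect_lt(abs(mean(fit$samples[, "t_sleep"]) - 28), 1)
  expect_lt(abs(mean(fit$samples[, "t_awake"]) - 60), 1)
})

test_that("stored logp matches recomputation and ranks true above shuffled", {
  u <- simulate_user(sleep_scenario(m_days = 3, lambda_awake = 6), seed = 5)
  fit <- fit_sleep_model(u$counts, "independent-independent",
                         n_samples = 300, burn_in = 200, chains = 1, seed = 2)
  expect_lt(max(abs(trace_logp(fit) - fit$logp)), 1e-8)

  spec <- model_spec("independent-independent", m = 3)
  truth <- list(lambda_sleep = 1e-4, lambda_awake = u$truth_tbl$lambda_awake,
                t_sleep = u$truth_tbl$t_sleep, t_awake = u$truth_tbl$t_awake)
  shuffled <- modifyList(truth, list(t_sleep = truth$t_awake %% 96,
                                     t_awake = truth$t_sleep))
  expect_gt(log_joint(spec, truth, u$counts),
            log_joint(spec, shuffled, u$counts))
})

test_that("clamped-switchpoint rate samples match the conjugate posterior", {
  u <- simulate_user(sleep_scenario(m_days = 5, t_sleep = 28, t_awake = 60,
                                    lambda_awake = 5), seed = 9)
  fit <- fit_sleep_model(u$counts, "pooled-pooled", n_samples = 4000,
                         burn_in = 1000, chains = 1, seed = 4,
                         fixed = list(t_sleep = 28, t_awake = 60))
  cm <- u$counts$counts
  Ka <- sum(cm[, -(29:60)])
  Na <- 5 * (96 - 32)
  closed_form <- (2.5 + Ka) / (1 + Na)
  la <- fit$samples[, "lambda_awake"]
  expect_lt(abs(mean(la) - closed_form), 3 * mcmc_se(la))
  # spread agrees too (generous band; SE of an SD is larger)
  expect_lt(abs(sd(la) - sqrt(2.5 + Ka) / (1 + Na)), 0.1 * sd(la) + 6 * mcmc_se(la))
})

test_that("overdispersed chains converge (split R-hat < 1.05)", {
  u <- simulate_user(sleep_scenario(m_days = 7, lambda_awake = 5), seed = 6)
  fit <- fit_sleep_model(u$counts, "hyper-hyper", n_samples = 5000,
                         burn_in = 2000, chains = 2, seed = 11)
  r <- rhat(fit)
  expect_true(all(is.finite(r$rhat)))
  expect_lt(max(r$rhat), 1.05)
})

test_that("traces persist and reload losslessly", {
  u <- simulate_user(sleep_scenario(m_days = 3), seed = 3)
  fit <- fit_sleep_model(u$counts, "hyper-hyper", n_samples = 150,
                         burn_in = 100, chains = 2, seed = 5)
  dir <- withr::local_tempdir()
  write_trace(fit, dir)
  back <- read_trace(dir)
  expect_equal(unname(back$samples), unname(fit$samples), tolerance = 1e-12)
  expect_equal(back$logp, fit$logp, tolerance = 1e-12)
  expect_identical(back$counts$counts, fit$counts$counts)
  expect_equal(back$spec, fit$spec)
})
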