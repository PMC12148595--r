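# fast fitting settings for small synthetic studies
fit_small <- function(r, ...) {
  fit_cumulative_probit(r, "moving", chains = 2, iter = 400, warmup = 300,
                        ...)
}

test_that("a null modality effect is recovered as a null", {
  r <- small_study(101, n_subjects = 12, n_stimuli_per_type = 8,
                   effects = effect_spec(beta_modality = 0, beta_type = 0,
                                         kappa = 0))
  fit <- fit_small(r, seed = 5)
  s <- summary(fit)
  b <- s[s$parameter == "beta_modality", ]
  expect_gt(b$q97.5, 0)
  expect_lt(b$q2.5, 0)
})

test_that("thresholds are ordered in every draw even from unordered inits", {
  r <- small_study(102)
  fit <- suppressWarnings(
    fit_small(r, seed = 2, init = list(tau = c(2, -1, 0, 3, -2, 1))))
  taus <- apply(fit$draws[, , grep("^tau", fit$parameters)], c(1, 2),
                function(x) all(diff(x) > 0))
  expect_true(all(taus))
})

test_that("degenerate single-category data raise an error", {
  r <- small_study(103)
  r$moving <- 4L
  expect_error(fit_cumulative_probit(r, "moving"), "one response category")
  r2 <- small_study(104)[1:4, ]
  r2$subject_id <- "S01"
  r2$stimulus_id <- paste0("A0", 1:4)
  expect_error(fit_cumulative_probit(r2, "moving"), "2 subjects")
})

test_that("posterior intervals shrink with the amount of data", {
  e <- effect_spec(beta_modality = -0.3, kappa = 0)
  r_small <- small_study(105, n_subjects = 5, n_stimuli_per_type = 10,
                         effects = e)   # 200 trials
  r_large <- small_study(106, n_subjects = 20, n_stimuli_per_type = 25,
                         effects = e)   # 2000 trials
  f1 <- suppressWarnings(fit_small(r_small, seed = 3))
  f2 <- suppressWarnings(fit_small(r_large, seed = 3))
  sd1 <- summary(f1)[1, "sd"]
  sd2 <- summary(f2)[1, "sd"]
  expect_lt(sd2, sd1)
})

test_that("diagnostics agree with the coda reference implementation", {
  skip_if_not_installed("coda")
  r <- small_study(107)
  fit <- suppressWarnings(fit_small(r, seed = 9))
  x <- fit$draws[, , "beta_modality"]
  cl <- coda::mcmc.list(lapply(seq_len(ncol(x)), function(ch) {
    coda::mcmc(x[, ch])
  }))
  gd <- coda::gelman.diag(cl, autoburnin = FALSE)$psrf[1, 1]
  expect_lt(abs(split_rhat(x) - gd), 0.06)
  ce <- coda::effectiveSize(cl)
  expect_gt(ess_basic(x) / max(ce, 1), 0.4)
  expect_lt(ess_basic(x) / max(ce, 1), 2.5)
})

test_that("interval coverage is calibrated under the prior-predictive", {
  # draw the modality effect from its prior, simulate, refit, and check
  # that 95% intervals cover the truth at roughly the nominal rate
  set.seed(42)
  n_rep <- 50
  covered <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    beta <- rnorm(1)
    r <- small_study(200 + i, n_subjects = 8, n_stimuli_per_type = 5,
                     effects = effect_spec(beta_modality = beta,
                                           beta_type = 0, kappa = 0,
                                           sd_subject = 0.3,
                                           sd_stimulus = 0.3))
    fit <- suppressWarnings(
      fit_cumulative_probit(r, "moving", chains = 2, iter = 350,
                            warmup = 250, seed = 300 + i))
    s <- summary(fit)
    b <- s[s$parameter == "beta_modality", ]
    covered[i] <- beta >= b$q2.5 && beta <= b$q97.5
  }
  # binomial(50, .95): >= 42 successes covers all but ~0.4% of runs
  expect_gte(sum(covered), 42)
})
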