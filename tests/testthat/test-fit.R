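test_that("the log-likelihood kernel matches hand arithmetic", {
  expect_equal(log_likelihood(freq_table(c(1, 0)), single_pi_model(2, n = 1), 1), 0)
  expect_equal(log_likelihood(freq_table(c(7, 3)), single_pi_model(2, n = 10), 0.4),
               7 * log(0.7) + 3 * log(0.3), tolerance = 1e-12)
  # zero probability with positive count
  m5 <- single_pi_model(2, n = 5)
  expect_identical(log_likelihood(freq_table(c(0, 5)), m5, 1), -Inf)
  # zero count in a zero-probability cell contributes nothing
  expect_equal(log_likelihood(freq_table(c(5, 0)), m5, 1), 0)
})

test_that("the m = 2 MLE equals the closed form max(0, 2 f1/n - 1)", {
  m <- single_pi_model(2)
  for (f1 in c(5, 6, 7, 9, 10)) {
    fit <- fit_pcm(freq_table(c(f1, 10 - f1)), m)
    expect_equal(unname(fit$theta), max(0, 2 * f1 / 10 - 1), tolerance = 1e-5)
  }
  fit <- fit_pcm(freq_table(c(7, 3)), m)
  expect_equal(fit$gsq, 0, tolerance = 1e-8)
  expect_equal(fit$df, 0L)
  expect_false(any(fit$boundary))
})

test_that("an interior-infeasible sample is clipped to the boundary and flagged", {
  m <- single_pi_model(2)
  fit <- fit_pcm(freq_table(c(3, 7)), m)
  expect_equal(unname(fit$theta), 0)
  expect_true(fit$boundary[["pi"]])
  expect_gt(fit$gsq, 0)
  expect_equal(fit$gsq, 2 * (7 * log(1.4) + 3 * log(0.6)), tolerance = 1e-6)
  expect_equal(fit$ci$method, "profile")
  expect_equal(fit$ci$lower, 0)
})

test_that("a forced-constant model yields the hand-computed G^2 against (5,5)", {
  d <- pcm_design(level = "a", set_size = 2, n = 10)
  cm <- dplyr::mutate(pcm_slots(d), parameter = NA_character_,
                      constant = ifelse(kind == "pi", 0, 0.5))
  m0 <- pcm_model(d, cm)  # S = 0: expected counts (5, 5)
  fit <- fit_pcm(freq_table(c(7, 3)), m0)
  expect_equal(fit$gsq, 1.6457, tolerance = 1e-4)
  expect_equal(fit$df, 1L)
  expect_equal(aic_bic(fit)$AIC, aic_bic(fit)$BIC)
})

test_that("G^2 is zero exactly when observed equals expected", {
  d <- pcm_design(level = "a", set_size = 2, n = 10)
  cm <- dplyr::mutate(pcm_slots(d), parameter = NA_character_,
                      constant = ifelse(kind == "pi", 0, 0.5))
  m0 <- pcm_model(d, cm)
  fit0 <- fit_pcm(freq_table(c(5, 5)), m0)
  expect_equal(fit0$gsq, 0, tolerance = 1e-12)
  expect_equal(fit0$p_value, 1)
  g <- gsq_test(fit0)
  expect_equal(g$gsq, fit0$gsq)
})

test_that("the estimator is consistent at large n", {
  d <- pcm_design(level = c("a", "a"), set_size = c(3, 5), n = c(1e5, 1e5))
  cm <- dplyr::mutate(pcm_slots(d),
                      parameter = ifelse(kind == "pi", "pi", NA),
                      constant = ifelse(kind == "pnew", 0.5, NA))
  m <- pcm_model(d, cm)
  x <- generate_dataset(d, m, 0.510, seed = 77)
  fit <- fit_pcm(x, m)
  expect_lt(abs(unname(fit$theta) - 0.510), 0.01)
  # interval width shrinks roughly like 1/sqrt(n)
  expect_lt(fit$ci$upper - fit$ci$lower, 0.02)
})

test_that("all multistarts agree on the study-scale design (unimodality)", {
  d <- mantonakis_design()
  x <- generate_dataset(d, pcm3_model(d), 0.51, seed = 13)
  fit <- fit_pcm(x, pcm1_model(d), n_starts = 10)
  expect_equal(fit$n_starts_agreeing, 10)
  expect_true(fit$converged)
})

test_that("likelihood-ratio tests respect nesting and are additive along the chain", {
  d <- mantonakis_design()
  x <- generate_dataset(d, pcm3_model(d), 0.51, seed = 21)
  f1 <- fit_pcm(x, pcm1_model(d))
  f2 <- fit_pcm(x, pcm2_model(d))
  f3 <- fit_pcm(x, pcm3_model(d))

  same <- lr_test(f3, f3)
  expect_equal(same$delta_gsq, 0)
  expect_equal(same$p_value, 1)

  t21 <- lr_test(f2, f1)
  t32 <- lr_test(f3, f2)
  expect_equal(t21$delta_df, 6L)
  expect_equal(t32$delta_df, 1L)
  expect_equal(f3$gsq, f1$gsq + t21$delta_gsq + t32$delta_gsq, tolerance = 1e-6)

  expect_error(lr_test(f1, f3), "not nested")
  y <- generate_dataset(d, pcm3_model(d), 0.51, seed = 22)
  expect_error(lr_test(fit_pcm(y, pcm3_model(d)), f2), "different data")
})

test_that("Wald intervals match the binomial delta method at m = 2", {
  m <- single_pi_model(2, n = 100)
  fit <- fit_pcm(freq_table(c(70, 30)), m)
  se <- 2 * sqrt(0.7 * 0.3 / 100)  # 0.09165
  expect_equal(fit$ci$method, "wald")
  expect_equal(fit$ci$lower, 0.4 - qnorm(0.975) * se, tolerance = 2e-3)
  expect_equal(fit$ci$upper, 0.4 + qnorm(0.975) * se, tolerance = 2e-3)
  ci90 <- confidence_intervals(fit, level = 0.90)
  expect_lt(ci90$lower, ci90$upper)
  expect_gt(ci90$lower, fit$ci$lower)
})

test_that("a singular information matrix is reported with the offending direction", {
  m <- fully_free_model(2)  # pi2 and pnew2 trade off: rank 1 < S = 2
  fit <- suppressWarnings(fit_pcm(freq_table(c(7, 3)), m, ci_level = NA))
  expect_error(confidence_intervals(fit), "not identified")
})

test_that("recovering the generating inertia is unbiased to Monte-Carlo error", {
  d <- mantonakis_design()
  m3 <- pcm3_model(d)
  for (truth in c(0.2, 0.8)) {
    r <- recovery_study(d, m3, truth, replicates = 60, seed = 404, n_starts = 3)
    mc_se <- r$parameters$rmse / sqrt(r$replicates)
    expect_lt(abs(r$parameters$bias), 2 * mc_se + 0.01)
  }
})
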