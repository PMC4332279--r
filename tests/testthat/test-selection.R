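test_that("Fisher information has the closed form 1/(1 - pi^2) for the m = 2 model", {
  m <- single_pi_model(2)
  for (p in c(0.001, 0.2, 0.5, 0.9)) {
    expect_equal(fisher_information(m, p)[1, 1], 1 / (1 - p^2), tolerance = 1e-10)
  }
  expect_error(fisher_information(m, 0), "interior")
  expect_error(fisher_information(m, 1), "interior")
})

test_that("information matrices are symmetric positive semi-definite at random probes", {
  set.seed(33)
  d <- mantonakis_design()
  m1 <- pcm1_model(d)
  for (rep in 1:5) {
    theta <- runif(m1$S, 0.05, 0.95)
    info <- fisher_information(m1, theta)
    expect_equal(info, t(info))
    expect_true(all(eigen(info, symmetric = TRUE, only.values = TRUE)$values > -1e-12))
  }
  m3 <- pcm3_model(d)
  expect_gt(fisher_information(m3, 0.4)[1, 1], 0)
})

test_that("MC complexity reproduces the two closed-form integrals", {
  # free-pi m=2 model: integral of 1/sqrt(1-pi^2) is pi/2
  cx <- model_complexity(single_pi_model(2), draws = 40000, seed = 1)
  expect_lt(abs(cx$C - log(pi / 2)), 3 * cx$mc_se)
  # free success probability (binomial): integral of 1/sqrt(p(1-p)) is pi
  cx2 <- model_complexity(free_pnew_binomial(), draws = 40000, seed = 2)
  expect_lt(abs(cx2$C - log(pi)), 3 * cx2$mc_se)
})

test_that("MC complexity estimates converge as draws increase", {
  # sqrt(det I) diverges (integrably) wherever a category probability
  # vanishes, so the integrand is heavy-tailed: the reported standard error
  # still shrinks with draws, though slower than the clean 1/sqrt law
  draws <- c(1e3, 1e4, 1e5)
  res <- lapply(draws, function(dr) model_complexity(free_pnew_binomial(),
                                                     draws = dr, seed = 5))
  ses <- vapply(res, `[[`, 0, "mc_se")
  expect_true(all(diff(ses) < 0))
  expect_gt(ses[1] / ses[3], 3)
  for (r in res) expect_lt(abs(r$C - log(pi)), 4 * r$mc_se)
})

test_that("FIA decomposes into its three components; S = 0 reduces to -lnL", {
  d <- pcm_design(level = "a", set_size = 2, n = 10)
  cm <- dplyr::mutate(pcm_slots(d), parameter = NA_character_,
                      constant = ifelse(kind == "pi", 0.2, 0.5))
  m0 <- pcm_model(d, cm)
  f0 <- fit_pcm(freq_table(c(6, 4)), m0)
  fi0 <- fia(f0)
  expect_equal(fi0$fia, -f0$logLik)
  expect_equal(fi0$complexity, 0)

  m <- single_pi_model(2, n = 50)
  f <- fit_pcm(freq_table(c(35, 15)), m)
  fi <- fia(f, draws = 5000)
  expect_equal(fi$fia, fi$minus_log_lik + fi$dimension_term + fi$complexity)
  expect_equal(fi$dimension_term, 0.5 * log(50 / (2 * pi)))
})

test_that("FIA weights normalise evidence as exp(-delta FIA)", {
  w <- fia_weights(c(166.4, 165.4, 163.8))
  expect_equal(sum(w), 1, tolerance = 1e-10)
  expect_equal(w, c(0.0582, 0.1582, 0.7836), tolerance = 1e-3)
  expect_equal(fia_weights(c(3, 3, 3)), rep(1 / 3, 3))
  expect_equal(fia_weights(c(0, log(2))), c(2 / 3, 1 / 3), tolerance = 1e-12)
  # invariance to a constant shift
  expect_equal(fia_weights(c(166.4, 165.4, 163.8) + 100), w)
  expect_error(fia_weights(numeric(0)), "no FIA")
  expect_error(fia_weights(c(1, Inf)), "finite")
})

test_that("AIC/BIC use the kernel deviance and parameter counts", {
  d <- mantonakis_design()
  x <- generate_dataset(d, pcm3_model(d), 0.51, seed = 31)
  f1 <- fit_pcm(x, pcm1_model(d), ci_level = NA)
  f3 <- fit_pcm(x, pcm3_model(d), ci_level = NA)
  ab1 <- aic_bic(f1); ab3 <- aic_bic(f3)
  expect_equal(ab1$AIC, -2 * f1$logLik + 2 * 8)
  expect_equal(ab1$BIC, -2 * f1$logLik + 8 * log(142))
  # AIC ordering equals (G^2 + 2S) ordering: shared saturated baseline
  expect_equal(ab1$AIC - ab3$AIC, (f1$gsq + 2 * 8) - (f3$gsq + 2 * 1),
               tolerance = 1e-8)
  # data from a single-pi truth: BIC prefers the single-pi model
  expect_lt(ab3$BIC, ab1$BIC)
})

test_that("the Heck bound follows its closed form and lands near 10 for PCM(3) vs PCM(1)", {
  d <- mantonakis_design()
  m1 <- pcm1_model(d); m3 <- pcm3_model(d)
  expect_equal(heck_lower_bound(m3, m1, C_simple = 1, C_complex = 1), 2 * pi)
  expect_equal(heck_lower_bound(m3, m1, C_simple = 1, C_complex = 0),
               2 * pi * exp(2 / 7))
  expect_error(heck_lower_bound(m1, m3, C_simple = 1, C_complex = 1), "fewer")
  nprime <- heck_lower_bound(m3, m1, draws = 20000)
  expect_gt(nprime, 2)
  expect_lt(nprime, 100)
  expect_gt(sum(d$n), nprime)  # FIA applicable at the study's sample size
})

test_that("select_models assembles a coherent table with unit-sum weights", {
  d <- mantonakis_design()
  x <- generate_dataset(d, pcm3_model(d), 0.51, seed = 41)
  sel <- select_models(x, list(pcm1_model(d), pcm2_model(d), pcm3_model(d)),
                       draws = 5000, ci_level = NA)
  expect_equal(sum(sel$w_FIA), 1, tolerance = 1e-10)
  expect_equal(sel$model, c("PCM(1)", "PCM(2)", "PCM(3)"))
  expect_equal(sel$df, c(12L, 18L, 19L))
  expect_equal(sel$AIC, -2 * sel$lnL + 2 * sel$S)
  # FIA equals its decomposition recomputed from the attached fits
  fits <- attr(sel, "fits")
  expect_equal(sel$lnL, unname(vapply(fits, `[[`, 0, "logLik")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_selection_tsv(sel, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(back$w_FIA, sel$w_FIA, tolerance = 1e-9)
})
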