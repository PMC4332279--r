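test_that("the nested family's parameter and df bookkeeping is exact", {
  d <- mantonakis_design()
  m1 <- pcm1_model(d)
  m2 <- pcm2_model(d)
  m3 <- pcm3_model(d)
  expect_equal(m1$n_categories, 20)  # 2 * (1 + 2 + 3 + 4)
  expect_equal(m1$S, 8)
  expect_equal(m1$df, 12L)
  expect_equal(m2$S, 2)
  expect_equal(m2$df, 18L)
  expect_equal(m3$S, 1)
  expect_equal(m3$df, 19L)
})

test_that("a one-level design gives one inertia parameter per step", {
  d1 <- pcm_design(level = "only", set_size = 2:5, n = rep(10L, 4))
  expect_equal(pcm1_model(d1)$S, 4)
})

test_that("a single m = 2 group with one free inertia is saturated", {
  m <- single_pi_model(2)
  expect_equal(m$S, 1)
  expect_equal(m$n_categories, 1)
  expect_equal(m$df, 0L)
})

test_that("constraint maps must cover every slot exactly once, with valid constants", {
  d <- pcm_design(level = "a", set_size = 3, n = 10)
  full <- dplyr::mutate(pcm_slots(d),
                        parameter = ifelse(kind == "pi", "pi", NA),
                        constant = ifelse(kind == "pnew", 0.5, NA))
  expect_error(pcm_model(d, full[-1, ]), "unassigned")
  expect_error(pcm_model(d, rbind(full, full[1, ])), "more than once")
  bad <- dplyr::mutate(full, constant = ifelse(kind == "pnew", 1.5, NA))
  expect_error(pcm_model(d, bad), "\\[0, 1\\]")
  both <- dplyr::mutate(full, parameter = "x", constant = 0.5)
  expect_error(pcm_model(d, both), "both")
  neither <- dplyr::mutate(full, parameter = NA_character_, constant = NA_real_)
  expect_error(pcm_model(d, neither), "either")
})

test_that("the PCM chain is nested in one direction only", {
  d <- mantonakis_design()
  m1 <- pcm1_model(d); m2 <- pcm2_model(d); m3 <- pcm3_model(d)
  expect_true(is_nested(m3, m2))
  expect_true(is_nested(m2, m1))
  expect_true(is_nested(m3, m1))
  expect_false(is_nested(m1, m2))
  expect_false(is_nested(m2, m3))
  expect_true(is_nested(m1, m1))
  # a model with pnew fixed elsewhere is not nested in the 0.5-family
  m_other <- pcm3_model(d, pnew = 0.4)
  expect_false(is_nested(m_other, m1))
})

test_that("freeing PCM(3)'s constraints step by step recovers the PCM(1) structure", {
  d <- mantonakis_design()
  m3 <- pcm3_model(d)
  freed <- m3$slots |>
    dplyr::mutate(parameter = ifelse(kind == "pi",
                                     paste0("pi", step, "_", level), parameter))
  m_freed <- pcm_model(d, freed)
  m1 <- pcm1_model(d)
  expect_equal(m_freed$S, m1$S)
  expect_equal(m_freed$df, m1$df)
  expect_true(is_nested(m3, m_freed) && is_nested(m_freed, m1) &&
                is_nested(m1, m_freed))
})

test_that("identifiability probing finds full rank for the standard family", {
  d <- mantonakis_design()
  expect_true(check_identifiability(pcm1_model(d))$identifiable)
  id3 <- check_identifiability(pcm3_model(d))
  expect_true(id3$identifiable)
  expect_true(all(id3$probes$rank == 1))
})

test_that("freeing both pi and pnew at an m = 2 step is flagged non-identified", {
  # the two parameters trade off inside a single category probability
  m <- fully_free_model(2)
  id <- check_identifiability(m)
  expect_false(id$identifiable)
  expect_true(all(id$probes$rank == 1))
  d <- pcm_design(level = "a", set_size = 2, n = 10)
  cm <- dplyr::mutate(pcm_slots(d), parameter = paste0(kind, step), constant = NA_real_)
  expect_warning(expect_warning(pcm_model(d, cm), "not locally identifiable"),
                 "more free parameters")
})
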