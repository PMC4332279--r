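test_that("the forward map matches hand-computed cases", {
  # m = 2: P(1) = pi + (1-pi)(1-pnew), P(2) = (1-pi) pnew
  m2 <- single_pi_model(2)
  expect_equal(unname(category_probabilities(m2, 0.3, "a", 2)), c(0.65, 0.35),
               tolerance = 1e-12)

  # full inertia keeps the first object with certainty
  m4 <- single_pi_model(4)
  expect_equal(unname(category_probabilities(m4, 1, "a", 4)), c(1, 0, 0, 0))

  # no inertia, fair competitions: survival and win both 0.5, telescoping
  m3 <- single_pi_model(3)
  expect_equal(unname(category_probabilities(m3, 0, "a", 3)), c(0.25, 0.25, 0.5),
               tolerance = 1e-12)

  # m = 5 at pi = 0.510: primacy-plus-recency shape; closed form
  # (s, w) = (0.755, 0.245) gives (s^4, w s^3, w s^2, w s, w)
  m5 <- single_pi_model(5)
  p5 <- category_probabilities(m5, 0.510, "a", 5)
  s <- 0.755; w <- 0.245
  expect_equal(unname(p5), c(s^4, w * s^3, w * s^2, w * s, w), tolerance = 1e-12)
  expect_equal(unname(p5), c(0.32493, 0.10544, 0.13966, 0.18497, 0.24500),
               tolerance = 2e-5)
  expect_gt(p5[1], p5[2])            # primacy
  expect_gt(p5[5], p5[4])            # recency
})

test_that("probabilities sum to one for random models and parameter values", {
  set.seed(101)
  for (m in 2:6) {
    model <- fully_free_model(m)
    for (rep in 1:25) {
      theta <- runif(model$S)
      p <- category_probabilities(model, theta, "a", m)
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_true(all(p >= 0))
    }
  }
})

test_that("closed form equals the path-enumeration oracle", {
  set.seed(202)
  for (m in 2:6) {
    model <- fully_free_model(m)
    for (rep in 1:100) {
      theta <- runif(model$S)
      expect_equal(category_probabilities(model, theta, "a", m),
                   path_enumeration_probabilities(model, theta, "a", m),
                   tolerance = 1e-10)
    }
  }
})

test_that("m = 2 enumeration walks exactly the three branches of the tree", {
  m <- fully_free_model(2)
  theta <- c(0.3, 0.6)  # pi2, pnew2
  p <- path_enumeration_probabilities(m, theta, "a", 2)
  expect_equal(unname(p), c(0.3 + 0.7 * 0.4, 0.7 * 0.6), tolerance = 1e-14)
})

test_that("primacy increases with inertia at any step; recency falls with last-step inertia", {
  d <- pcm_design(level = "a", set_size = 5, n = 10)
  cm <- dplyr::mutate(pcm_slots(d),
                      parameter = ifelse(kind == "pi", paste0("pi", step), NA),
                      constant = ifelse(kind == "pnew", 0.5, NA))
  model <- pcm_model(d, cm)
  theta0 <- rep(0.4, 4)
  p0 <- category_probabilities(model, theta0, "a", 5)
  for (j in 1:4) {
    up <- theta0; up[j] <- 0.6
    p1 <- category_probabilities(model, up, "a", 5)
    expect_gt(p1[1], p0[1])
  }
  up_last <- theta0; up_last[4] <- 0.6
  expect_lt(category_probabilities(model, up_last, "a", 5)[5], p0[5])
})

test_that("forward-map input validation catches the usual mistakes", {
  m <- single_pi_model(3)
  expect_error(category_probabilities(m, 0.5, "b", 3), "no group")
  expect_error(category_probabilities(m, 0.5, "a", 4), "no group")
  expect_error(category_probabilities(m, c(0.5, 0.5), "a", 3), "length")
  expect_error(category_probabilities(m, 1.5, "a", 3), "\\[0, 1\\]")
  big <- single_pi_model(9)
  expect_error(path_enumeration_probabilities(big, 0.5, "a", 9), "too large")
})
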