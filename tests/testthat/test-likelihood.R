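test_that("half-normal encounter probability matches closed forms", {
  expect_equal(halfnormal_encounter_prob(0.2, 2, 0), 0.2)
  expect_equal(halfnormal_encounter_prob(0.2, 2, 2), 0.2 * exp(-0.5),
               tolerance = 1e-9)
  expect_equal(halfnormal_encounter_prob(0.5, 1, 3), 0.5 * exp(-4.5),
               tolerance = 1e-9)
  expect_error(halfnormal_encounter_prob(0.2, 0, 1), "positive")
  expect_error(halfnormal_encounter_prob(0.2, 1, -1), "nonnegative")
})

test_that("encounter probability decreases with distance, increases with sigma", {
  d <- seq(0, 20, by = 0.5)
  p <- halfnormal_encounter_prob(0.3, 3, d)
  expect_true(all(diff(p) < 0))
  s <- seq(0.5, 10, by = 0.5)
  ps <- halfnormal_encounter_prob(0.3, s, 5)
  expect_true(all(diff(ps) > 0))
})

test_that("baseline encounter probability is the inverse-logit regression", {
  expect_equal(baseline_encounter_prob(c(0, 0, 0, 0), 0, 0, 0), 0.5)
  g <- c(-2, 1, -1, 0.5)
  expect_equal(baseline_encounter_prob(g, 1, 0, 0), plogis(-1))
  expect_equal(baseline_encounter_prob(g, 1, 0, 0), 0.268941, tolerance = 2e-6)
  expect_equal(baseline_encounter_prob(g, 0, 1, 1), plogis(-2.5))
  expect_equal(baseline_encounter_prob(g, 0, 1, 1), 0.075858, tolerance = 2e-5)
})

test_that("log-linear sigma model honours the inclusion indicator", {
  expect_equal(sigma_value(log(5), 0.7, -1.2, 1, 0, 0), 5)
  expect_equal(sigma_value(1, 0.2, 0.4, 1, 1, 1), exp(1.6), tolerance = 1e-9)
  expect_equal(sigma_value(1, 0.2, 0.4, 0, 1, 1), exp(1.2), tolerance = 1e-9)
  # with theta2 = 0 or w = 0 the data types share sigma
  for (sex in 0:1) {
    expect_equal(sigma_value(0.3, 0.1, 0, 1, sex, 1),
                 sigma_value(0.3, 0.1, 0, 1, sex, 0))
    expect_equal(sigma_value(0.3, 0.1, 0.8, 0, sex, 1),
                 sigma_value(0.3, 0.1, 0.8, 0, sex, 0))
  }
})

test_that("structured likelihood reduces to single Bernoulli terms", {
  space <- toy_space(1)                    # one pixel at (2, 0)
  traps <- toy_traps(c(2, 0), K = 1L)      # trap at the centroid
  # p0 = 0.2 at distance zero: gamma0 = logit(0.2)
  params <- default_params(gamma = c(qlogis(0.2), 0, 0, 0), theta_sigma = 0)
  det1 <- data.frame(individual_id = "A", trap_id = "T1", occasion = 1)
  sex1 <- data.frame(individual_id = "A", sex = "F")
  d1 <- scr_data(space, traps, det1, sex1, M = 1L)
  lat <- list(s = 1L, z = 1L, sex = 0L)
  expect_equal(scr_log_likelihood(d1, lat, params), log(0.2), tolerance = 1e-9)

  # same configuration, no detection
  d0 <- scr_data(space, traps, det1[0, ], sex1[0, ], M = 1L)
  expect_equal(scr_log_likelihood(d0, list(s = 1L, z = 1L, sex = 0L), params),
               log(0.8), tolerance = 1e-9)
  # a phantom contributes nothing
  expect_equal(scr_log_likelihood(d0, list(s = 1L, z = 0L, sex = 0L), params), 0)
  # detection for a phantom is inconsistent
  expect_error(scr_log_likelihood(d1, list(s = 1L, z = 0L, sex = 0L), params),
               "z = 0")
})

test_that("movement likelihood is the bivariate normal around the centroid", {
  d <- toy_dataset(M = 1L, aux = FALSE)
  params <- default_params(theta_sigma = 0)   # sigma = 1 everywhere
  mk <- function(x, y, n = 1) {
    aux <- data.frame(individual = rep(1L, n), x = rep(x, n), y = rep(y, n),
                      occasion = 1L, source = "telemetry")
    d2 <- d; d2$aux <- aux; d2$n <- 1L
    d2
  }
  lat <- list(s = 1L, z = 1L, sex = 0L)     # centroid (2, 0)
  cfg <- scr_model_config("full")
  expect_equal(movement_log_likelihood(mk(2, 0), lat, params, cfg),
               -log(2 * pi), tolerance = 1e-9)
  expect_equal(movement_log_likelihood(mk(3, 1), lat, params, cfg),
               -log(2 * pi) - 1, tolerance = 1e-9)
  expect_equal(movement_log_likelihood(mk(2, 0, n = 2), lat, params, cfg),
               -2 * log(2 * pi), tolerance = 1e-9)
  expect_error(movement_log_likelihood(mk(2, 0), list(s = 1L, z = 0L, sex = 0L),
                                       params, cfg), "z = 0")
})

test_that("joint log posterior is additive in its terms", {
  d <- toy_dataset()
  params <- default_params(gamma = c(-1, 0.5, -0.5, 0.2), beta1 = 0.3,
                           theta_sigma = log(2), theta1 = 0.1, theta2 = 0.2)
  lat <- list(s = c(1L, 2L, 1L), z = c(1L, 1L, 0L), sex = c(0L, 1L, 0L))
  cfg <- scr_model_config("full")
  pi_s <- pixel_probabilities(d$space, params$beta1)
  manual <- scr_log_likelihood(d, lat, params) +
    movement_log_likelihood(d, lat, params, cfg) +
    sum(lat$z * log(params$psi) + (1 - lat$z) * log(1 - params$psi)) +
    sum(lat$sex * log(params$omega) + (1 - lat$sex) * log(1 - params$omega)) +
    sum(log(pi_s[lat$s])) +
    scrint:::log_prior(params, cfg)
  expect_equal(scr_log_posterior(d, lat, params, cfg), manual,
               tolerance = 1e-12)
})

test_that("posterior is -Inf outside the prior support", {
  d <- toy_dataset()
  lat <- list(s = c(1L, 1L, 1L), z = c(1L, 0L, 0L), sex = c(0L, 0L, 0L))
  cfg <- scr_model_config("full")
  good <- default_params()
  expect_true(is.finite(scr_log_posterior(d, lat, good, cfg)))
  expect_identical(scr_log_posterior(d, lat, default_params(theta1 = 3.5), cfg),
                   -Inf)
  expect_identical(scr_log_posterior(d, lat, default_params(psi = 1), cfg),
                   -Inf)
  expect_identical(
    scr_log_posterior(d, lat, default_params(theta2 = 3.5),
                      scr_model_config("full-gvs", sigma_mode = "split")),
    -Inf)
})

test_that("ignoring auxiliary data reproduces the trap-only posterior", {
  d <- toy_dataset()
  lat <- list(s = c(2L, 1L, 2L), z = c(1L, 1L, 1L), sex = c(0L, 1L, 1L))
  p <- default_params(gamma = c(-1, 0.3, 0, 0.1), theta_sigma = log(3))
  cfg_scr <- scr_model_config("scr")
  d_noaux <- toy_dataset(aux = FALSE)
  # the SCR-only model never touches aux records
  expect_equal(scr_log_posterior(d, lat, p, cfg_scr),
               scr_log_posterior(d_noaux, lat, p, cfg_scr) +
                 0,  # identical datasets apart from aux
               tolerance = 1e-12)
})
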