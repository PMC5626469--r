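test_that("alive-indicator conditional matches Bayes' rule", {
  zc <- scrint:::z_conditional_prob
  expect_equal(zc(0.5, 0.9), 0.45 / 0.95, tolerance = 1e-12)
  expect_equal(zc(0.5, 0.9), 0.473684, tolerance = 1e-6)
  expect_equal(zc(0.5, 1), 0.5)            # zero exposure: prior only
  expect_equal(zc(0.2, 1), 0.2)
})

test_that("sex conditional matches the two-point enumeration", {
  sc <- scrint:::sex_conditional_prob
  expect_equal(sc(0.5, 1, 1), 0.5)         # z = 0: prior only
  expect_equal(sc(0.5, 0.9, 0.8), 0.9 / 1.7, tolerance = 1e-12)
  expect_equal(sc(0.5, 0.9, 0.8), 0.529412, tolerance = 1e-6)
})

test_that("activity-center conditional matches the two-point enumeration", {
  # two pixels 4 km apart, one fix at the first centroid, sigma = 1:
  # log-density difference is 16/2 = 8
  p <- scrint:::softmax_log(c(-0, -8))
  expect_equal(p[1], 1 / (1 + exp(-8)), tolerance = 1e-9)
  expect_equal(p[1], 0.999665, tolerance = 1e-6)
})

test_that("GVS inclusion conditional matches the two-point enumeration", {
  wc <- scrint:::w_conditional_prob
  expect_equal(wc(0, 0, log(1 / 6), log(1 / 6)), 0.5)
  expect_equal(wc(1, 0, log(0.3), log(0.3)), exp(1) / (1 + exp(1)),
               tolerance = 1e-9)
  expect_equal(wc(1, 0, log(0.3), log(0.3)), 0.731059, tolerance = 1e-6)
  expect_equal(wc(-2, 0, log(0.3), log(0.3)), 0.119203, tolerance = 1e-6)
})

test_that("inclusion-probability conjugate updates use all M individuals", {
  # posterior shape parameters implied by the Beta(1, 1) prior
  expect_equal(1 + 40, 41)                  # sum z = 40, M = 300
  m <- 41 / 302
  expect_equal(m, 0.135762, tolerance = 1e-5)
  # verified through the sampler: with psi's conditional Beta(1 + sum z,
  # 1 + M - sum z), a no-data chain keeps psi at its Uniform(0, 1) prior
  d <- nodata_dataset(M = 10L)
  fit <- scr_fit(d, "scr", control = scr_mcmc_control(
    n_chains = 1, n_iter = 4000, n_burnin = 200, seed = 5))
  psi <- scrint:::pooled_draws(fit)[, "psi"]
  expect_gt(mean(psi), 0.45)
  expect_lt(mean(psi), 0.55)
})

test_that("latent Gibbs sweep targets the enumerated conditional posterior", {
  d <- toy_dataset()                        # M = 3, nG = 2
  cfg <- scr_model_config("full")
  params <- default_params(gamma = c(-0.5, 0.4, -0.3, 0.2), beta1 = 0.5,
                           theta_sigma = log(2), theta1 = 0.3,
                           psi = 0.4, omega = 0.6)
  pre <- scrint:::sampler_precompute(d, cfg)
  logpi <- log(pixel_probabilities(d$space, params$beta1))

  # exact posterior of the latent state by enumeration
  configs <- oracle_configs(d)
  probs <- vapply(configs, function(l)
    oracle_config_prob(d, l, params, cfg), numeric(1))
  probs <- probs / sum(probs)
  exact <- function(f) sum(probs * vapply(configs, f, numeric(1)))
  p_z2 <- exact(function(l) l$z[2])
  p_sex2 <- exact(function(l) l$sex[2])
  p_s1 <- exact(function(l) l$s[1] == 1L)

  set.seed(99)
  state <- list(s = c(1L, 1L, 2L), z = c(1L, 1L, 0L), sex = c(0L, 1L, 0L))
  n_sweep <- 4000L
  hits <- c(z2 = 0, sex2 = 0, s1 = 0)
  for (t in seq_len(n_sweep)) {
    state <- scrint:::gibbs_latent_step(state, params, 0L, logpi, d, pre,
                                        scr_mcmc_control())
    hits <- hits + c(state$z[2], state$sex[2], state$s[1] == 1L)
  }
  freq <- hits / n_sweep
  # Monte-Carlo tolerance: the latent chain decorrelates within a few sweeps
  expect_equal(unname(freq["z2"]), p_z2, tolerance = 0.12)
  expect_equal(unname(freq["sex2"]), p_sex2, tolerance = 0.12)
  expect_equal(unname(freq["s1"]), p_s1, tolerance = 0.12)
  # pinned coordinates never move
  expect_equal(state$z[1], 1L)
})

test_that("Gelman-Rubin diagnostic matches its defining formula", {
  expect_equal(gelman_rubin(cbind(1:4, 1:4)), sqrt(1.25 / (5 / 3)),
               tolerance = 1e-9)
  expect_equal(gelman_rubin(cbind(1:4, 1:4)), 0.8660, tolerance = 1e-4)
  set.seed(3)
  ch <- cbind(rnorm(10000), rnorm(10000))
  expect_equal(gelman_rubin(ch), 1, tolerance = 0.01)
  expect_error(gelman_rubin(cbind(rep(0, 4), rep(1, 4))), "degenerate")
  expect_error(gelman_rubin(matrix(rnorm(10), 10, 1)), "2 chains")
})

test_that("home-range areas follow the chi-square circle formula", {
  expect_equal(home_range_area(0), 0)
  expect_equal(home_range_area(1), pi * qchisq(0.95, 2), tolerance = 1e-9)
  expect_equal(home_range_area(1), 18.8227, tolerance = 1e-4)
  expect_error(home_range_area(1, level = 1.2), "level")
  expect_error(home_range_area(-1), "nonnegative")
  # posterior-mean area uses E[sigma^2] = mean^2 + sd^2
  expect_equal(home_range_area(3, sd = 0.5),
               pi * qchisq(0.95, 2) * 9.25, tolerance = 1e-9)
})

test_that("percent differences use the rounded relative-change convention", {
  expect_identical(percent_difference(16, 13), 19)
  expect_identical(percent_difference(58, 25), 57)
  expect_identical(percent_difference(10, 10), 0)
})

test_that("posterior summaries use type-7 quantiles and handle constants", {
  draws <- matrix(c(rep(7, 10), 1:10), 10, 2,
                  dimnames = list(NULL, c("a", "b")))
  s <- scrint:::draws_summary(draws)
  expect_equal(s$mean[1], 7)
  expect_equal(s$sd[1], 0)
  expect_equal(s$`q50`[1], 7)
  expect_equal(s$`q50`[2], quantile(1:10, 0.5, type = 7, names = FALSE))
})

test_that("the neighbour-move Metropolis fallback targets the same posterior", {
  # force the local-move update by setting the exact-Gibbs cap below nG
  d <- toy_dataset()
  cfg <- scr_model_config("full")
  params <- default_params(gamma = c(-0.5, 0.4, -0.3, 0.2), beta1 = 0.5,
                           theta_sigma = log(2), theta1 = 0.3,
                           psi = 0.4, omega = 0.6)
  pre <- scrint:::sampler_precompute(d, cfg)
  logpi <- log(pixel_probabilities(d$space, params$beta1))
  configs <- oracle_configs(d)
  probs <- vapply(configs, function(l)
    oracle_config_prob(d, l, params, cfg), numeric(1))
  probs <- probs / sum(probs)
  p_s1 <- sum(probs * vapply(configs, function(l) l$s[1] == 1L, numeric(1)))

  set.seed(123)
  ctl <- scr_mcmc_control(pixel_gibbs_cap = 0L)
  state <- list(s = c(1L, 1L, 2L), z = c(1L, 1L, 0L), sex = c(0L, 1L, 0L))
  hit <- 0
  n_sweep <- 4000L
  for (t in seq_len(n_sweep)) {
    state <- scrint:::gibbs_latent_step(state, params, 0L, logpi, d, pre, ctl)
    hit <- hit + (state$s[1] == 1L)
  }
  expect_lt(abs(hit / n_sweep - p_s1), 0.05)
})
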