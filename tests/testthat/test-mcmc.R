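test_that("identical seeds give identical chains", {
  sc <- scr_scenario(n_hair = 16L, n_rub = 9L, spacing = 4, K = 3L,
                     resolution = 4, buffer = 8, M = 40L, N = 15L,
                     omega = 0.5, theta_sigma = log(3), theta1 = 0.3,
                     theta2 = 0, n_collared = 1L, telemetry_days = 20L,
                     n_opportunistic = 5L, seed = 7)
  d <- scr_simulate(sc)
  ctl <- scr_mcmc_control(n_chains = 2, n_iter = 300, n_burnin = 100, seed = 21)
  f1 <- scr_fit(d, "full", control = ctl)
  f2 <- scr_fit(d, "full", control = ctl)
  expect_identical(f1$draws, f2$draws)
  # chains use different streams
  expect_false(identical(f1$draws[[1]], f1$draws[[2]]))
})

test_that("theta_sigma posterior matches 1-D quadrature on movement-only data", {
  # one pixel, one never-operational trap, one identified individual with
  # bivariate-normal fixes: the only informed parameter is theta_sigma
  space <- toy_space(1)
  traps <- toy_traps(c(2, 0), K = 1L, operation = matrix(0L, 1, 1))
  set.seed(14)
  R <- 25L
  fx <- rnorm(R, 2, 1.5); fy <- rnorm(R, 0, 1.5)
  aux <- data.frame(individual_id = "A", x_km = fx, y_km = fy,
                    occasion = 1, source = "telemetry")
  d <- scr_data(space, traps,
                data.frame(individual_id = character(0),
                           trap_id = character(0), occasion = integer(0)),
                data.frame(individual_id = "A", sex = "F"), aux, M = 1L)

  # quadrature oracle: posterior of theta_sigma under the N(0, 15) prior
  ssd <- sum((fx - 2)^2 + (fy - 0)^2)
  grid <- seq(-2, 3, length.out = 4001)
  loglik <- -2 * R * grid - ssd / (2 * exp(2 * grid)) # BVN kernel in log sigma
  logpost <- loglik + dnorm(grid, 0, sqrt(15), log = TRUE)
  wgt <- exp(logpost - max(logpost)); wgt <- wgt / sum(wgt)
  mean_q <- sum(wgt * grid)
  sd_q <- sqrt(sum(wgt * (grid - mean_q)^2))

  fit <- scr_fit(d, "full", control = scr_mcmc_control(
    n_chains = 2, n_iter = 5000, n_burnin = 1000, seed = 3))
  ts <- scrint:::pooled_draws(fit)[, "theta_sigma"]
  expect_lt(abs(mean(ts) - mean_q), 4 * sd_q / sqrt(500))
  expect_lt(abs(sd(ts) - sd_q), 0.25 * sd_q)
})

test_that("with no data the sampler reproduces the priors (short run)", {
  d <- nodata_dataset(M = 8L)
  fit <- scr_fit(d, "full", control = scr_mcmc_control(
    n_chains = 1, n_iter = 6000, n_burnin = 1000, seed = 2))
  dr <- scrint:::pooled_draws(fit)
  expect_lt(abs(mean(dr[, "gamma0"])), 1.2)      # prior mean 0, sd 10
  expect_lt(abs(sd(dr[, "gamma0"]) - 10), 2)
  expect_lt(abs(mean(dr[, "theta1"])), 0.25)     # Uniform(-3, 3)
  expect_lt(abs(mean(dr[, "psi"]) - 0.5), 0.05)
  expect_lt(abs(mean(dr[, "omega"]) - 0.5), 0.05)
})

test_that("GVS with no data leaves the inclusion indicator at its prior", {
  d <- nodata_dataset(M = 6L)
  fit <- scr_fit(d, "full-gvs", control = scr_mcmc_control(
    n_chains = 1, n_iter = 6000, n_burnin = 1000, seed = 8))
  expect_lt(abs(inclusion_probability(fit) - 0.5), 0.1)
  # theta2 given w = 1 follows the Uniform(-3, 3) slab
  dr <- scrint:::pooled_draws(fit)
  t2 <- dr[dr[, "w"] == 1, "theta2"]
  expect_gt(length(t2), 1000)
  expect_lt(abs(mean(t2)), 0.35)
  expect_lt(abs(sd(t2) - sqrt(3)), 0.35)
})

test_that("GVS requires a pseudo-prior source", {
  d <- nodata_dataset(M = 4L)
  expect_error(
    scr_fit(d, "full-gvs", gvs = scr_gvs_control(pilot_fraction = 0),
            control = scr_mcmc_control(n_chains = 1, n_iter = 50,
                                       n_burnin = 20, seed = 1)),
    "pseudo-prior")
})

test_that("derived population sizes respect the augmentation bound", {
  sc <- scr_scenario(n_hair = 16L, n_rub = 0L, spacing = 4, K = 2L,
                     resolution = 4, buffer = 8, M = 30L, N = 10L,
                     theta2 = 0, n_collared = 0L, telemetry_days = 0L,
                     n_opportunistic = 0L, seed = 4)
  d <- scr_simulate(sc)
  fit <- scr_fit(d, "scr", control = scr_mcmc_control(
    n_chains = 1, n_iter = 400, n_burnin = 100, seed = 9))
  dr <- scrint:::pooled_draws(fit)
  expect_true(all(dr[, "N"] <= 30))
  expect_true(all(dr[, "N"] >= d$n))
  expect_equal(dr[, "N"], dr[, "N_female"] + dr[, "N_male"])
})
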