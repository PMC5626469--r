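test_that("activity centers follow the pixel probabilities", {
  sp <- toy_space(8)
  tt <- simulate_truth(sp, beta1 = 0, N = 50000L, omega = 0.5, seed = 31)
  counts <- tabulate(tt$s, nbins = 8)
  gof <- chisq.test(counts, p = rep(1 / 8, 8))
  expect_gt(gof$p.value, 0.001)
  # sex ratio within the binomial 3-sigma band
  tt2 <- simulate_truth(sp, 0, 10000L, 0.5, seed = 5)
  expect_lt(abs(mean(tt2$sex) - 0.5), 3 * sqrt(0.25 / 10000))
  # extreme covariate weight pushes all centers into the first pixel
  sp2 <- toy_space(2, covariate = c(0, 10))
  tt3 <- simulate_truth(sp2, beta1 = -5, N = 2000L, omega = 0.5, seed = 6)
  expect_true(all(tt3$s == 1L))
})

test_that("trap detections have the analytic Bernoulli rates", {
  sp <- toy_space(1)
  tr <- toy_traps(c(2, 0), K = 5L)         # trap at the only centroid
  truth <- list(s = rep(1L, 2000L), sex = rep(0L, 2000L))
  y <- simulate_scr(truth, tr, sp, gamma = c(qlogis(0.2), 0, 0, 0),
                    theta_sigma = log(10), theta1 = 0, seed = 77)
  # at distance 0 each occasion is Bernoulli(0.2): per-individual mean 1
  m <- mean(apply(y, 1, sum))
  expect_lt(abs(m - 1), 0.06)
  # degenerate baseline: no detections
  y0 <- simulate_scr(truth, tr, sp, gamma = c(-Inf, 0, 0, 0),
                     theta_sigma = log(10), theta1 = 0, seed = 1)
  expect_equal(sum(y0), 0)
})

test_that("no detections are generated at non-operational trap-occasions", {
  sp <- toy_space(1)
  oper <- matrix(c(1L, 0L, 1L, 0L, 0L), 1, 5)
  tr <- toy_traps(c(2, 0), K = 5L, operation = oper)
  truth <- list(s = rep(1L, 500L), sex = rep(0L, 500L))
  y <- simulate_scr(truth, tr, sp, gamma = c(2, 0, 0, 0),
                    theta_sigma = log(10), theta1 = 0, seed = 3)
  expect_equal(sum(y[, 1, oper[1, ] == 0L]), 0)
  expect_gt(sum(y[, 1, oper[1, ] == 1L]), 0)
})

test_that("auxiliary fixes have the unstructured-data spread", {
  sp <- toy_space(2)
  truth <- list(s = c(1L, 2L), sex = c(0L, 1L))
  aux <- simulate_aux(truth, sp, collared = 1L, detected = 1:2,
                      theta_sigma = log(2), theta1 = 0, theta2 = 0,
                      telemetry_days = 10000L, n_opportunistic = 0L,
                      K = 5L, seed = 12)
  expect_equal(nrow(aux), 10000L)
  expect_lt(abs(sd(aux$x) - 2) / 2, 0.02)
  expect_lt(abs(sd(aux$y) - 2) / 2, 0.02)
  expect_equal(mean(aux$x), 2, tolerance = 0.05)
  # rate zero gives an empty set
  none <- simulate_aux(truth, sp, collared = integer(0), detected = 1:2,
                       theta_sigma = log(2), theta1 = 0, theta2 = 0,
                       telemetry_days = 0L, n_opportunistic = 0L, K = 5L)
  expect_equal(nrow(none), 0L)
})

test_that("the data-type effect propagates to the stored truth", {
  d0 <- scr_simulate(recovery_scenario(theta2 = 0, seed = 2))
  tr0 <- attr(d0, "truth")
  expect_equal(tr0$sigma_un_f, tr0$sigma_st_f)
  expect_equal(tr0$sigma_un_m, tr0$sigma_st_m)
  d1 <- scr_simulate(recovery_scenario(theta2 = 0.4, seed = 2))
  tr1 <- attr(d1, "truth")
  expect_equal(tr1$sigma_un_f / tr1$sigma_st_f, exp(0.4))
})

test_that("the default bear-like scenario builds and validates", {
  d <- scr_simulate(scr_scenario(seed = 9))
  expect_s3_class(d, "scr_data")
  expect_equal(d$traps$J, 188L)            # 99 hair traps + 89 rub trees
  expect_equal(d$M, 300L)
  expect_equal(d$traps$K, 5L)
  expect_equal(d$space$resolution, 4)
  expect_gt(d$n, 0)
  expect_true(all(d$y[d$n + seq_len(d$M - d$n), , ] == 0L))
})

test_that("generation is deterministic given the scenario seed", {
  sc <- recovery_scenario(theta2 = 0.4, seed = 123)
  d1 <- scr_simulate(sc)
  d2 <- scr_simulate(sc)
  expect_identical(d1$y, d2$y)
  expect_identical(d1$aux, d2$aux)
  expect_identical(d1$traps$coords, d2$traps$coords)
  # and the written files are byte-for-byte identical
  t1 <- file.path(tempdir(), "scr-det-a"); t2 <- file.path(tempdir(), "scr-det-b")
  write_scr_data(d1, t1); write_scr_data(d2, t2)
  for (f in list.files(t1)) {
    expect_identical(readLines(file.path(t1, f)), readLines(file.path(t2, f)),
                     label = f)
  }
  unlink(c(t1, t2), recursive = TRUE)
})

test_that("the generating parameters beat perturbed ones in likelihood", {
  # self-consistency: average log likelihood at the truth exceeds the one
  # with sigma inflated by 50%
  diffs <- vapply(1:5, function(r) {
    d <- scr_simulate(recovery_scenario(theta2 = 0, seed = 100 + r))
    tr <- attr(d, "truth")
    lat <- list(s = c(tr$s[match(d$ids, sprintf("B%03d", seq_along(tr$s)))],
                      rep(1L, d$M - d$n)),
                z = c(rep(1L, d$n), rep(0L, d$M - d$n)),
                sex = ifelse(is.na(d$sex), 0L, d$sex))
    p_true <- default_params(gamma = tr$gamma, beta1 = tr$beta1,
                             theta_sigma = tr$theta_sigma, theta1 = tr$theta1)
    p_pert <- p_true; p_pert$theta_sigma <- p_true$theta_sigma + log(1.5)
    cfg <- scr_model_config("full")
    ll_t <- scr_log_likelihood(d, lat, p_true) +
      movement_log_likelihood(d, lat, p_true, cfg)
    ll_p <- scr_log_likelihood(d, lat, p_pert) +
      movement_log_likelihood(d, lat, p_pert, cfg)
    expect_true(is.finite(ll_t))
    ll_t - ll_p
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})
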