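#' @export
print.scr_fit <- function(x, ...) {
  cat(sprintf("Integrated SCR model fit ('%s')\n", x$config$model))
  cat(sprintf("  data: n = %d observed, M = %d, J = %d traps, K = %d occasions, %d pixels\n",
              x$n, x$M, x$J, x$K, x$n_pixels))
  cat(sprintf("  aux records used: telemetry %s, opportunistic %s\n",
              if (x$config$use_telemetry) x$R_tel else "off",
              if (x$config$use_opportunistic) x$R_opp else "off"))
  cat(sprintf("  chains: %d x %d post-burn-in draws (burn-in %d)\n",
              x$control$n_chains, nrow(x$draws[[1]]), x$control$n_burnin))
  d <- pooled_draws(x)
  cat(sprintf("  posterior median N = %.0f (females %.0f, males %.0f)\n",
              stats::median(d[, "N"]), stats::median(d[, "N_female"]),
              stats::median(d[, "N_male"])))
  if (x$config$sigma_mode == "gvs")
    cat(sprintf("  Pr(data-type effect on sigma) = %.3f\n", mean(d[, "w"])))
  invisible(x)
}

#' Posterior summary table of an integrated SCR fit
#'
#' Mean, SD and 2.5/50/97.5% quantiles per parameter and derived quantity,
#' plus the Gelman-Rubin R-hat when at least two chains were run.
#'
#' @param object an [scr_fit] object.
#' @param pars optional subset of parameter names.
#' @param ... unused.
#' @return data frame, one row per parameter.
#' @export
summary.scr_fit <- function(object, pars = NULL, ...) {
  d <- pooled_draws(object)
  if (!is.null(pars)) d <- d[, pars, drop = FALSE]
  out <- draws_summary(d)
  if (object$control$n_chains >= 2L) {
    out$Rhat <- vapply(out$parameter, function(p) {
      mat <- sapply(object$draws, function(ch) ch[, p])
      if (stats::sd(mat) == 0) return(NA_real_)
      tryCatch(gelman_rubin(mat), error = function(e) NA_real_)
    }, numeric(1))
  }
  out
}

#' @export
coef.scr_fit <- function(object, ...) {
  d <- pooled_draws(object)
  pars <- c("gamma0", "gamma1", "gamma2", "gamma3", "beta1",
            "theta_sigma", "theta1", "theta2", "psi", "omega")
  colMeans(d[, pars])
}

#' Traceplots and posterior densities
#'
#' @param x an [scr_fit] object.
#' @param pars parameters to show (default: the main structural ones).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.scr_fit <- function(x, pars = c("N", "sigma_st_f", "sigma_st_m",
                                     "theta2", "psi", "beta1"), ...) {
  pars <- intersect(pars, colnames(x$draws[[1]]))
  old <- graphics::par(mfrow = c(length(pars), 2),
                       mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(old))
  for (p in pars) {
    mat <- sapply(x$draws, function(ch) ch[, p])
    graphics::matplot(mat, type = "l", lty = 1, ylab = p, xlab = "", ...)
    dens <- stats::density(as.numeric(mat))
    graphics::plot(dens, main = "", xlab = "", ylab = p)
  }
  invisible(x)
}

#' Posterior mean density surface
#'
#' Expected number of activity centers per pixel (and per km^2), averaging
#' `N * pi_g(beta1)` over the posterior draws.
#'
#' @param object an [scr_fit] object.
#' @param space the [scr_state_space] the model was fitted on.
#' @param ... unused.
#' @return data frame with pixel centroids, expected counts and density
#'   (individuals per km^2).
#' @export
predict.scr_fit <- function(object, space, ...) {
  stopifnot(inherits(space, "scr_state_space"))
  d <- pooled_draws(object)
  idx <- seq(1, nrow(d), length.out = min(nrow(d), 2000L))
  ex <- rep(0, space$n_pixels)
  for (r in idx) {
    ex <- ex + d[r, "N"] * pixel_probabilities(space, d[r, "beta1"])
  }
  ex <- ex / length(idx)
  data.frame(x = space$centroids[, 1], y = space$centroids[, 2],
             expected_n = ex, density = ex / space$resolution^2)
}

#' Simulate datasets from posterior draws
#'
#' Posterior-predictive style simulation: draws parameter vectors from the
#' fitted posterior and generates new datasets with the synthetic-data
#' generator on a user-supplied design (state space, traps, auxiliary
#' design).
#'
#' @param object an [scr_fit] object.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param scenario an [scr_scenario()] providing the design; its truth
#'   parameters are replaced by posterior draws.
#' @param ... unused.
#' @return list of [scr_data] objects with a `truth` attribute each.
#' @export
simulate.scr_fit <- function(object, nsim = 1, seed = 1L, scenario, ...) {
  stopifnot(inherits(scenario, "scr_scenario"))
  d <- pooled_draws(object)
  set.seed(seed)
  rows <- sample.int(nrow(d), nsim, replace = TRUE)
  lapply(rows, function(r) {
    sc <- scenario
    sc$truth$gamma <- as.numeric(d[r, c("gamma0", "gamma1", "gamma2", "gamma3")])
    sc$truth$beta1 <- d[r, "beta1"]
    sc$truth$theta_sigma <- d[r, "theta_sigma"]
    sc$truth$theta1 <- d[r, "theta1"]
    sc$truth$theta2 <- d[r, "w"] * d[r, "theta2"]
    sc$truth$omega <- d[r, "omega"]
    sc$truth$N <- as.integer(round(d[r, "N"]))
    sc$seed <- sample.int(.Machine$integer.max %/% 2L, 1)
    scr_simulate(sc)
  })
}
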