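#' MCMC sampler settings
#'
#' @param n_chains number of independent chains (default 3; at least 2 are
#'   needed for the Gelman-Rubin diagnostic).
#' @param n_iter post-burn-in iterations per chain (study default 30000).
#' @param n_burnin burn-in iterations (study default 3000).
#' @param thin thinning interval.
#' @param seed integer seed; identical seed, data and settings give
#'   identical draws.  Chain c uses `seed + c - 1`.
#' @param proposal_scales optional named vector of random-walk SDs for
#'   `gamma0..gamma3`, `beta1`, `theta_sigma`, `theta1`, `theta2`.
#' @param adapt adapt proposal scales during burn-in (frozen afterwards so
#'   the post-burn-in kernel preserves detailed balance).
#' @param pixel_gibbs_cap exact categorical activity-center updates are
#'   used when the state space has at most this many pixels; above it a
#'   local Metropolis move between neighbouring pixels is used.
#' @return list of class `scr_mcmc_control`.
#' @export
scr_mcmc_control <- function(n_chains = 3L, n_iter = 30000L, n_burnin = 3000L,
                             thin = 1L, seed = 1L, proposal_scales = NULL,
                             adapt = TRUE, pixel_gibbs_cap = 2000L) {
  stopifnot(n_chains >= 1L, n_iter >= 1L, n_burnin >= 0L, thin >= 1L)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed), proposal_scales = proposal_scales,
                 adapt = isTRUE(adapt),
                 pixel_gibbs_cap = as.integer(pixel_gibbs_cap)),
            class = "scr_mcmc_control")
}

#' Gibbs-variable-selection settings
#'
#' The data-type effect on log sigma uses a slab-and-spike scheme: when the
#' inclusion indicator is off, the coefficient is drawn from a pseudo-prior
#' (a Normal truncated to the slab support) so the chain keeps mixing over
#' the indicator.  By default the pseudo-prior is fitted by moments to
#' pilot draws taken during the first part of burn-in with the indicator
#' pinned on.
#'
#' @param pseudo_prior_mean,pseudo_prior_sd fix the pseudo-prior instead of
#'   pilot tuning (both must be given).
#' @param pilot_fraction fraction of burn-in used as the pilot phase.
#' @return list of class `scr_gvs_control`.
#' @export
scr_gvs_control <- function(pseudo_prior_mean = NULL, pseudo_prior_sd = NULL,
                            pilot_fraction = 0.5) {
  if (!is.null(pseudo_prior_sd) && pseudo_prior_sd <= 0)
    stop("pseudo_prior_sd must be positive")
  structure(list(pseudo_prior_mean = pseudo_prior_mean,
                 pseudo_prior_sd = pseudo_prior_sd,
                 pilot_fraction = pilot_fraction),
            class = "scr_gvs_control")
}

#' Fit an integrated spatial capture-recapture model
#'
#' Runs the Metropolis-within-Gibbs sampler for one of the five model
#' variants: trap data only (`"scr"`), trap data plus telemetry and/or
#' opportunistic locations assuming one sigma per sex across data types
#' (`"scr+tel"`, `"scr+opp"`, `"full"`), or the fully integrated model
#' with a Gibbs-variable-selection test of a data-type effect on sigma
#' (`"full-gvs"`).  Auxiliary records in the dataset that the chosen model
#' does not use are ignored with a message.
#'
#' Derived quantities stored per iteration: sex-specific population sizes
#' (sums of alive indicators by sex), and sigma by sex and data type.
#'
#' @param data an [scr_data] object.
#' @param model model name, see [scr_model_config()]; alternatively pass a
#'   ready-made config object.
#' @param control an [scr_mcmc_control()].
#' @param gvs an [scr_gvs_control()] (used by `"full-gvs"` only).
#' @param verbose print progress and block acceptance rates.
#' @return An object of class `scr_fit` with elements `draws` (list of
#'   per-chain matrices, iterations x parameters), `config`, `control`,
#'   `acceptance`, and dataset dimensions.  Use `summary()`, `coef()`,
#'   `plot()`, `predict()` and [gelman_rubin()] on it.
#' @export
scr_fit <- function(data, model = "scr", control = scr_mcmc_control(),
                    gvs = scr_gvs_control(), verbose = FALSE) {
  stopifnot(inherits(data, "scr_data"))
  config <- if (inherits(model, "scr_model_config")) model
            else scr_model_config(model)
  if (!is.null(data$aux)) {
    used <- aux_subset(data, config$use_telemetry, config$use_opportunistic)
    n_used <- if (is.null(used)) 0L else nrow(used)
    if (n_used < nrow(data$aux))
      message(sprintf("model '%s' ignores %d of %d auxiliary records",
                      config$model, nrow(data$aux) - n_used, nrow(data$aux)))
  }
  pre <- sampler_precompute(data, config)
  chains <- vector("list", control$n_chains)
  for (c in seq_len(control$n_chains)) {
    if (verbose) message(sprintf("chain %d/%d", c, control$n_chains))
    chains[[c]] <- run_chain(data, config, control, gvs, pre,
                             chain_seed = control$seed + c - 1L,
                             verbose = verbose)
  }
  structure(
    list(draws = lapply(chains, `[[`, "draws"),
         acceptance = lapply(chains, `[[`, "acceptance"),
         pseudo_prior = chains[[1]]$pseudo_prior,
         config = config, control = control, gvs = gvs,
         n = data$n, M = data$M, J = data$traps$J, K = data$traps$K,
         n_pixels = data$space$n_pixels,
         R_tel = data$R_tel, R_opp = data$R_opp,
         call = match.call()),
    class = "scr_fit"
  )
}

# all chains row-bound into one draw matrix
pooled_draws <- function(fit) {
  do.call(rbind, fit$draws)
}

#' Posterior inclusion probability of the data-type effect
#'
#' The posterior mean of the inclusion indicator: the probability that
#' structured and unstructured data carry different spatial scale
#' parameters.  Only meaningful for the `"full-gvs"` model.
#'
#' @param fit an [scr_fit] object.
#' @return scalar probability.
#' @export
inclusion_probability <- function(fit) {
  stopifnot(inherits(fit, "scr_fit"))
  if (fit$config$sigma_mode != "gvs")
    stop("inclusion probability is defined only for the GVS model")
  mean(pooled_draws(fit)[, "w"])
}
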