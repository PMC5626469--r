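#' Half-normal encounter probability
#'
#' Detection probability declines with the distance between a trap and an
#' activity center as \eqn{p = p_0 \exp(-d^2 / (2\sigma^2))}, where
#' \eqn{\sigma} is the spatial scale parameter.
#'
#' @param p0 baseline encounter probability at distance 0.
#' @param sigma spatial scale parameter (km), positive.
#' @param dist distance (km), nonnegative; vectorised.
#' @return encounter probability in `[0, p0]`.
#' @export
halfnormal_encounter_prob <- function(p0, sigma, dist) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (any(p0 < 0 | p0 > 1)) stop("p0 must be a probability")
  if (any(dist < 0)) stop("dist must be nonnegative")
  p0 * exp(-dist^2 / (2 * sigma^2))
}

#' Baseline encounter probability (logit-linear)
#'
#' Logistic regression of the baseline encounter probability on sex, trap
#' type and the standardized time-since-last-check covariate:
#' \eqn{\mathrm{logit}(p_0) = \gamma_0 + \gamma_1 \mathrm{sex} +
#' \gamma_2 \mathrm{trap} + \gamma_3 \mathrm{time}}.  The reference
#' category (all zero) is a female at a hair trap.
#'
#' @param gamma numeric vector of 4 coefficients
#'   (intercept, sex, trap type, time).
#' @param sex 0 = female, 1 = male.
#' @param trap_type 0 = hair trap, 1 = rub tree.
#' @param time_std standardized time covariate.
#' @return baseline probability; vectorised over the covariates.
#' @export
baseline_encounter_prob <- function(gamma, sex, trap_type, time_std) {
  stopifnot(length(gamma) == 4L)
  stats::plogis(gamma[1] + gamma[2] * sex + gamma[3] * trap_type +
                gamma[4] * time_std)
}

#' Spatial scale parameter under the log-linear model
#'
#' \eqn{\log \sigma_{type,sex} = \theta_\sigma + \theta_1 sex + w \theta_2
#' type}, so `exp(theta_sigma)` is the female sigma for structured (trap)
#' data.  The inclusion indicator `w` toggles the data-type effect: with
#' `w = 0` structured and unstructured data share one sigma per sex.
#'
#' @param theta_sigma log-scale intercept.
#' @param theta1 sex effect on log sigma.
#' @param theta2 data-type effect on log sigma.
#' @param w inclusion indicator, 0 or 1.
#' @param sex 0 = female, 1 = male.
#' @param data_type 0 = structured (traps), 1 = unstructured
#'   (telemetry/opportunistic).
#' @return sigma (km), positive.
#' @export
sigma_value <- function(theta_sigma, theta1, theta2, w, sex, data_type) {
  stopifnot(all(w %in% c(0, 1)))
  exp(theta_sigma + theta1 * sex + w * theta2 * data_type)
}

#' Model configuration for the five integrated-model variants
#'
#' The five fitted models are: `"scr"` (trap data only), `"scr+tel"`,
#' `"scr+opp"`, `"full"` (all three sources, one sigma per sex shared
#' across data types), and `"full-gvs"` (all three sources with the
#' Gibbs-variable-selection test of the data-type effect on sigma).  The
#' shared-sigma models are special cases of the gvs model with the
#' data-type effect fixed at zero.  `sigma_mode = "split"` (data-type
#' effect always included, no selection) is also available for direct
#' fitting of the inconsistency-accounting model.
#'
#' @param model one of `"scr"`, `"scr+tel"`, `"scr+opp"`, `"full"`,
#'   `"full-gvs"`.
#' @param sigma_mode optional override of the sigma structure:
#'   `"shared"`, `"gvs"` or `"split"`.
#' @return list of class `scr_model_config` with flags `use_telemetry`,
#'   `use_opportunistic`, `sigma_mode`.
#' @export
scr_model_config <- function(model = c("scr", "scr+tel", "scr+opp", "full", "full-gvs"),
                             sigma_mode = NULL) {
  model <- match.arg(model)
  cfg <- switch(model,
    "scr"      = list(use_telemetry = FALSE, use_opportunistic = FALSE, sigma_mode = "shared"),
    "scr+tel"  = list(use_telemetry = TRUE,  use_opportunistic = FALSE, sigma_mode = "shared"),
    "scr+opp"  = list(use_telemetry = FALSE, use_opportunistic = TRUE,  sigma_mode = "shared"),
    "full"     = list(use_telemetry = TRUE,  use_opportunistic = TRUE,  sigma_mode = "shared"),
    "full-gvs" = list(use_telemetry = TRUE,  use_opportunistic = TRUE,  sigma_mode = "gvs")
  )
  if (!is.null(sigma_mode)) {
    cfg$sigma_mode <- match.arg(sigma_mode, c("shared", "gvs", "split"))
  }
  cfg$model <- model
  class(cfg) <- "scr_model_config"
  cfg
}

# default parameter list; gamma = (intercept, sex, trap type, time)
scr_params <- function(gamma = c(0, 0, 0, 0), beta1 = 0, theta_sigma = 0,
                       theta1 = 0, theta2 = 0, w = 1L, psi = 0.5, omega = 0.5) {
  list(gamma = gamma, beta1 = beta1, theta_sigma = theta_sigma,
       theta1 = theta1, theta2 = theta2, w = as.integer(w),
       psi = psi, omega = omega)
}

# effective w given the sigma mode
effective_w <- function(params, config) {
  switch(config$sigma_mode,
         shared = 0L,
         split = 1L,
         gvs = as.integer(params$w))
}

#' Structured (trap-array) log likelihood
#'
#' Sum over real individuals (`z = 1`) and operational trap-occasions of
#' Bernoulli log mass for the binary detections, with encounter
#' probabilities from the half-normal model, the logit-linear baseline and
#' the structured-data sigma for the individual's sex.  Individuals with
#' `z = 0` have structurally all-zero histories and contribute nothing.
#'
#' @param data an [scr_data] object.
#' @param latent list with integer vectors `s` (pixel index per
#'   individual), `z` (0/1), `sex` (0/1), each of length `M`.
#' @param params parameter list (see [scr_fit()] details).
#' @return scalar log likelihood.
#' @export
scr_log_likelihood <- function(data, latent, params) {
  traps <- data$traps
  y <- data$y
  M <- data$M
  ll <- 0
  act <- traps$operation == 1
  for (i in seq_len(M)) {
    yi <- matrix(y[i, , ], traps$J, traps$K)
    if (latent$z[i] == 0L) {
      if (any(yi == 1L))
        stop("detection recorded for an individual with z = 0")
      next
    }
    if (any(yi[!act] == 1L))
      stop("detection recorded at a non-operational trap-occasion")
    sig <- sigma_value(params$theta_sigma, params$theta1, params$theta2,
                       0L, latent$sex[i], 0L)   # structured data: type = 0
    d2 <- (traps$coords[, 1] - data$space$centroids[latent$s[i], 1])^2 +
          (traps$coords[, 2] - data$space$centroids[latent$s[i], 2])^2
    kern <- exp(-d2 / (2 * sig^2))
    p0 <- baseline_encounter_prob(params$gamma,
                                  sex = latent$sex[i],
                                  trap_type = matrix(traps$type, traps$J, traps$K),
                                  time_std = traps$time_std)
    p <- p0 * matrix(kern, traps$J, traps$K)
    ll <- ll + sum(ifelse(yi[act] == 1L, log(p[act]), log1p(-p[act])))
  }
  ll
}

#' Movement (auxiliary location) log likelihood
#'
#' Auxiliary fixes (telemetry and opportunistic) are modelled as
#' conditionally independent bivariate normal draws centred on the
#' individual's activity-center centroid with diagonal covariance
#' \eqn{\sigma^2_{un,sex} I}, where the unstructured-data sigma comes from
#' the log-linear sigma model.
#'
#' @param aux data frame of records with columns `individual`, `x`, `y`
#'   (as stored in an [scr_data] object), or an [scr_data] whose `aux`
#'   element is used.
#' @inheritParams scr_log_likelihood
#' @param config model configuration (controls the data-type effect via
#'   the effective inclusion indicator).
#' @return scalar log likelihood (0 when there are no records).
#' @export
movement_log_likelihood <- function(data, latent, params,
                                    config = scr_model_config("full")) {
  aux <- if (inherits(data, "scr_data")) {
    aux_subset(data, config$use_telemetry, config$use_opportunistic)
  } else data$aux
  if (is.null(aux) || nrow(aux) == 0L) return(0)
  if (any(aux$individual > data$n))
    stop("auxiliary record refers to an augmented (unobserved) individual")
  if (any(latent$z[aux$individual] == 0L))
    stop("auxiliary record for an individual with z = 0")
  w_eff <- effective_w(params, config)
  cent <- data$space$centroids[latent$s[aux$individual], , drop = FALSE]
  sig <- sigma_value(params$theta_sigma, params$theta1, params$theta2,
                     w_eff, latent$sex[aux$individual], 1L)
  d2 <- (aux$x - cent[, 1])^2 + (aux$y - cent[, 2])^2
  sum(-log(2 * pi * sig^2) - d2 / (2 * sig^2))
}

# log prior density of the continuous parameters; -Inf outside support.
# The constant Bernoulli(0.5) prior mass of the inclusion indicator is
# state-independent and omitted, so shared-sigma and gvs-with-w=0 states
# have identical joint posterior values (model nesting).
log_prior <- function(params, config) {
  if (params$psi <= 0 || params$psi >= 1) return(-Inf)
  if (params$omega <= 0 || params$omega >= 1) return(-Inf)
  if (abs(params$theta1) > 3) return(-Inf)
  lp <- sum(stats::dnorm(params$gamma, 0, 10, log = TRUE)) +
    stats::dnorm(params$beta1, 0, 10, log = TRUE) +
    stats::dnorm(params$theta_sigma, 0, sqrt(15), log = TRUE) +
    stats::dunif(params$theta1, -3, 3, log = TRUE)
  active <- config$sigma_mode == "split" ||
    (config$sigma_mode == "gvs" && params$w == 1L)
  if (active) {
    if (abs(params$theta2) > 3) return(-Inf)
    lp <- lp + stats::dunif(params$theta2, -3, 3, log = TRUE)
  }
  lp
}

#' Joint log posterior of the integrated model
#'
#' Assembles the structured-data likelihood, the movement likelihood (when
#' auxiliary data are used), the data-augmentation and sex Bernoulli
#' terms, the activity-center prior over pixels, and the parameter priors:
#' Normal(0, 100) on the detection coefficients and the density slope
#' (variance parameterisation), Normal(0, 15) on the log-sigma intercept,
#' Uniform(-3, 3) on the sex and (when active) data-type effects, and
#' Uniform(0, 1) on the augmentation and sex-ratio probabilities.
#'
#' @inheritParams scr_log_likelihood
#' @param config an [scr_model_config].
#' @return scalar log posterior density (up to a normalising constant);
#'   `-Inf` outside the prior support.
#' @export
scr_log_posterior <- function(data, latent, params,
                              config = scr_model_config("scr")) {
  lp <- log_prior(params, config)
  if (!is.finite(lp)) return(-Inf)
  pi_s <- pixel_probabilities(data$space, params$beta1)
  lp <- lp + sum(log(pi_s[latent$s]))
  lp <- lp + sum(latent$z * log(params$psi) + (1 - latent$z) * log1p(-params$psi))
  lp <- lp + sum(latent$sex * log(params$omega) + (1 - latent$sex) * log1p(-params$omega))
  lp <- lp + scr_log_likelihood(data, latent, params)
  if (config$use_telemetry || config$use_opportunistic)
    lp <- lp + movement_log_likelihood(data, latent, params, config)
  lp
}
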