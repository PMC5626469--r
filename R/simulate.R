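# Synthetic-data generator.  Emulates the bear-study design: a mixed array
# of hair traps and rub trees checked over K occasions with variable gaps,
# activity centers from a log-linear inhomogeneous density on a pixel
# grid, sex-specific half-normal trap detections, and auxiliary fixes
# (telemetry: one fix per tracked day; opportunistic: isolated records of
# detected individuals) from the bivariate normal movement model whose
# sigma may differ from the trap-data sigma by the factor exp(theta2).

#' Describe a simulation scenario
#'
#' Bundles the landscape, trap design, generating parameters and auxiliary
#' data design.  The default mirrors the scale of the bear study: 99 hair
#' traps on a regular grid plus 89 randomly placed rub trees, K = 5
#' occasions with 3-10 day gaps, a 4 km pixel grid with a 21 km buffer,
#' augmentation to M = 300, and a density covariate equal to the distance
#' (km) from the landscape center (a synthetic stand-in for distance from
#' a release point).
#'
#' @param n_hair,n_rub numbers of hair traps and rub trees.
#' @param spacing hair-trap grid spacing (km).
#' @param K number of occasions.
#' @param resolution,buffer state-space pixel size and buffer (km).
#' @param M augmented size.
#' @param N true population size (activity centers are drawn conditional
#'   on N; the fitted model's augmentation probability then corresponds to
#'   N / M).
#' @param omega true probability that an individual is male.
#' @param gamma true detection coefficients (intercept, sex, trap type,
#'   time since last check on the standardized scale).
#' @param beta1 true log-density slope on the pixel covariate.
#' @param theta_sigma,theta1,theta2 true log-sigma intercept, sex effect
#'   and data-type effect (theta2 = 0 simulates consistent data types).
#' @param n_collared number of telemetered individuals (balanced across
#'   sexes where possible; collared individuals are chosen among those
#'   detected by the trap array).
#' @param telemetry_days tracked days per collared individual (one fix per
#'   day).
#' @param n_opportunistic total number of opportunistic fixes, spread
#'   uniformly over detected individuals.
#' @param seed integer seed making the generated dataset reproducible.
#' @return list of class `scr_scenario`.
#' @export
scr_scenario <- function(n_hair = 99L, n_rub = 89L, spacing = 4,
                         K = 5L, resolution = 4, buffer = 21, M = 300L,
                         N = 40L, omega = 0.3,
                         gamma = c(-1.5, 1, -1, 0.5), beta1 = -0.05,
                         theta_sigma = log(6), theta1 = 0.22, theta2 = 0.39,
                         n_collared = 2L, telemetry_days = 70L,
                         n_opportunistic = 30L, seed = 1L) {
  stopifnot(N >= 0, M >= 1, K >= 1, n_hair + n_rub >= 1,
            abs(theta1) <= 3, abs(theta2) <= 3, omega > 0, omega < 1)
  structure(
    list(n_hair = as.integer(n_hair), n_rub = as.integer(n_rub),
         spacing = spacing, K = as.integer(K),
         resolution = resolution, buffer = buffer, M = as.integer(M),
         truth = list(N = as.integer(N), omega = omega, gamma = gamma,
                      beta1 = beta1, theta_sigma = theta_sigma,
                      theta1 = theta1, theta2 = theta2),
         aux = list(n_collared = as.integer(n_collared),
                    telemetry_days = as.integer(telemetry_days),
                    n_opportunistic = as.integer(n_opportunistic)),
         seed = as.integer(seed)),
    class = "scr_scenario"
  )
}

#' Draw the latent truth: activity centers and sexes
#'
#' N activity centers are drawn iid from the pixel probabilities of the
#' inhomogeneous density model; sexes are iid Bernoulli(omega).
#'
#' @param space an [scr_state_space].
#' @param beta1 log-density slope.
#' @param N number of individuals.
#' @param omega probability of being male.
#' @param seed optional seed (uses the current RNG stream when `NULL`).
#' @return list with integer vectors `s` (pixel indices) and `sex` (0/1).
#' @export
simulate_truth <- function(space, beta1, N, omega, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(N >= 0)
  pi_s <- pixel_probabilities(space, beta1)
  list(s = if (N > 0) sample.int(space$n_pixels, N, replace = TRUE, prob = pi_s)
           else integer(0),
       sex = if (N > 0) stats::rbinom(N, 1, omega) else integer(0))
}

#' Simulate trap-array detections
#'
#' Bernoulli detections at operational trap-occasions with half-normal
#' encounter probabilities and the structured-data sigma for each
#' individual's sex.
#'
#' @param truth list with `s` and `sex` as from [simulate_truth()].
#' @param traps an [scr_traps].
#' @param space an [scr_state_space].
#' @param gamma,theta_sigma,theta1 generating parameters.
#' @param seed optional seed.
#' @return N x J x K binary array.
#' @export
simulate_scr <- function(truth, traps, space, gamma, theta_sigma, theta1,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- length(truth$s)
  y <- array(0L, dim = c(N, traps$J, traps$K))
  if (N == 0) return(y)
  act <- traps$operation == 1
  for (i in seq_len(N)) {
    sig <- exp(theta_sigma + theta1 * truth$sex[i])
    d2 <- (traps$coords[, 1] - space$centroids[truth$s[i], 1])^2 +
          (traps$coords[, 2] - space$centroids[truth$s[i], 2])^2
    p0 <- baseline_encounter_prob(gamma, truth$sex[i],
                                  matrix(traps$type, traps$J, traps$K),
                                  traps$time_std)
    p <- p0 * matrix(exp(-d2 / (2 * sig^2)), traps$J, traps$K)
    p[!act] <- 0
    y[i, , ] <- stats::rbinom(traps$J * traps$K, 1, as.numeric(p))
  }
  y
}

#' Simulate auxiliary (telemetry and opportunistic) fixes
#'
#' Fixes are iid bivariate normal around each individual's activity-center
#' centroid with the unstructured-data sigma
#' `exp(theta_sigma + theta1 sex + theta2)`.  Telemetry: one fix per
#' tracked day per collared individual.  Opportunistic: `n_opportunistic`
#' isolated fixes attributed to uniformly chosen detected individuals.
#'
#' @param truth latent truth (see [simulate_truth()]).
#' @param space an [scr_state_space].
#' @param collared integer indices of telemetered individuals.
#' @param detected integer indices of trap-detected individuals (the pool
#'   for opportunistic records).
#' @param theta_sigma,theta1,theta2 generating parameters.
#' @param telemetry_days fixes per collared individual.
#' @param n_opportunistic total opportunistic fixes.
#' @param K number of occasions (fix days are mapped evenly onto 1..K for
#'   bookkeeping; occasion labels do not enter the likelihood).
#' @param seed optional seed.
#' @return data frame with columns `individual`, `x`, `y`, `occasion`,
#'   `source` (possibly zero rows).
#' @export
simulate_aux <- function(truth, space, collared, detected,
                         theta_sigma, theta1, theta2,
                         telemetry_days, n_opportunistic, K, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  one <- function(i, n, source) {
    if (n <= 0) return(NULL)
    sig <- exp(theta_sigma + theta1 * truth$sex[i] + theta2)
    cx <- space$centroids[truth$s[i], 1]
    cy <- space$centroids[truth$s[i], 2]
    data.frame(individual = i,
               x = stats::rnorm(n, cx, sig), y = stats::rnorm(n, cy, sig),
               occasion = pmin(K, 1L + ((seq_len(n) - 1L) * K) %/% max(n, 1L)),
               source = source, stringsAsFactors = FALSE)
  }
  out <- list()
  for (i in collared) out[[length(out) + 1L]] <- one(i, telemetry_days, "telemetry")
  if (n_opportunistic > 0 && length(detected)) {
    who <- detected[sample.int(length(detected), n_opportunistic, replace = TRUE)]
    for (i in unique(who))
      out[[length(out) + 1L]] <- one(i, sum(who == i), "opportunistic")
  }
  if (!length(out))
    return(data.frame(individual = integer(0), x = numeric(0), y = numeric(0),
                      occasion = integer(0), source = character(0)))
  do.call(rbind, out)
}

#' Generate a complete synthetic dataset from a scenario
#'
#' Builds the landscape and trap array, draws the latent truth, simulates
#' trap detections and auxiliary fixes, and assembles a validated
#' [scr_data] object.  The generating parameters and the latent truth are
#' attached as attribute `"truth"` for parameter-recovery experiments.
#'
#' @param scenario an [scr_scenario()].
#' @return An [scr_data] object with attribute `truth`.
#' @export
scr_simulate <- function(scenario) {
  stopifnot(inherits(scenario, "scr_scenario"))
  set.seed(scenario$seed)
  tr <- scenario$truth

  # trap array: hair traps on a near-square grid, rub trees scattered
  nx <- max(1L, as.integer(ceiling(sqrt(scenario$n_hair))))
  ny <- as.integer(ceiling(scenario$n_hair / nx))
  gx <- (seq_len(nx) - 1) * scenario$spacing
  gy <- (seq_len(ny) - 1) * scenario$spacing
  hair <- cbind(rep(gx, times = ny), rep(gy, each = nx))[seq_len(scenario$n_hair), , drop = FALSE]
  ext_x <- range(hair[, 1]); ext_y <- range(hair[, 2])
  rub <- cbind(stats::runif(scenario$n_rub, ext_x[1], ext_x[2]),
               stats::runif(scenario$n_rub, ext_y[1], ext_y[2]))
  coords <- rbind(hair, rub)
  type <- c(rep("hair", scenario$n_hair), rep("rub", scenario$n_rub))
  J <- nrow(coords); K <- scenario$K
  operation <- matrix(1L, J, K)
  # 3-10 day gaps between checks, shared across traps of a type
  gaps_hair <- sample(3:10, K, replace = TRUE)
  gaps_rub <- sample(3:10, K, replace = TRUE)
  time_raw <- rbind(
    matrix(rep(gaps_hair, each = scenario$n_hair), scenario$n_hair, K),
    matrix(rep(gaps_rub, each = scenario$n_rub), scenario$n_rub, K))
  traps <- scr_traps(coords, type, operation, time_raw)

  cen <- c(mean(ext_x), mean(ext_y))
  space <- scr_state_space(coords, buffer = scenario$buffer,
                           resolution = scenario$resolution,
                           covariate = function(x, y)
                             sqrt((x - cen[1])^2 + (y - cen[2])^2))

  truth <- simulate_truth(space, tr$beta1, tr$N, tr$omega)
  y <- simulate_scr(truth, traps, space, tr$gamma, tr$theta_sigma, tr$theta1)
  detected <- which(apply(y, 1, sum) > 0)

  # collared individuals: detected ones, balanced across sexes if possible
  collared <- integer(0)
  if (scenario$aux$n_collared > 0 && length(detected)) {
    by_sex <- split(detected, truth$sex[detected])
    want <- scenario$aux$n_collared
    pool <- unlist(lapply(by_sex, function(v) v[seq_len(min(length(v),
                            ceiling(want / length(by_sex))))]))
    collared <- utils::head(unique(c(pool, detected)), want)
  }
  aux <- simulate_aux(truth, space, collared, detected,
                      tr$theta_sigma, tr$theta1, tr$theta2,
                      scenario$aux$telemetry_days,
                      scenario$aux$n_opportunistic, K)

  observed <- sort(unique(c(detected, aux$individual)))
  ids <- sprintf("B%03d", seq_along(truth$s))
  det_idx <- which(y == 1L, arr.ind = TRUE)
  detections <- data.frame(individual_id = ids[det_idx[, 1]],
                           trap_id = traps$ids[det_idx[, 2]],
                           occasion = det_idx[, 3],
                           stringsAsFactors = FALSE)
  sexes <- data.frame(individual_id = ids[observed],
                      sex = ifelse(truth$sex[observed] == 1L, "M", "F"),
                      stringsAsFactors = FALSE)
  aux_df <- if (nrow(aux)) {
    data.frame(individual_id = ids[aux$individual],
               x_km = aux$x, y_km = aux$y, occasion = aux$occasion,
               source = aux$source, stringsAsFactors = FALSE)
  } else NULL

  data <- scr_data(space, traps, detections, sexes, aux_df, M = scenario$M)
  attr(data, "truth") <- c(tr, list(
    s = truth$s, sex = truth$sex, n_observed = length(observed),
    sigma_st_f = exp(tr$theta_sigma),
    sigma_st_m = exp(tr$theta_sigma + tr$theta1),
    sigma_un_f = exp(tr$theta_sigma + tr$theta2),
    sigma_un_m = exp(tr$theta_sigma + tr$theta1 + tr$theta2),
    N_female = sum(truth$sex == 0L), N_male = sum(truth$sex == 1L)))
  data
}
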