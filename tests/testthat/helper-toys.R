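# Small deterministic fixtures used across the suite.

# 1-D strip of nG pixels of side `resolution`, centroids at
# resolution * (g - 0.5) on the x axis, y = 0
toy_space <- function(nG, covariate = rep(0, nG), resolution = 4) {
  scr_state_space(rbind(c(0, 0), c(resolution * nG, 0)),
                  buffer = 0, resolution = resolution,
                  covariate = covariate)
}

toy_traps <- function(coords, K = 1L, type = NULL, operation = NULL,
                      time_raw = NULL) {
  coords <- matrix(coords, ncol = 2)
  J <- nrow(coords)
  if (is.null(type)) type <- rep("hair", J)
  if (is.null(operation)) operation <- matrix(1L, J, K)
  scr_traps(coords, type, operation, time_raw)
}

# two-pixel, two-trap, two-occasion toy with one detected individual
# (female, one detection, one telemetry fix) and M = 3
toy_dataset <- function(M = 3L, aux = TRUE) {
  space <- toy_space(2)                     # centroids (2, 0), (6, 0)
  traps <- toy_traps(rbind(c(1, 0), c(5, 0)), K = 2L,
                     type = c("hair", "rub"),
                     operation = rbind(c(1L, 1L), c(1L, 0L)),
                     time_raw = rbind(c(3, 8), c(5, 0)))
  detections <- data.frame(individual_id = "A", trap_id = "T1", occasion = 1)
  sexes <- data.frame(individual_id = "A", sex = "F")
  aux_df <- if (aux)
    data.frame(individual_id = "A", x_km = 2.5, y_km = 0.4,
               occasion = 1, source = "telemetry")
  else NULL
  scr_data(space, traps, detections, sexes, aux_df, M = M)
}

# dataset with no usable observation process: one never-operational trap,
# no detections, no auxiliary data (posterior = prior)
nodata_dataset <- function(M = 8L, nG = 4L) {
  space <- toy_space(nG)
  traps <- toy_traps(c(0, 0), K = 1L, operation = matrix(0L, 1, 1))
  detections <- data.frame(individual_id = character(0),
                           trap_id = character(0), occasion = integer(0))
  sexes <- data.frame(individual_id = character(0), sex = character(0))
  scr_data(space, traps, detections, sexes, NULL, M = M)
}

# scaled-down bear-like recovery scenario (square trap grid plus rub
# trees, collared individual per sex, opportunistic records)
recovery_scenario <- function(theta2, seed) {
  scr_scenario(n_hair = 36L, n_rub = 24L, spacing = 3, K = 5L,
               resolution = 4, buffer = 12, M = 100L,
               N = 40L, omega = 0.5,
               gamma = c(-1, 0.5, -1, 0.3), beta1 = -0.05,
               theta_sigma = log(3), theta1 = 0.4, theta2 = theta2,
               n_collared = 2L, telemetry_days = 70L,
               n_opportunistic = 30L, seed = seed)
}

default_params <- function(...) scrint:::scr_params(...)
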