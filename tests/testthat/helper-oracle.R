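# Brute-force enumeration oracle for small-support toys.  Computes, with
# plain arithmetic independent of the package's likelihood code, the
# probability of every latent configuration (z, sex, s) given fixed
# parameters, and from it the marginal of the data and the exact full
# conditionals.  Feasible for nG <= 4, M <= 3.

# probability of one latent configuration times the data likelihood
oracle_config_prob <- function(data, latent, params, config) {
  space <- data$space; traps <- data$traps
  pi_s <- {
    mu <- exp(params$beta1 * space$covariate)
    mu / sum(mu)
  }
  pr <- 1
  for (i in seq_len(data$M)) {
    pr <- pr * params$psi^latent$z[i] * (1 - params$psi)^(1 - latent$z[i])
    pr <- pr * params$omega^latent$sex[i] * (1 - params$omega)^(1 - latent$sex[i])
    pr <- pr * pi_s[latent$s[i]]
  }
  # structured likelihood
  for (i in seq_len(data$M)) {
    yi <- matrix(data$y[i, , ], traps$J, traps$K)
    if (latent$z[i] == 0L) {
      if (any(yi == 1L)) return(0)
      next
    }
    sig <- exp(params$theta_sigma + params$theta1 * latent$sex[i])
    for (j in seq_len(traps$J)) {
      d <- sqrt(sum((traps$coords[j, ] - space$centroids[latent$s[i], ])^2))
      for (k in seq_len(traps$K)) {
        if (traps$operation[j, k] == 0L) next
        p0 <- 1 / (1 + exp(-(params$gamma[1] + params$gamma[2] * latent$sex[i] +
                             params$gamma[3] * traps$type[j] +
                             params$gamma[4] * traps$time_std[j, k])))
        p <- p0 * exp(-d^2 / (2 * sig^2))
        pr <- pr * ifelse(yi[j, k] == 1L, p, 1 - p)
      }
    }
  }
  # movement likelihood for the data sources the model uses
  if (!is.null(data$aux) && (config$use_telemetry || config$use_opportunistic)) {
    keep <- (data$aux$source == "telemetry" & config$use_telemetry) |
            (data$aux$source == "opportunistic" & config$use_opportunistic)
    aux <- data$aux[keep, , drop = FALSE]
    w_eff <- switch(config$sigma_mode, shared = 0L, split = 1L,
                    gvs = params$w)
    if (nrow(aux)) {
      for (r in seq_len(nrow(aux))) {
        i <- aux$individual[r]
        if (latent$z[i] == 0L) return(0)
        sig <- exp(params$theta_sigma + params$theta1 * latent$sex[i] +
                   w_eff * params$theta2)
        cen <- data$space$centroids[latent$s[i], ]
        pr <- pr * stats::dnorm(aux$x[r], cen[1], sig) *
                   stats::dnorm(aux$y[r], cen[2], sig)
      }
    }
  }
  pr
}

# all admissible latent configurations (observed individuals keep their
# sex; individuals with detections or aux records have z = 1)
oracle_configs <- function(data) {
  M <- data$M; G <- data$space$n_pixels
  has_data <- rep(FALSE, M)
  if (data$n) has_data[seq_len(data$n)] <- apply(data$y[seq_len(data$n), , , drop = FALSE], 1, sum) > 0
  has_data <- has_data | data$aux_forced
  z_opts <- lapply(seq_len(M), function(i) if (has_data[i]) 1L else 0:1)
  sex_opts <- lapply(seq_len(M), function(i)
    if (!is.na(data$sex[i])) data$sex[i] else 0:1)
  s_opts <- rep(list(seq_len(G)), M)
  grid <- expand.grid(c(z_opts, sex_opts, s_opts), KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(r) {
    v <- as.integer(grid[r, ])
    list(z = v[seq_len(M)], sex = v[M + seq_len(M)], s = v[2 * M + seq_len(M)])
  })
}

# log marginal probability of the data (summed over latent configurations)
oracle_log_marginal <- function(data, params, config) {
  configs <- oracle_configs(data)
  log(sum(vapply(configs, function(l)
    oracle_config_prob(data, l, params, config), numeric(1))))
}

# exact conditional distribution of one latent coordinate given the rest
oracle_conditional <- function(data, latent, params, config, what, i,
                               support) {
  p <- vapply(support, function(v) {
    l <- latent
    l[[what]][i] <- v
    oracle_config_prob(data, l, params, config)
  }, numeric(1))
  p / sum(p)
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}
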