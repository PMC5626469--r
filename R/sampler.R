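# Metropolis-within-Gibbs machinery for the integrated SCR model.
#
# The sampler alternates exact Gibbs updates for the latent state
# (alive indicators z, sexes, activity-center pixels s, and the conjugate
# Beta updates of the augmentation and sex-ratio probabilities) with
# adaptive random-walk Metropolis steps for the continuous parameters and
# a Gibbs-variable-selection (slab-and-spike) update for the data-type
# effect on log sigma.  Heavy likelihood terms go through the C++ kernels
# (src/kernels.cpp): the per-pixel log survival of an all-zero history is
# shared by every undetected individual of a sex, which makes the exact
# categorical activity-center update affordable at several hundred pixels.

# ---- elementary full conditionals (kept separate so they can be checked
# ---- against brute-force enumeration) ---------------------------------

# P(z = 1 | ...) for an augmented all-zero individual with survival q
z_conditional_prob <- function(psi, q) {
  psi * q / (psi * q + (1 - psi))
}

# P(sex = male | ...) given per-sex likelihoods of the individual's data
sex_conditional_prob <- function(omega, lik_male, lik_female) {
  omega * lik_male / (omega * lik_male + (1 - omega) * lik_female)
}

# categorical probabilities from unnormalised log weights
softmax_log <- function(logw) {
  w <- exp(logw - max(logw))
  w / sum(w)
}

# P(w = 1 | ...) in the GVS update: log-likelihood under the active and
# inactive states plus the slab and pseudo-prior log densities at theta2
w_conditional_prob <- function(ll_active, ll_inactive, log_slab, log_pseudo) {
  stats::plogis((ll_active + log_slab) - (ll_inactive + log_pseudo))
}

# slab: Uniform(-3, 3); pseudo-prior: Normal truncated to the slab support
log_slab_density <- function(x) ifelse(abs(x) <= 3, log(1 / 6), -Inf)

log_pseudo_density <- function(x, mean, sd) {
  z <- stats::pnorm(3, mean, sd) - stats::pnorm(-3, mean, sd)
  stats::dnorm(x, mean, sd, log = TRUE) - log(z)
}

r_pseudo <- function(mean, sd) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (abs(x) <= 3) return(x)
  }
}

# ---- precomputation ----------------------------------------------------

sampler_precompute <- function(data, config) {
  traps <- data$traps
  dist2 <- trap_pixel_dist2(traps, data$space)          # J x G
  # per-individual detection index lists (observed individuals only)
  det <- vector("list", data$n)
  for (i in seq_len(data$n)) {
    hits <- which(data$y[i, , , drop = FALSE] == 1L, arr.ind = TRUE)
    det[[i]] <- list(j = as.integer(hits[, 2]), k = as.integer(hits[, 3]))
  }
  detected <- if (data$n) vapply(det, function(d) length(d$j) > 0L, logical(1))
              else logical(0)

  # CSR layout of detections per sex (observed sexes are fixed), for the
  # batched likelihood kernel
  det_csr <- lapply(0:1, function(sx) {
    ind <- which(detected & data$sex[seq_len(data$n)] == sx)
    j <- unlist(lapply(det[ind], `[[`, "j")); if (is.null(j)) j <- integer(0)
    k <- unlist(lapply(det[ind], `[[`, "k")); if (is.null(k)) k <- integer(0)
    off <- c(0L, cumsum(vapply(det[ind], function(d) length(d$j), integer(1))))
    list(ind = ind, j = as.integer(j), k = as.integer(k),
         offsets = as.integer(off))
  })

  # auxiliary sufficient statistics for the active data sources:
  # for individual a with R_a fixes, ssd[a, g] = sum_r ||x_r - c_g||^2
  aux <- aux_subset(data, config$use_telemetry, config$use_opportunistic)
  aux_stats <- NULL
  if (!is.null(aux)) {
    idx <- sort(unique(aux$individual))
    Rn <- Sx <- Sy <- Sq <- numeric(length(idx))
    for (a in seq_along(idx)) {
      rec <- aux[aux$individual == idx[a], , drop = FALSE]
      Rn[a] <- nrow(rec)
      Sx[a] <- sum(rec$x); Sy[a] <- sum(rec$y)
      Sq[a] <- sum(rec$x^2 + rec$y^2)
    }
    cx <- data$space$centroids[, 1]; cy <- data$space$centroids[, 2]
    ssd <- outer(Rn, cx^2 + cy^2) - 2 * (outer(Sx, cx) + outer(Sy, cy)) + Sq
    aux_stats <- list(individual = idx, R = Rn, ssd = ssd)
  }

  pinned <- rep(FALSE, data$M)
  if (data$n) pinned[seq_len(data$n)][detected] <- TRUE
  pinned <- pinned | data$aux_forced

  list(dist2 = dist2, det = det, detected = detected, det_csr = det_csr,
       aux = aux_stats, pinned = pinned, G = data$space$n_pixels)
}

# baseline encounter probability matrices (J x K) for one sex
p0_matrix <- function(traps, gamma, sex) {
  eta <- gamma[1] + gamma[2] * sex +
    outer(gamma[3] * traps$type, rep(1, traps$K)) + gamma[4] * traps$time_std
  stats::plogis(eta)
}

# structured-data log likelihood for one sex, given the latent state.
# Uses the shared all-zero log survival at occupied pixels plus the
# per-individual detection adjustments.
structured_ll_sex <- function(sexval, p0, sigma, state, data, pre,
                              kern = NULL) {
  idx <- which(state$z == 1L & state$sex == sexval)
  if (!length(idx)) return(0)
  pix <- state$s[idx]
  upix <- unique(pix)
  B <- if (is.null(kern))
    kernel_logsurv(pre$dist2, p0, data$traps$operation, sigma, upix)
  else
    kernel_logsurv_k(kern, p0, data$traps$operation, upix)
  ll <- sum(B[match(pix, upix)])
  csr <- pre$det_csr[[sexval + 1L]]
  if (length(csr$ind)) {
    adj <- if (is.null(kern))
      kernel_det_adjust_batch(pre$dist2, p0, csr$j, csr$k, csr$offsets,
                              sigma, state$s[csr$ind])
    else
      kernel_det_adjust_batch_k(pre$dist2, kern, p0, csr$j, csr$k,
                                csr$offsets, sigma, state$s[csr$ind])
    ll <- ll + sum(adj)
  }
  ll
}

structured_ll <- function(state, params, data, pre) {
  sig_f <- exp(params$theta_sigma)
  sig_m <- exp(params$theta_sigma + params$theta1)
  p0f <- p0_matrix(data$traps, params$gamma, 0)
  p0m <- p0_matrix(data$traps, params$gamma, 1)
  structured_ll_sex(0L, p0f, sig_f, state, data, pre) +
    structured_ll_sex(1L, p0m, sig_m, state, data, pre)
}

# movement log likelihood at the current activity centers
movement_ll <- function(state, params, w_eff, data, pre) {
  a <- pre$aux
  if (is.null(a)) return(0)
  sex_a <- state$sex[a$individual]
  sig <- exp(params$theta_sigma + params$theta1 * sex_a + w_eff * params$theta2)
  ssd_cur <- a$ssd[cbind(seq_along(a$individual), state$s[a$individual])]
  sum(-a$R * log(2 * pi * sig^2) - ssd_cur / (2 * sig^2))
}

# One sweep of the exact Gibbs updates for the latent state (z, sex, s)
# with the continuous parameters held fixed.  With fixed parameters,
# iterating this step alone targets p(z, sex, s | y, aux, params), which
# small-support toys can verify by exhaustive enumeration.
gibbs_latent_step <- function(state, params, w_eff, logpi, data, pre, control,
                              kerns = NULL) {
  traps <- data$traps
  M <- data$M; G <- pre$G
  sig_f <- exp(params$theta_sigma)
  sig_m <- exp(params$theta_sigma + params$theta1)
  p0f <- p0_matrix(traps, params$gamma, 0)
  p0m <- p0_matrix(traps, params$gamma, 1)
  allpix <- seq_len(G)
  if (is.null(kerns))
    kerns <- list(f = halfnorm_kernel(pre$dist2, sig_f),
                  m = halfnorm_kernel(pre$dist2, sig_m))
  Bf <- kernel_logsurv_k(kerns$f, p0f, traps$operation, allpix)
  Bm <- kernel_logsurv_k(kerns$m, p0m, traps$operation, allpix)

  # z: augmented all-zero individuals (detected/aux individuals stay 1)
  aug <- which(!pre$pinned)
  if (length(aug)) {
    B_at <- ifelse(state$sex[aug] == 1L, Bm[state$s[aug]], Bf[state$s[aug]])
    pz <- z_conditional_prob(params$psi, exp(B_at))
    state$z[aug] <- stats::rbinom(length(aug), 1, pz)
  }

  # sex: individuals whose sex is unobserved
  unk_sex <- which(is.na(data$sex))
  if (length(unk_sex)) {
    lm <- ifelse(state$z[unk_sex] == 1L, exp(Bm[state$s[unk_sex]]), 1)
    lf <- ifelse(state$z[unk_sex] == 1L, exp(Bf[state$s[unk_sex]]), 1)
    pm <- sex_conditional_prob(params$omega, lm, lf)
    state$sex[unk_sex] <- stats::rbinom(length(unk_sex), 1, pm)
  }

  # activity centers
  sig_un_f <- exp(params$theta_sigma + w_eff * params$theta2)
  sig_un_m <- exp(params$theta_sigma + params$theta1 + w_eff * params$theta2)
  aux_row <- rep(NA_integer_, M)
  if (!is.null(pre$aux)) aux_row[pre$aux$individual] <- seq_along(pre$aux$individual)
  if (G <= control$pixel_gibbs_cap) {
    # exact categorical Gibbs; undetected individuals of a sex share one
    # conditional, individualised only for detected/aux individuals
    prior_only <- softmax_log(logpi)
    w_f <- softmax_log(logpi + Bf); w_m <- softmax_log(logpi + Bm)
    for (i in seq_len(data$n)) {
      male <- state$sex[i] == 1L
      lw <- logpi + (if (male) Bm else Bf)
      d <- pre$det[[i]]
      if (length(d$j))
        lw <- lw + kernel_det_adjust_k(pre$dist2,
                                       if (male) kerns$m else kerns$f,
                                       if (male) p0m else p0f,
                                       d$j, d$k,
                                       if (male) sig_m else sig_f,
                                       allpix)
      if (!is.na(aux_row[i])) {
        sig_un <- if (state$sex[i] == 1L) sig_un_m else sig_un_f
        lw <- lw - pre$aux$ssd[aux_row[i], ] / (2 * sig_un^2)
      }
      state$s[i] <- sample_categorical_log(lw)
    }
    rest <- which(seq_len(M) > data$n)
    if (length(rest)) {
      pz0 <- rest[state$z[rest] == 0L]
      if (length(pz0)) state$s[pz0] <- sample.int(G, length(pz0), TRUE, prior_only)
      for (sx in 0:1) {
        grp <- rest[state$z[rest] == 1L & state$sex[rest] == sx]
        if (length(grp))
          state$s[grp] <- sample.int(G, length(grp), TRUE,
                                     if (sx == 1L) w_m else w_f)
      }
    }
  } else {
    # Metropolis move to a neighbouring pixel (large state spaces)
    state$s <- update_s_metropolis(state, params, data, pre, logpi,
                                   Bf, Bm, p0f, p0m, sig_f, sig_m,
                                   sig_un_f, sig_un_m, aux_row)
  }
  state
}

# ---- single-chain driver ----------------------------------------------

run_chain <- function(data, config, control, gvs_control, pre, chain_seed,
                      verbose = FALSE) {
  set.seed(chain_seed)
  M <- data$M; G <- pre$G
  traps <- data$traps

  # --- initialization ---
  s <- integer(M)
  for (i in seq_len(data$n)) {
    pts <- NULL
    d <- pre$det[[i]]
    if (length(d$j)) pts <- traps$coords[d$j, , drop = FALSE]
    if (!is.null(data$aux)) {
      rec <- data$aux[data$aux$individual == i, , drop = FALSE]
      if (nrow(rec)) pts <- rbind(pts, cbind(rec$x, rec$y))
    }
    s[i] <- if (is.null(pts)) sample.int(G, 1)
            else nearest_pixel(data$space, mean(pts[, 1]), mean(pts[, 2]))
  }
  if (M > data$n) s[(data$n + 1):M] <- sample.int(G, M - data$n, replace = TRUE)
  z <- ifelse(pre$pinned, 1L, stats::rbinom(M, 1, 0.5))
  sex <- data$sex
  sex[is.na(sex)] <- stats::rbinom(sum(is.na(sex)), 1, 0.5)

  spacing <- if (traps$J >= 2) {
    d <- as.matrix(stats::dist(traps$coords)); diag(d) <- Inf
    mean(apply(d, 1, min))
  } else data$space$resolution
  params <- scr_params(theta_sigma = log(max(spacing / 2, 0.01)), w = 1L)

  state <- list(s = s, z = z, sex = sex)
  if (!is.finite(scr_log_posterior(data, state, params, config)))
    stop("non-finite joint log posterior at initialization; check data scaling")

  # --- proposal scales & adaptation ---
  blocks <- c("gamma0", "gamma1", "gamma2", "gamma3", "beta1",
              "theta_sigma", "theta1", "theta2")
  scales <- control$proposal_scales
  if (is.null(scales))
    scales <- c(gamma0 = 0.3, gamma1 = 0.3, gamma2 = 0.3, gamma3 = 0.2,
                beta1 = 0.2, theta_sigma = 0.1, theta1 = 0.15, theta2 = 0.1)
  acc <- att <- stats::setNames(numeric(length(blocks)), blocks)
  acc_total <- att_total <- acc

  # --- GVS bookkeeping ---
  gvs_on <- config$sigma_mode == "gvs"
  pseudo <- c(mean = gvs_control$pseudo_prior_mean,
              sd = gvs_control$pseudo_prior_sd)
  pseudo_fixed <- !is.null(gvs_control$pseudo_prior_mean) &&
                  !is.null(gvs_control$pseudo_prior_sd)
  pilot_n <- if (gvs_on && !pseudo_fixed)
    max(10L, as.integer(gvs_control$pilot_fraction * control$n_burnin)) else 0L
  if (gvs_on && !pseudo_fixed && gvs_control$pilot_fraction <= 0)
    stop("GVS requires a pseudo-prior: supply pseudo_prior_mean/sd or enable pilot tuning")
  pilot_draws <- numeric(0)
  w_eff <- effective_w(params, config)

  # --- storage ---
  n_keep <- control$n_iter %/% control$thin
  par_names <- c("gamma0", "gamma1", "gamma2", "gamma3", "beta1",
                 "theta_sigma", "theta1", "theta2", "w", "psi", "omega",
                 "N", "N_female", "N_male",
                 "sigma_st_f", "sigma_st_m", "sigma_un_f", "sigma_un_m")
  draws <- matrix(NA_real_, n_keep, length(par_names),
                  dimnames = list(NULL, par_names))

  logpi <- log(pixel_probabilities(data$space, params$beta1))
  total_iter <- control$n_burnin + control$n_iter
  aug <- which(!pre$pinned)                # individuals with free z
  unk_sex <- which(is.na(data$sex))        # individuals with free sex

  for (iter in seq_len(total_iter)) {
    in_burnin <- iter <= control$n_burnin
    sig_f <- exp(params$theta_sigma)
    sig_m <- exp(params$theta_sigma + params$theta1)
    p0f <- p0_matrix(traps, params$gamma, 0)
    p0m <- p0_matrix(traps, params$gamma, 1)
    # half-normal kernel matrices: shared by every update at this sigma
    kern_f <- halfnorm_kernel(pre$dist2, sig_f)
    kern_m <- halfnorm_kernel(pre$dist2, sig_m)

    # -- latent state: alive indicators, sexes, activity centers --
    state <- gibbs_latent_step(state, params, w_eff, logpi, data, pre, control,
                               kerns = list(f = kern_f, m = kern_m))

    # -- conjugate Beta updates --
    params$psi <- stats::rbeta(1, 1 + sum(state$z), 1 + M - sum(state$z))
    params$omega <- stats::rbeta(1, 1 + sum(state$sex), 1 + M - sum(state$sex))

    # -- beta1 (density slope): cheap MH on the pixel prior --
    att["beta1"] <- att["beta1"] + 1
    prop <- params$beta1 + stats::rnorm(1, 0, scales["beta1"])
    logpi_prop <- log(pixel_probabilities(data$space, prop))
    lr <- sum(logpi_prop[state$s]) - sum(logpi[state$s]) +
      stats::dnorm(prop, 0, 10, log = TRUE) -
      stats::dnorm(params$beta1, 0, 10, log = TRUE)
    if (is.finite(lr) && log(stats::runif(1)) < lr) {
      params$beta1 <- prop; logpi <- logpi_prop
      acc["beta1"] <- acc["beta1"] + 1
    }

    # -- detection coefficients gamma: scalar random-walk MH --
    ll_f <- structured_ll_sex(0L, p0f, sig_f, state, data, pre, kern_f)
    ll_m <- structured_ll_sex(1L, p0m, sig_m, state, data, pre, kern_m)
    for (c in 1:4) {
      b <- blocks[c]
      att[b] <- att[b] + 1
      gam_prop <- params$gamma
      gam_prop[c] <- gam_prop[c] + stats::rnorm(1, 0, scales[b])
      both <- c != 2L                      # gamma1 enters males only
      p0f_p <- if (both) p0_matrix(traps, gam_prop, 0) else p0f
      p0m_p <- p0_matrix(traps, gam_prop, 1)
      ll_f_p <- if (both)
        structured_ll_sex(0L, p0f_p, sig_f, state, data, pre, kern_f)
      else ll_f
      ll_m_p <- structured_ll_sex(1L, p0m_p, sig_m, state, data, pre, kern_m)
      lr <- (ll_f_p + ll_m_p) - (ll_f + ll_m) +
        stats::dnorm(gam_prop[c], 0, 10, log = TRUE) -
        stats::dnorm(params$gamma[c], 0, 10, log = TRUE)
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        params$gamma <- gam_prop
        p0f <- p0f_p; p0m <- p0m_p; ll_f <- ll_f_p; ll_m <- ll_m_p
        acc[b] <- acc[b] + 1
      }
    }

    # -- log-sigma intercept and sex effect: affect traps and movement --
    ll_mv <- movement_ll(state, params, w_eff, data, pre)
    for (b in c("theta_sigma", "theta1")) {
      att[b] <- att[b] + 1
      par_prop <- params
      par_prop[[b]] <- par_prop[[b]] + stats::rnorm(1, 0, scales[b])
      lp_new <- if (b == "theta_sigma")
        stats::dnorm(par_prop[[b]], 0, sqrt(15), log = TRUE)
      else if (abs(par_prop[[b]]) <= 3) log(1 / 6) else -Inf
      lp_old <- if (b == "theta_sigma")
        stats::dnorm(params[[b]], 0, sqrt(15), log = TRUE)
      else log(1 / 6)
      if (!is.finite(lp_new)) next
      sig_f_p <- exp(par_prop$theta_sigma)
      sig_m_p <- exp(par_prop$theta_sigma + par_prop$theta1)
      ll_f_p <- if (b == "theta1") ll_f
                else structured_ll_sex(0L, p0f, sig_f_p, state, data, pre)
      ll_m_p <- structured_ll_sex(1L, p0m, sig_m_p, state, data, pre)
      ll_mv_p <- movement_ll(state, par_prop, w_eff, data, pre)
      lr <- (ll_f_p + ll_m_p + ll_mv_p + lp_new) -
            (ll_f + ll_m + ll_mv + lp_old)
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        params <- par_prop
        sig_f <- sig_f_p; sig_m <- sig_m_p
        ll_f <- ll_f_p; ll_m <- ll_m_p; ll_mv <- ll_mv_p
        acc[b] <- acc[b] + 1
      }
    }

    # -- data-type effect theta2 / inclusion indicator w --
    if (config$sigma_mode == "split" ||
        (gvs_on && (iter <= pilot_n || params$w == 1L))) {
      # MH for theta2 against the slab (active state)
      att["theta2"] <- att["theta2"] + 1
      prop <- params$theta2 + stats::rnorm(1, 0, scales["theta2"])
      if (abs(prop) <= 3) {
        par_prop <- params; par_prop$theta2 <- prop
        ll_mv_p <- movement_ll(state, par_prop, 1L, data, pre)
        ll_mv_cur <- movement_ll(state, params, 1L, data, pre)
        if (log(stats::runif(1)) < ll_mv_p - ll_mv_cur) {
          params$theta2 <- prop
          acc["theta2"] <- acc["theta2"] + 1
        }
      }
    }
    if (gvs_on) {
      if (iter <= pilot_n) {
        params$w <- 1L                      # pilot phase: slab pinned on
        pilot_draws <- c(pilot_draws, params$theta2)
        if (iter == pilot_n && !pseudo_fixed) {
          pseudo <- c(mean = mean(pilot_draws),
                      sd = max(stats::sd(pilot_draws), 0.05))
        }
      } else {
        ll_act <- movement_ll(state, params, 1L, data, pre)
        ll_ina <- movement_ll(state, params, 0L, data, pre)
        pw <- w_conditional_prob(ll_act, ll_ina,
                                 log_slab_density(params$theta2),
                                 log_pseudo_density(params$theta2,
                                                    pseudo["mean"], pseudo["sd"]))
        params$w <- stats::rbinom(1, 1, pw)
        if (params$w == 0L)
          params$theta2 <- r_pseudo(pseudo["mean"], pseudo["sd"])
      }
      w_eff <- effective_w(params, config)
    }
    ll_mv <- movement_ll(state, params, w_eff, data, pre)

    # -- adaptation (burn-in only; frozen afterwards) --
    if (in_burnin && control$adapt && iter %% 25L == 0L) {
      rate <- ifelse(att > 0, acc / pmax(att, 1), NA)
      for (b in blocks) {
        if (!is.na(rate[b])) {
          scales[b] <- scales[b] * exp(0.3 * (rate[b] - 0.35))
          scales[b] <- min(max(scales[b], 1e-3), 50)
        }
      }
      acc_total <- acc_total + acc; att_total <- att_total + att
      acc[] <- 0; att[] <- 0
    }

    # -- storage --
    if (!in_burnin) {
      it <- iter - control$n_burnin
      if (it %% control$thin == 0L) {
        row <- it %/% control$thin
        w_store <- effective_w(params, config)
        draws[row, ] <- c(params$gamma, params$beta1, params$theta_sigma,
                          params$theta1, params$theta2, w_store,
                          params$psi, params$omega,
                          sum(state$z),
                          sum(state$z * (state$sex == 0L)),
                          sum(state$z * (state$sex == 1L)),
                          exp(params$theta_sigma),
                          exp(params$theta_sigma + params$theta1),
                          exp(params$theta_sigma + w_store * params$theta2),
                          exp(params$theta_sigma + params$theta1 +
                              w_store * params$theta2))
      }
    }
    if (verbose && iter %% 1000L == 0L) {
      message(sprintf("iter %d/%d  acceptance: %s", iter, total_iter,
                      paste(sprintf("%s %.2f", blocks,
                                    acc_total / pmax(att_total, 1)),
                            collapse = " ")))
    }
  }

  acc_total <- acc_total + acc; att_total <- att_total + att
  list(draws = draws,
       acceptance = acc_total / pmax(att_total, 1),
       scales = scales,
       pseudo_prior = if (gvs_on) pseudo else NULL)
}

# Metropolis fallback for the activity-center update on very large grids:
# propose one of the (up to) 4 rook-neighbour pixels uniformly.
update_s_metropolis <- function(state, params, data, pre, logpi,
                                Bf, Bm, p0f, p0m, sig_f, sig_m,
                                sig_un_f, sig_un_m, aux_row) {
  sp <- data$space
  G <- sp$n_pixels
  s_logw <- function(i, g) {
    lw <- logpi[g] + if (state$z[i] == 1L) {
      (if (state$sex[i] == 1L) Bm[g] else Bf[g])
    } else 0
    if (i <= data$n && state$z[i] == 1L) {
      d <- pre$det[[i]]
      if (length(d$j))
        lw <- lw + kernel_det_adjust(pre$dist2,
                                     if (state$sex[i] == 1L) p0m else p0f,
                                     d$j, d$k,
                                     if (state$sex[i] == 1L) sig_m else sig_f,
                                     g)[1]
      if (!is.na(aux_row[i])) {
        sig_un <- if (state$sex[i] == 1L) sig_un_m else sig_un_f
        lw <- lw - pre$aux$ssd[aux_row[i], g] / (2 * sig_un^2)
      }
    }
    lw
  }
  s <- state$s
  for (i in seq_len(data$M)) {
    g <- s[i]
    gx <- (g - 1L) %% sp$nx; gy <- (g - 1L) %/% sp$nx
    nb <- c(if (gx > 0L) g - 1L, if (gx < sp$nx - 1L) g + 1L,
            if (gy > 0L) g - sp$nx, if (gy < sp$ny - 1L) g + sp$nx)
    prop <- nb[sample.int(length(nb), 1)]
    # neighbour counts differ at edges: Hastings correction
    lr <- s_logw(i, prop) - s_logw(i, g) +
      log(length(nb)) - log(neighbour_count(prop, sp))
    if (is.finite(lr) && log(stats::runif(1)) < lr) s[i] <- prop
  }
  s
}

neighbour_count <- function(g, sp) {
  gx <- (g - 1L) %% sp$nx; gy <- (g - 1L) %/% sp$nx
  sum(gx > 0L, gx < sp$nx - 1L, gy > 0L, gy < sp$ny - 1L)
}
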