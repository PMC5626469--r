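#' Multi-model comparison report
#'
#' Assembles the comparison across fitted model variants: sex-specific
#' population size, sigma by sex (and data type for the GVS/split model),
#' 95% home-range areas, the rounded percent difference in median
#' abundance relative to a reference model, and the posterior inclusion
#' probability of the data-type effect where applicable.
#'
#' @param fits named list of [scr_fit] objects (names become the model
#'   column; defaults to each fit's model name).
#' @param reference name or index of the reference model for percent
#'   differences (default: the first).
#' @param hr_level home-range probability level.
#' @return data frame with one row per model x parameter.
#' @export
scr_report <- function(fits, reference = 1L, hr_level = 0.95) {
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, logical(1), "scr_fit")))
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, function(f) f$config$model, character(1))
  ref <- fits[[reference]]
  ref_med <- apply(pooled_draws(ref)[, c("N_female", "N_male")], 2, stats::median)

  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    d <- pooled_draws(f)
    split_sigma <- f$config$sigma_mode %in% c("gvs", "split")
    pars <- c("N_female", "N_male",
              if (split_sigma) c("sigma_st_f", "sigma_st_m",
                                 "sigma_un_f", "sigma_un_m")
              else c("sigma_st_f", "sigma_st_m"))
    s <- draws_summary(d[, pars, drop = FALSE])
    if (!split_sigma)
      s$parameter <- sub("sigma_st", "sigma", s$parameter)
    s$model <- nm
    hr <- grepl("^sigma", s$parameter)
    s$hr_area <- ifelse(hr, home_range_area(s$mean, sd = s$sd, level = hr_level), NA)
    s$hr_lwr <- ifelse(hr, home_range_area(s$`q2.5`, level = hr_level), NA)
    s$hr_upr <- ifelse(hr, home_range_area(s$`q97.5`, level = hr_level), NA)
    s$pct_diff_vs_ref <- NA_real_
    for (p in c("N_female", "N_male")) {
      i <- s$parameter == p
      s$pct_diff_vs_ref[i] <- percent_difference(ref_med[p], s$`q50`[i])
    }
    s$pr_w <- if (f$config$sigma_mode == "gvs") mean(d[, "w"]) else NA_real_
    s
  })
  out <- do.call(rbind, rows)
  out[, c("model", "parameter", "mean", "sd", "q2.5", "q50", "q97.5",
          "hr_area", "hr_lwr", "hr_upr", "pct_diff_vs_ref", "pr_w")]
}

#' Write posterior draws as a tidy CSV
#'
#' One row per (chain, iteration, parameter, value).
#'
#' @param fit an [scr_fit].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(fit, path) {
  stopifnot(inherits(fit, "scr_fit"))
  tabs <- lapply(seq_along(fit$draws), function(c) {
    d <- fit$draws[[c]]
    data.frame(chain = c, iteration = rep(seq_len(nrow(d)), ncol(d)),
               parameter = rep(colnames(d), each = nrow(d)),
               value = as.numeric(d))
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
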