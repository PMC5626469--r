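#' Gelman-Rubin potential scale reduction factor
#'
#' Classical R-hat computed from between- and within-chain variances:
#' with m chains of length n, within-chain variance W (mean of the
#' per-chain sample variances) and B/n the variance of the chain means,
#' \eqn{\hat R = \sqrt{((n-1)/n \, W + B/n) / W}}.  Values near 1 indicate
#' convergence; the study used a threshold of 1.02.
#'
#' @param chains a matrix with one column per chain (rows = iterations),
#'   or a list of equal-length numeric vectors.
#' @return scalar R-hat.
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  m <- ncol(chains); n <- nrow(chains)
  if (m < 2L) stop("at least 2 chains are required")
  if (n < 2L) stop("chains must have length >= 2")
  W <- mean(apply(chains, 2, stats::var))
  if (W == 0) stop("degenerate chains: zero within-chain variance")
  B_over_n <- stats::var(colMeans(chains))
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' 95% home-range area from the spatial scale parameter
#'
#' Area of the circle containing a given probability mass of a bivariate
#' normal utilisation distribution with scale `sigma`:
#' \eqn{A = \pi \, \chi^2_{level}(2) \, \sigma^2} (km^2).  When a
#' posterior summary (mean and SD) of sigma is supplied, the posterior
#' mean area is \eqn{\pi \chi^2 (\mathrm{mean}^2 + \mathrm{SD}^2)} because
#' \eqn{E[\sigma^2] = E[\sigma]^2 + Var[\sigma]}; quantile endpoints map
#' through the monotone transform \eqn{A(q) = \pi \chi^2 q^2}.
#'
#' @param sigma spatial scale (km), or its posterior mean when `sd` is
#'   given; vectorised.
#' @param sd optional posterior SD of sigma.
#' @param level probability level of the home range (default 0.95).
#' @return home-range area in km^2.
#' @examples
#' home_range_area(1)                      # pi * 5.99146 = 18.82 km^2
#' home_range_area(3.355, sd = 0.582)      # posterior-mean area
#' @export
home_range_area <- function(sigma, sd = NULL, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (any(sigma < 0)) stop("sigma must be nonnegative")
  q2 <- stats::qchisq(level, df = 2)
  if (is.null(sd)) {
    pi * q2 * sigma^2
  } else {
    if (any(sd < 0)) stop("sd must be nonnegative")
    pi * q2 * (sigma^2 + sd^2)
  }
}

#' Rounded percent difference between two point estimates
#'
#' `round(100 * (a - b) / a)`, the convention used to report the shift in
#' median abundance between two models.
#'
#' @param a reference estimate.
#' @param b comparison estimate.
#' @return integer percent difference.
#' @export
percent_difference <- function(a, b) {
  round(100 * (a - b) / a)
}

# posterior summary of a draw matrix: mean, SD, 2.5/50/97.5% quantiles
# (type-7 linear-interpolation quantiles, the R default)
draws_summary <- function(draws) {
  draws <- as.matrix(draws)
  qs <- t(apply(draws, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
                type = 7, names = FALSE))
  data.frame(
    parameter = colnames(draws),
    mean = colMeans(draws),
    sd = apply(draws, 2, stats::sd),
    `q2.5` = qs[, 1], `q50` = qs[, 2], `q97.5` = qs[, 3],
    check.names = FALSE, row.names = NULL
  )
}
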