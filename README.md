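# scrint

Integrated Bayesian spatial capture-recapture (SCR) with a model-based
test for consistency of the spatial scale parameter across data types.

## The problem

SCR estimates animal density and space use from spatially referenced
encounter histories: the probability that individual *i* is detected at
trap *j* declines with the distance between the trap and the
individual's latent activity center *s<sub>i</sub>*. For rare or elusive
species the structured trap data are sparse, so it is attractive to fold
in other georeferenced observations of identified individuals —
telemetry fixes from collared animals and opportunistic records (e.g.
DNA from damage sites reported by the public). Both are direct
observations of space use and share the activity centers and the spatial
scale parameter σ with the trap model.

Joint modelling, however, silently assumes that all data types measure
the *same* σ. Trap encounters may be tied to specific behaviours
(territorial rubbing, hair deposition near a home-range core) while
telemetry records passive movement, so the implied scales can differ.
`scrint` fits the integrated model and, in the same framework, tests the
consistency assumption with Bayesian variable selection.

## The model

Detections are Bernoulli with a sex-specific half-normal kernel,

> y<sub>ijk</sub> ~ Bernoulli(p<sub>ijk</sub>),
> p<sub>ijk</sub> = p<sub>0,ijk</sub> exp(−d(x<sub>j</sub>, s<sub>i</sub>)² / 2σ²<sub>sex</sub>),
> logit(p<sub>0,ijk</sub>) = γ₀ + γ₁ sex<sub>i</sub> + γ₂ trap<sub>j</sub> + γ₃ time<sub>jk</sub>,

with trap type (hair trap vs rub tree) and standardized
time-since-last-check covariates. Activity centers live on a discrete
pixel grid with a log-linear density covariate (inhomogeneous binomial
point process), log μ(s<sub>g</sub>) = β₁ c<sub>g</sub>, normalised to
pixel probabilities π(s<sub>g</sub>). Auxiliary locations are bivariate
normal around the activity center with the unstructured-data σ. Total
and sex-specific population size come from data augmentation
(z<sub>i</sub> ~ Bernoulli(ψ), sex<sub>i</sub> ~ Bernoulli(ω)).

The consistency test writes the scale parameter as

> log σ<sub>type,sex</sub> = θ<sub>σ</sub> + θ₁ sex + w θ₂ type,

where `type` flags unstructured data and *w* is a latent inclusion
indicator with a Bernoulli(0.5) prior, sampled by Gibbs variable
selection with a pilot-tuned pseudo-prior (slab-and-spike). The
posterior mean of *w* is the probability that structured and
unstructured data carry different spatial scales; θ₂ | w = 1 estimates
the difference. Space use is summarised as the 95% home-range area
A = π χ²₀.₉₅(2) σ².

Everything is fitted with a bespoke Metropolis-within-Gibbs sampler
(exact categorical updates for activity centers, conjugate updates for
ψ and ω, adaptive random-walk Metropolis for the regression
coefficients), with C++ kernels for the likelihood hot path.

## Worked example

Simulate a reduced-scale study (60 traps, 5 occasions, N = 40, two
collared individuals, 30 opportunistic records) with a true data-type
effect θ₂ = 0.4, then fit the fully integrated model with the
consistency test:

```r
library(scrint)

sc <- scr_scenario(n_hair = 36, n_rub = 24, spacing = 3, K = 5,
                   resolution = 4, buffer = 12, M = 100, N = 40,
                   omega = 0.5, gamma = c(-1, 0.5, -1, 0.3), beta1 = -0.05,
                   theta_sigma = log(3), theta1 = 0.4, theta2 = 0.4,
                   n_collared = 2, telemetry_days = 70,
                   n_opportunistic = 30, seed = 42)
bears <- scr_simulate(sc)
fit <- scr_fit(bears, "full-gvs",
               control = scr_mcmc_control(n_chains = 3, n_iter = 4000,
                                          n_burnin = 800, seed = 1))
fit
#> Integrated SCR model fit ('full-gvs')
#>   data: n = 30 observed, M = 100, J = 60 traps, K = 5 occasions, 100 pixels
#>   aux records used: telemetry 140, opportunistic 30
#>   chains: 3 x 4000 post-burn-in draws (burn-in 800)
#>   posterior median N = 40 (females 12, males 27)
#>   Pr(data-type effect on sigma) = 1.000

summary(fit, pars = c("N_female", "N_male", "sigma_st_f", "sigma_un_f",
                      "theta2", "w"))
#>    parameter       mean         sd       q2.5        q50      q97.5     Rhat
#> 1   N_female 13.0514167 4.14859903  7.0000000 12.0000000 23.0000000 1.000797
#> 2     N_male 27.7667500 3.15335901 23.0000000 27.0000000 35.0000000 1.002068
#> 3 sigma_st_f  2.8000638 0.18694589  2.4874796  2.7836689  3.2259443 1.003326
#> 4 sigma_un_f  4.2160776 0.22255275  3.8070267  4.2032286  4.6908628 1.003720
#> 5     theta2  0.4100648 0.05901461  0.2862931  0.4125974  0.5189878 1.002267
#> 6          w  1.0000000 0.00000000  1.0000000  1.0000000  1.0000000       NA
```

The true values (N = 40, σ<sub>st,f</sub> = 3, θ₂ = 0.4) sit inside the
95% credible intervals; the posterior inclusion probability
`inclusion_probability(fit)` is 1 — the sampler flags the simulated
inconsistency between trap-based and location-based space use. The
female structured-data 95% home range follows as

```r
s_f <- summary(fit, pars = "sigma_st_f")
home_range_area(s_f$mean, sd = s_f$sd)
#> [1] 148.2348   # km^2
```

All five model variants (`"scr"`, `"scr+tel"`, `"scr+opp"`, `"full"`,
`"full-gvs"`) are compared with `scr_report(list_of_fits)`, which
tabulates sex-specific abundance, σ by sex/data type, home-range areas
and percent differences in median abundance.

A thin command-line front end wrapping these functions (simulate / fit /
summarize / report, YAML config) is installed at
`system.file("cli", "scrint.R", package = "scrint")`.

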