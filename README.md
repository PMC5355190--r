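# mastSSM

Bayesian seasonal state-space modelling of woodland rodent population
dynamics driven by ash masting, winter temperature and density dependence —
for population ecologists analysing long-term capture–mark–release series
of bank voles (*Myodes glareolus*) and wood mice (*Apodemus sylvaticus*)
censused twice a year, and for anyone who needs a fully testable
implementation of this model family.

## The model

True abundances are latent: December adults `Na_dec,t`, June adults
`Na_jun,t` and June juveniles `Nj_t`. Each year decomposes into three
stochastic Gompertz transitions whose log-scale rates are linear in
standardized forcings and (centered) log abundance:

    wgrowth_t = a_wg + b1*Ash_mar[t-1] + b2*Temp[t-1] + b3*log(Na_dec[t-1])
                + b4*Ash_mar[t-1]*log(Na_dec[t-1])
                + b5*Temp[t-1]*log(Na_dec[t-1]) + e_wg,t
    Na_jun,t ~ Poisson(Na_dec,t-1 * exp(wgrowth_t))

with analogous *reproduction* (`Nj_t`) and *summer growth* equations (the
summer submodel replaces temperature with current September–December
fruit-fall and uses the June total `Na_jun + Nj`). Observations are
two-occasion binomial removal samples per class: `c1 ~ Bin(N, p)`,
`c2 ~ Bin(N - c1, p)`. Inference is MCMC (JAGS) under non-informative
priors — Gamma(0.001, 0.001) on precisions, Normal(0, 1000) on
coefficients, Uniform(0, 1) on capture probabilities — with the two-stage
centering procedure for the latent log-abundance terms. An effect is
declared significant when its 95% credible interval excludes zero.

A simplified model (`fitExperiment()`) estimates year-specific rates
separately for control and fruit-addition areas and classifies the
credible-interval overlap per year; deterministic helpers
(`seedsToDensity()`, `additionDensity()`, `abortedFraction()`) implement
the fruit-fall accounting arithmetic.

See the vignette `vignettes/seasonal-state-space-model.Rmd` for the
complete account, including the synthetic-data generator that defines the
study conditions every test runs under.

## Worked example

```r
library(mastSSM)

cfg <- scenarioConfig(seed = 42)        # 33-year study conditions
ds  <- generateDataset(cfg)             # trap counts + generating truth

fit <- fitStateSpace(ds$trap, ds$covariates,
                     mcmc = mcmcConfig(nChains = 3, nAdapt = 500,
                                       nIter = 2500, nBurnin = 1000,
                                       seed = 7))
parameterTable(fit$posterior)
```

Selected rows of the output (medians with 95% CrIs; generating values
`alpha_wg = -1.2`, `beta_wg_1 = 0.8`, `p_adult_june = 0.6`):

    parameter        median  lower  upper  excludesZero rhat
    alpha_wg         -1.155 -1.369 -0.957  TRUE         1.0
    beta_wg_1         0.851  0.574  1.170  TRUE         1.0
    beta_wg_3        -0.286 -0.507 -0.013  TRUE         1.0
    beta_wg_4         0.461 -0.252  1.188  FALSE        1.0
    p_adult_june      0.622  0.555  0.685  TRUE         1.0
    sigma_wg          0.152  0.034  0.363  TRUE         1.0

The mast coefficient on winter growth (`beta_wg_1`) is recovered with an
interval excluding zero — the analysis' headline inference — while the
interaction (`beta_wg_4`, true value 0) correctly does not. The capture
probability and density-dependence (`beta_wg_3`, true −0.4) estimates
bracket their generating values. `plotCoefficients(fit$posterior)` draws
the forest plot; `runFit()` wraps the same pipeline with CSV/figure/
manifest output, and `runSimulation()` / `runExperiment()` do the same
for data generation and the food-addition comparison.

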