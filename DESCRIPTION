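Package: mastSSM
Title: Seasonal State-Space Models of Masting-Driven Rodent Population Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Bayesian seasonal state-space modelling of woodland rodent
    (bank vole and wood mouse) population dynamics driven by ash fruit-fall
    (masting), winter temperature and density dependence. The process layer
    couples three stochastic Gompertz submodels (winter growth, spring
    reproduction, summer growth) through Poisson state transitions; the
    observation layer is a two-occasion binomial removal model for trap
    counts. Includes MCMC inference via JAGS with the two-stage centering
    procedure for latent log-abundances, a simplified year-by-year rate
    model for food-addition experiments, a synthetic-data generator for
    parameter-recovery studies, and deterministic fruit-fall accounting
    utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, rjags, coda, jsonlite, ggplot2
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
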