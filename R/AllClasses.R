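#' @import methods
#' @importFrom stats rnorm rpois rbinom runif dbinom quantile median sd var setNames
NULL

TRAP_COLS <- c("adults_june_1", "adults_june_2",
               "juveniles_june_1", "juveniles_june_2",
               "adults_december_1", "adults_december_2")

SUBMODELS <- c("wg", "r", "sg")

#' TrapSeries: yearly two-occasion removal trap counts
#'
#' Holds, for each study year, the two successive 24-hr trap counts for three
#' demographic classes: adults in June, juveniles in June, and adults in
#' December. Occasion-2 counts exclude animals already caught on occasion 1
#' (removal design); this disjointness is a semantic contract of the data,
#' asserted by the synthetic generator. Missing trapping sessions are `NA`
#' and contribute no observation likelihood, but their years remain in the
#' latent state chain.
#'
#' @slot years integer vector, strictly increasing study years.
#' @slot counts integer matrix, one row per year, columns
#'   `adults_june_1/2`, `juveniles_june_1/2`, `adults_december_1/2`;
#'   `NA` marks a missing session.
#' @export
setClass("TrapSeries",
  representation(years = "integer", counts = "matrix"))

setValidity("TrapSeries", function(object) {
  msg <- character()
  y <- object@years
  cnt <- object@counts
  if (nrow(cnt) != length(y))
    msg <- c(msg, "counts must have one row per year")
  if (!identical(colnames(cnt), TRAP_COLS))
    msg <- c(msg, sprintf("counts columns must be: %s",
                          paste(TRAP_COLS, collapse = ", ")))
  if (length(y) && any(diff(y) <= 0))
    msg <- c(msg, "years must be strictly increasing")
  v <- cnt[!is.na(cnt)]
  if (length(v)) {
    if (any(v < 0)) msg <- c(msg, "trap counts must be non-negative")
    if (any(v != round(v))) msg <- c(msg, "trap counts must be integers")
  }
  if (length(msg)) msg else TRUE
})

#' CovariateSeries: mast and winter-temperature forcings
#'
#' Raw and standardized (z-scored) environmental covariates. Indexing
#' convention (important): the winter spanning calendar years (t-1, t) is
#' stored under index t-1, matching the model subscripts Ash_mar[t-1] and
#' Temp[t-1]. So the row for year t carries the September(t)--March(t+1)
#' fruit-fall and the December(t)--March(t+1) mean minimum temperature that
#' drive the December(t) -> June(t+1) transition, together with the
#' September(t)--December(t) early fruit-fall Ash_dec that drives the
#' June(t) -> December(t) transition of the same calendar year t... with
#' one caveat: `ashDec` is indexed by the calendar year of its own autumn,
#' i.e. row t holds Ash_dec[t].
#'
#' @slot years integer vector of index years t.
#' @slot raw numeric matrix with columns `ash_mar`, `ash_dec`, `temp`
#'   (g/m2 dry edible seed, g/m2, degrees C).
#' @slot z numeric matrix of per-column z-scores over non-missing years.
#' @slot scaling numeric matrix (2 rows: mean, sd) used for standardization,
#'   retained for back-transformation.
#' @export
setClass("CovariateSeries",
  representation(years = "integer", raw = "matrix",
                 z = "matrix", scaling = "matrix"))

setValidity("CovariateSeries", function(object) {
  msg <- character()
  cols <- c("ash_mar", "ash_dec", "temp")
  if (!identical(colnames(object@raw), cols))
    msg <- c(msg, "raw columns must be ash_mar, ash_dec, temp")
  if (nrow(object@raw) != length(object@years))
    msg <- c(msg, "raw must have one row per year")
  if (!identical(dim(object@raw), dim(object@z)))
    msg <- c(msg, "z must match raw in shape")
  ash <- object@raw[, c("ash_mar", "ash_dec")]
  if (any(ash < 0, na.rm = TRUE))
    msg <- c(msg, "ash fruit-fall must be non-negative")
  for (j in cols) {
    zj <- object@z[, j][!is.na(object@z[, j])]
    if (length(zj) >= 2) {
      if (abs(mean(zj)) > 1e-9)
        msg <- c(msg, sprintf("standardized %s must have mean 0", j))
      if (abs(sd(zj) - 1) > 1e-9)
        msg <- c(msg, sprintf("standardized %s must have sd 1", j))
    }
  }
  if (length(msg)) msg else TRUE
})

#' LatentStates: true yearly abundances
#'
#' Latent abundances per study year: adults in June (`naJun`), juveniles in
#' June (`nj`), adults in December (`naDec`). There are no December
#' juveniles (no winter breeding). In model fits these are estimated; in
#' synthetic datasets they are the generating truth. `NA` marks states that
#' are undefined under the chain's timing (e.g. June of the first year,
#' which precedes the first modelled December).
#'
#' @slot years integer vector.
#' @slot naJun,nj,naDec integer vectors of abundances (>= 0).
#' @export
setClass("LatentStates",
  representation(years = "integer", naJun = "integer",
                 nj = "integer", naDec = "integer"))

setValidity("LatentStates", function(object) {
  msg <- character()
  n <- length(object@years)
  for (s in c("naJun", "nj", "naDec")) {
    v <- slot(object, s)
    if (length(v) != n) msg <- c(msg, sprintf("%s must have length %d", s, n))
    if (any(v < 0, na.rm = TRUE)) msg <- c(msg, sprintf("%s must be >= 0", s))
  }
  if (length(msg)) msg else TRUE
})

#' ProcessParams: parameters of the three seasonal submodels
#'
#' Each seasonal submodel s in {wg (winter growth), r (reproduction),
#' sg (summer growth)} has a log-scale intercept alpha_s, five coefficients
#' beta_s,1..5 and a process standard deviation sigma_s. For wg and r the
#' coefficients multiply (1) standardized September--March ash fruit-fall,
#' (2) standardized winter temperature, (3) centered log December adult
#' abundance, and (4,5) the two covariate-by-log-abundance interactions.
#' For sg they multiply (1) lagged September--March ash, (2) current
#' September--December ash, (3) centered log June total abundance, and
#' (4,5) the interactions.
#'
#' @slot alpha named numeric(3), log-scale intercepts for wg, r, sg.
#' @slot beta 3x5 numeric matrix, rows wg/r/sg.
#' @slot sigma named numeric(3), process SDs (> 0).
#' @export
setClass("ProcessParams",
  representation(alpha = "numeric", beta = "matrix", sigma = "numeric"))

setValidity("ProcessParams", function(object) {
  msg <- character()
  if (!identical(names(object@alpha), SUBMODELS))
    msg <- c(msg, "alpha must be named wg, r, sg")
  if (!identical(rownames(object@beta), SUBMODELS) ||
      ncol(object@beta) != 5L)
    msg <- c(msg, "beta must be a 3x5 matrix with rows wg, r, sg")
  if (!identical(names(object@sigma), SUBMODELS))
    msg <- c(msg, "sigma must be named wg, r, sg")
  if (any(!is.finite(object@sigma)) || any(object@sigma <= 0))
    msg <- c(msg, "all sigma must be > 0")
  if (length(msg)) msg else TRUE
})

#' CaptureProbs: per-class capture probabilities
#'
#' One capture probability per demographic class and season, shared by the
#' two removal occasions and constant across all years (constant
#' trappability within each trapping period).
#'
#' @slot pAdultJune,pJuvenile,pAdultDecember numeric in [0, 1].
#' @export
setClass("CaptureProbs",
  representation(pAdultJune = "numeric", pJuvenile = "numeric",
                 pAdultDecember = "numeric"))

setValidity("CaptureProbs", function(object) {
  p <- c(object@pAdultJune, object@pJuvenile, object@pAdultDecember)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    "capture probabilities must lie in [0, 1]" else TRUE
})

#' CenteringConstants: fixed centering for latent log-abundances
#'
#' The latent log-abundances entering the density-dependence terms cannot be
#' centered before fitting (they are estimated). The two-stage procedure
#' fits the no-interaction model first and uses the posterior means of
#' log(Na_dec) and log(Na_jun + Nj), averaged over years, as fixed centering
#' constants in the final interaction model.
#'
#' @slot meanLogNaDec numeric, centering constant for log December adults.
#' @slot meanLogNJunTotal numeric, centering constant for log June total.
#' @export
setClass("CenteringConstants",
  representation(meanLogNaDec = "numeric", meanLogNJunTotal = "numeric"))

setValidity("CenteringConstants", function(object) {
  if (!is.finite(object@meanLogNaDec) || !is.finite(object@meanLogNJunTotal))
    "centering constants must be finite" else TRUE
})

#' PriorSpec: prior hyperparameters for the state-space fits
#'
#' Defaults follow the non-informative choices of the study: Gamma priors
#' with mean 1 and variance 1000 on the process precisions 1/sigma^2
#' (shape = rate = 0.001 -- stated explicitly because the Gamma
#' shape/rate-vs-scale ambiguity is a classic replication trap), Normal
#' mean 0 variance 1000 on intercepts and coefficients (sd = sqrt(1000)),
#' Uniform(0, 1) on capture probabilities, and Uniform(0, 1000) on the
#' number of adults in December of the first year.
#'
#' @slot precisionShape,precisionRate Gamma hyperparameters on 1/sigma^2.
#' @slot coefMean,coefSd Normal hyperparameters on alpha and beta.
#' @slot initAbundanceMax upper bound of the Uniform prior on the first
#'   December adult abundance.
#' @export
setClass("PriorSpec",
  representation(precisionShape = "numeric", precisionRate = "numeric",
                 coefMean = "numeric", coefSd = "numeric",
                 initAbundanceMax = "numeric"))

setValidity("PriorSpec", function(object) {
  msg <- character()
  if (object@precisionShape <= 0 || object@precisionRate <= 0)
    msg <- c(msg, "Gamma hyperparameters must be positive")
  if (object@coefSd <= 0) msg <- c(msg, "coefSd must be positive")
  if (object@initAbundanceMax <= 0)
    msg <- c(msg, "initAbundanceMax must be positive")
  if (length(msg)) msg else TRUE
})

#' McmcConfig: MCMC protocol
#'
#' @slot nChains number of chains (>= 2 for convergence diagnostics).
#' @slot nAdapt adaptation iterations.
#' @slot nIter total post-adaptation iterations per chain.
#' @slot nBurnin iterations discarded as burn-in (< nIter).
#' @slot thin retain one draw in `thin`.
#' @slot seed base RNG seed; chain c uses seed + c.
#' @export
setClass("McmcConfig",
  representation(nChains = "integer", nAdapt = "integer", nIter = "integer",
                 nBurnin = "integer", thin = "integer", seed = "integer"))

setValidity("McmcConfig", function(object) {
  msg <- character()
  if (object@nBurnin >= object@nIter)
    msg <- c(msg, "nBurnin must be smaller than nIter")
  if (object@thin < 1L) msg <- c(msg, "thin must be >= 1")
  if (object@nChains < 1L) msg <- c(msg, "nChains must be >= 1")
  if (length(msg)) msg else TRUE
})

#' PosteriorSummary: per-parameter posterior summaries
#'
#' Medians, central 95% credible intervals (2.5% and 97.5% quantiles,
#' type-7), the excludes-zero flag used as the study's significance
#' convention, and the Gelman--Rubin R-hat per parameter. Latent-state
#' summaries are kept in a separate table. The thinned post-burn-in draws
#' are retained as a `coda::mcmc.list` for downstream use.
#'
#' @slot parameters data.frame: parameter, median, lower, upper,
#'   excludesZero, rhat.
#' @slot latents data.frame: state, year, median, lower, upper.
#' @slot draws mcmc.list of monitored scalar parameters.
#' @slot centering CenteringConstants used in the fit (stage-2 fits).
#' @slot converged logical: TRUE when all reported R-hat <= threshold.
#' @slot rhatThreshold numeric convergence cutoff (default 1.1).
#' @export
setClass("PosteriorSummary",
  representation(parameters = "data.frame", latents = "data.frame",
                 draws = "ANY", centering = "ANY",
                 converged = "logical", rhatThreshold = "numeric"))

setValidity("PosteriorSummary", function(object) {
  msg <- character()
  need <- c("parameter", "median", "lower", "upper", "excludesZero", "rhat")
  if (!all(need %in% names(object@parameters)))
    msg <- c(msg, sprintf("parameters must contain columns: %s",
                          paste(need, collapse = ", ")))
  p <- object@parameters
  if (nrow(p)) {
    bad <- !is.na(p$lower) & (p$lower > p$median | p$median > p$upper)
    if (any(bad))
      msg <- c(msg, "credible intervals must bracket the median")
    flag <- (p$lower > 0) | (p$upper < 0)
    if (any(flag != p$excludesZero, na.rm = TRUE))
      msg <- c(msg, "excludesZero inconsistent with interval bounds")
  }
  if (length(msg)) msg else TRUE
})

#' ScenarioConfig: synthetic-data generating scenario
#'
#' Defines the stochastic structure of a synthetic study: a two-component
#' masting mixture (rare heavy mast years over a mostly-low baseline), an
#' early-fall fraction linking September--December to September--March
#' fruit-fall, a clipped-Normal winter temperature distribution, the true
#' process parameters, capture probabilities and centering constants, and
#' the initial December abundance.
#'
#' @slot nYears number of study years.
#' @slot mastProb probability a winter is a mast year.
#' @slot mastRange g/m2 range of mast-year September--March fruit-fall.
#' @slot baselineRange g/m2 range of ordinary-year fruit-fall.
#' @slot earlyFallRange range of the ash_dec / ash_mar fraction (< 1).
#' @slot tempMean,tempSd,tempRange winter temperature distribution (deg C),
#'   Normal clipped to tempRange.
#' @slot trueParams ProcessParams used to simulate.
#' @slot trueCaptureProbs CaptureProbs used to simulate.
#' @slot centering CenteringConstants used in the generating predictors.
#' @slot initAbundance December adult abundance of year 1.
#' @slot seed base RNG seed.
#' @export
setClass("ScenarioConfig",
  representation(nYears = "integer", mastProb = "numeric",
                 mastRange = "numeric", baselineRange = "numeric",
                 earlyFallRange = "numeric", tempMean = "numeric",
                 tempSd = "numeric", tempRange = "numeric",
                 trueParams = "ProcessParams",
                 trueCaptureProbs = "CaptureProbs",
                 centering = "CenteringConstants",
                 initAbundance = "integer", seed = "integer"))

setValidity("ScenarioConfig", function(object) {
  msg <- character()
  if (object@mastProb < 0 || object@mastProb > 1)
    msg <- c(msg, "mastProb must be in [0, 1]")
  for (s in c("mastRange", "baselineRange", "earlyFallRange", "tempRange")) {
    v <- slot(object, s)
    if (length(v) != 2L || v[1] > v[2])
      msg <- c(msg, sprintf("%s must be an ordered length-2 range", s))
  }
  if (any(object@mastRange < 0) || any(object@baselineRange < 0))
    msg <- c(msg, "fruit-fall magnitudes must be >= 0")
  if (any(object@earlyFallRange < 0) || any(object@earlyFallRange > 1))
    msg <- c(msg, "earlyFallRange must lie in [0, 1]")
  if (object@nYears < 3L) msg <- c(msg, "nYears must be >= 3")
  if (object@initAbundance < 0) msg <- c(msg, "initAbundance must be >= 0")
  if (length(msg)) msg else TRUE
})
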