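#' Default generating parameters for synthetic studies
#'
#' A parameter set producing the qualitative regime of the long-term study:
#' winter decline (negative winter-growth intercept), positive summer
#' growth (most recruitment enters the trappable population after June, so
#' December is the annual peak and June the trough), a strong positive
#' effect of September--March fruit-fall on winter growth, weaker positive
#' effects on reproduction, negative density dependence in all three
#' submodels, and moderate process noise. Interactions default to zero.
#' The intercepts satisfy (exp(alpha_wg) + exp(alpha_r)) * exp(alpha_sg)
#' = 1 at the centering point, so trajectories fluctuate around a
#' stationary level instead of drifting.
#'
#' @return a [ProcessParams-class].
#' @export
defaultProcessParams <- function() {
  a_wg <- -1.2
  a_r <- -0.9
  a_sg <- -log(exp(a_wg) + exp(a_r))
  ProcessParams(
    alpha = c(a_wg, a_r, a_sg),
    beta = rbind(wg = c(0.8, 0.3, -0.4, 0, 0),
                 r = c(0.5, 0.2, -0.2, 0, 0),
                 sg = c(0.3, -0.15, -0.4, 0, 0)),
    sigma = c(0.2, 0.25, 0.2))
}

#' Construct a synthetic-study scenario
#'
#' Defaults emulate the observed study conditions: 33 study years; rare
#' heavy mast winters (probability ~0.27, September--March fruit-fall
#' 8--23 g/m2) over a mostly-low baseline (0--3 g/m2); early
#' (September--December) fruit-fall a fraction 0.2--0.7 of the full-winter
#' fall; winter temperature Normal(mean 1 degC, sd 1.2) clipped to
#' [-2.1, 3.1]; capture probabilities high for adults (slightly higher in
#' June than December) and lower for juveniles, so that well over 70% of
#' adults present are caught over the two occasions; initial December
#' abundance 50. Centering constants default to the stationary log
#' abundances implied by [defaultProcessParams()].
#'
#' @param nYears number of study years.
#' @param mastProb probability a winter is a mast year.
#' @param mastRange,baselineRange g/m2 ranges (uniform within each).
#' @param earlyFallRange range of the ash_dec/ash_mar fraction.
#' @param tempMean,tempSd,tempRange temperature distribution, degrees C.
#' @param trueParams generating [ProcessParams-class].
#' @param trueCaptureProbs generating [CaptureProbs-class].
#' @param centering generating [CenteringConstants-class].
#' @param initAbundance December adult abundance in year 1.
#' @param seed base RNG seed.
#' @return a validated [ScenarioConfig-class].
#' @export
scenarioConfig <- function(nYears = 33, mastProb = 0.27,
                           mastRange = c(8, 23), baselineRange = c(0, 3),
                           earlyFallRange = c(0.2, 0.7),
                           tempMean = 1, tempSd = 1.2,
                           tempRange = c(-2.1, 3.1),
                           trueParams = defaultProcessParams(),
                           trueCaptureProbs = CaptureProbs(0.6, 0.4, 0.55),
                           centering = CenteringConstants(log(50),
                                                          log(0.71 * 50)),
                           initAbundance = 50, seed = 1) {
  new("ScenarioConfig", nYears = as.integer(nYears), mastProb = mastProb,
      mastRange = as.numeric(mastRange),
      baselineRange = as.numeric(baselineRange),
      earlyFallRange = as.numeric(earlyFallRange),
      tempMean = tempMean, tempSd = tempSd,
      tempRange = as.numeric(tempRange), trueParams = trueParams,
      trueCaptureProbs = trueCaptureProbs, centering = centering,
      initAbundance = as.integer(initAbundance), seed = as.integer(seed))
}

#' Generate a synthetic covariate series
#'
#' September--March fruit-fall is a two-component mixture: with probability
#' `mastProb` a mast year drawn uniformly from `mastRange`, otherwise a
#' baseline year from `baselineRange`. Early (September--December)
#' fruit-fall is the full-winter value times a uniform fraction from
#' `earlyFallRange`, so ash_dec <= ash_mar year-wise. Temperature is
#' Normal clipped to `tempRange`.
#'
#' @param config a [ScenarioConfig-class].
#' @param seed RNG seed (default: the scenario's).
#' @return a [CovariateSeries-class] over years 1..nYears.
#' @export
generateCovariates <- function(config, seed = config@seed) {
  set.seed(seed)
  T <- config@nYears
  isMast <- runif(T) < config@mastProb
  ashMar <- ifelse(isMast,
                   runif(T, config@mastRange[1], config@mastRange[2]),
                   runif(T, config@baselineRange[1], config@baselineRange[2]))
  ashDec <- ashMar * runif(T, config@earlyFallRange[1],
                           config@earlyFallRange[2])
  temp <- pmin(pmax(rnorm(T, config@tempMean, config@tempSd),
                    config@tempRange[1]), config@tempRange[2])
  CovariateSeries(seq_len(T), ashMar, ashDec, temp)
}

#' Generate a complete synthetic dataset with its generating truth
#'
#' Forward-simulates covariates, the latent three-season abundance chain
#' and two-occasion removal trap counts, and returns observations together
#' with the generating truth so that recovery tests are self-describing.
#' June observations of year 1 precede the first modelled December and are
#' set missing. By construction occasion-2 counts exclude occasion-1
#' captures and c1 + c2 never exceeds the latent abundance.
#'
#' @param config a [ScenarioConfig-class].
#' @param seed RNG seed (default: the scenario's).
#' @return list with `trap` ([TrapSeries-class]), `covariates`
#'   ([CovariateSeries-class]), `latents` (true [LatentStates-class]),
#'   `params` (true [ProcessParams-class]), `captureProbs`, `centering`.
#' @export
generateDataset <- function(config, seed = config@seed) {
  set.seed(seed)
  cov <- generateCovariates(config, seed = seed)
  lat <- simulateTrajectory(config@trueParams, cov, config@initAbundance,
                            config@centering)
  p <- config@trueCaptureProbs
  capt <- function(n, prob) {
    out <- matrix(NA_integer_, length(n), 2)
    ok <- !is.na(n)
    out[ok, ] <- sampleCaptures(n[ok], prob)
    out
  }
  aj <- capt(naJun(lat), p@pAdultJune)
  jj <- capt(nJuv(lat), p@pJuvenile)
  ad <- capt(naDec(lat), p@pAdultDecember)
  trap <- TrapSeries(studyYears(cov), aj, jj, ad)
  list(trap = trap, covariates = cov, latents = lat,
       params = config@trueParams, captureProbs = p,
       centering = config@centering)
}

#' Generate a matched control/experimental pair for the addition experiment
#'
#' Simulates two areas under the simplified experiment model: year-specific
#' rates drawn independently per area from Normal(alpha_s, sigma_s^2)
#' (no covariates, no density dependence), Poisson transitions, and removal
#' observations. In `additionYears` (indices of the winter preceding June
#' of that year), `deltaWinterGrowth` is added to the experimental area's
#' winter growth rate — zero for null-calibration runs.
#'
#' @param config a [ScenarioConfig-class] (its alphas, sigmas, capture
#'   probabilities and initial abundance are used).
#' @param deltaWinterGrowth log-scale shift applied to experimental winter
#'   growth in addition years.
#' @param additionYears integer indices t (2..nYears) of Junes following a
#'   fruit-addition winter.
#' @param seed RNG seed.
#' @return list with `control` and `experimental` (each a list with `trap`,
#'   `latents`, `rates`), plus `additionYears`.
#' @export
generateExperimentPair <- function(config, deltaWinterGrowth = 0,
                                   additionYears = integer(),
                                   seed = config@seed) {
  set.seed(seed)
  T <- config@nYears
  pars <- config@trueParams
  p <- config@trueCaptureProbs
  simArea <- function(deltaWg) {
    wg <- rnorm(T, pars@alpha["wg"], pars@sigma["wg"]) + deltaWg
    r <- rnorm(T, pars@alpha["r"], pars@sigma["r"])
    sg <- rnorm(T, pars@alpha["sg"], pars@sigma["sg"])
    naJun <- nj <- naDec <- rep(NA_real_, T)
    naDec[1] <- config@initAbundance
    for (t in 2:T) {
      naJun[t] <- stepAbundance(naDec[t - 1], wg[t])
      nj[t] <- stepAbundance(naDec[t - 1], r[t])
      naDec[t] <- stepAbundance(naJun[t] + nj[t], sg[t])
    }
    lat <- LatentStates(seq_len(T), naJun, nj, naDec)
    capt <- function(n, prob) {
      out <- matrix(NA_integer_, length(n), 2)
      ok <- !is.na(n)
      out[ok, ] <- sampleCaptures(n[ok], prob)
      out
    }
    trap <- TrapSeries(seq_len(T), capt(naJun, p@pAdultJune),
                       capt(nj, p@pJuvenile), capt(naDec, p@pAdultDecember))
    list(trap = trap, latents = lat,
         rates = data.frame(year = seq_len(T), wgrowth = wg, reprod = r,
                            sgrowth = sg))
  }
  deltaVec <- rep(0, T)
  deltaVec[additionYears] <- deltaWinterGrowth
  ctrl <- simArea(rep(0, T))
  expt <- simArea(deltaVec)
  list(control = ctrl, experimental = expt, additionYears = additionYears)
}
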