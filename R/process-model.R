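#' Construct ProcessParams
#'
#' @param alpha length-3 numeric of log-scale intercepts, order wg
#'   (winter growth), r (reproduction), sg (summer growth); names optional.
#' @param beta 3x5 numeric matrix of coefficients (rows wg, r, sg), or a
#'   list of three length-5 vectors.
#' @param sigma length-3 numeric of process SDs (> 0).
#' @return a validated [ProcessParams-class].
#' @export
ProcessParams <- function(alpha, beta, sigma) {
  if (is.list(beta)) beta <- do.call(rbind, beta)
  beta <- as.matrix(beta)
  alpha <- setNames(as.numeric(alpha), SUBMODELS)
  sigma <- setNames(as.numeric(sigma), SUBMODELS)
  dimnames(beta) <- list(SUBMODELS, paste0("beta", 1:5))
  new("ProcessParams", alpha = alpha, beta = beta, sigma = sigma)
}

#' Construct CaptureProbs
#' @param pAdultJune,pJuvenile,pAdultDecember capture probabilities in
#'   [0, 1] for the three demographic classes.
#' @return a validated [CaptureProbs-class].
#' @export
CaptureProbs <- function(pAdultJune, pJuvenile, pAdultDecember) {
  new("CaptureProbs", pAdultJune = pAdultJune, pJuvenile = pJuvenile,
      pAdultDecember = pAdultDecember)
}

#' Construct CenteringConstants
#' @param meanLogNaDec,meanLogNJunTotal centering constants for the latent
#'   log-abundance terms (finite reals).
#' @return a validated [CenteringConstants-class].
#' @export
CenteringConstants <- function(meanLogNaDec, meanLogNJunTotal) {
  new("CenteringConstants", meanLogNaDec = meanLogNaDec,
      meanLogNJunTotal = meanLogNJunTotal)
}

.linearRate <- function(alpha, beta, x1, x2, logNc, eps) {
  unname(alpha + beta[1] * x1 + beta[2] * x2 + beta[3] * logNc +
           beta[4] * x1 * logNc + beta[5] * x2 * logNc + eps)
}

#' Seasonal log-scale demographic rates
#'
#' Linear predictors of the three seasonal submodels. `winterGrowthRate`
#' gives the December -> June log growth rate (usually negative, reflecting
#' winter mortality, but not restricted to be: immigration can make it
#' positive); `reproductionRate` the log ratio of June juveniles to the
#' previous December's adults; `summerGrowthRate` the June -> December log
#' growth rate (usually positive, as most reproduction recruits after
#' June). Winter growth and reproduction share the covariate set
#' (standardized September--March ash fruit-fall, standardized winter
#' temperature, centered log December adult abundance, and the two
#' interactions); summer growth replaces temperature with current
#' September--December ash fruit-fall and uses the centered log June total
#' abundance.
#'
#' All are pure functions: covariates must already be standardized and the
#' log-abundance term already centered (see
#' [CenteringConstants-class]); `eps` is the Normal(0, sigma^2) process
#' noise, 0 for the deterministic mean rate.
#'
#' @param params a [ProcessParams-class].
#' @param ashMarZ standardized September--March ash fruit-fall.
#' @param tempZ standardized winter temperature.
#' @param ashDecZ standardized September--December ash fruit-fall.
#' @param logNaDecC centered log December adult abundance.
#' @param logNJunTotalC centered log June total (adults + juveniles).
#' @param eps process noise (default 0).
#' @return log-scale rate (vectorized over the inputs).
#' @export
winterGrowthRate <- function(params, ashMarZ, tempZ, logNaDecC, eps = 0) {
  .linearRate(params@alpha["wg"], params@beta["wg", ], ashMarZ, tempZ,
              logNaDecC, eps)
}

#' @rdname winterGrowthRate
#' @export
reproductionRate <- function(params, ashMarZ, tempZ, logNaDecC, eps = 0) {
  .linearRate(params@alpha["r"], params@beta["r", ], ashMarZ, tempZ,
              logNaDecC, eps)
}

#' @rdname winterGrowthRate
#' @export
summerGrowthRate <- function(params, ashMarZ, ashDecZ, logNJunTotalC,
                             eps = 0) {
  .linearRate(params@alpha["sg"], params@beta["sg", ], ashMarZ, ashDecZ,
              logNJunTotalC, eps)
}

#' Poisson state transition
#'
#' Draws the next abundance from Poisson(nPrev * exp(rate)); the
#' deterministic variant returns the mean itself (used to build analytic
#' oracles). Extinction is absorbing: nPrev = 0 gives 0 with probability 1.
#'
#' @param nPrev current integer abundance (>= 0).
#' @param rate finite log-scale rate.
#' @param deterministic if TRUE return the Poisson mean instead of a draw.
#' @param cap guard: error if the Poisson mean exceeds this (overflow /
#'   runaway trajectory), default 1e9.
#' @return integer draw (or numeric mean in deterministic mode).
#' @export
stepAbundance <- function(nPrev, rate, deterministic = FALSE, cap = 1e9) {
  stopifnot(all(nPrev >= 0), all(is.finite(rate) | nPrev == 0))
  mu <- nPrev * exp(rate)
  mu[nPrev == 0] <- 0
  if (any(mu > cap))
    stop(sprintf("stepAbundance: Poisson mean %.3g exceeds cap %.3g",
                 max(mu), cap))
  if (deterministic) mu else rpois(length(mu), mu)
}

# centered log abundance with the log(0) guard: log(max(N, 1)) keeps the
# predictor defined for extinct states, which stay absorbing through the
# Poisson mean of 0.
.centeredLogN <- function(n, centerConst) log(pmax(n, 1)) - centerConst

#' Simulate a latent abundance trajectory
#'
#' Forward-simulates the three-season process chain: from December adults of
#' year t-1, winter growth produces June adults of year t and reproduction
#' produces June juveniles of year t; summer growth takes the June total to
#' December adults of year t. Process noise is drawn fresh per year per
#' submodel, independent across submodels. December of year 1 is the
#' initial state; June states of year 1 are undefined (`NA`).
#'
#' @param params a [ProcessParams-class].
#' @param covariates a [CovariateSeries-class] covering the simulated years
#'   (z-scores are used).
#' @param n0 initial December adult abundance (year 1).
#' @param centering a [CenteringConstants-class] used in the predictors.
#' @param deterministic if TRUE, zero process noise and mean transitions
#'   (oracle mode).
#' @param cap passed to [stepAbundance()].
#' @return a [LatentStates-class] over the covariate years.
#' @export
simulateTrajectory <- function(params, covariates, n0, centering,
                               deterministic = FALSE, cap = 1e9) {
  z <- zCovariates(covariates)
  yrs <- studyYears(covariates)
  T <- length(yrs)
  naJun <- nj <- naDec <- rep(NA_real_, T)
  naDec[1] <- n0
  draw <- function(n, rate) {
    as.numeric(stepAbundance(n, rate, deterministic = deterministic,
                             cap = cap))
  }
  for (t in 2:T) {
    sig <- if (deterministic) setNames(c(0, 0, 0), SUBMODELS) else params@sigma
    logNdC <- .centeredLogN(naDec[t - 1], centering@meanLogNaDec)
    wg <- winterGrowthRate(params, z[t - 1, "ash_mar"], z[t - 1, "temp"],
                           logNdC, eps = rnorm(1, 0, sig["wg"]))
    naJun[t] <- draw(naDec[t - 1], wg)
    re <- reproductionRate(params, z[t - 1, "ash_mar"], z[t - 1, "temp"],
                           logNdC, eps = rnorm(1, 0, sig["r"]))
    nj[t] <- draw(naDec[t - 1], re)
    logNjC <- .centeredLogN(naJun[t] + nj[t], centering@meanLogNJunTotal)
    sg <- summerGrowthRate(params, z[t - 1, "ash_mar"], z[t, "ash_dec"],
                           logNjC, eps = rnorm(1, 0, sig["sg"]))
    naDec[t] <- draw(naJun[t] + nj[t], sg)
  }
  LatentStates(yrs, naJun, nj, naDec)
}
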