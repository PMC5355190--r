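#' Prior specification with the study defaults
#'
#' Gamma(shape = 0.001, rate = 0.001) on each process precision 1/sigma^2 —
#' the unique shape/rate pair with mean shape/rate = 1 and variance
#' shape/rate^2 = 1000; Normal(0, variance 1000) on intercepts and
#' coefficients; Uniform(0, 1) on capture probabilities; Uniform(0, 1000)
#' on the first-year December adult abundance.
#'
#' @param precisionShape,precisionRate Gamma hyperparameters.
#' @param coefMean,coefSd Normal hyperparameters (sd = sqrt(1000) by
#'   default).
#' @param initAbundanceMax upper bound for the initial-abundance prior.
#' @return a validated [PriorSpec-class].
#' @export
priorSpec <- function(precisionShape = 0.001, precisionRate = 0.001,
                      coefMean = 0, coefSd = sqrt(1000),
                      initAbundanceMax = 1000) {
  new("PriorSpec", precisionShape = precisionShape,
      precisionRate = precisionRate, coefMean = coefMean, coefSd = coefSd,
      initAbundanceMax = initAbundanceMax)
}

#' MCMC protocol configuration
#'
#' Defaults follow the observational-data protocol: three chains with
#' different initial values, 10,000 iterations each with the first 5,000
#' discarded as burn-in, no thinning. The experiment model conventionally
#' uses the longer 100,000 / 50,000 / thin-10 protocol
#' (`experimentMcmcConfig()`). Reduced protocols (fewer iterations) are
#' appropriate for simulation studies and agree with the full protocol
#' within Monte-Carlo error.
#'
#' @param nChains,nAdapt,nIter,nBurnin,thin,seed see [McmcConfig-class].
#' @return a validated [McmcConfig-class].
#' @export
mcmcConfig <- function(nChains = 3, nAdapt = 1000, nIter = 10000,
                       nBurnin = 5000, thin = 1, seed = 1) {
  new("McmcConfig", nChains = as.integer(nChains),
      nAdapt = as.integer(nAdapt), nIter = as.integer(nIter),
      nBurnin = as.integer(nBurnin), thin = as.integer(thin),
      seed = as.integer(seed))
}

#' @rdname mcmcConfig
#' @export
experimentMcmcConfig <- function(nChains = 3, nAdapt = 1000,
                                 nIter = 100000, nBurnin = 50000,
                                 thin = 10, seed = 1) {
  mcmcConfig(nChains, nAdapt, nIter, nBurnin, thin, seed)
}

#' Gelman--Rubin potential scale reduction factor
#'
#' Classic between/within-chain R-hat: with m chains of n draws,
#' W = mean within-chain variance, B/n = variance of chain means, and
#' R-hat = sqrt(((n-1)/n * W + B/n) / W). Values near 1 indicate the
#' chains have mixed; the package flags parameters above the threshold
#' (default 1.1).
#'
#' @param chains an n x m matrix (iterations x chains) for one parameter,
#'   or a `coda::mcmc.list`, in which case a named vector with one R-hat
#'   per monitored parameter is returned.
#' @return scalar (matrix input) or named numeric vector (mcmc.list).
#' @export
rhat <- function(chains) {
  if (inherits(chains, "mcmc.list")) {
    vars <- colnames(chains[[1]])
    return(vapply(vars, function(v) {
      rhat(sapply(chains, function(ch) as.numeric(ch[, v])))
    }, 0))
  }
  chains <- as.matrix(chains)
  m <- ncol(chains)
  n <- nrow(chains)
  if (m < 2L) stop("rhat: need at least 2 chains")
  W <- mean(apply(chains, 2, var))
  B_over_n <- var(colMeans(chains))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

# -- JAGS model code ---------------------------------------------------------

# Full seasonal state-space model. Interactions (beta 4, 5) are included
# only in stage 2; stage 1 fixes them at zero and runs with zero centering,
# exactly the two-stage procedure. The first December abundance carries the
# Uniform(0, initMax) prior via a Poisson-mixed uniform rate (dbin needs a
# discrete parent). A 1e-10 floor keeps Poisson means positive when a
# latent state hits zero; log(max(N, 1)) keeps the density-dependence
# predictor defined there.
.ssmModelString <- function(interactions) {
  inter_wg <- if (interactions)
    "+ beta[1,4]*ashmar[t-1]*logNd[t] + beta[1,5]*temp[t-1]*logNd[t]" else ""
  inter_r <- if (interactions)
    "+ beta[2,4]*ashmar[t-1]*logNd[t] + beta[2,5]*temp[t-1]*logNd[t]" else ""
  inter_sg <- if (interactions)
    "+ beta[3,4]*ashmar[t-1]*logNj[t] + beta[3,5]*ashdec[t]*logNj[t]" else ""
  nbeta <- if (interactions) 5 else 3
  sprintf('
model {
  for (s in 1:3) {
    tau[s] ~ dgamma(prShape, prRate)
    sigma[s] <- 1 / sqrt(tau[s])
    alpha[s] ~ dnorm(coefMean, coefPrec)
    for (k in 1:%d) {
      beta[s,k] ~ dnorm(coefMean, coefPrec)
    }
  }
  pAJun ~ dunif(0, 1)
  pJ ~ dunif(0, 1)
  pADec ~ dunif(0, 1)

  lambda1 ~ dunif(0, initMax)
  Nadec[1] ~ dpois(lambda1)

  for (t in 2:T) {
    logNd[t] <- log(max(Nadec[t-1], 1)) - cDec
    muwg[t] <- alpha[1] + beta[1,1]*ashmar[t-1] + beta[1,2]*temp[t-1]
               + beta[1,3]*logNd[t] %s
    wg[t] ~ dnorm(muwg[t], tau[1])
    Najun[t] ~ dpois(Nadec[t-1] * exp(wg[t]) + 1.0E-10)

    mur[t] <- alpha[2] + beta[2,1]*ashmar[t-1] + beta[2,2]*temp[t-1]
              + beta[2,3]*logNd[t] %s
    r[t] ~ dnorm(mur[t], tau[2])
    Nj[t] ~ dpois(Nadec[t-1] * exp(r[t]) + 1.0E-10)

    Ntot[t] <- Najun[t] + Nj[t]
    logNj[t] <- log(max(Ntot[t], 1)) - cJun
    musg[t] <- alpha[3] + beta[3,1]*ashmar[t-1] + beta[3,2]*ashdec[t]
               + beta[3,3]*logNj[t] %s
    sg[t] ~ dnorm(musg[t], tau[3])
    Nadec[t] ~ dpois(Ntot[t] * exp(sg[t]) + 1.0E-10)

    cAJ1[t] ~ dbin(pAJun, Najun[t])
    cAJ2[t] ~ dbin(pAJun, Najun[t] - cAJ1[t])
    cJ1[t] ~ dbin(pJ, Nj[t])
    cJ2[t] ~ dbin(pJ, Nj[t] - cJ1[t])
  }
  for (t in 1:T) {
    cAD1[t] ~ dbin(pADec, Nadec[t])
    cAD2[t] ~ dbin(pADec, Nadec[t] - cAD1[t])
  }
}', nbeta, inter_wg, inter_r, inter_sg)
}

# Simplified experiment model: year-specific free demographic rates, no
# covariates or density dependence.
.experimentModelString <- '
model {
  pAJun ~ dunif(0, 1)
  pJ ~ dunif(0, 1)
  pADec ~ dunif(0, 1)

  lambda1 ~ dunif(0, initMax)
  Nadec[1] ~ dpois(lambda1)

  for (t in 2:T) {
    wg[t] ~ dnorm(0, ratePrec)
    r[t] ~ dnorm(0, ratePrec)
    sg[t] ~ dnorm(0, ratePrec)
    Najun[t] ~ dpois(Nadec[t-1] * exp(wg[t]) + 1.0E-10)
    Nj[t] ~ dpois(Nadec[t-1] * exp(r[t]) + 1.0E-10)
    Ntot[t] <- Najun[t] + Nj[t]
    Nadec[t] ~ dpois(Ntot[t] * exp(sg[t]) + 1.0E-10)

    cAJ1[t] ~ dbin(pAJun, Najun[t])
    cAJ2[t] ~ dbin(pAJun, Najun[t] - cAJ1[t])
    cJ1[t] ~ dbin(pJ, Nj[t])
    cJ2[t] ~ dbin(pJ, Nj[t] - cJ1[t])
  }
  for (t in 1:T) {
    cAD1[t] ~ dbin(pADec, Nadec[t])
    cAD2[t] ~ dbin(pADec, Nadec[t] - cAD1[t])
  }
}'

# -- shared fitting machinery ------------------------------------------------

.trapData <- function(trap) {
  cnt <- trapCounts(trap)
  list(cAJ1 = cnt[, "adults_june_1"], cAJ2 = cnt[, "adults_june_2"],
       cJ1 = cnt[, "juveniles_june_1"], cJ2 = cnt[, "juveniles_june_2"],
       cAD1 = cnt[, "adults_december_1"], cAD2 = cnt[, "adults_december_2"])
}

# latent initial values safely above the observed removal totals; June
# nodes of year 1 are undefined in the model and must be NA in the inits
.latentInits <- function(trap) {
  tot <- trapTotals(trap)
  fill <- function(v) {
    v[is.na(v)] <- if (all(is.na(v))) 5L else as.integer(round(mean(v, na.rm = TRUE)))
    v
  }
  firstNA <- function(v) { v[1] <- NA_integer_; v }
  list(Najun = firstNA(fill(tot[, "adults_june"]) * 2L + 5L),
       Nj = firstNA(fill(tot[, "juveniles_june"]) * 2L + 5L),
       Nadec = fill(tot[, "adults_december"]) * 2L + 5L)
}

.runJagsFit <- function(modelString, data, initsFun, monitors, mcmc) {
  inits <- lapply(seq_len(mcmc@nChains), function(ch) {
    c(initsFun(ch),
      list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = mcmc@seed + ch))
  })
  jm <- rjags::jags.model(textConnection(modelString), data = data,
                          inits = inits, n.chains = mcmc@nChains,
                          n.adapt = mcmc@nAdapt, quiet = TRUE)
  update(jm, mcmc@nBurnin, progress.bar = "none")
  rjags::coda.samples(jm, monitors, n.iter = mcmc@nIter - mcmc@nBurnin,
                      thin = mcmc@thin, progress.bar = "none")
}

.crSummary <- function(draws) {
  med <- median(draws)
  qs <- quantile(draws, c(0.025, 0.975), names = FALSE, type = 7)
  c(median = med, lower = qs[1], upper = qs[2])
}

#' Summarize posterior draws
#'
#' Medians, central 95% credible intervals (type-7 quantiles), the
#' excludes-zero significance flag and per-parameter R-hat for every
#' monitored scalar in an `mcmc.list`.
#'
#' @param draws a `coda::mcmc.list`.
#' @param rhatThreshold convergence cutoff; any parameter above it marks
#'   the summary as not converged (with a warning).
#' @param latentPattern regular expression matching monitor names to report
#'   in the latent-state table instead of the parameter table (default:
#'   the abundance monitors `Najun`, `Nj`, `Nadec`).
#' @return a [PosteriorSummary-class].
#' @export
summarizePosterior <- function(draws, rhatThreshold = 1.1,
                               latentPattern = "^(Najun|Nj|Nadec)\\[") {
  vars <- colnames(draws[[1]])
  pooled <- do.call(rbind, lapply(draws, as.matrix))
  isLatent <- grepl(latentPattern, vars)
  rh <- if (length(draws) >= 2L) rhat(draws) else setNames(rep(NA_real_, length(vars)), vars)

  pv <- vars[!isLatent]
  ptab <- data.frame(parameter = pv, t(vapply(pv, function(v)
    .crSummary(pooled[, v]), c(median = 0, lower = 0, upper = 0))),
    row.names = NULL)
  ptab$excludesZero <- ptab$lower > 0 | ptab$upper < 0
  ptab$rhat <- unname(rh[pv])

  lv <- vars[isLatent]
  ltab <- if (length(lv)) {
    stateYear <- regmatches(lv, regexec("^([A-Za-z]+)\\[(\\d+)\\]$", lv))
    data.frame(state = vapply(stateYear, `[`, "", 2),
               index = as.integer(vapply(stateYear, `[`, "", 3)),
               t(vapply(lv, function(v) .crSummary(pooled[, v]),
                        c(median = 0, lower = 0, upper = 0))),
               row.names = NULL)
  } else {
    data.frame(state = character(), index = integer(), median = numeric(),
               lower = numeric(), upper = numeric())
  }

  conv <- all(is.na(ptab$rhat)) || max(ptab$rhat, na.rm = TRUE) <= rhatThreshold
  if (!conv)
    warning(sprintf("possible non-convergence: max R-hat %.3f > %.2f",
                    max(ptab$rhat, na.rm = TRUE), rhatThreshold))
  new("PosteriorSummary", parameters = ptab, latents = ltab, draws = draws,
      centering = NULL, converged = conv, rhatThreshold = rhatThreshold)
}

.renameSsmParams <- function(summary, interactions) {
  map <- c(
    "alpha[1]" = "alpha_wg", "alpha[2]" = "alpha_r", "alpha[3]" = "alpha_sg",
    "sigma[1]" = "sigma_wg", "sigma[2]" = "sigma_r", "sigma[3]" = "sigma_sg",
    pAJun = "p_adult_june", pJ = "p_juvenile", pADec = "p_adult_december")
  sub <- c("wg", "r", "sg")
  for (s in 1:3) for (k in 1:5)
    map[sprintf("beta[%d,%d]", s, k)] <- sprintf("beta_%s_%d", sub[s], k)
  p <- summary@parameters
  hit <- p$parameter %in% names(map)
  p$parameter[hit] <- unname(map[p$parameter[hit]])
  summary@parameters <- p
  summary
}

.checkFitInputs <- function(trap, cov) {
  if (!identical(studyYears(trap), studyYears(cov)))
    stop("trap and covariate series must cover the same years")
  z <- zCovariates(cov)
  T <- nYears(cov)
  need <- c(z[seq_len(T - 1), "ash_mar"], z[seq_len(T - 1), "temp"],
            z[2:T, "ash_dec"])
  if (all(is.na(z)))
    stop("covariates are all missing")
  if (anyNA(need))
    stop("missing covariate values in years required by the process model")
  invisible(TRUE)
}

.ssmJagsData <- function(trap, cov, priors, cDec, cJun) {
  z <- zCovariates(cov)
  c(list(T = nYears(trap),
         ashmar = z[, "ash_mar"], temp = z[, "temp"], ashdec = z[, "ash_dec"],
         cDec = cDec, cJun = cJun,
         prShape = priors@precisionShape, prRate = priors@precisionRate,
         coefMean = priors@coefMean, coefPrec = 1 / priors@coefSd^2,
         initMax = priors@initAbundanceMax),
    .trapData(trap))
}

.ssmInitsFun <- function(trap, priors, mcmc, nbeta) {
  lat <- .latentInits(trap)
  T <- length(lat$Nadec)
  function(ch) {
    set.seed(mcmc@seed * 1000L + ch)
    c(lat,
      list(alpha = rnorm(3, 0, 0.5),
           beta = matrix(rnorm(3 * nbeta, 0, 0.3), 3, nbeta),
           tau = runif(3, 0.5, 4),
           pAJun = runif(1, 0.3, 0.9), pJ = runif(1, 0.3, 0.9),
           pADec = runif(1, 0.3, 0.9),
           lambda1 = min(lat$Nadec[1] + 1, priors@initAbundanceMax * 0.9),
           wg = c(NA, rep(0, T - 1)), r = c(NA, rep(0, T - 1)),
           sg = c(NA, rep(0, T - 1))))
  }
}

# the June observations of year 1 precede the first modelled December and
# have no parent state; they are excluded from the likelihood.
.dropFirstJune <- function(data) {
  for (v in c("cAJ1", "cAJ2", "cJ1", "cJ2")) data[[v]][1] <- NA
  data
}

#' Stage 1: no-interaction fit and centering constants
#'
#' Fits the seasonal state-space model with the interaction coefficients
#' fixed at zero (and zero centering), then returns the posterior together
#' with the centering constants for the final interaction model: the
#' posterior means of log(Na_dec) and log(Na_jun + Nj) per year
#' (log(max(N, 1))), averaged over years.
#'
#' @param trap a [TrapSeries-class].
#' @param cov a [CovariateSeries-class] on the same years.
#' @param priors a [PriorSpec-class].
#' @param mcmc a [McmcConfig-class].
#' @return list with elements `posterior` (a
#'   [PosteriorSummary-class]) and `centering`
#'   (a [CenteringConstants-class]).
#' @export
fitStage1 <- function(trap, cov, priors = priorSpec(), mcmc = mcmcConfig()) {
  .checkFitInputs(trap, cov)
  data <- .dropFirstJune(.ssmJagsData(trap, cov, priors, cDec = 0, cJun = 0))
  draws <- .runJagsFit(.ssmModelString(interactions = FALSE), data,
                       .ssmInitsFun(trap, priors, mcmc, nbeta = 3),
                       monitors = c("alpha", "beta", "sigma",
                                    "pAJun", "pJ", "pADec",
                                    "Najun", "Nj", "Nadec"),
                       mcmc)
  post <- .renameSsmParams(summarizePosterior(draws), interactions = FALSE)
  post@centering <- NULL

  pooled <- do.call(rbind, lapply(draws, as.matrix))
  T <- nYears(trap)
  logMeanOver <- function(prefix, idx) {
    cols <- sprintf("%s[%d]", prefix, idx)
    mean(colMeans(log(pmax(pooled[, cols, drop = FALSE], 1))))
  }
  cDec <- logMeanOver("Nadec", seq_len(T))
  junTot <- pooled[, sprintf("Najun[%d]", 2:T), drop = FALSE] +
    pooled[, sprintf("Nj[%d]", 2:T), drop = FALSE]
  cJun <- mean(colMeans(log(pmax(junTot, 1))))
  list(posterior = post,
       centering = CenteringConstants(meanLogNaDec = cDec,
                                      meanLogNJunTotal = cJun))
}

#' Stage 2: full interaction model
#'
#' Fits the complete seasonal state-space model (all five coefficients per
#' submodel) with the latent log-abundance terms centered by the fixed
#' constants estimated in stage 1.
#'
#' @inheritParams fitStage1
#' @param centering a [CenteringConstants-class] from [fitStage1()].
#' @param rhatThreshold convergence cutoff for the R-hat flag.
#' @return a [PosteriorSummary-class]; its `centering` slot records the
#'   constants used.
#' @export
fitFull <- function(trap, cov, priors = priorSpec(), mcmc = mcmcConfig(),
                    centering, rhatThreshold = 1.1) {
  stopifnot(is(centering, "CenteringConstants"))
  .checkFitInputs(trap, cov)
  data <- .dropFirstJune(.ssmJagsData(trap, cov, priors,
                                      cDec = centering@meanLogNaDec,
                                      cJun = centering@meanLogNJunTotal))
  draws <- .runJagsFit(.ssmModelString(interactions = TRUE), data,
                       .ssmInitsFun(trap, priors, mcmc, nbeta = 5),
                       monitors = c("alpha", "beta", "sigma",
                                    "pAJun", "pJ", "pADec",
                                    "Najun", "Nj", "Nadec"),
                       mcmc)
  post <- .renameSsmParams(summarizePosterior(draws, rhatThreshold),
                           interactions = TRUE)
  post@centering <- centering
  post
}

#' Two-stage fit convenience wrapper
#'
#' Runs [fitStage1()] then [fitFull()] with the estimated centering
#' constants, the complete two-stage procedure.
#'
#' @inheritParams fitStage1
#' @param rhatThreshold convergence cutoff.
#' @return list with `stage1`, `centering` and `posterior` (the final
#'   [PosteriorSummary-class]).
#' @export
fitStateSpace <- function(trap, cov, priors = priorSpec(),
                          mcmc = mcmcConfig(), rhatThreshold = 1.1) {
  s1 <- fitStage1(trap, cov, priors, mcmc)
  full <- fitFull(trap, cov, priors, mcmc, s1$centering, rhatThreshold)
  list(stage1 = s1$posterior, centering = s1$centering, posterior = full)
}
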