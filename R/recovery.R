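.trueParamVector <- function(params, captureProbs) {
  out <- c(alpha_wg = unname(params@alpha["wg"]),
           alpha_r = unname(params@alpha["r"]),
           alpha_sg = unname(params@alpha["sg"]),
           sigma_wg = unname(params@sigma["wg"]),
           sigma_r = unname(params@sigma["r"]),
           sigma_sg = unname(params@sigma["sg"]),
           p_adult_june = captureProbs@pAdultJune,
           p_juvenile = captureProbs@pJuvenile,
           p_adult_december = captureProbs@pAdultDecember)
  for (s in c("wg", "r", "sg")) for (k in 1:5)
    out[sprintf("beta_%s_%d", s, k)] <- params@beta[s, k]
  out
}

#' Parameter-recovery simulation study
#'
#' Generates `nReplicates` synthetic datasets from a scenario, fits each
#' with the two-stage procedure, and records for every generating
#' parameter whether it falls inside its marginal 95% credible interval,
#' together with the excludes-zero flag. With a correctly implemented
#' model the pooled coverage is close to the nominal 95%; the study also
#' quantifies the power to detect the scenario's mast effect (the fraction
#' of replicates whose interval for the September--March ash coefficient
#' on winter growth excludes zero).
#'
#' @param nReplicates number of replicate datasets/fits.
#' @param config generating [ScenarioConfig-class]; defaults are the
#'   standard study conditions (33 years, mast effect 0.8, sd 0.2).
#' @param mcmc a [McmcConfig-class] applied to each fit (its seed is
#'   re-derived per replicate).
#' @param baseSeed integer controlling data generation and fit seeds.
#' @return data.frame with one row per replicate x parameter: `replicate`,
#'   `parameter`, `truth`, `lower`, `upper`, `covered`, `excludesZero`.
#' @export
coverageStudy <- function(nReplicates = 20, config = scenarioConfig(),
                          mcmc = mcmcConfig(nChains = 2, nAdapt = 400,
                                            nIter = 2000, nBurnin = 800),
                          baseSeed = 1) {
  truth <- .trueParamVector(config@trueParams, config@trueCaptureProbs)
  rows <- vector("list", nReplicates)
  for (i in seq_len(nReplicates)) {
    ds <- generateDataset(config, seed = as.integer(baseSeed * 101L + i))
    m <- mcmc
    m@seed <- as.integer(baseSeed * 211L + i)
    fit <- suppressWarnings(
      fitStateSpace(ds$trap, ds$covariates, mcmc = m))
    p <- parameterTable(fit$posterior)
    p <- p[p$parameter %in% names(truth), ]
    rows[[i]] <- data.frame(
      replicate = i, parameter = p$parameter,
      truth = unname(truth[p$parameter]),
      lower = p$lower, upper = p$upper,
      covered = truth[p$parameter] >= p$lower & truth[p$parameter] <= p$upper,
      excludesZero = p$excludesZero, row.names = NULL)
  }
  do.call(rbind, rows)
}

#' Null calibration of the experiment-area comparison
#'
#' Simulates `nReplicates` control/experimental pairs with no rate
#' difference (the null), fits the simplified experiment model to each
#' area and classifies the per-year credible-interval overlaps. Reports
#' the rate of false "non-overlapping" calls, which should stay below the
#' nominal error of the comparison rule.
#'
#' @param nReplicates number of replicate pairs.
#' @param config generating [ScenarioConfig-class] (small `nYears`
#'   recommended, matching the short experimental window).
#' @param mcmc a [McmcConfig-class] applied per area fit.
#' @param baseSeed integer seed control.
#' @param barelyFrac passed to [compareAreas()].
#' @return list with `falseNonOverlapRate` (pooled over replicates, years
#'   and rates) and `perReplicate` (data.frame of counts).
#' @export
experimentNullCalibration <- function(nReplicates = 50,
                                      config = scenarioConfig(nYears = 5),
                                      mcmc = mcmcConfig(nChains = 2,
                                                        nAdapt = 400,
                                                        nIter = 4000,
                                                        nBurnin = 1500),
                                      baseSeed = 1, barelyFrac = 0.1) {
  counts <- vector("list", nReplicates)
  for (i in seq_len(nReplicates)) {
    pair <- generateExperimentPair(config, deltaWinterGrowth = 0,
                                   seed = as.integer(baseSeed * 307L + i))
    m <- mcmc
    m@seed <- as.integer(baseSeed * 401L + i)
    fits <- suppressWarnings(
      fitExperiment(pair$control$trap, pair$experimental$trap, mcmc = m))
    comp <- compareAreas(fits$control, fits$experimental, barelyFrac)
    counts[[i]] <- data.frame(
      replicate = i, nCalls = nrow(comp),
      nNonOverlap = sum(comp$classification == "non-overlapping"))
  }
  perRep <- do.call(rbind, counts)
  list(falseNonOverlapRate = sum(perRep$nNonOverlap) / sum(perRep$nCalls),
       perReplicate = perRep)
}
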