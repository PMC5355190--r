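#' Write a run manifest
#'
#' Every pipeline output directory gets exactly one `manifest.json`
#' recording the package version, seeds, input-file digests, configuration
#' echo and per-stage timings, so a run can be reproduced and audited.
#'
#' @param outDir output directory.
#' @param seeds named list/vector of seeds used.
#' @param inputs character vector of input file paths (digested with
#'   `tools::md5sum`).
#' @param config list echoed into the manifest.
#' @param timings named numeric vector of elapsed seconds per stage.
#' @return the manifest path, invisibly.
#' @export
writeRunManifest <- function(outDir, seeds = list(), inputs = character(),
                             config = list(), timings = numeric()) {
  manifest <- list(
    package = "mastSSM",
    version = as.character(utils::packageVersion("mastSSM")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = seeds,
    inputs = if (length(inputs))
      as.list(tools::md5sum(inputs)) else list(),
    config = config,
    timings_sec = as.list(timings))
  path <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

.paramsToList <- function(p) {
  list(alpha = as.list(p@alpha),
       beta = apply(p@beta, 1, as.list),
       sigma = as.list(p@sigma))
}

#' Simulate a dataset to files
#'
#' Runs [generateDataset()] and writes the observation files
#' (`trap_counts.csv`, `covariates.csv`), the generating truth
#' (`truth_latents.csv`, `truth_params.json`), the scenario echo
#' (`scenario.json`) and a run manifest. Deterministic under a fixed seed.
#'
#' @param config a [ScenarioConfig-class].
#' @param outDir output directory (created if absent).
#' @param seed RNG seed (default: the scenario's).
#' @return list of written paths, invisibly; the generated dataset as the
#'   `dataset` attribute-free element `data`.
#' @export
runSimulation <- function(config, outDir, seed = config@seed) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  ds <- generateDataset(config, seed = seed)
  paths <- list(
    trap = writeTrapSeries(ds$trap, file.path(outDir, "trap_counts.csv")),
    covariates = writeCovariateSeries(ds$covariates,
                                      file.path(outDir, "covariates.csv")),
    truth_latents = writeLatentStates(ds$latents,
                                      file.path(outDir, "truth_latents.csv")))
  truth <- c(.paramsToList(ds$params),
             list(capture_probs = list(
                    p_adult_june = ds$captureProbs@pAdultJune,
                    p_juvenile = ds$captureProbs@pJuvenile,
                    p_adult_december = ds$captureProbs@pAdultDecember),
                  centering = list(
                    mean_log_na_dec = ds$centering@meanLogNaDec,
                    mean_log_njun_total = ds$centering@meanLogNJunTotal)))
  jsonlite::write_json(truth, file.path(outDir, "truth_params.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  scen <- list(nYears = config@nYears, mastProb = config@mastProb,
               mastRange = config@mastRange,
               baselineRange = config@baselineRange,
               earlyFallRange = config@earlyFallRange,
               tempMean = config@tempMean, tempSd = config@tempSd,
               tempRange = config@tempRange,
               initAbundance = config@initAbundance, seed = seed)
  jsonlite::write_json(scen, file.path(outDir, "scenario.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeRunManifest(outDir, seeds = list(seed = seed),
                   inputs = unlist(paths), config = scen,
                   timings = c(simulate = proc.time()[["elapsed"]] - t0))
  invisible(c(paths, list(data = ds)))
}

#' Fit the state-space model from files and write results
#'
#' Reads trap-count and covariate CSVs, runs the two-stage fit
#' ([fitStage1()] then [fitFull()]), and writes the posterior parameter
#' table, latent-state table, R-hat table, a coefficient forest plot and a
#' run manifest.
#'
#' @param trapPath,covPath input CSV paths (dialect of
#'   [readTrapSeries()] / [readCovariateSeries()]).
#' @param outDir output directory.
#' @param priors a [PriorSpec-class].
#' @param mcmc a [McmcConfig-class].
#' @return the final [PosteriorSummary-class], invisibly.
#' @export
runFit <- function(trapPath, covPath, outDir, priors = priorSpec(),
                   mcmc = mcmcConfig()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  trap <- readTrapSeries(trapPath)
  cov <- readCovariateSeries(covPath)
  t0 <- proc.time()[["elapsed"]]
  fit <- fitStateSpace(trap, cov, priors, mcmc)
  tFit <- proc.time()[["elapsed"]] - t0
  post <- fit$posterior
  ptab <- parameterTable(post)
  utils::write.csv(ptab, file.path(outDir, "posterior_parameters.csv"),
                   row.names = FALSE)
  utils::write.csv(latentTable(post),
                   file.path(outDir, "posterior_latents.csv"),
                   row.names = FALSE)
  utils::write.csv(ptab[, c("parameter", "rhat")],
                   file.path(outDir, "rhat.csv"), row.names = FALSE)
  gg <- plotCoefficients(post)
  ggplot2::ggsave(file.path(outDir, "coefficients.svg"), gg,
                  device = grDevices::svg, width = 7, height = 5)
  writeRunManifest(outDir, seeds = list(seed = mcmc@seed),
                   inputs = c(trapPath, covPath),
                   config = list(nChains = mcmc@nChains, nIter = mcmc@nIter,
                                 nBurnin = mcmc@nBurnin, thin = mcmc@thin,
                                 centering = list(
                                   mean_log_na_dec = fit$centering@meanLogNaDec,
                                   mean_log_njun_total = fit$centering@meanLogNJunTotal)),
                   timings = c(fit = tFit))
  invisible(post)
}

#' Fit and compare the food-addition experiment from files
#'
#' Reads control and experimental trap CSVs covering identical years, fits
#' the simplified experiment model per area, writes per-area posterior
#' tables, the per-year overlap classification and a rate comparison plot.
#'
#' @param controlPath,experimentalPath input CSV paths.
#' @param outDir output directory.
#' @param priors a [PriorSpec-class].
#' @param mcmc a [McmcConfig-class]; see [experimentMcmcConfig()] for the
#'   long protocol.
#' @param barelyFrac passed to [compareAreas()].
#' @return the comparison data.frame, invisibly.
#' @export
runExperiment <- function(controlPath, experimentalPath, outDir,
                          priors = priorSpec(), mcmc = mcmcConfig(),
                          barelyFrac = 0.1) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ctrl <- readTrapSeries(controlPath)
  expt <- readTrapSeries(experimentalPath)
  t0 <- proc.time()[["elapsed"]]
  fits <- fitExperiment(ctrl, expt, priors, mcmc)
  tFit <- proc.time()[["elapsed"]] - t0
  utils::write.csv(parameterTable(fits$control),
                   file.path(outDir, "posterior_control.csv"),
                   row.names = FALSE)
  utils::write.csv(parameterTable(fits$experimental),
                   file.path(outDir, "posterior_experimental.csv"),
                   row.names = FALSE)
  comp <- compareAreas(fits$control, fits$experimental, barelyFrac)
  utils::write.csv(comp, file.path(outDir, "area_comparison.csv"),
                   row.names = FALSE)
  gg <- plotExperimentComparison(comp)
  ggplot2::ggsave(file.path(outDir, "experiment_rates.svg"), gg,
                  device = grDevices::svg, width = 8, height = 6)
  writeRunManifest(outDir, seeds = list(seed = mcmc@seed),
                   inputs = c(controlPath, experimentalPath),
                   config = list(nChains = mcmc@nChains, nIter = mcmc@nIter,
                                 nBurnin = mcmc@nBurnin, thin = mcmc@thin,
                                 barelyFrac = barelyFrac),
                   timings = c(fit = tFit))
  invisible(comp)
}

#' Coefficient forest plot
#'
#' Median and 95% credible interval per process coefficient (intercepts,
#' covariate effects, density dependence, interactions), in the style used
#' to report these models: points at posterior medians, horizontal lines
#' spanning the 95% CrI, a dashed zero reference; intervals excluding zero
#' are emphasised.
#'
#' @param summary a [PosteriorSummary-class].
#' @param pattern regular expression selecting parameters to draw.
#' @return a ggplot object.
#' @export
plotCoefficients <- function(summary,
                             pattern = "^(alpha|beta)_") {
  p <- parameterTable(summary)
  p <- p[grepl(pattern, p$parameter), ]
  p$parameter <- factor(p$parameter, levels = rev(p$parameter))
  ggplot2::ggplot(p, ggplot2::aes(x = median, y = parameter)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = lower,
                                         xmax = upper,
                                         colour = excludesZero),
                            height = 0) +
    ggplot2::geom_point(ggplot2::aes(colour = excludesZero)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black",
                                            `FALSE` = "grey60"),
                                 guide = "none") +
    ggplot2::labs(x = "posterior median and 95% CrI", y = NULL) +
    ggplot2::theme_minimal()
}

#' Experiment rate comparison plot
#'
#' Per-year demographic rates (exponential scale) for control and
#' experimental areas with 95% credible intervals, one panel per rate.
#'
#' @param comparison output of [compareAreas()].
#' @return a ggplot object.
#' @export
plotExperimentComparison <- function(comparison) {
  long <- rbind(
    data.frame(area = "control", rate = comparison$rate,
               index = comparison$index,
               median = comparison$control_median,
               lower = comparison$control_lower,
               upper = comparison$control_upper),
    data.frame(area = "experimental", rate = comparison$rate,
               index = comparison$index,
               median = comparison$experimental_median,
               lower = comparison$experimental_lower,
               upper = comparison$experimental_upper))
  pd <- ggplot2::position_dodge(width = 0.4)
  ggplot2::ggplot(long, ggplot2::aes(x = index, y = median,
                                     colour = area)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = lower,
                                        ymax = upper),
                           width = 0.2, position = pd) +
    ggplot2::geom_point(position = pd) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~rate, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "year index", y = "rate (exp scale, log axis)") +
    ggplot2::theme_minimal()
}
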