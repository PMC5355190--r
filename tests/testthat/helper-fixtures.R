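# shared fixtures: small scenarios and reduced MCMC protocols used across
# the fitting tests. Protocol sizes are chosen so single fits take seconds
# and replicate suites minutes.

shortMcmc <- function(seed = 1, nChains = 3) {
  mcmcConfig(nChains = nChains, nAdapt = 500, nIter = 2500, nBurnin = 1000,
             seed = seed)
}

tinyMcmc <- function(seed = 1) {
  mcmcConfig(nChains = 2, nAdapt = 300, nIter = 1200, nBurnin = 500,
             seed = seed)
}

smallScenario <- function(nYears = 12, seed = 1) {
  scenarioConfig(nYears = nYears, seed = seed)
}

writeTempTrapCsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(c(paste0("year,", paste(c(
    "adults_june_1", "adults_june_2", "juveniles_june_1",
    "juveniles_june_2", "adults_december_1", "adults_december_2"),
    collapse = ",")), lines), path)
  path
}

# independent mean/sd for the standardization oracle: plain arithmetic,
# no calls into the package
oracleZScores <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  s <- sqrt(sum((x - m)^2) / (n - 1))
  (x - m) / s
}
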