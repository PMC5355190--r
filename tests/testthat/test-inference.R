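# Single fits here use the reduced protocols from helper-fixtures.R; the
# replicate-level recovery checks live in test-acceptance.R.

test_that("precision prior has the stated mean-1, variance-1000 parametrization", {
  pr <- priorSpec()
  expect_equal(pr@precisionShape / pr@precisionRate, 1)
  expect_equal(pr@precisionShape / pr@precisionRate^2, 1000)
  expect_equal(pr@coefSd^2, 1000)
})

test_that("rhat is ~1 for identical chains and large for disjoint ones", {
  set.seed(31)
  x <- rnorm(5000)
  expect_equal(rhat(cbind(x, x, x)), 1, tolerance = 1e-3)
  # well-mixed: three independent chains from the same Normal
  ch <- matrix(rnorm(3e4), ncol = 3)
  expect_lt(rhat(ch), 1.05)
  # disjoint means 0 vs 10, sd 1: between-chain variance dominates
  bad <- cbind(rnorm(2000, 0), rnorm(2000, 10))
  expect_gt(rhat(bad), 2)
  expect_error(rhat(matrix(1:10, ncol = 1)), "2 chains")
})

test_that("rhat agrees with the coda implementation on mcmc lists", {
  set.seed(32)
  mk <- function() coda::mcmc(cbind(a = rnorm(2000), b = rnorm(2000, 0, 3)))
  ml <- coda::mcmc.list(mk(), mk(), mk())
  mine <- rhat(ml)
  ref <- coda::gelman.diag(ml, autoburnin = FALSE,
                           multivariate = FALSE)$psrf[, 1]
  expect_equal(unname(mine), unname(ref), tolerance = 0.02)
})

test_that("posterior summaries use type-7 quantiles and flag zero exclusion", {
  draws <- coda::mcmc.list(coda::mcmc(cbind(a = 1:100, b = -50:49 + 0.5)))
  s <- summarizePosterior(draws, latentPattern = "^$")
  p <- parameterTable(s)
  expect_equal(p$median[p$parameter == "a"], 50.5)
  expect_equal(p$lower[p$parameter == "a"],
               unname(quantile(1:100, 0.025, type = 7)))
  expect_true(p$excludesZero[p$parameter == "a"])
  expect_false(p$excludesZero[p$parameter == "b"])
})

test_that("stage-1 centering constants recover the true mean log-abundances", {
  cfg <- scenarioConfig(seed = 51)
  ds <- generateDataset(cfg)
  s1 <- suppressWarnings(
    fitStage1(ds$trap, ds$covariates, mcmc = shortMcmc(seed = 52)))
  lat <- ds$latents
  trueCDec <- mean(log(pmax(naDec(lat), 1)))
  trueCJun <- mean(log(pmax(naJun(lat) + nJuv(lat), 1)), na.rm = TRUE)
  expect_lt(abs(s1$centering@meanLogNaDec - trueCDec), 0.2)
  expect_lt(abs(s1$centering@meanLogNJunTotal - trueCJun), 0.2)
})

test_that("fits are deterministic under a fixed seed and data", {
  cfg <- scenarioConfig(nYears = 10, seed = 53)
  ds <- generateDataset(cfg)
  a <- suppressWarnings(
    fitStage1(ds$trap, ds$covariates, mcmc = tinyMcmc(seed = 54)))
  b <- suppressWarnings(
    fitStage1(ds$trap, ds$covariates, mcmc = tinyMcmc(seed = 54)))
  expect_equal(a$centering@meanLogNaDec, b$centering@meanLogNaDec)
  expect_equal(parameterTable(a$posterior)$median,
               parameterTable(b$posterior)$median)
})

test_that("degenerate 3-year series runs and reports wide intervals", {
  cfg <- scenarioConfig(nYears = 3, seed = 55)
  ds <- generateDataset(cfg)
  fit <- suppressWarnings(
    fitStateSpace(ds$trap, ds$covariates, mcmc = tinyMcmc(seed = 56)))
  p <- parameterTable(fit$posterior)
  bwg1 <- p[p$parameter == "beta_wg_1", ]
  # almost no information: the interval should span much of the prior scale
  expect_gt(bwg1$upper - bwg1$lower, 5)
})

test_that("covariate problems are rejected before fitting", {
  cfg <- scenarioConfig(nYears = 8, seed = 57)
  ds <- generateDataset(cfg)
  raw <- rawCovariates(ds$covariates)
  holed <- ds$covariates
  holed@z[3, "ash_mar"] <- NA
  expect_error(fitStage1(ds$trap, holed, mcmc = tinyMcmc()), "missing covariate")
  short <- CovariateSeries(1:7, raw[-1, "ash_mar"], raw[-1, "ash_dec"],
                           raw[-1, "temp"])
  expect_error(fitStage1(ds$trap, short, mcmc = tinyMcmc()), "same years")
})

test_that("posterior latent abundances dominate the observed removal totals", {
  cfg <- scenarioConfig(nYears = 12, seed = 58)
  ds <- generateDataset(cfg)
  fit <- suppressWarnings(
    fitStateSpace(ds$trap, ds$covariates, mcmc = shortMcmc(seed = 59)))
  tot <- trapTotals(ds$trap)
  draws <- posteriorDraws(fit$posterior)
  pooled <- do.call(rbind, lapply(draws, as.matrix))
  T <- nYears(ds$trap)
  # support constraint: every retained draw of each latent abundance is at
  # least the corresponding two-day trap total
  for (t in seq_len(T)) {
    expect_true(all(pooled[, sprintf("Nadec[%d]", t)] >=
                    tot[t, "adults_december"]))
    if (t >= 2 && !is.na(tot[t, "adults_june"]))
      expect_true(all(pooled[, sprintf("Najun[%d]", t)] >=
                      tot[t, "adults_june"]))
  }
  # and the modeled (median) numbers sit at or slightly above the totals
  lt <- latentTable(fit$posterior)
  dec <- lt[lt$state == "Nadec", ]
  expect_true(all(dec$median >= tot[dec$index, "adults_december"]))
})

test_that("capture-probability intervals quantify the removal-design identifiability", {
  cfg <- scenarioConfig(nYears = 12, seed = 60)
  ds <- generateDataset(cfg)
  fit <- suppressWarnings(
    fitStateSpace(ds$trap, ds$covariates, mcmc = shortMcmc(seed = 61)))
  p <- parameterTable(fit$posterior)
  caps <- p[grepl("^p_", p$parameter), ]
  # two removal occasions with constant p identify p only weakly; CrIs are
  # reported, must be inside (0,1) and not degenerate
  expect_true(all(caps$lower > 0 & caps$upper < 1))
  expect_true(all(caps$upper - caps$lower > 0.01))
  expect_true(all(caps$upper - caps$lower < 0.8))
})
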