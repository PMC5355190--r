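test_that("mast probability 0 yields an all-baseline series", {
  cfg <- scenarioConfig(nYears = 50, mastProb = 0, seed = 2)
  cov <- generateCovariates(cfg)
  expect_true(all(rawCovariates(cov)[, "ash_mar"] <= cfg@baselineRange[2]))
})

test_that("empirical mast frequency matches the configured probability", {
  cfg <- scenarioConfig(nYears = 10000, mastProb = 0.27, seed = 3)
  cov <- generateCovariates(cfg)
  isMast <- rawCovariates(cov)[, "ash_mar"] >= cfg@mastRange[1]
  se <- sqrt(0.27 * 0.73 / 10000)
  expect_lt(abs(mean(isMast) - 0.27), 2 * se)
})

test_that("covariates respect their structural constraints", {
  cfg <- scenarioConfig(nYears = 500, seed = 4)
  cov <- generateCovariates(cfg)
  raw <- rawCovariates(cov)
  expect_true(all(raw[, "ash_dec"] <= raw[, "ash_mar"]))
  expect_true(all(raw[, "ash_mar"] >= 0))
  expect_true(all(raw[, "temp"] >= cfg@tempRange[1] &
                  raw[, "temp"] <= cfg@tempRange[2]))
  z <- zCovariates(cov)
  expect_lt(max(abs(colMeans(z))), 1e-9)
})

test_that("generation is reproducible under a fixed seed", {
  cfg <- scenarioConfig(nYears = 20, seed = 11)
  a <- generateDataset(cfg)
  b <- generateDataset(cfg)
  expect_identical(trapCounts(a$trap), trapCounts(b$trap))
  expect_identical(naDec(a$latents), naDec(b$latents))
  expect_equal(rawCovariates(a$covariates), rawCovariates(b$covariates))
})

test_that("perfect detection makes trap totals equal latent abundances", {
  cfg <- scenarioConfig(nYears = 10, seed = 5,
                        trueCaptureProbs = CaptureProbs(1, 1, 1))
  ds <- generateDataset(cfg)
  tot <- trapTotals(ds$trap)
  expect_identical(unname(tot[, "adults_december"]), naDec(ds$latents))
  expect_identical(unname(tot[-1, "adults_june"]), naJun(ds$latents)[-1])
  expect_identical(unname(tot[-1, "juveniles_june"]), nJuv(ds$latents)[-1])
})

test_that("trap totals never exceed the generating latent abundances", {
  cfg <- scenarioConfig(nYears = 25, seed = 6)
  ds <- generateDataset(cfg)
  tot <- trapTotals(ds$trap)
  expect_true(all(tot[, "adults_december"] <= naDec(ds$latents)))
  expect_true(all(tot[-1, "adults_june"] <= naJun(ds$latents)[-1]))
})

test_that("strong mast effect raises winter growth in mast years (latent truth)", {
  cfg <- scenarioConfig(nYears = 400, seed = 7)
  ds <- generateDataset(cfg)
  lat <- ds$latents
  isMastWinter <- rawCovariates(ds$covariates)[, "ash_mar"] >= cfg@mastRange[1]
  # realized winter growth log(Najun_t / Nadec_{t-1}) vs the winter's mast state
  T <- nYears(lat)
  wg <- log(pmax(naJun(lat)[2:T], 1) / pmax(naDec(lat)[1:(T - 1)], 1))
  mast <- isMastWinter[1:(T - 1)]
  expect_gt(mean(wg[mast]), mean(wg[!mast]) + 0.5)
})

test_that("annual cycle: December exceeds June adults when alpha_sg > 0 > alpha_wg", {
  cfg <- scenarioConfig(nYears = 300, seed = 8)
  expect_gt(cfg@trueParams@alpha["sg"], 0)
  expect_lt(cfg@trueParams@alpha["wg"], 0)
  ds <- generateDataset(cfg)
  lat <- ds$latents
  expect_gt(mean(naDec(lat)[-1]), mean(naJun(lat)[-1]))
})

test_that("generated files pass data-model validation round-trip", {
  cfg <- scenarioConfig(nYears = 8, seed = 9)
  out <- withr::local_tempdir()
  res <- runSimulation(cfg, out)
  expect_true(file.exists(file.path(out, "manifest.json")))
  trap <- readTrapSeries(file.path(out, "trap_counts.csv"))
  cov <- readCovariateSeries(file.path(out, "covariates.csv"))
  lat <- readLatentStates(file.path(out, "truth_latents.csv"))
  expect_identical(trapCounts(trap), trapCounts(res$data$trap))
  expect_identical(naDec(lat), naDec(res$data$latents))
  expect_equal(rawCovariates(cov), rawCovariates(res$data$covariates),
               tolerance = 1e-6)
})

test_that("experiment pair generator: perfect symmetry of the null design", {
  cfg <- scenarioConfig(nYears = 5, seed = 10)
  pair <- generateExperimentPair(cfg, deltaWinterGrowth = 0)
  expect_identical(dim(trapCounts(pair$control$trap)),
                   dim(trapCounts(pair$experimental$trap)))
  # addition shifts only the experimental winter rates in addition years
  pair2 <- generateExperimentPair(cfg, deltaWinterGrowth = 1,
                                  additionYears = c(2, 5), seed = 12)
  pair0 <- generateExperimentPair(cfg, deltaWinterGrowth = 0,
                                  additionYears = c(2, 5), seed = 12)
  dw <- pair2$experimental$rates$wgrowth - pair0$experimental$rates$wgrowth
  expect_equal(dw, c(0, 1, 0, 0, 1))
  expect_equal(pair2$control$rates$wgrowth, pair0$control$rates$wgrowth)
})
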