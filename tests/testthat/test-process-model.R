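zeroParams <- function() {
  ProcessParams(alpha = c(0, 0, 0), beta = matrix(0, 3, 5),
                sigma = c(1, 1, 1))
}

test_that("rate functions are the stated linear forms", {
  p0 <- zeroParams()
  expect_identical(winterGrowthRate(p0, 1.3, -0.2, 0.7), 0)
  expect_identical(reproductionRate(p0, 1.3, -0.2, 0.7), 0)
  expect_identical(summerGrowthRate(p0, 1.3, -0.2, 0.7), 0)

  # hand-summed arbitrary point: -0.5 + 0.3*1 + 0.1*0 - 0.4*1 + 0.2*1*1 + 0
  p <- ProcessParams(alpha = c(-0.5, -0.5, -0.5),
                     beta = rbind(c(0.3, 0.1, -0.4, 0.2, 0),
                                  c(0.3, 0.1, -0.4, 0.2, 0),
                                  c(0.3, 0.1, -0.4, 0.2, 0)),
                     sigma = c(1, 1, 1))
  expect_equal(winterGrowthRate(p, 1, 0, 1), -0.4)
  expect_equal(reproductionRate(p, 1, 0, 1), -0.4)
  expect_equal(summerGrowthRate(p, 1, 0, 1), -0.4)
  # process noise enters additively
  expect_equal(winterGrowthRate(p, 1, 0, 1, eps = 0.25), -0.15)
})

test_that("rates are exactly linear in each covariate (finite differences)", {
  set.seed(11)
  p <- ProcessParams(alpha = rnorm(3), beta = matrix(rnorm(15), 3, 5),
                     sigma = c(0.5, 0.5, 0.5))
  base <- c(ash = 0.4, x2 = -1.1, logN = 0.8)
  h <- 1
  for (fn in list(winterGrowthRate, reproductionRate, summerGrowthRate)) {
    s <- if (identical(fn, winterGrowthRate)) "wg"
         else if (identical(fn, reproductionRate)) "r" else "sg"
    b <- p@beta[s, ]
    slope1 <- (fn(p, base[1] + h, base[2], base[3]) -
               fn(p, base[1], base[2], base[3])) / h
    expect_equal(slope1, b[1] + b[4] * base[3], tolerance = 1e-12,
                 ignore_attr = TRUE)
    slope2 <- (fn(p, base[1], base[2] + h, base[3]) -
               fn(p, base[1], base[2], base[3])) / h
    expect_equal(slope2, b[2] + b[5] * base[3], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("sign flip of a covariate flips only its own contribution", {
  p <- ProcessParams(alpha = c(0.2, 0.2, 0.2),
                     beta = rbind(c(0.7, -0.3, 0.5, 0, 0),
                                  c(0.7, -0.3, 0.5, 0, 0),
                                  c(0.7, -0.3, 0.5, 0, 0)),
                     sigma = c(1, 1, 1))
  delta <- winterGrowthRate(p, 1, 0.4, 0.9) - winterGrowthRate(p, -1, 0.4, 0.9)
  expect_equal(delta, 2 * 0.7, ignore_attr = TRUE)
})

test_that("Poisson transition: absorbing zero and closed-form mean", {
  expect_identical(stepAbundance(0, 5), 0L)
  expect_equal(stepAbundance(50, log(2), deterministic = TRUE), 100,
               ignore_attr = TRUE)
  expect_error(stepAbundance(10, 100), "cap")
})

test_that("transition conserves expectation (Monte Carlo vs Poisson moments)", {
  set.seed(21)
  n <- 1e5
  draws <- stepAbundance(rep(100L, n), 0)
  se <- sqrt(100 / n)
  expect_lt(abs(mean(draws) - 100), 4 * se)
  draws2 <- stepAbundance(rep(60L, n), log(1.5))
  expect_lt(abs(mean(draws2) - 90), 4 * sqrt(90 / n))
})

test_that("deterministic no-feedback trajectory is constant; reproduction off", {
  pars <- ProcessParams(alpha = c(0, -30, 0), beta = matrix(0, 3, 5),
                        sigma = c(1e-12, 1e-12, 1e-12))
  cov <- CovariateSeries(1:6, c(1, 2, 3, 1, 2, 3), c(0.5, 1, 2, 0.5, 1, 1),
                         c(0, 1, 2, 0, 1, 2))
  lat <- simulateTrajectory(pars, cov, n0 = 40, CenteringConstants(0, 0),
                            deterministic = TRUE)
  expect_true(all(naDec(lat) == 40))
  expect_true(all(nJuv(lat)[-1] == 0))
  expect_true(all(naJun(lat)[-1] == 40))
  expect_true(is.na(naJun(lat)[1]))
})

test_that("trajectories are reproducible under a fixed seed", {
  cfg <- smallScenario(nYears = 15, seed = 8)
  cov <- generateCovariates(cfg)
  set.seed(123)
  a <- simulateTrajectory(cfg@trueParams, cov, 50, cfg@centering)
  set.seed(123)
  b <- simulateTrajectory(cfg@trueParams, cov, 50, cfg@centering)
  expect_identical(naDec(a), naDec(b))
  expect_identical(naJun(a), naJun(b))
  expect_identical(nJuv(a), nJuv(b))
})

test_that("extinction is absorbing in stochastic trajectories", {
  pars <- ProcessParams(alpha = c(-6, -6, -6), beta = matrix(0, 3, 5),
                        sigma = c(0.1, 0.1, 0.1))
  cov <- CovariateSeries(1:10, 1:10, 0.5 * (1:10), rnorm(10))
  set.seed(5)
  lat <- simulateTrajectory(pars, cov, 5, CenteringConstants(0, 0))
  d <- naDec(lat)
  firstZero <- which(d == 0)[1]
  expect_false(is.na(firstZero))
  expect_true(all(d[firstZero:length(d)] == 0))
})

test_that("log-abundance chain matches the Gompertz AR(1) stationary law", {
  # reproduction off and covariate effects zero collapse the annual map to
  # x_t = phi x_{t-1} + const + innovations with phi = (1+b_wg)(1+b_sg)
  # and innovation variance (1+b_sg)^2 sd_wg^2 + sd_sg^2; large abundance
  # keeps Poisson noise negligible.
  pars <- ProcessParams(alpha = c(-0.5, -20, 0.5),
                        beta = rbind(c(0, 0, -0.3, 0, 0),
                                     c(0, 0, 0, 0, 0),
                                     c(0, 0, -0.3, 0, 0)),
                        sigma = c(0.15, 0.1, 0.15))
  cen <- CenteringConstants(8, 7.5)
  set.seed(99)
  nY <- 5000
  cov <- CovariateSeries(1:nY, runif(nY), runif(nY) * 0.5, rnorm(nY))
  lat <- simulateTrajectory(pars, cov, n0 = 3000, cen)
  x <- log(naDec(lat)[-(1:50)])
  phi <- (1 - 0.3)^2
  innovVar <- (1 - 0.3)^2 * 0.15^2 + 0.15^2
  statVar <- innovVar / (1 - phi^2)
  expect_lt(abs(var(x) - statVar) / statVar, 0.10)
  expect_lt(abs(mean(x) - 8), 0.1)
})
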