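test_that("error function: zero at equality, linear in tInv, direct-sum oracle", {
  model <- sin(seq(0, 3, length.out = 50))
  expect_identical(errorFunction(model, model, ySem = 0.1), 0)

  data <- model + 0.03
  e1 <- errorFunction(model, data, ySem = 0.02, tInv = 1)
  e2 <- errorFunction(model, data, ySem = 0.02, tInv = 2)
  expect_equal(e2, 2 * e1)

  # data offset by exactly one ySem at every point: E = tInv * n
  n <- 50
  expect_equal(errorFunction(model, model + 0.02, ySem = 0.02, tInv = 1.5),
               1.5 * n)

  expect_error(errorFunction(model, data[-1], ySem = 0.1), "different grids")
  expect_error(errorFunction(model, data, ySem = 0), "ySem")
})

test_that("sampler reproduces a 1-D Gaussian posterior and adapts to ~50%", {
  # E = ((x - 2) / 0.5)^2 so the stationary density is N(2, 0.5^2 / 2)
  cfg <- mcmcConfig(nAdapt1 = 300, nAdapt2 = 300, nProduction = 8000,
                    ySem = 0.5, seed = 101)
  tr <- runMCMC(function(p) p, data = 2,
                bounds = data.frame(parameter = "x", lower = -20, upper = 20),
                config = cfg)
  x <- traceSamples(tr)[, 1]
  expect_equal(mean(x), 2, tolerance = 0.05)
  expect_equal(sd(x), 0.5 / sqrt(2), tolerance = 0.10)
  expect_true(all(x >= -20 & x <= 20))
  expect_gte(tr@acceptance[1], 0.35)
  expect_lte(tr@acceptance[1], 0.65)

  # identical configuration => identical trace
  tr2 <- runMCMC(function(p) p, data = 2,
                 bounds = data.frame(parameter = "x", lower = -20, upper = 20),
                 config = cfg)
  expect_identical(traceSamples(tr), traceSamples(tr2))

  # the production default matches the published run length
  expect_equal(mcmcConfig()@nProduction, 20000L)
})

test_that("sampler reproduces the covariance of a correlated 2-D Gaussian", {
  # forward = A p, data = 0, ySem = 1: E = |A p|^2, density exp(-E),
  # covariance (2 A'A)^{-1}
  A <- matrix(c(1, 0, 0.9, 0.8), 2, 2)
  covTrue <- solve(2 * crossprod(A))
  cfg <- mcmcConfig(nAdapt1 = 400, nAdapt2 = 400, nProduction = 30000,
                    ySem = 1, seed = 5)
  tr <- runMCMC(function(p) as.numeric(A %*% p), data = c(0, 0),
                bounds = data.frame(lower = c(-20, -20), upper = c(20, 20)),
                config = cfg)
  covHat <- cov(traceSamples(tr))
  expect_lt(max(abs(covHat - covTrue)) / max(abs(covTrue)), 0.15)
})

test_that("boundary reflection keeps the chain inside a tight box", {
  cfg <- mcmcConfig(nAdapt1 = 100, nAdapt2 = 100, nProduction = 3000,
                    ySem = 1, seed = 3)
  # posterior mode at 2 but the box ends at 1: samples pile at the boundary
  tr <- runMCMC(function(p) p, data = 2,
                bounds = data.frame(lower = 0, upper = 1), config = cfg)
  x <- traceSamples(tr)[, 1]
  expect_true(all(x >= 0 & x <= 1))
  # truncated-Gaussian oracle: density exp(-(x-2)^2) restricted to [0, 1]
  g <- function(u) exp(-(u - 2)^2)
  meanTrue <- stats::integrate(function(u) u * g(u), 0, 1)$value /
    stats::integrate(g, 0, 1)$value
  expect_equal(mean(x), meanTrue, tolerance = 0.05)
})

test_that("posterior summary: symmetrized intervals against quantile oracles", {
  mkTrace <- function(x) new("MCMCTrace",
    samples = matrix(x, ncol = 1, dimnames = list(NULL, "p")),
    errors = (x - stats::median(x))^2, acceptance = c(p = 0.5),
    stepSizes = c(p = 1), bounds = rbind(lower = -Inf, upper = Inf),
    config = mcmcConfig())

  set.seed(99)
  zn <- rnorm(20000)
  s <- summarizePosterior(mkTrace(zn))
  expect_equal(unname(ci95Half(s)["p"]), 1.96, tolerance = 0.05 / 1.96)

  zu <- runif(20000)
  su <- summarizePosterior(mkTrace(zu))
  expect_equal(unname(ci95Half(su)["p"]), 0.475, tolerance = 0.01 / 0.475)

  sc <- summarizePosterior(mkTrace(rep(1.3, 100)))
  expect_identical(unname(ci95Half(sc)["p"]), 0)
  expect_identical(unname(bestFit(sc)["p"]), 1.3)

  # best is the minimum-error sample
  expect_equal(unname(bestFit(s)["p"]), zn[which.min((zn - median(zn))^2)])
})

test_that("step autocorrelation: white-noise bound and AR(1) closed form", {
  set.seed(21)
  n <- 20000
  white <- rnorm(n)
  acW <- stepAutocorrelation(white, maxLag = 50)
  expect_identical(acW[1], 1)
  expect_lt(max(abs(acW[-1])), 3 / sqrt(n))

  phi <- 0.9
  ar1 <- as.numeric(stats::arima.sim(list(ar = phi), n))
  acA <- stepAutocorrelation(ar1, maxLag = 10)
  expect_equal(acA[2], phi, tolerance = 0.03 / phi)

  expect_error(stepAutocorrelation(rep(2, 100), maxLag = 10), "zero-variance")
  expect_error(stepAutocorrelation(white, maxLag = n + 5), "below the trace")
})
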