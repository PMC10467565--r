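test_that("buildModel enumerates pools, rate groups and fractions per variant", {
  spec <- buildModel("restricted", 1.0, 110.7)
  expect_equal(nPools(spec), 10)
  expect_length(rateGroups(spec), 6)
  expect_equal(poolTable(spec)$fraction[poolTable(spec)$label == "C1_alpha"],
               0.36 / (5 * 1.0 + 110.7))

  sa <- buildModel("split_anomeric", 1.0, 110.7)
  expect_equal(nPools(sa), 7)
  expect_length(rateGroups(sa), 6)
  expect_setequal(poolTable(sa)$label,
                  c("C1_alpha", "C1_beta", "C2", "C3", "C4", "C6", "water"))

  expect_equal(nPools(buildModel("split2")), 8)
  expect_length(rateGroups(buildModel("split2")), 7)
  expect_equal(nPools(buildModel("split3")), 9)
  expect_length(rateGroups(buildModel("split3")), 8)

  expect_error(buildModel("no_such_model"), "unknown model variant")

  # fractions always sum to one and stay positive
  set.seed(11)
  for (v in c("split_anomeric", "split2", "split3", "restricted",
              "restricted_cross")) {
    g <- runif(1, 0.01, 3)
    w <- runif(1, 50, 200)
    p <- poolTable(buildModel(v, g, w))
    expect_equal(sum(p$fraction), 1, tolerance = 1e-14)
    expect_true(all(p$fraction > 0))
  }
})

test_that("free-parameter counts follow the model ladder", {
  countSpectral <- function(v) {
    s <- buildModel(v)
    sum(poolTable(s)$anomer != "water") + length(rateGroups(s))
  }
  expect_equal(countSpectral("split_anomeric"), 12)  # 6 shifts + 6 rates
  expect_equal(countSpectral("restricted"), 15)      # 9 shifts + 6 rates
  expect_lt(countSpectral("restricted"), countSpectral("split3"))

  # restricted: 15 spectral + 3 baseline + 1 scale = 19 free parameters
  b <- parameterBounds(buildModel("restricted"), "initial")
  expect_equal(nrow(b), 19)
})

test_that("exchange matrix conserves population and has the right stationary state", {
  # symmetric two-site closed form
  m <- symmetricTwoSite(1.0, 100)
  K <- assembleExchangeMatrix(m$spec, m$params)
  expect_equal(unname(K), matrix(c(-100, 100, 100, -100), 2, 2),
               tolerance = 1e-14)

  set.seed(42)
  for (v in c("split_anomeric", "split2", "split3", "restricted",
              "restricted_cross")) {
    spec <- buildModel(v)
    nr <- length(rateGroups(spec))
    params <- modelParameters(
      spec,
      deltas = stats::setNames(runif(sum(poolTable(spec)$anomer != "water"),
                                     0.5, 3),
                               poolTable(spec)$label[
                                 poolTable(spec)$anomer != "water"]),
      rates = stats::setNames(runif(nr, 10, 3000), names(rateGroups(spec))),
      crossRates = runif(length(spec@crossPairs), 0, 500))
    K <- assembleExchangeMatrix(spec, params)
    f <- poolTable(spec)$fraction
    scale <- max(abs(K))
    expect_lt(max(abs(colSums(K))), 1e-10 * scale)
    expect_lt(max(abs(K %*% f)), 1e-10 * scale)
  }

  # cross model with zero cross rates collapses exactly onto restricted
  r <- buildModel("restricted")
  rc <- buildModel("restricted_cross")
  pr <- glucoseModelParameters(r, 6.21, 270)
  prc <- glucoseModelParameters(rc, 6.21, 270)
  expect_identical(assembleExchangeMatrix(r, pr),
                   assembleExchangeMatrix(rc, prc))

  expect_error(assembleExchangeMatrix(r, modelParameters(
    r, deltas = pr@deltas, rates = pr@rates[1:3])), "expected 6 rates")
})

test_that("stationary fractions match brute-force ODE population dynamics", {
  # water-dominated three-pool system, rates 200 and 400 1/s
  spec <- customSpec(c("A", "B"), c(0.05, 0.05, 0.90))
  params <- modelParameters(spec, deltas = c(A = 1, B = 2),
                            rates = c(A = 200, B = 400))
  K <- assembleExchangeMatrix(spec, params)
  p0 <- c(0.2, 0.7, 0.1)  # any distribution relaxes to the pool fractions
  sol <- deSolve::ode(y = p0, times = c(0, 1),
                      func = function(t, y, parms) list(K %*% y),
                      parms = NULL)
  expect_equal(as.numeric(sol[2, 2:4]), poolTable(spec)$fraction,
               tolerance = 1e-8)
})

test_that("parameter bounds: stages, anchors and the integral-scale window", {
  spec <- buildModel("restricted")

  b0 <- parameterBounds(spec, "initial")
  expect_true(all(b0$upper > b0$lower))
  sc <- b0[b0$type == "scale", ]
  expect_equal(c(sc$lower, sc$upper), c(0.8, 1.2))
  # wide rate windows: a posterior mode of 2635 1/s lies strictly inside
  rates <- b0[b0$type == "rate", ]
  expect_true(all(rates$lower < 2635 & 2635 < rates$upper))

  b1 <- parameterBounds(spec, "assignment_fixed",
                        priors = glucoseShiftTable(6.21))
  d <- b1[b1$type == "delta", ]
  o <- order(d$lower)
  expect_true(all(d$upper[o][-nrow(d)] <= d$lower[o][-1]))  # pairwise disjoint
  expect_equal(b1[b1$type == "scale", ]$lower, 0.8)

  expect_error(parameterBounds(spec, "assignment_fixed"),
               "needs prior shifts")
})
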