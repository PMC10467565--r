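test_that("CPMG R2: no exchange partner means no decay; fast-exchange closed form", {
  # water-only model: nothing decays (no relaxation terms in the model)
  m1 <- customSpec(character(0), 1)
  p1 <- modelParameters(m1, deltas = stats::setNames(numeric(0), character(0)),
                        rates = stats::setNames(numeric(0), character(0)))
  cp <- cpmgSpec(10, 0.010, "ideal", spectrometerFreqMHz = 500)
  expect_equal(simulateCpmgR2(m1, p1, cp), 0, tolerance = 1e-10)

  # dilute two-site fast exchange: Swift-Connick R2 = fb dw^2 k/(k^2 + dw^2)
  fb <- 1e-3
  delta <- 1.0
  k <- 2e4
  m <- poolModel(fb, delta, k)
  r2 <- simulateCpmgR2(m$spec, m$params, cp)
  dw <- 2 * pi * delta * 500
  expect_equal(r2, fb * dw^2 * k / (k^2 + dw^2), tolerance = 0.05)

  # dispersion plateau: halving tau changes R2 by < 2% when k*tau >> 1
  r2half <- simulateCpmgR2(m$spec, m$params,
                           cpmgSpec(20, 0.005, "ideal",
                                    spectrometerFreqMHz = 500))
  expect_equal(r2half, r2, tolerance = 0.02)
})

test_that("relaxivity: zero-rate limit, dilution guard, linear regime", {
  cp <- cpmgSpec(10, 0.010, "ideal", spectrometerFreqMHz = 499.9)
  expect_equal(relaxivity(1.44, 0, cpmg = cp)@relaxivity, 0)
  expect_error(relaxivity(1.44, 4600, glucoseMM = 1500, cpmg = cp),
               "dilute assumption")
  # 1 mM is in the linear regime: the 5x cross-check stays silent
  expect_silent(r <- relaxivity(1.44, 4600, glucoseMM = 1, cpmg = cp))
  expect_equal(r@R2ex / r@glucoseMM, r@relaxivity)
})

test_that("R2(k) disperses with a single maximum near k = delta-omega", {
  fb <- 1e-3
  delta <- 1.44
  dw <- 2 * pi * delta * 500
  cp <- cpmgSpec(10, 0.010, "ideal", spectrometerFreqMHz = 500)
  ks <- 10^seq(2, 6, length.out = 17)
  r2 <- vapply(ks, function(k) {
    m <- poolModel(fb, delta, k)
    simulateCpmgR2(m$spec, m$params, cp)
  }, numeric(1))
  s <- sign(diff(r2))
  expect_lte(sum(diff(s) != 0), 1)        # unimodal over the grid
  kmax <- ks[which.max(r2)]
  expect_lt(abs(log(kmax / dw)), log(3))  # maximum within 3x of delta-omega
})

test_that("field dependence: quadratic growth while k >> dw, saturating beyond", {
  # k = 4600 1/s fixed; 3 T -> 7 T is nearly quadratic in field, the step
  # to 11.7 T falls below the quadratic prediction as dw approaches k
  cp <- function(fq) cpmgSpec(10, 0.010, "ideal", spectrometerFreqMHz = fq)
  r3 <- relaxivity(1.44, 4600, cpmg = cp(127.7))@relaxivity
  r7 <- relaxivity(1.44, 4600, cpmg = cp(298))@relaxivity
  r117 <- relaxivity(1.44, 4600, cpmg = cp(499.9))@relaxivity
  expect_equal(r7 / r3, (298 / 127.7)^2, tolerance = 0.25)
  expect_lt(r117 / r7, (499.9 / 298)^2 * 0.85)
  expect_gt(r117, r7)
})

test_that("multi-pool relaxivity is additive over dilute pools", {
  # dilute restricted glucose model vs the sum of independent two-site models
  spec <- buildModel("restricted", glucoseMolar = 1e-3)
  params <- glucoseModelParameters(spec, 6.21, 295)
  cp <- cpmgSpec(10, 0.010, "ideal", spectrometerFreqMHz = 500)
  r2all <- simulateCpmgR2(spec, params, cp)

  p <- poolTable(spec)
  nonWater <- which(p$anomer != "water")
  kPool <- glucoExchange:::.poolRates(spec, params)
  r2sum <- sum(vapply(nonWater, function(i) {
    m <- poolModel(p$fraction[i], unname(params@deltas[p$label[i]]),
                   unname(kPool[p$label[i]]))
    simulateCpmgR2(m$spec, m$params, cp)
  }, numeric(1)))
  expect_equal(r2all, r2sum, tolerance = 0.03)
})

test_that("relaxivity vs temperature from the Eyring tables is smooth and single-peaked", {
  spec <- buildModel("restricted", glucoseMolar = 1e-3)
  cp <- cpmgSpec(10, 0.010, "ideal", spectrometerFreqMHz = 499.9)
  temps <- seq(260, 320, by = 7.5)
  rel <- vapply(temps, function(T) {
    params <- glucoseModelParameters(spec, 7.00, T)
    relaxivityFromModel(spec, params, 1, cp)@relaxivity
  }, numeric(1))
  expect_true(all(is.finite(rel)) && all(rel > 0))
  s <- sign(diff(rel))
  expect_lte(sum(diff(s) != 0), 1)  # rises to a single maximum then falls
})

test_that("CPMG-filtered spectra: zero-delay limit and refocusing invariance", {
  m <- poolModel(c(0.004, 0.006), c(1.1, 2.3), c(150, 420))
  acq <- smallAcq(td = 2048)

  plain <- simulateSpectrum(m$params, m$spec, acq)
  filt0 <- cpmgFilteredSpectrum(m$spec, m$params, acq, d20List = 1e-9,
                                nEchoes = 4, pulseMode = "ideal")[[1]]
  expect_lt(max(abs(intensity(filt0) - intensity(plain))),
            1e-3 * max(abs(intensity(plain))))

  # a single on-resonance pool refocuses perfectly: no d20 dependence
  w <- customSpec(character(0), 1)
  pw <- modelParameters(w, deltas = stats::setNames(numeric(0), character(0)),
                        rates = stats::setNames(numeric(0), character(0)))
  fw <- cpmgFilteredSpectrum(w, pw, acq, d20List = c(1e-3, 0.02),
                             pulseMode = "ideal")
  expect_equal(intensity(fw[[1]]), intensity(fw[[2]]), tolerance = 1e-9)

  # longer delays imprint structure: traces differ from the plain spectrum
  filt <- cpmgFilteredSpectrum(m$spec, m$params, acq,
                               d20List = c(0.0015, 0.005),
                               pulseMode = "ideal")
  expect_gt(max(abs(intensity(filt[[1]]) - intensity(plain))),
            0.02 * max(abs(intensity(plain))))
})

test_that("two-site echo train matches piecewise Bloch-McConnell propagation", {
  fb <- 0.01
  delta <- 1.8
  k <- 600
  m <- poolModel(fb, delta, k)
  acq <- smallAcq(td = 256)
  nE <- 4

  # oracle: 2x2 single-quantum propagation with instantaneous 180y pulses
  # acting as m -> -conj(m) (hermiticity of the density operator)
  A <- assembleExchangeMatrix(m$spec, m$params) +
    1i * diag(c(2 * pi * delta * 500, 0))
  f <- poolTable(m$spec)$fraction
  for (d20 in c(0.001, 0.004, 0.012)) {
    P <- glucoExchange:::.expmG(A, d20)
    v <- as.vector(f + 0i)
    for (e in seq_len(nE)) v <- P %*% (-Conj(P %*% v))
    oracleM <- Mod(sum(v))

    run <- glucoExchange:::.runCpmgTrain(
      m$spec, m$params, acq,
      new("CPMGSpec", nEchoes = as.integer(nE), halfEchoS = d20,
          pulseMode = "ideal", pulseB1Hz = 25000, spectrometerFreqMHz = 500))
    # the ideal 90x excitation scales the I- block by 1/2
    expect_equal(run$mEnd, oracleM / 2, tolerance = 1e-8)
  }
})
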