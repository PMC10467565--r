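test_that("extended Liouvillian: dimension, trivial limit, single-quantum block", {
  spec <- buildModel("restricted")
  params <- glucoseModelParameters(spec, 6.21, 270)
  acq <- paperAcq()
  G <- buildExtendedLiouvillian(spec, params, acq)
  expect_equal(dim(G), c(40, 40))

  # one pool, zero offset, no exchange: the 4x4 zero generator
  m1 <- customSpec(character(0), 1)
  p1 <- modelParameters(m1, deltas = stats::setNames(numeric(0), character(0)),
                        rates = stats::setNames(numeric(0), character(0)))
  G1 <- buildExtendedLiouvillian(m1, p1, acq)
  expect_equal(dim(G1), c(4, 4))
  expect_true(all(G1 == 0))

  # two pools: the I- block equals the Bloch-McConnell matrix i*Omega + K
  m2 <- poolModel(0.1, deltaPpm = 1.3, kEx = 250)
  G2 <- buildExtendedLiouvillian(m2$spec, m2$params, acq)
  K2 <- assembleExchangeMatrix(m2$spec, m2$params)
  omega2 <- c(2 * pi * 1.3 * acq@spectrometerFreqMHz, 0)
  expect_equal(unname(G2[3:4, 3:4]), unname(K2 + 1i * diag(omega2)),
               tolerance = 1e-14)
})

test_that("FID: pure oscillation, unit start, full vs reduced propagation", {
  acq <- smallAcq(td = 512)

  # single solute pool at +2 ppm without exchange: pure phase evolution
  m <- poolModel(1e-9, deltaPpm = 2, kEx = 0)
  m$spec@pools$fraction <- c(1 - 1e-12, 1e-12)  # essentially all signal at 2 ppm
  fid <- simulateFid(buildExtendedLiouvillian(m$spec, m$params, acq),
                     m$spec, acq)
  tax <- (seq_len(acq@td) - 1) * (1 / (15 * 500))
  expect_equal(fid, exp(2i * pi * (2 * 500) * tax), tolerance = 1e-9)

  # unit initial transverse magnetization for every variant, and agreement
  # between the 4N extended-space propagation and the reduced N-dimensional
  # single-quantum Bloch-McConnell propagation
  for (v in c("split_anomeric", "restricted", "restricted_cross")) {
    spec <- buildModel(v)
    nD <- sum(poolTable(spec)$anomer != "water")
    set.seed(7)
    params <- modelParameters(
      spec,
      deltas = stats::setNames(seq(0.7, 2.9, length.out = nD),
                               poolTable(spec)$label[
                                 poolTable(spec)$anomer != "water"]),
      rates = stats::setNames(runif(length(rateGroups(spec)), 50, 800),
                              names(rateGroups(spec))),
      crossRates = runif(length(spec@crossPairs), 0, 200))
    full <- simulateFid(buildExtendedLiouvillian(spec, params, acq), spec, acq)
    reduced <- glucoExchange:::.bmFid(spec, params, acq)
    expect_lt(Mod(full[1] - 1), 1e-12)
    expect_lt(max(Mod(full - reduced)) / max(Mod(reduced)), 1e-9)
  }
})

test_that("processing: apodization linewidth and slow/fast exchange limits", {
  # water-only model: the line acquires FWHM = lb within grid accuracy
  acqFine <- acquisitionConfig(spectrometerFreqMHz = 500, sweepWidthPpm = 2,
                               td = 16384, lbHz = 1)
  m1 <- customSpec(character(0), 1)
  p1 <- modelParameters(m1, deltas = stats::setNames(numeric(0), character(0)),
                        rates = stats::setNames(numeric(0), character(0)))
  sp <- simulateSpectrum(p1, m1, acqFine)
  y <- intensity(sp)
  hz <- axisPpm(sp) * 500
  half <- max(y) / 2
  above <- which(y > half)
  # linear interpolation at the half-height crossings
  i1 <- min(above); i2 <- max(above)
  xl <- hz[i1 - 1] + (half - y[i1 - 1]) / (y[i1] - y[i1 - 1]) *
    (hz[i1] - hz[i1 - 1])
  xr <- hz[i2] + (half - y[i2]) / (y[i2 + 1] - y[i2]) * (hz[i2 + 1] - hz[i2])
  expect_equal(xr - xl, 1.0, tolerance = 0.02)

  # two equal pools 200 Hz apart: resolved doublet at slow exchange, one
  # motionally averaged line at the population mean in fast exchange
  acq2 <- acquisitionConfig(spectrometerFreqMHz = 500, sweepWidthPpm = 4,
                            td = 16384, lbHz = 1)
  slow <- symmetricTwoSite(0.4, 1e-3)
  ySlow <- intensity(simulateSpectrum(slow$params, slow$spec, acq2))
  expect_equal(countPeaks(ySlow), 2)
  fast <- symmetricTwoSite(0.4, 1e6)
  spFast <- simulateSpectrum(fast$params, fast$spec, acq2)
  yFast <- intensity(spFast)
  expect_equal(countPeaks(yFast), 1)
  expect_equal(axisPpm(spFast)[which.max(yFast)], 0.2, tolerance = 0.01)
})

test_that("two-site lineshape matches the closed-form exchange lineshape", {
  # oracle: continuous-FT lineshape from direct matrix inversion,
  # S(nu) = Re 1' ((2i pi nu + pi lb) I - A)^{-1} f  with A = i Omega + K
  delta <- 0.4   # 200 Hz at 500 MHz
  k <- 300
  m <- symmetricTwoSite(delta, k)
  # very fine dwell so the discrete spectrum approximates the continuous FT
  acq <- acquisitionConfig(spectrometerFreqMHz = 500, sweepWidthPpm = 960,
                           td = 2^20, lbHz = 1)
  sp <- simulateSpectrum(m$params, m$spec, acq)
  sel <- abs(axisPpm(sp)) <= 1.6
  y <- intensity(sp)[sel]
  nuHz <- axisPpm(sp)[sel] * 500

  A <- assembleExchangeMatrix(m$spec, m$params) +
    1i * diag(c(2 * pi * delta * 500, 0))
  f <- poolTable(m$spec)$fraction
  oracle <- vapply(nuHz, function(nu)
    Re(sum(solve((2i * pi * nu + pi * acq@lbHz) * diag(2) - A, f))),
    numeric(1))
  expect_lt(max(abs(y / max(y) - oracle / max(oracle))), 0.01)
})

test_that("symmetric two-site peaks merge at the standard coalescence rate", {
  dnu <- 200
  acq <- acquisitionConfig(spectrometerFreqMHz = 500, sweepWidthPpm = 4,
                           td = 16384, lbHz = 0.1)
  ks <- seq(300, 600, by = 5)
  nPeaks <- vapply(ks, function(k) {
    m <- symmetricTwoSite(dnu / 500, k)
    countPeaks(intensity(simulateSpectrum(m$params, m$spec, acq)),
               relThreshold = 0.02)
  }, numeric(1))
  kc <- ks[min(which(nPeaks == 1))]
  expect_equal(kc, pi * dnu / sqrt(2), tolerance = 0.10)
})

test_that("total spectral integral is conserved under exchange", {
  spec <- buildModel("restricted")
  acq <- smallAcq(td = 8192)
  base <- glucoseModelParameters(spec, 6.21, 270)
  ints <- vapply(c(0.01, 1, 100), function(mult) {
    p <- base
    p@rates <- base@rates * mult
    sp <- simulateSpectrum(p, spec, acq)
    sum(intensity(sp)) * diff(axisPpm(sp))[1]
  }, numeric(1))
  expect_lt(max(abs(ints - 1)), 1e-3)
})

test_that("baseline addition, normalization and extraction behave as specified", {
  # synthetic spectrum with a known bump: direct hand-computed oracle
  acq <- smallAcq(td = 2048)
  ax <- glucoExchange:::.fullAxis(acq)
  y <- exp(-((ax - 1.5) / 0.2)^2)
  sp <- new("Spectrum", axisPpm = ax, intensity = y)
  idx <- c(900L, 1600L)
  poly <- c(0.02, -0.01, 0.004)
  seg <- applyBaselineAndExtract(sp, poly, 1.1, acq, indexRange = idx)
  axs <- ax[idx[1]:idx[2]]
  expY <- y[idx[1]:idx[2]] + poly[1] + poly[2] * axs + poly[3] * axs^2
  dppm <- axs[2] - axs[1]
  tz <- (sum(expY) - 0.5 * (expY[1] + expY[length(expY)])) * dppm
  expect_equal(intensity(seg), expY / tz * 1.1, tolerance = 1e-12)

  # zero polynomial, unit scale: exactly unit trapezoid integral
  seg0 <- applyBaselineAndExtract(sp, c(0, 0, 0), 1, acq, indexRange = idx)
  y0 <- intensity(seg0)
  expect_equal((sum(y0) - 0.5 * (y0[1] + y0[length(y0)])) * dppm, 1,
               tolerance = 1e-9)

  # a spectrum that only decays away from the water line has no hydroxyl
  # valley: extraction must refuse
  yc <- 1 / (1 + (ax / 0.5)^2)
  expect_error(applyBaselineAndExtract(new("Spectrum", axisPpm = ax,
                                           intensity = yc),
                                       c(0, 0, 0), 1, acq),
               "no local minimum")
})

test_that("forward model is deterministic and coalesces at extreme rates", {
  spec <- buildModel("restricted")
  acq <- smallAcq(td = 8192)
  params <- glucoseModelParameters(spec, 6.21, 270)
  seg1 <- forwardModel(params, spec, acq)
  seg2 <- forwardModel(params, spec, acq)
  expect_identical(intensity(seg1), intensity(seg2))

  # downfield anomeric features where they belong
  ax <- axisPpm(seg1)
  y <- intensity(seg1)
  pk <- ax[which(diff(sign(diff(y))) == -2) + 1]
  expect_true(any(abs(pk - 2.116) < 0.05))
  expect_true(any(abs(pk - 2.835) < 0.05))

  # extreme fast exchange: hydroxyl features vanish into a smooth baseline
  # (compared on the physical intensity scale, against the slow-exchange
  # hydroxyl peak height)
  fast <- params
  fast@rates <- params@rates * 1e6
  spF <- simulateSpectrum(fast, spec, acq)
  axF <- axisPpm(spF)
  inOH <- axF >= 0.8 & axF <= 3.2
  yF <- intensity(spF)[inOH]
  smooth <- stats::smooth.spline(axF[inOH], yF, df = 8)
  spSlow <- simulateSpectrum(params, spec, acq)
  peakSlow <- max(intensity(spSlow)[inOH])
  expect_lt(max(abs(yF - stats::predict(smooth, axF[inOH])$y)),
            0.01 * peakSlow)
})
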