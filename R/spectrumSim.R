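#' @include AllClasses.R exchangeModels.R
#' @useDynLib glucoExchange, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Acquisition settings constructor
#'
#' Defaults mirror a plain pulse-acquire 1D proton acquisition at 11.7 T:
#' 500 MHz Larmor frequency, 15 ppm sweep width, 16384 complex time-domain
#' points, 1 Hz exponential line broadening and no zero filling. The
#' hydroxyl extraction window ends 3.8 ppm downfield of water (8.5 ppm
#' absolute for water at 4.7 ppm).
#'
#' @param spectrometerFreqMHz 1H Larmor frequency, MHz.
#' @param sweepWidthPpm spectral width, ppm.
#' @param td complex time-domain points.
#' @param lbHz exponential line broadening, Hz.
#' @param extractionUpperPpm downfield edge of the hydroxyl window (ppm
#'   offset from water).
#' @param temperatureK temperature label, K.
#' @return an [AcquisitionConfig-class].
#' @export
#' @examples
#' acquisitionConfig()
acquisitionConfig <- function(spectrometerFreqMHz = 500, sweepWidthPpm = 15,
                              td = 16384, lbHz = 1,
                              extractionUpperPpm = 3.8,
                              temperatureK = NA_real_) {
  new("AcquisitionConfig", spectrometerFreqMHz = spectrometerFreqMHz,
      sweepWidthPpm = sweepWidthPpm, td = as.integer(td), lbHz = lbHz,
      extractionUpperPpm = extractionUpperPpm, temperatureK = temperatureK)
}

## rotating-frame offsets (rad/s) in pool order; water = 0
.omegaVector <- function(spec, params, acq) {
  labels <- spec@pools$label
  nonWater <- labels[spec@pools$anomer != "water"]
  d <- params@deltas
  if (is.null(names(d))) names(d) <- nonWater
  if (!all(nonWater %in% names(d)))
    stop("deltas must be named for every non-water pool")
  omega <- numeric(length(labels))
  names(omega) <- labels
  omega[nonWater] <- 2 * pi * d[nonWater] * acq@spectrometerFreqMHz
  omega
}

.dwell <- function(acq) 1 / (acq@sweepWidthPpm * acq@spectrometerFreqMHz)

.dppm <- function(acq) acq@sweepWidthPpm / acq@td

.fullAxis <- function(acq) {
  td <- acq@td
  (seq_len(td) - 1 - td / 2) * .dppm(acq)
}

## basis order of the single-spin Liouville space used throughout
.spinBasis <- c("E", "Im", "Ip", "Iz")

#' Build the extended-Liouville generator
#'
#' Returns the full generator of the coupled spin/chemical dynamics for N
#' pools of isolated spin-1/2 nuclei: the single-spin Liouville space (basis
#' operators E, I-, I+, Iz) tensored with the N-dimensional chemical
#' configuration space, giving a 4N x 4N complex matrix. Free evolution under
#' the chemical-shift Hamiltonian contributes +/- i*Omega_j on the I-/I+
#' blocks; chemical exchange contributes the rate matrix K identically on
#' each spin block; an optional RF field (for finite-pulse simulations)
#' couples the transverse blocks to Iz. No relaxation terms are included:
#' linewidths arise from exchange alone.
#'
#' The detected coherence is the I- block (the "J minus" projection), which
#' evolves as exp(+i*Omega*t) so that downfield offsets appear at positive
#' ppm.
#'
#' @param spec an [ExchangeModelSpec-class].
#' @param params a [ModelParameters-class].
#' @param acq an [AcquisitionConfig-class].
#' @param rfHz RF nutation frequency (Hz); 0 for free evolution.
#' @param rfPhase RF phase (radians; 0 = x, pi/2 = y).
#' @return complex 4N x 4N matrix with attributes `nPools`, `basis` and
#'   `poolOrder`.
#' @export
#' @examples
#' spec <- buildModel("restricted")
#' params <- glucoseModelParameters(spec, 6.21, 270)
#' dim(buildExtendedLiouvillian(spec, params, acquisitionConfig()))  # 40 40
buildExtendedLiouvillian <- function(spec, params, acq, rfHz = 0,
                                     rfPhase = 0) {
  n <- nrow(spec@pools)
  omega <- .omegaVector(spec, params, acq)
  K <- assembleExchangeMatrix(spec, params)
  G <- matrix(0 + 0i, 4 * n, 4 * n)
  blk <- function(s) ((s - 1) * n + 1):(s * n)
  iE <- blk(1); iM <- blk(2); iP <- blk(3); iZ <- blk(4)
  ## exchange acts identically on every spin block
  for (s in 1:4) G[blk(s), blk(s)] <- G[blk(s), blk(s)] + K
  ## chemical shift evolution of the single-quantum coherences
  G[cbind(iM, iM)] <- G[cbind(iM, iM)] + 1i * omega
  G[cbind(iP, iP)] <- G[cbind(iP, iP)] - 1i * omega
  if (rfHz != 0) {
    w1 <- 2 * pi * rfHz
    eip <- exp(1i * rfPhase)
    ## columns I-/I+ feed Iz; column Iz feeds I+/I-
    G[cbind(iZ, iM)] <- G[cbind(iZ, iM)] - 1i * w1 / eip
    G[cbind(iZ, iP)] <- G[cbind(iZ, iP)] + 1i * w1 * eip
    G[cbind(iP, iZ)] <- G[cbind(iP, iZ)] + 1i * (w1 / 2) / eip
    G[cbind(iM, iZ)] <- G[cbind(iM, iZ)] - 1i * (w1 / 2) * eip
  }
  rn <- paste(rep(.spinBasis, each = n), spec@pools$label, sep = ".")
  dimnames(G) <- list(rn, rn)
  attr(G, "nPools") <- n
  attr(G, "basis") <- .spinBasis
  attr(G, "poolOrder") <- spec@pools$label
  G
}

## propagate v0 under generator G sampled every dwell for td points and
## project on the detection vector d at each step (eigendecomposition +
## geometric recurrence)
.propagateDetect <- function(G, v0, d, td, dwell) {
  ev <- eigen(G)
  w <- solve(ev$vectors, v0)
  cm <- as.vector(t(d) %*% ev$vectors) * w
  z <- exp(ev$values * dwell)
  fid <- complex(td)
  zpow <- rep(1 + 0i, length(z))
  for (n in seq_len(td)) {
    fid[n] <- sum(cm * zpow)
    zpow <- zpow * z
  }
  if (any(!is.finite(fid)))
    stop("propagator produced non-finite FID (exchange rates too large?)")
  fid
}

#' Simulate the free induction decay in extended Liouville space
#'
#' Starts from unit transverse magnetization distributed over pools in
#' proportion to their fractions (an ideal 90 degree pulse on equilibrium),
#' applies the dwell-time propagator of the full 4N generator repeatedly and
#' records the total single-quantum (I-) detection at every dwell point.
#' FID[1] equals 1 by construction.
#'
#' @param generator matrix from [buildExtendedLiouvillian()].
#' @param spec the [ExchangeModelSpec-class] the generator was built from.
#' @param acq an [AcquisitionConfig-class] (dwell time = 1 / sweep width).
#' @return complex vector of length `td`.
#' @export
simulateFid <- function(generator, spec, acq) {
  n <- attr(generator, "nPools")
  if (is.null(n) || n != nrow(spec@pools))
    stop("generator was not built for this model spec")
  f <- spec@pools$fraction
  v0 <- complex(4 * n)
  v0[seq_len(n)] <- f                    # E block: populations
  v0[n + seq_len(n)] <- f                # I- block: detected transverse
  v0[2 * n + seq_len(n)] <- f            # I+ block: hermitian counterpart
  d <- numeric(4 * n)
  d[n + seq_len(n)] <- 1                 # detect sum of I- coefficients
  .propagateDetect(generator, v0, d, acq@td, .dwell(acq))
}

## reduced single-quantum Bloch-McConnell FID (the fast route; identical to
## the I- block of the full propagation)
.bmFid <- function(spec, params, acq) {
  omega <- .omegaVector(spec, params, acq)
  K <- assembleExchangeMatrix(spec, params)
  .bmFidCpp(unname(omega), unname(K), spec@pools$fraction, acq@td,
            .dwell(acq))
}

#' Process an FID into a real spectrum
#'
#' Applies exponential apodization exp(-pi * lb * t) (so an infinitely
#' narrow line acquires a full width at half maximum of `lbHz`), discrete
#' Fourier transform without zero filling, and takes the real part (the
#' simulation is intrinsically in phase). Intensities are scaled so the
#' integral over the full ppm axis equals the initial transverse
#' magnetization (1 for [simulateFid()] output).
#'
#' @param fid complex FID of length `td`.
#' @param acq an [AcquisitionConfig-class].
#' @return a [Spectrum-class] on the ppm-offset axis (water at 0, ascending,
#'   spacing sweepWidthPpm/td).
#' @export
processFid <- function(fid, acq) {
  td <- acq@td
  if (length(fid) != td) stop("fid length must equal td")
  tax <- (seq_len(td) - 1) * .dwell(acq)
  y <- fid * exp(-pi * acq@lbHz * tax)
  ## halve the first point: removes the constant DFT baseline pedestal and
  ## makes the absorption-mode integral equal to FID[0]/2
  y[1] <- y[1] / 2
  X <- stats::fft(y)
  X <- c(X[(td / 2 + 1):td], X[1:(td / 2)])
  new("Spectrum", axisPpm = .fullAxis(acq),
      intensity = Re(X) * 2 / td / .dppm(acq),
      metadata = list(acquisition = acq))
}

## 5-point moving average used before the segment-start minimum search
.smooth5 <- function(x) {
  n <- length(x)
  xs <- stats::filter(x, rep(1 / 5, 5), sides = 2)
  xs <- as.numeric(xs)
  xs[is.na(xs)] <- x[is.na(xs)]
  xs
}

## locate the hydroxyl window: first local minimum downfield of the water
## maximum (on the smoothed spectrum), up to the configured upper edge
.locateSegment <- function(spectrum, acq) {
  y <- .smooth5(spectrum@intensity)
  ax <- spectrum@axisPpm
  iEnd <- max(which(ax <= acq@extractionUpperPpm))
  iw <- which.max(y)
  i <- iw + 1
  found <- FALSE
  while (i < iEnd) {
    if (y[i] <= y[i - 1] && y[i] < y[i + 1]) { found <- TRUE; break }
    i <- i + 1
  }
  if (!found)
    stop("no local minimum between the water line and the upper edge; ",
         "spectrum appears fully coalesced")
  c(i, iEnd)
}

#' Add the baseline polynomial and extract the normalized hydroxyl window
#'
#' Adds the quadratic baseline polynomial (in ppm offset) over the window,
#' then extracts the section starting at the first local minimum downfield
#' of the water maximum (searched on a 5-point moving-average smoothed copy)
#' and ending at `extractionUpperPpm`, normalizes it to unit trapezoid
#' integral, and multiplies by the integral scale factor.
#'
#' @param spectrum a [Spectrum-class] on the full grid.
#' @param baselinePoly numeric length 3 (constant, linear, quadratic).
#' @param integralScale scale factor in [0.8, 1.2].
#' @param acq an [AcquisitionConfig-class].
#' @param indexRange optional integer length 2; fixes the window instead of
#'   locating it (used to extract the model on exactly the data window).
#' @return a [SpectrumSegment-class].
#' @export
applyBaselineAndExtract <- function(spectrum, baselinePoly = c(0, 0, 0),
                                    integralScale = 1, acq,
                                    indexRange = NULL) {
  if (is.null(indexRange)) indexRange <- .locateSegment(spectrum, acq)
  idx <- indexRange[1]:indexRange[2]
  ax <- spectrum@axisPpm[idx]
  y <- spectrum@intensity[idx]
  y <- y + baselinePoly[1] + baselinePoly[2] * ax + baselinePoly[3] * ax^2
  dppm <- ax[2] - ax[1]
  integral <- (sum(y) - 0.5 * (y[1] + y[length(y)])) * dppm
  if (!(integral > 0)) stop("non-positive segment integral; cannot normalize")
  new("SpectrumSegment", axisPpm = ax, intensity = y * integralScale / integral,
      metadata = spectrum@metadata,
      indexRange = as.integer(c(indexRange[1], indexRange[2])))
}

#' Forward model: parameters to normalized hydroxyl segment
#'
#' Deterministic composition of generator construction, FID propagation,
#' processing, baseline addition and window extraction. Identical inputs
#' give identical output. When `indexRange` is supplied (the usual case
#' during fitting, where the window is fixed by the measured spectrum) the
#' whole composition runs in compiled code.
#'
#' @param params a [ModelParameters-class].
#' @param spec an [ExchangeModelSpec-class].
#' @param acq an [AcquisitionConfig-class].
#' @param indexRange optional fixed extraction window (integer length 2).
#' @return a [SpectrumSegment-class].
#' @export
#' @examples
#' spec <- buildModel("restricted")
#' params <- glucoseModelParameters(spec, 6.21, 270)
#' seg <- forwardModel(params, spec, acquisitionConfig())
#' length(axisPpm(seg))
forwardModel <- function(params, spec, acq, indexRange = NULL) {
  omega <- unname(.omegaVector(spec, params, acq))
  K <- unname(assembleExchangeMatrix(spec, params))
  f <- spec@pools$fraction
  if (is.null(indexRange)) {
    specFull <- new("Spectrum", axisPpm = .fullAxis(acq),
                    intensity = as.numeric(.bmSpectrumCpp(omega, K, f, acq@td,
                                                          .dwell(acq),
                                                          acq@lbHz,
                                                          .dppm(acq))),
                    metadata = list(acquisition = acq))
    return(applyBaselineAndExtract(specFull, params@baselinePoly,
                                   params@integralScale, acq))
  }
  ax <- .fullAxis(acq)[indexRange[1]:indexRange[2]]
  y <- .forwardSegmentCpp(omega, K, f, acq@td, .dwell(acq), acq@lbHz,
                          .dppm(acq), indexRange[1] - 1L, indexRange[2] - 1L,
                          ax, params@baselinePoly, params@integralScale)
  new("SpectrumSegment", axisPpm = ax, intensity = as.numeric(y),
      metadata = list(acquisition = acq),
      indexRange = as.integer(indexRange))
}

#' Simulate the plain processed spectrum of a model (full grid)
#'
#' Convenience wrapper: reduced Bloch-McConnell propagation + processing,
#' without baseline or extraction.
#'
#' @inheritParams forwardModel
#' @return a [Spectrum-class].
#' @export
simulateSpectrum <- function(params, spec, acq) {
  omega <- unname(.omegaVector(spec, params, acq))
  K <- unname(assembleExchangeMatrix(spec, params))
  new("Spectrum", axisPpm = .fullAxis(acq),
      intensity = as.numeric(.bmSpectrumCpp(omega, K, spec@pools$fraction,
                                            acq@td, .dwell(acq), acq@lbHz,
                                            .dppm(acq))),
      metadata = list(acquisition = acq))
}
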