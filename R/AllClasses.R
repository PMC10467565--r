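#' @import methods
NULL

## ---------------------------------------------------------------------------
## Exchange model classes
## ---------------------------------------------------------------------------

#' Multi-pool hydroxyl exchange model
#'
#' An `ExchangeModelSpec` describes the set of exchangeable proton pools
#' (glucose hydroxyl sites plus water), the population fraction of each pool,
#' and the rate-sharing topology: which pools share a single pseudo
#' first-order exchange rate with water. The optional `crossPairs` slot lists
#' directed hydroxyl-hydroxyl exchange pathways (only used by the
#' `"restricted_cross"` variant).
#'
#' Pools live in the `pools` data.frame with columns `label`, `anomer`
#' (`"alpha"`, `"beta"`, `"shared"` or `"water"`) and `fraction` (proton
#' population fraction, summing to one). The alpha:beta anomer weighting of
#' split sites is 0.36:0.64.
#'
#' @slot variant character, one of `"split_anomeric"`, `"split2"`,
#'   `"split3"`, `"restricted"`, `"restricted_cross"`.
#' @slot pools data.frame with one row per pool (water last).
#' @slot rateGroups named list; each element is a character vector of
#'   non-water pool labels sharing one exchange-rate parameter.
#' @slot crossPairs list of length-2 character vectors (donor, acceptor).
#' @slot glucoseMolar numeric, glucose concentration (mol/L).
#' @slot waterProtonMolar numeric, water proton concentration (mol/L).
#'
#' @seealso [buildModel()], [assembleExchangeMatrix()], [parameterBounds()]
#' @export
setClass("ExchangeModelSpec",
  representation(
    variant = "character",
    pools = "data.frame",
    rateGroups = "list",
    crossPairs = "list",
    glucoseMolar = "numeric",
    waterProtonMolar = "numeric"
  )
)

setValidity("ExchangeModelSpec", function(object) {
  p <- object@pools
  msg <- character()
  if (!all(c("label", "anomer", "fraction") %in% names(p)))
    msg <- c(msg, "pools must have columns label, anomer, fraction")
  else {
    if (any(p$fraction <= 0)) msg <- c(msg, "all pool fractions must be > 0")
    if (abs(sum(p$fraction) - 1) > 1e-12)
      msg <- c(msg, "pool fractions must sum to 1 within 1e-12")
    if (sum(p$anomer == "water") != 1)
      msg <- c(msg, "exactly one water pool required")
    nonWater <- p$label[p$anomer != "water"]
    grouped <- unlist(object@rateGroups, use.names = FALSE)
    if (!setequal(grouped, nonWater) || anyDuplicated(grouped))
      msg <- c(msg, "every non-water pool must belong to exactly one rate group")
  }
  if (length(msg)) msg else TRUE
})

#' Parameters of the forward spectral model
#'
#' Holds everything the forward simulation needs beyond the model topology:
#' chemical-shift offsets from water for each non-water pool (ppm, downfield
#' positive), one exchange rate per rate group (1/s; the rate at which a
#' proton leaves its hydroxyl site), optional hydroxyl-hydroxyl cross rates,
#' the three coefficients of the quadratic baseline polynomial and the
#' integral scale factor (constrained to 0.8-1.2) that together make up the
#' four baseline fitting parameters.
#'
#' @slot deltas named numeric, ppm offset from water per non-water pool.
#' @slot rates named numeric, exchange rate (1/s) per rate group.
#' @slot crossRates numeric, cross-exchange rates (1/s), one per cross pair.
#' @slot baselinePoly numeric length 3: quadratic baseline coefficients
#'   (constant, linear, quadratic in ppm offset).
#' @slot integralScale numeric in [0.8, 1.2].
#' @export
setClass("ModelParameters",
  representation(
    deltas = "numeric",
    rates = "numeric",
    crossRates = "numeric",
    baselinePoly = "numeric",
    integralScale = "numeric"
  ),
  prototype(crossRates = numeric(0), baselinePoly = c(0, 0, 0),
            integralScale = 1)
)

setValidity("ModelParameters", function(object) {
  msg <- character()
  if (any(object@rates < 0)) msg <- c(msg, "rates must be >= 0")
  if (length(object@crossRates) && any(object@crossRates < 0))
    msg <- c(msg, "crossRates must be >= 0")
  if (length(object@baselinePoly) != 3)
    msg <- c(msg, "baselinePoly must have length 3")
  if (object@integralScale < 0.8 || object@integralScale > 1.2)
    msg <- c(msg, "integralScale must lie in [0.8, 1.2]")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Spectrum classes
## ---------------------------------------------------------------------------

#' Acquisition and processing settings
#'
#' Mirrors a plain pulse-acquire 1D proton acquisition: Larmor frequency,
#' sweep width, number of complex time-domain points, exponential line
#' broadening, and the downfield edge (as ppm offset from water) of the
#' hydroxyl extraction window.
#'
#' @slot spectrometerFreqMHz numeric, 1H Larmor frequency in MHz.
#' @slot sweepWidthPpm numeric, spectral width in ppm.
#' @slot td integer, complex time-domain points.
#' @slot lbHz numeric, exponential line broadening in Hz.
#' @slot extractionUpperPpm numeric, downfield edge of the hydroxyl window
#'   as offset from water (ppm).
#' @slot temperatureK numeric label (not used by the simulation itself).
#' @export
setClass("AcquisitionConfig",
  representation(
    spectrometerFreqMHz = "numeric",
    sweepWidthPpm = "numeric",
    td = "integer",
    lbHz = "numeric",
    extractionUpperPpm = "numeric",
    temperatureK = "numeric"
  )
)

setValidity("AcquisitionConfig", function(object) {
  msg <- character()
  if (object@td < 2) msg <- c(msg, "td must be >= 2")
  if (object@sweepWidthPpm <= 0) msg <- c(msg, "sweepWidthPpm must be > 0")
  if (object@spectrometerFreqMHz <= 0)
    msg <- c(msg, "spectrometerFreqMHz must be > 0")
  if (length(msg)) msg else TRUE
})

#' One-dimensional real spectrum
#'
#' A processed 1D spectrum on a uniform ppm grid of offsets from water
#' (water at 0, downfield positive, ascending axis).
#'
#' @slot axisPpm numeric, uniform strictly increasing ppm axis.
#' @slot intensity numeric, real intensities (same length as axis).
#' @slot metadata list, acquisition settings and provenance.
#' @export
setClass("Spectrum",
  representation(
    axisPpm = "numeric",
    intensity = "numeric",
    metadata = "list"
  ),
  prototype(metadata = list())
)

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@axisPpm) != length(object@intensity))
    msg <- c(msg, "axis and intensity lengths differ")
  d <- diff(object@axisPpm)
  if (length(d)) {
    if (any(d <= 0)) msg <- c(msg, "axis must be strictly increasing")
    else if (max(d) - min(d) > 1e-6 * stats::median(d))
      msg <- c(msg, "axis must be uniform")
  }
  if (length(msg)) msg else TRUE
})

#' Extracted, normalized hydroxyl window of a spectrum
#'
#' The section of a spectrum between the first minimum downfield of the water
#' line and the configured upper edge, normalized to (integralScale times)
#' unit trapezoid integral.
#'
#' @slot indexRange integer length 2, index range into the parent spectrum.
#' @export
setClass("SpectrumSegment",
  contains = "Spectrum",
  representation(indexRange = "integer")
)

## ---------------------------------------------------------------------------
## MCMC classes
## ---------------------------------------------------------------------------

#' Settings of the adaptive Metropolis sampler
#'
#' @slot nAdapt1,nAdapt2 integer, lengths (in sweeps) of the two step-size
#'   adaptation phases.
#' @slot nProduction integer, production sweeps (default 20000).
#' @slot targetAcceptance numeric in (0,1), adaptation target (default 0.5).
#' @slot adaptWindow integer, sweeps between step-size updates.
#' @slot tInv numeric, inverse MCMC temperature scaling the error.
#' @slot annealStart numeric, relative inverse temperature at the start of
#'   the first adaptation phase (geometric ramp up to `tInv`; 1 disables
#'   annealing).
#' @slot seed integer RNG seed.
#' @slot ySem numeric noise scale, or NA to estimate it from the signal-free
#'   downfield end of the data segment.
#' @export
setClass("MCMCConfig",
  representation(
    nAdapt1 = "integer",
    nAdapt2 = "integer",
    nProduction = "integer",
    targetAcceptance = "numeric",
    adaptWindow = "integer",
    tInv = "numeric",
    annealStart = "numeric",
    seed = "integer",
    ySem = "numeric"
  ),
  prototype(annealStart = 1e-3)
)

setValidity("MCMCConfig", function(object) {
  msg <- character()
  if (object@nProduction < 1) msg <- c(msg, "nProduction must be >= 1")
  if (object@targetAcceptance <= 0 || object@targetAcceptance >= 1)
    msg <- c(msg, "targetAcceptance must be in (0,1)")
  if (length(msg)) msg else TRUE
})

#' Production samples of an MCMC run
#'
#' @slot samples numeric matrix, nProduction x nParams.
#' @slot errors numeric, per-sweep error E.
#' @slot acceptance numeric, per-parameter acceptance fraction (production).
#' @slot stepSizes numeric, final per-parameter step sizes.
#' @slot bounds numeric matrix 2 x nParams (lower; upper).
#' @slot config the `MCMCConfig` used.
#' @export
setClass("MCMCTrace",
  representation(
    samples = "matrix",
    errors = "numeric",
    acceptance = "numeric",
    stepSizes = "numeric",
    bounds = "matrix",
    config = "MCMCConfig"
  )
)

#' Posterior summary with symmetrized 95% intervals
#'
#' @slot best numeric, parameter vector at the minimum error.
#' @slot bestError numeric, the minimum error.
#' @slot ci95Half numeric, symmetrized half-widths: half the 2.5-97.5%
#'   interquantile range.
#' @slot quantiles numeric matrix 3 x nParams (2.5%, 50%, 97.5%).
#' @export
setClass("PosteriorSummary",
  representation(
    best = "numeric",
    bestError = "numeric",
    ci95Half = "numeric",
    quantiles = "matrix"
  )
)

setValidity("PosteriorSummary", function(object) {
  if (any(object@ci95Half < 0)) "ci95Half must be >= 0" else TRUE
})

## ---------------------------------------------------------------------------
## Eyring classes
## ---------------------------------------------------------------------------

#' Eyring transition-state parameters for one exchange site
#'
#' Parameterizes k(T) = kappa * (kB*T/h) * exp(-dG/(R*T)). The covariance
#' slot stores the 2x2 covariance of (slope, intercept) of the linearized fit
#' y = ln(k/T) = a*(1/T) + b, from which first-order uncertainties of rates
#' at any temperature are propagated.
#'
#' @slot kappa numeric, transmission coefficient (dimensionless, > 0).
#' @slot dG numeric, Gibbs activation energy (J/mol, > 0).
#' @slot sigmaKappa,sigmaDG numeric, 1-sigma uncertainties.
#' @slot cov numeric 2x2 covariance of (slope a, intercept b).
#' @slot tempRangeK numeric, temperature range of the underlying data
#'   (length 0 if unknown).
#' @slot reliableExtrapolation logical; FALSE flags parameter sets (such as
#'   sparse two-point series) whose rates should not be trusted far outside
#'   `tempRangeK`.
#' @export
setClass("EyringParams",
  representation(
    kappa = "numeric",
    dG = "numeric",
    sigmaKappa = "numeric",
    sigmaDG = "numeric",
    cov = "matrix",
    tempRangeK = "numeric",
    reliableExtrapolation = "logical"
  ),
  prototype(sigmaKappa = 0, sigmaDG = 0, cov = matrix(0, 2, 2),
            tempRangeK = numeric(0), reliableExtrapolation = TRUE)
)

setValidity("EyringParams", function(object) {
  msg <- character()
  if (object@kappa <= 0) msg <- c(msg, "kappa must be > 0")
  if (object@dG <= 0) msg <- c(msg, "dG must be > 0")
  if (!all(dim(object@cov) == c(2, 2))) msg <- c(msg, "cov must be 2x2")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Virtual-experiment classes
## ---------------------------------------------------------------------------

#' CPMG echo-train settings
#'
#' @slot nEchoes integer, number of echo periods.
#' @slot halfEchoS numeric, half-echo delay tau in seconds (Bruker d20).
#' @slot pulseMode character, `"ideal"` (instantaneous rotations) or
#'   `"rectangular"` (finite rectangular pulses).
#' @slot pulseB1Hz numeric, B1 amplitude in Hz for rectangular pulses.
#' @slot spectrometerFreqMHz numeric, 1H Larmor frequency in MHz.
#' @export
setClass("CPMGSpec",
  representation(
    nEchoes = "integer",
    halfEchoS = "numeric",
    pulseMode = "character",
    pulseB1Hz = "numeric",
    spectrometerFreqMHz = "numeric"
  )
)

setValidity("CPMGSpec", function(object) {
  msg <- character()
  if (object@nEchoes < 1) msg <- c(msg, "nEchoes must be >= 1")
  if (object@halfEchoS <= 0) msg <- c(msg, "halfEchoS must be > 0")
  if (!object@pulseMode %in% c("ideal", "rectangular"))
    msg <- c(msg, "pulseMode must be 'ideal' or 'rectangular'")
  if (length(msg)) msg else TRUE
})

#' Exchange relaxivity of a dilute solute
#'
#' @slot fieldLabel character (e.g. "11.7 T").
#' @slot spectrometerFreqMHz numeric.
#' @slot R2ex numeric, exchange-induced transverse relaxation rate (1/s).
#' @slot glucoseMM numeric, glucose concentration in mM.
#' @slot relaxivity numeric, R2ex / glucoseMM (1/s/mM).
#' @export
setClass("RelaxivityResult",
  representation(
    fieldLabel = "character",
    spectrometerFreqMHz = "numeric",
    R2ex = "numeric",
    glucoseMM = "numeric",
    relaxivity = "numeric"
  )
)

setValidity("RelaxivityResult", function(object) {
  ok <- abs(object@relaxivity - object@R2ex / object@glucoseMM) <=
    1e-12 * max(1, abs(object@relaxivity))
  if (!ok) "relaxivity must equal R2ex / glucoseMM" else TRUE
})
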