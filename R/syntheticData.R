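#' @include AllClasses.R spectrumSim.R eyring.R
NULL

#' Configuration of a synthetic temperature series
#'
#' Defines the ground truth for a simulated measurement series emulating a
#' 1 M glucose / 1x PBS sample: one Eyring parameter set per rate group
#' (the truth the pipeline should recover), per-pool chemical shifts with an
#' optional linear temperature drift, the list of temperatures, acquisition
#' settings, the peak signal-to-noise ratio of the hydroxyl region, and the
#' true baseline polynomial.
#'
#' @param variant model variant (default `"restricted"`).
#' @param eyringTruth named list of [EyringParams-class], one per rate group.
#' @param deltaTruth named ppm offsets per non-water pool.
#' @param deltaDriftPerK linear shift drift, ppm/K (default 0; the real
#'   temperature dependence of the shifts is modest).
#' @param temperaturesK temperatures of the series (within 260-320 K).
#' @param acq an [AcquisitionConfig-class].
#' @param snr peak-signal to noise-SD ratio of the hydroxyl region (> 0).
#' @param baselinePolyTruth true baseline polynomial (length 3).
#' @param glucoseMolar,waterProtonMolar concentrations, mol/L.
#' @param seed RNG seed.
#' @return a validated list of class `"seriesConfig"`.
#' @export
#' @examples
#' cfg <- seriesConfig(temperaturesK = c(270, 275), snr = 200, seed = 1)
seriesConfig <- function(variant = "restricted",
                         eyringTruth = glucoseEyringTable(6.21),
                         deltaTruth = glucoseShiftTable(6.21),
                         deltaDriftPerK = 0,
                         temperaturesK = seq(270, 295, by = 5),
                         acq = acquisitionConfig(),
                         snr = 200,
                         baselinePolyTruth = c(0, 0, 0),
                         glucoseMolar = 1, waterProtonMolar = 110.7,
                         seed = 1L) {
  stopifnot(snr > 0)
  if (length(temperaturesK) &&
      (any(temperaturesK < 260) || any(temperaturesK > 320)))
    stop("temperatures must lie within [260, 320] K")
  spec <- buildModel(variant, glucoseMolar, waterProtonMolar)
  if (!setequal(names(eyringTruth), names(spec@rateGroups)))
    stop("eyringTruth must name every rate group of the variant")
  structure(list(variant = variant, spec = spec, eyringTruth = eyringTruth,
                 deltaTruth = deltaTruth, deltaDriftPerK = deltaDriftPerK,
                 temperaturesK = temperaturesK, acq = acq, snr = snr,
                 baselinePolyTruth = baselinePolyTruth,
                 seed = as.integer(seed)),
            class = "seriesConfig")
}

#' Generate one noisy synthetic spectrum
#'
#' Computes the noiseless processed spectrum of the model on the full grid,
#' adds the truth baseline polynomial (in ppm offset) and i.i.d. Gaussian
#' noise with standard deviation (max hydroxyl-region intensity) / snr.
#' Reproducible given the seed.
#'
#' @param params true [ModelParameters-class].
#' @param spec an [ExchangeModelSpec-class].
#' @param acq an [AcquisitionConfig-class].
#' @param snr peak-signal to noise-SD ratio (> 0).
#' @param seed RNG seed.
#' @return a [Spectrum-class] with noise and baseline applied.
#' @export
generateSpectrum <- function(params, spec, acq, snr, seed = 1L) {
  stopifnot(snr > 0)
  clean <- simulateSpectrum(params, spec, acq)
  ax <- clean@axisPpm
  ohRegion <- ax >= 0.3 & ax <= acq@extractionUpperPpm
  noiseSD <- max(clean@intensity[ohRegion]) / snr
  base <- params@baselinePoly[1] + params@baselinePoly[2] * ax +
    params@baselinePoly[3] * ax^2
  set.seed(seed)
  new("Spectrum", axisPpm = ax,
      intensity = clean@intensity + base + stats::rnorm(length(ax), 0, noiseSD),
      metadata = c(clean@metadata, list(snr = snr, seed = seed,
                                        noiseSD = noiseSD)))
}

#' Generate a synthetic temperature series with its ground-truth manifest
#'
#' One spectrum per temperature, with exchange rates evaluated from the
#' truth Eyring parameters at each temperature and (optionally drifted)
#' chemical shifts. The manifest records the exact per-temperature
#' parameters, so recovery can be checked against the truth.
#'
#' @param config a [seriesConfig()] list.
#' @return list with elements `spectra` (list of [Spectrum-class]),
#'   `manifest` (per-temperature true parameters + config echo) and
#'   `spec` (the model).
#' @export
generateTemperatureSeries <- function(config) {
  stopifnot(inherits(config, "seriesConfig"))
  spec <- config$spec
  temps <- config$temperaturesK
  refT <- if (length(temps)) temps[1] else NA_real_
  spectra <- vector("list", length(temps))
  paramsList <- vector("list", length(temps))
  names(spectra) <- names(paramsList) <- sprintf("%gK", temps)
  for (i in seq_along(temps)) {
    T <- temps[i]
    rates <- vapply(names(spec@rateGroups), function(g)
      unname(eyringRate(config$eyringTruth[[g]], T)$k), numeric(1))
    deltas <- config$deltaTruth + config$deltaDriftPerK * (T - refT)
    p <- new("ModelParameters", deltas = deltas, rates = rates,
             crossRates = rep(0, length(spec@crossPairs)),
             baselinePoly = config$baselinePolyTruth, integralScale = 1)
    paramsList[[i]] <- p
    acqT <- config$acq
    acqT@temperatureK <- T
    spectra[[i]] <- generateSpectrum(p, spec, acqT, config$snr,
                                     seed = config$seed + i)
  }
  list(spectra = spectra,
       manifest = list(temperaturesK = temps, trueParameters = paramsList,
                       eyringTruth = config$eyringTruth, seed = config$seed,
                       config = config),
       spec = spec)
}
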