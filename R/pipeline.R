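#' @include AllClasses.R spectrumSim.R mcmc.R eyring.R
NULL

#' Read a two-column spectrum table
#'
#' Accepts CSV or whitespace-separated tables of (ppm offset, intensity)
#' with `#` comment lines. Rows are sorted by axis (with a warning when
#' shuffled); non-uniform grids are resampled onto a uniform grid with a
#' warning.
#'
#' @param path file path.
#' @return a [Spectrum-class].
#' @export
readSpectrumTable <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("no data rows in ", path)
  sep <- if (grepl(",", lines[1])) "," else ""
  df <- tryCatch(
    utils::read.table(text = lines, sep = sep, header = FALSE,
                      colClasses = "numeric"),
    error = function(e) stop("non-numeric rows in ", path, ": ",
                             conditionMessage(e)))
  if (ncol(df) < 2) stop("expected two columns in ", path)
  ax <- df[[1]]
  y <- df[[2]]
  bad <- which(!is.finite(ax) | !is.finite(y))
  if (length(bad))
    stop("non-finite values in ", path, " at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (length(ax) < 16) stop("fewer than 16 points in ", path)
  if (is.unsorted(ax)) {
    warning("axis not sorted in ", path, "; sorting rows")
    o <- order(ax)
    ax <- ax[o]
    y <- y[o]
  }
  d <- diff(ax)
  if (max(d) - min(d) > 1e-6 * stats::median(d)) {
    warning("non-uniform grid in ", path, "; resampling to a uniform grid")
    grid <- seq(min(ax), max(ax), length.out = length(ax))
    y <- stats::approx(ax, y, xout = grid)$y
    ax <- grid
  }
  new("Spectrum", axisPpm = ax, intensity = y,
      metadata = list(source = path))
}

#' Write a spectrum as a two-column CSV (with metadata comments)
#'
#' Values are written with full double precision, so a write/read round
#' trip is lossless.
#'
#' @param spectrum a [Spectrum-class].
#' @param path output path.
#' @param sidecar optional path for a JSON metadata sidecar.
#' @return invisibly, `path`.
#' @export
writeSpectrumTable <- function(spectrum, path, sidecar = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# ppm_offset,intensity", con)
  writeLines(paste(format(spectrum@axisPpm, digits = 17, trim = TRUE),
                   format(spectrum@intensity, digits = 17, trim = TRUE),
                   sep = ","), con)
  if (!is.null(sidecar)) {
    meta <- spectrum@metadata
    meta <- meta[!vapply(meta, is, logical(1), "AcquisitionConfig")]
    jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

## map a flat parameter vector (ordered as parameterBounds rows) back to a
## ModelParameters object
.vectorToParams <- function(par, spec, boundsTable) {
  type <- boundsTable$type
  nonWater <- spec@pools$label[spec@pools$anomer != "water"]
  deltas <- stats::setNames(par[type == "delta"], nonWater)
  rates <- stats::setNames(par[type == "rate"], names(spec@rateGroups))
  new("ModelParameters", deltas = deltas, rates = rates,
      crossRates = par[type == "cross"],
      baselinePoly = par[type == "baseline"],
      integralScale = par[type == "scale"])
}

.paramsToVector <- function(params, boundsTable) {
  c(params@deltas, params@rates, params@crossRates, params@baselinePoly,
    params@integralScale)
}

#' Fit one spectrum by MCMC
#'
#' Extracts and normalizes the hydroxyl window of the measured spectrum,
#' builds a forward closure on exactly that window, and runs the adaptive
#' Metropolis sampler over the bounded parameter box.
#'
#' @param spectrum a full-grid [Spectrum-class].
#' @param spec an [ExchangeModelSpec-class].
#' @param acq an [AcquisitionConfig-class].
#' @param bounds bounds table from [parameterBounds()].
#' @param config an [MCMCConfig-class].
#' @param logRates sample the exchange rates (and cross rates) on a log10
#'   scale (default TRUE). Rates are scale parameters: log sampling keeps
#'   the flat coalescence plateau small in proposal space and spreads
#'   initialization over decades. A linear rate lower bound of 0 becomes
#'   0.05 1/s on the log scale (no measurable exchange). The returned
#'   trace, intervals and best fit are always in linear units (quantiles
#'   are equivariant under the monotone back-transform).
#' @param optimStart initialize the chain at a preliminary bounded
#'   Levenberg-Marquardt least-squares fit (default TRUE). The optimizer
#'   runs from the centre of the bounds box plus `nStarts - 1` random
#'   starts and the best solution seeds the sampler, whose annealed
#'   burn-in is then skipped; the chain's job reduces to measuring the
#'   posterior around the optimum. With FALSE the chain starts at a random
#'   position and relies on the annealed burn-in, which needs much longer
#'   runs on heavily overlapped spectra.
#' @param nStarts number of Levenberg-Marquardt starts (>= 1).
#' @return list with `trace` ([MCMCTrace-class]), `summary`
#'   ([PosteriorSummary-class]), `bestParams` ([ModelParameters-class]),
#'   `dataSegment` and `indexRange`.
#' @export
fitSpectrum <- function(spectrum, spec, acq, bounds, config,
                        logRates = TRUE, optimStart = TRUE, nStarts = 3) {
  idx <- .locateSegment(spectrum, acq)
  dataSeg <- applyBaselineAndExtract(spectrum, c(0, 0, 0), 1, acq,
                                     indexRange = idx)
  omegaScale <- 2 * pi * acq@spectrometerFreqMHz
  f <- spec@pools$fraction
  type <- bounds$type
  iDelta <- which(type == "delta")
  iRate <- which(type == "rate")
  iCross <- which(type == "cross")
  iBase <- which(type == "baseline")
  iScale <- which(type == "scale")
  labels <- spec@pools$label
  nonWater <- which(spec@pools$anomer != "water")
  iw <- which(spec@pools$anomer == "water")
  n <- length(labels)
  ## pool index -> rate parameter index
  rateOfPool <- integer(n)
  for (g in seq_along(spec@rateGroups))
    rateOfPool[match(spec@rateGroups[[g]], labels)] <- g
  crossIdx <- lapply(spec@crossPairs, function(pr) match(pr, labels))
  segAxis <- .fullAxis(acq)[idx[1]:idx[2]]
  dwell <- .dwell(acq)
  dppm <- .dppm(acq)

  iLog <- if (logRates) c(iRate, iCross) else integer(0)
  mcBounds <- bounds
  if (length(iLog)) {
    mcBounds$lower[iLog] <- log10(pmax(bounds$lower[iLog], 0.05))
    mcBounds$upper[iLog] <- log10(bounds$upper[iLog])
  }

  forward <- function(par) {
    if (length(iLog)) par[iLog] <- 10^par[iLog]
    omega <- numeric(n)
    omega[nonWater] <- par[iDelta] * omegaScale
    K <- matrix(0, n, n)
    kPool <- par[iRate][rateOfPool[nonWater]]
    K[iw, nonWater] <- kPool
    K[cbind(nonWater, iw)] <- kPool * f[nonWater] / f[iw]
    for (m in seq_along(crossIdx)) {
      dI <- crossIdx[[m]][1]; aI <- crossIdx[[m]][2]
      kc <- par[iCross][m]
      K[aI, dI] <- K[aI, dI] + kc
      K[dI, aI] <- K[dI, aI] + kc * f[dI] / f[aI]
    }
    diag(K) <- diag(K) - colSums(K)
    .forwardSegmentCpp(omega, K, f, acq@td, dwell, acq@lbHz, dppm,
                       idx[1] - 1L, idx[2] - 1L, segAxis, par[iBase],
                       par[iScale])
  }

  ## coordinated moves along the directions coupled by the segment
  ## normalization: all rates together, all shifts together
  joint <- list()
  if (length(iRate) > 1) joint <- c(joint, list(iRate))
  if (length(iDelta) > 1) joint <- c(joint, list(iDelta))

  init <- NULL
  initStep <- NULL
  if (optimStart) {
    ySemHat <- if (is.na(config@ySem)) estimateYSem(dataSeg) else config@ySem
    resFun <- function(par) {
      m <- tryCatch(forward(par), error = function(e) NULL)
      if (is.null(m)) return(rep(1e6, length(segAxis)))
      (dataSeg@intensity - m) / ySemHat
    }
    set.seed(config@seed)
    best <- NULL
    for (s in seq_len(max(1, nStarts))) {
      p0 <- if (s == 1) (mcBounds$lower + mcBounds$upper) / 2
            else mcBounds$lower +
              stats::runif(nrow(mcBounds)) * (mcBounds$upper - mcBounds$lower)
      o <- tryCatch(
        minpack.lm::nls.lm(p0, lower = mcBounds$lower,
                           upper = mcBounds$upper, fn = resFun,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$deviance < best$deviance))
        best <- o
    }
    if (!is.null(best)) {
      init <- pmin(pmax(best$par, mcBounds$lower), mcBounds$upper)
      config@annealStart <- 1   # burn-in from the optimum, no annealing
      ## seed step sizes from the Gauss-Newton curvature: the conditional
      ## posterior width of parameter i is 1/sqrt(2 tInv (J'J)_ii)
      h <- diag(best$hessian)
      initStep <- ifelse(h > 0, 2.4 / sqrt(2 * config@tInv * h), NA_real_)
    }
  }

  trace <- runMCMC(forward, dataSeg, mcBounds, config, jointGroups = joint,
                   init = init, initStep = initStep)
  if (length(iLog)) {
    trace@samples[, iLog] <- 10^trace@samples[, iLog]
    trace@bounds[, iLog] <- 10^trace@bounds[, iLog]
  }
  summ <- summarizePosterior(trace)
  list(trace = trace, summary = summ,
       bestParams = .vectorToParams(summ@best, spec, bounds),
       dataSegment = dataSeg, indexRange = idx)
}

#' Run configuration for a temperature-series analysis
#'
#' @param spectra list of [Spectrum-class] objects or file paths.
#' @param temperaturesK one temperature per spectrum, strictly increasing.
#' @param variant model variant.
#' @param mcmc an [MCMCConfig-class] (per-spectrum seeds are derived from
#'   its seed).
#' @param acq an [AcquisitionConfig-class].
#' @param priorShifts optional named shifts used to fix the assignment for
#'   the coldest spectrum too; when NULL the coldest spectrum is fitted
#'   with the broad initial bounds and its posterior fixes the assignment
#'   for the warmer ones.
#' @param shiftWindow half-width (ppm) of the assignment-fixed windows.
#' @param rateUpper upper edge of the exchange-rate windows (1/s); see
#'   [parameterBounds()].
#' @param glucoseMolar,waterProtonMolar concentrations, mol/L.
#' @param outputDir optional directory for CSV/JSON artefacts.
#' @return list of class `"runConfig"`.
#' @export
runConfig <- function(spectra, temperaturesK, variant = "restricted",
                      mcmc = mcmcConfig(), acq = acquisitionConfig(),
                      priorShifts = NULL, shiftWindow = 0.12,
                      rateUpper = 2e4, glucoseMolar = 1,
                      waterProtonMolar = 110.7, outputDir = NULL) {
  if (length(spectra) != length(temperaturesK))
    stop("need exactly one temperature per spectrum")
  if (is.unsorted(temperaturesK, strictly = TRUE))
    stop("temperatures must be strictly increasing")
  structure(list(spectra = spectra, temperaturesK = temperaturesK,
                 variant = variant, mcmc = mcmc, acq = acq,
                 priorShifts = priorShifts, shiftWindow = shiftWindow,
                 rateUpper = rateUpper, glucoseMolar = glucoseMolar,
                 waterProtonMolar = waterProtonMolar,
                 outputDir = outputDir),
            class = "runConfig")
}

## cheap polynomial rolling hash of a serialized object, for provenance
## stamping of output tables
.configHash <- function(x) {
  bytes <- as.integer(serialize(x, NULL))
  h <- 17
  for (b in bytes[seq(1, length(bytes), by = 7)])
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Full temperature-series pipeline
#'
#' Stage 1 fits every spectrum by MCMC, coldest first; the coldest fit uses
#' the broad initial bounds (unless `priorShifts` fixes the assignment) and
#' its posterior chemical shifts centre the narrowed, non-overlapping
#' assignment-fixed windows used for the warmer spectra. Stage 2 fits the
#' Eyring temperature law per rate group through the fitted rates and their
#' credible intervals. Stage 3 tabulates rates over 260-310 K in 0.25 K
#' steps. All stages are deterministic given the configured seeds.
#'
#' @param config a [runConfig()] list.
#' @return list with `fits` (per-temperature [fitSpectrum()] results),
#'   `rates` (data.frame of fitted rates per group and temperature),
#'   `eyring` (named list of [EyringParams-class]), `rateTables` (named
#'   list of data.frames) and `provenance`.
#' @export
fitSeries <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  spectra <- lapply(config$spectra, function(s)
    if (is.character(s)) readSpectrumTable(s) else s)
  temps <- config$temperaturesK
  spec <- buildModel(config$variant, config$glucoseMolar,
                     config$waterProtonMolar)
  nT <- length(temps)

  fits <- vector("list", nT)
  names(fits) <- sprintf("%gK", temps)
  for (i in seq_len(nT)) {
    boundsI <- if (i == 1 && is.null(config$priorShifts)) {
      parameterBounds(spec, "initial", rateUpper = config$rateUpper)
    } else {
      priors <- if (i == 1) config$priorShifts
                else bestFit(fits[[1]]$summary)[
                  grep("^delta\\.", names(bestFit(fits[[1]]$summary)))]
      names(priors) <- sub("^delta\\.", "", names(priors))
      parameterBounds(spec, "assignment_fixed", priors = priors,
                      shiftWindow = config$shiftWindow,
                      rateUpper = config$rateUpper)
    }
    cfg <- config$mcmc
    cfg@seed <- config$mcmc@seed + i - 1L
    acqI <- config$acq
    acqI@temperatureK <- temps[i]
    fits[[i]] <- fitSpectrum(spectra[[i]], spec, acqI, boundsI, cfg)
  }

  groups <- names(spec@rateGroups)
  rateRows <- do.call(rbind, lapply(seq_len(nT), function(i) {
    s <- fits[[i]]$summary
    nm <- paste0("rate.", groups)
    data.frame(T_K = temps[i], group = groups,
               k = unname(bestFit(s)[nm]),
               ci95 = unname(ci95Half(s)[nm]))
  }))

  eyring <- rateTables <- NULL
  if (nT >= 2) {
    eyring <- lapply(groups, function(g) {
      pts <- rateRows[rateRows$group == g, ]
      fitEyringLinearized(data.frame(T_K = pts$T_K, k = pts$k,
                                     ci95 = pts$ci95))
    })
    names(eyring) <- groups
    rateTables <- lapply(eyring, tabulateRates)
  } else {
    warning("insufficient temperatures for the Eyring stage (need >= 2)")
  }

  prov <- list(configHash = .configHash(config[c("temperaturesK", "variant",
                                                 "shiftWindow")]),
               seed = config$mcmc@seed, nProduction = config$mcmc@nProduction,
               temperaturesK = temps, variant = config$variant)

  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(rateRows,
                     file.path(config$outputDir, "fitted_rates.csv"),
                     row.names = FALSE)
    if (!is.null(eyring)) {
      eyTab <- data.frame(group = groups,
                          kappa = vapply(eyring, slot, numeric(1), "kappa"),
                          sigmaKappa = vapply(eyring, slot, numeric(1),
                                              "sigmaKappa"),
                          dG = vapply(eyring, slot, numeric(1), "dG"),
                          sigmaDG = vapply(eyring, slot, numeric(1),
                                           "sigmaDG"))
      utils::write.csv(eyTab,
                       file.path(config$outputDir, "eyring_parameters.csv"),
                       row.names = FALSE)
      for (g in groups)
        utils::write.csv(rateTables[[g]],
                         file.path(config$outputDir,
                                   paste0("rates_260_310_", g, ".csv")),
                         row.names = FALSE)
    }
    jsonlite::write_json(prov,
                         file.path(config$outputDir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
    for (i in seq_len(nT))
      writeTrace(fits[[i]]$trace, fits[[i]]$summary, config$outputDir,
                 prefix = sprintf("fit_%gK", temps[i]))
  }

  list(fits = fits, rates = rateRows, eyring = eyring,
       rateTables = rateTables, spec = spec, provenance = prov)
}
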