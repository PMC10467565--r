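#' @include AllClasses.R
NULL

#' MCMC sampler settings constructor
#'
#' @param nAdapt1,nAdapt2 sweeps in the two step-size adaptation phases.
#' @param nProduction production sweeps (one sweep = one single-parameter
#'   Metropolis update of every parameter in turn).
#' @param targetAcceptance target per-parameter acceptance rate during
#'   adaptation (0.5: the sampling is most efficient near 50%).
#' @param adaptWindow sweeps between multiplicative step-size updates.
#' @param tInv inverse MCMC temperature scaling the error. With
#'   `tInv = 0.5` and `ySem` equal to the 1-sigma noise, exp(-E) is exactly
#'   the Gaussian likelihood, so the sampled posterior (and hence the 95%
#'   intervals) is calibrated; the default 1 samples a sharper surface.
#' @param annealStart relative inverse temperature at the start of the
#'   first adaptation phase. The first phase ramps the inverse temperature
#'   geometrically from `annealStart * tInv` up to `tInv` (simulated
#'   annealing burn-in), which lets the chain cross the barriers between
#'   the many local minima of overlapped spectra before the step sizes are
#'   tuned at the final temperature. Set to 1 to disable.
#' @param seed RNG seed (the run is fully reproducible given the seed).
#' @param ySem noise scale of the data; `NA` (default) estimates it as the
#'   standard deviation of the signal-free most-downfield 0.2 ppm of the
#'   data segment.
#' @return an [MCMCConfig-class].
#' @export
mcmcConfig <- function(nAdapt1 = 1000, nAdapt2 = 1000, nProduction = 20000,
                       targetAcceptance = 0.5, adaptWindow = 50, tInv = 1,
                       annealStart = 1e-3, seed = 1L, ySem = NA_real_) {
  new("MCMCConfig", nAdapt1 = as.integer(nAdapt1),
      nAdapt2 = as.integer(nAdapt2), nProduction = as.integer(nProduction),
      targetAcceptance = targetAcceptance,
      adaptWindow = as.integer(adaptWindow), tInv = tInv,
      annealStart = annealStart, seed = as.integer(seed),
      ySem = as.numeric(ySem))
}

#' Scaled sum-of-squares error between model and data segments
#'
#' E = tInv * sum(((data - model) / ySem)^2). With `ySem` equal to the
#' 1-sigma noise level and `tInv = 1`, exp(-E) is (up to a factor of 2 in
#' the exponent convention) the Gaussian likelihood sampled by the chain.
#'
#' @param model,data numeric vectors on identical grids (or
#'   [SpectrumSegment-class] objects).
#' @param ySem positive noise scale.
#' @param tInv inverse MCMC temperature.
#' @return scalar error E.
#' @export
#' @examples
#' errorFunction(c(1, 2), c(1, 2), ySem = 0.1)     # 0
errorFunction <- function(model, data, ySem, tInv = 1) {
  if (is(model, "SpectrumSegment")) model <- model@intensity
  if (is(data, "SpectrumSegment")) data <- data@intensity
  if (length(model) != length(data))
    stop("model and data segments are on different grids")
  if (!is.finite(ySem) || ySem <= 0) stop("ySem must be > 0")
  tInv * sum(((data - model) / ySem)^2)
}

## reflect a proposal back into [lo, hi] by mirroring at the crossed boundary
.reflect <- function(x, lo, hi) {
  if (hi <= lo) return(lo)
  width <- hi - lo
  for (dummy in 1:100) {
    if (x > hi) x <- 2 * hi - x
    else if (x < lo) x <- 2 * lo - x
    else return(x)
  }
  ## pathological step >> width: fold into range
  lo + (abs(x - lo) %% (2 * width)) %% width
}

#' Estimate the noise scale from the downfield end of a segment
#'
#' Standard deviation of the most-downfield `windowPpm` of the segment,
#' which is free of hydroxyl signal, after removing a linear trend.
#'
#' @param data numeric intensities or a [SpectrumSegment-class].
#' @param axis ppm axis (not needed when `data` is a segment).
#' @param windowPpm width of the tail window (ppm).
#' @return estimated 1-sigma noise level.
#' @export
estimateYSem <- function(data, axis = NULL, windowPpm = 0.2) {
  if (is(data, "SpectrumSegment")) {
    axis <- data@axisPpm
    data <- data@intensity
  }
  if (is.null(axis)) stop("axis required")
  sel <- axis >= (max(axis) - windowPpm)
  y <- data[sel]
  x <- axis[sel]
  r <- stats::residuals(stats::lm(y ~ x))
  stats::sd(r)
}

#' Adaptive Metropolis MCMC over a bounded parameter box
#'
#' Samples the density exp(-E) where E is the scaled sum-of-squares error of
#' the forward model against the data. One sweep perturbs each parameter in
#' turn by `runif(-1, 1) * k_i`; a proposal is accepted when the error
#' decreases, or with probability exp(-deltaE) otherwise. Proposals leaving
#' the bounded box are reflected at the crossed boundary. During the two
#' adaptation phases the per-parameter step sizes k_i are rescaled every
#' `adaptWindow` sweeps by exp(acceptance - target), bounded below by 1e-4
#' of the box width; they are frozen during production (preserving the
#' Markov property). The first adaptation phase anneals: the inverse
#' temperature ramps geometrically from `annealStart * tInv` to `tInv`,
#' letting the chain escape the local minima of heavily overlapped spectra;
#' the second phase and production run at the fixed final temperature.
#' Forward-model failures at a proposal reject the proposal and are counted
#' in the trace metadata.
#'
#' @param forward function mapping a parameter vector to a model vector on
#'   the data grid (or to a [SpectrumSegment-class]).
#' @param data numeric data vector or [SpectrumSegment-class].
#' @param bounds data.frame with columns `lower` and `upper` (one row per
#'   parameter, finite), e.g. from [parameterBounds()].
#' @param config an [MCMCConfig-class].
#' @param jointGroups optional list of integer index vectors. For each
#'   group, every sweep additionally proposes one coordinated move that
#'   adds the same scalar to all member parameters (a symmetric translation
#'   kernel, so the Metropolis rule is unchanged). Coordinated moves walk
#'   the correlated valleys that arise when all exchange rates must rescale
#'   together through the segment normalization, which single-coordinate
#'   steps only descend in tiny zig-zags.
#' @param init optional initial parameter vector (inside the bounds).
#'   When omitted the chain starts at a random position in the box.
#' @param initStep optional initial per-parameter step sizes (e.g. scaled
#'   conditional posterior widths from a preliminary fit); default is a
#'   tenth of the box width.
#' @return an [MCMCTrace-class] holding the production samples. Acceptance
#'   fractions and step sizes for coordinated moves are reported under
#'   `joint.<n>` names.
#' @export
#' @examples
#' ## sample a 1-D Gaussian density exp(-((x - 2) / 0.5)^2)
#' tr <- runMCMC(function(p) p, data = 2, bounds = data.frame(lower = -10,
#'   upper = 10), config = mcmcConfig(200, 200, 2000, ySem = 0.5, seed = 7))
#' sd(traceSamples(tr))   # about 0.5 / sqrt(2)
runMCMC <- function(forward, data, bounds, config, jointGroups = list(),
                    init = NULL, initStep = NULL) {
  if (is(data, "SpectrumSegment")) {
    if (is.na(config@ySem)) config@ySem <- estimateYSem(data)
    data <- data@intensity
  }
  if (is.na(config@ySem))
    stop("ySem is NA and data is not a SpectrumSegment; supply ySem")
  ySem <- config@ySem
  tInv <- config@tInv
  lo <- bounds$lower
  hi <- bounds$upper
  np <- length(lo)
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(hi <= lo))
    stop("bounds must be finite with upper > lower")
  pn <- if (!is.null(bounds$parameter)) bounds$parameter
        else paste0("p", seq_len(np))

  ## raw scaled sum of squares (inverse temperature applied at acceptance,
  ## so the annealed burn-in only rescales dE, never re-evaluates)
  evalE1 <- function(par) {
    m <- tryCatch(forward(par), error = function(e) NULL)
    if (is.null(m)) return(NULL)
    if (is(m, "SpectrumSegment")) m <- m@intensity
    E1 <- sum(((data - m) / ySem)^2)
    if (!is.finite(E1)) return(NULL)
    E1
  }

  set.seed(config@seed)
  if (!is.null(init)) {
    if (length(init) != np || any(init < lo) || any(init > hi))
      stop("init must lie inside the bounds")
    par <- as.numeric(init)
    E1 <- evalE1(par)
    if (is.null(E1)) stop("forward model failed at the supplied init")
  } else {
    par <- lo + stats::runif(np) * (hi - lo)
    E1 <- evalE1(par)
    tries <- 0
    while (is.null(E1) && tries < 100) {
      par <- lo + stats::runif(np) * (hi - lo)
      E1 <- evalE1(par)
      tries <- tries + 1
    }
    if (is.null(E1)) stop("forward model failed at 100 random initial points")
  }

  width <- hi - lo
  kFloor <- width * 1e-6
  k <- width / 10
  if (!is.null(initStep)) {
    ok <- is.finite(initStep) & initStep > 0
    k[ok] <- pmin(pmax(initStep[ok], kFloor[ok]), width[ok])
  }
  nFail <- 0
  nJ <- length(jointGroups)
  kJ <- vapply(jointGroups, function(idx) mean(width[idx]) / 10, numeric(1))
  kJFloor <- kJ * 1e-3
  kJCap <- kJ * 10

  runPhase <- function(nSweeps, adapt, record, beta) {
    acc <- numeric(np + nJ)
    tot <- numeric(np + nJ)
    accWin <- numeric(np + nJ)
    totWin <- numeric(np + nJ)
    nWin <- max(1, ceiling(nSweeps / config@adaptWindow))
    ## geometric inverse-temperature ramp across the adaptation windows
    betaOfWin <- if (length(beta) == 1) rep(beta, nWin)
                 else exp(seq(log(beta[1]), log(beta[2]), length.out = nWin))
    win <- 1
    samples <- if (record) matrix(NA_real_, nSweeps, np) else NULL
    errs <- if (record) numeric(nSweeps) else NULL
    for (s in seq_len(nSweeps)) {
      b <- betaOfWin[win]
      for (i in seq_len(np)) {
        prop <- par
        ## mixture kernel: mostly local steps, occasionally a box-wide
        ## uniform draw (symmetric, so the Metropolis rule is unchanged);
        ## the wide moves rescue parameters stranded on the tilted
        ## coalescence plateau where gradient-tuned steps crawl
        if (stats::runif(1) < 0.1) {
          prop[i] <- lo[i] + stats::runif(1) * width[i]
        } else {
          prop[i] <- .reflect(par[i] + stats::runif(1, -1, 1) * k[i],
                              lo[i], hi[i])
        }
        Ep <- evalE1(prop)
        totWin[i] <- totWin[i] + 1
        tot[i] <- tot[i] + 1
        if (is.null(Ep)) {
          nFail <<- nFail + 1
        } else {
          dE <- b * (Ep - E1)
          if (dE < 0 || stats::runif(1) < exp(-dE)) {
            par <<- prop
            E1 <<- Ep
            accWin[i] <- accWin[i] + 1
            acc[i] <- acc[i] + 1
          }
        }
      }
      for (g in seq_len(nJ)) {
        idx <- jointGroups[[g]]
        prop <- par
        shift <- stats::runif(1, -1, 1) * kJ[g]
        for (i in idx) prop[i] <- .reflect(par[i] + shift, lo[i], hi[i])
        Ep <- evalE1(prop)
        j <- np + g
        totWin[j] <- totWin[j] + 1
        tot[j] <- tot[j] + 1
        if (is.null(Ep)) {
          nFail <<- nFail + 1
        } else {
          dE <- b * (Ep - E1)
          if (dE < 0 || stats::runif(1) < exp(-dE)) {
            par <<- prop
            E1 <<- Ep
            accWin[j] <- accWin[j] + 1
            acc[j] <- acc[j] + 1
          }
        }
      }
      if (adapt && s %% config@adaptWindow == 0) {
        rate <- ifelse(totWin > 0, accWin / totWin, config@targetAcceptance)
        k <<- pmin(pmax(k * exp(rate[seq_len(np)] -
                                  config@targetAcceptance), kFloor), width)
        if (nJ > 0)
          kJ <<- pmin(pmax(kJ * exp(rate[np + seq_len(nJ)] -
                                      config@targetAcceptance), kJFloor),
                      kJCap)
        accWin[] <- 0
        totWin[] <- 0
        win <- min(win + 1, nWin)
      }
      if (record) {
        samples[s, ] <- par
        errs[s] <- config@tInv * E1
      }
    }
    list(samples = samples, errs = errs,
         acceptance = ifelse(tot > 0, acc / tot, NA_real_))
  }

  a0 <- if (length(config@annealStart)) config@annealStart else 1
  if (config@nAdapt1 > 0)
    runPhase(config@nAdapt1, adapt = TRUE, record = FALSE,
             beta = if (a0 < 1) tInv * c(a0, 1) else tInv)
  if (config@nAdapt2 > 0)
    runPhase(config@nAdapt2, adapt = TRUE, record = FALSE, beta = tInv)
  prod <- runPhase(config@nProduction, adapt = FALSE, record = TRUE,
                   beta = tInv)

  colnames(prod$samples) <- pn
  allNames <- c(pn, if (nJ > 0) paste0("joint.", seq_len(nJ)))
  tr <- new("MCMCTrace", samples = prod$samples, errors = prod$errs,
            acceptance = stats::setNames(prod$acceptance, allNames),
            stepSizes = stats::setNames(c(k, kJ), allNames),
            bounds = rbind(lower = lo, upper = hi), config = config)
  attr(tr, "nForwardFailures") <- nFail
  tr
}

#' Summarize a trace: best fit and symmetrized 95% intervals
#'
#' The best fit is the sample with the minimum error; the raw interval is
#' the (alpha/2, 1 - alpha/2) sample quantile pair and the symmetrized
#' half-width is half the interquantile range (the credible distributions
#' are close enough to symmetric for this to be a fair summary).
#'
#' @param trace an [MCMCTrace-class].
#' @param alpha credibility tail mass (default 0.05 for 95% intervals).
#' @return a [PosteriorSummary-class].
#' @export
summarizePosterior <- function(trace, alpha = 0.05) {
  s <- trace@samples
  if (!nrow(s)) stop("empty trace")
  ib <- which.min(trace@errors)
  q <- apply(s, 2, stats::quantile,
             probs = c(alpha / 2, 0.5, 1 - alpha / 2), names = FALSE)
  rownames(q) <- c("lower", "median", "upper")
  new("PosteriorSummary",
      best = stats::setNames(s[ib, ], colnames(s)),
      bestError = trace@errors[ib],
      ci95Half = stats::setNames((q[3, ] - q[1, ]) / 2, colnames(s)),
      quantiles = q)
}

#' Normalized autocorrelation of one parameter's production samples
#'
#' A convergence diagnostic: the chain is long enough when the
#' autocorrelation decays on a scale much shorter than the trajectory.
#'
#' @param trace an [MCMCTrace-class] (or a numeric vector).
#' @param paramIndex column of the trace to analyse.
#' @param maxLag largest lag (must be below the trace length).
#' @return numeric vector of autocorrelations at lags 0..maxLag (lag 0 = 1).
#' @export
stepAutocorrelation <- function(trace, paramIndex = 1, maxLag = 100) {
  x <- if (is(trace, "MCMCTrace")) trace@samples[, paramIndex] else trace
  if (maxLag >= length(x)) stop("maxLag must be below the trace length")
  if (stats::sd(x) == 0) stop("zero-variance trace")
  ac <- stats::acf(x, lag.max = maxLag, plot = FALSE, demean = TRUE)
  as.numeric(ac$acf)
}

#' Write an MCMC trace as CSV (samples) plus a JSON fit report
#'
#' @param trace an [MCMCTrace-class].
#' @param summary optional [PosteriorSummary-class] (computed if missing).
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
writeTrace <- function(trace, summary = NULL, dir = ".", prefix = "fit") {
  if (is.null(summary)) summary <- summarizePosterior(trace)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(prefix, "_trace.csv"))
  utils::write.csv(data.frame(trace@samples, E = trace@errors), csv,
                   row.names = FALSE)
  rep <- file.path(dir, paste0(prefix, "_report.json"))
  jsonlite::write_json(list(
    best = as.list(summary@best), bestError = summary@bestError,
    ci95Half = as.list(summary@ci95Half),
    acceptance = as.list(trace@acceptance),
    stepSizes = as.list(trace@stepSizes),
    seed = trace@config@seed, nProduction = trace@config@nProduction
  ), rep, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, rep))
}
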