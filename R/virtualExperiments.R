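#' @include AllClasses.R spectrumSim.R
NULL

#' CPMG settings constructor
#'
#' @param nEchoes number of echo periods (each 2 * halfEchoS long).
#' @param halfEchoS half-echo delay tau, seconds (Bruker d20).
#' @param pulseMode `"ideal"` or `"rectangular"`.
#' @param pulseB1Hz B1 amplitude (Hz) for rectangular pulses; the default
#'   25 kHz gives a 10 us 90 and a 20 us 180 pulse.
#' @param spectrometerFreqMHz 1H Larmor frequency, MHz.
#' @return a [CPMGSpec-class].
#' @export
cpmgSpec <- function(nEchoes = 10, halfEchoS = 0.010,
                     pulseMode = c("rectangular", "ideal"),
                     pulseB1Hz = 25000, spectrometerFreqMHz = 499.9) {
  new("CPMGSpec", nEchoes = as.integer(nEchoes), halfEchoS = halfEchoS,
      pulseMode = match.arg(pulseMode), pulseB1Hz = pulseB1Hz,
      spectrometerFreqMHz = spectrometerFreqMHz)
}

## matrix exponential of the (complex, diagonalizable) generator
.expmG <- function(G, t) {
  ev <- eigen(G)
  ev$vectors %*% (exp(ev$values * t) * solve(ev$vectors))
}

## ideal-rotation superoperator (angle theta about an axis at angle phi from
## x in the transverse plane), acting on the (E, I-, I+, Iz) coefficients of
## every pool
.rotationSuperop <- function(nPools, theta, phi) {
  n <- c(cos(phi), sin(phi), 0)
  cross <- matrix(c(0, n[3], -n[2], -n[3], 0, n[1], n[2], -n[1], 0), 3, 3)
  R <- diag(3) * cos(theta) + (1 - cos(theta)) * tcrossprod(n) +
    sin(theta) * cross
  ## (c-, c+, cz) -> (cx, cy, cz)
  T3 <- matrix(c(1, -1i, 0, 1, 1i, 0, 0, 0, 1), 3, 3)
  S3 <- solve(T3) %*% R %*% T3
  S4 <- diag(4) + 0i
  S4[2:4, 2:4] <- S3
  kronecker(S4, diag(nPools))
}

## propagators for the pulses of a CPMG train
.cpmgPulseOps <- function(spec, params, acq, cpmg) {
  n <- nrow(spec@pools)
  if (cpmg@pulseMode == "ideal") {
    list(P90 = .rotationSuperop(n, pi / 2, 0),
         P180 = .rotationSuperop(n, pi, pi / 2))
  } else {
    G90 <- buildExtendedLiouvillian(spec, params, acq, rfHz = cpmg@pulseB1Hz,
                                    rfPhase = 0)
    G180 <- buildExtendedLiouvillian(spec, params, acq,
                                     rfHz = cpmg@pulseB1Hz, rfPhase = pi / 2)
    list(P90 = .expmG(G90, 1 / (4 * cpmg@pulseB1Hz)),
         P180 = .expmG(G180, 1 / (2 * cpmg@pulseB1Hz)))
  }
}

.equilibriumState <- function(spec) {
  n <- nrow(spec@pools)
  f <- spec@pools$fraction
  v <- complex(4 * n)
  v[seq_len(n)] <- f          # E block (populations)
  v[3 * n + seq_len(n)] <- f  # Iz block (longitudinal equilibrium)
  v
}

## total single-quantum detection <J-|rho>
.detectJm <- function(state, nPools) sum(state[nPools + seq_len(nPools)])

## run the 90x - [tau - 180y - tau]^n train; returns state trajectory info
.runCpmgTrain <- function(spec, params, acq, cpmg) {
  n <- nrow(spec@pools)
  G <- buildExtendedLiouvillian(spec, params, acq)
  ops <- .cpmgPulseOps(spec, params, acq, cpmg)
  Ptau <- .expmG(G, cpmg@halfEchoS)
  echo <- Ptau %*% ops$P180 %*% Ptau
  state <- ops$P90 %*% .equilibriumState(spec)
  m0 <- abs(.detectJm(state, n))
  for (e in seq_len(cpmg@nEchoes)) state <- echo %*% state
  list(state = as.vector(state), m0 = m0,
       mEnd = abs(.detectJm(state, n)), nPools = n, G = G)
}

#' Exchange-induced R2 from a virtual CPMG experiment
#'
#' Simulates the sequence 90x - [tau - 180y - tau] x n on the equilibrium
#' state of the exchange model (no relaxation terms: all decay of the
#' echo-train magnetization is caused by chemical exchange), detects the
#' total transverse magnitude via the J- projection, and converts the
#' end/start ratio to a rate: R2ex = -ln(M_end / M_0) / (2 n tau).
#'
#' @param spec an [ExchangeModelSpec-class].
#' @param params a [ModelParameters-class].
#' @param cpmg a [CPMGSpec-class].
#' @return R2ex in 1/s.
#' @export
#' @examples
#' m <- twoSiteModel(fractionSolute = 5e-3 / 110.7)
#' cp <- cpmgSpec(10, 0.010, "ideal")
#' simulateCpmgR2(m$spec, modelParameters(m$spec, deltas = c(solute = 1.44),
#'   rates = c(solute = 4600)), cp)
simulateCpmgR2 <- function(spec, params, cpmg) {
  acq <- acquisitionConfig(spectrometerFreqMHz = cpmg@spectrometerFreqMHz)
  run <- .runCpmgTrain(spec, params, acq, cpmg)
  if (!is.finite(run$mEnd) || run$mEnd <= 0)
    stop("magnetization vanished during the CPMG train")
  -log(run$mEnd / run$m0) / (2 * cpmg@nEchoes * cpmg@halfEchoS)
}

#' Two-site water/solute exchange model
#'
#' Convenience builder for the dilute two-pool model used in relaxivity
#' simulations: one solute pool of the given fraction plus water.
#'
#' @param fractionSolute proton population fraction of the solute pool.
#' @return list with elements `spec` (an [ExchangeModelSpec-class] whose
#'   single rate group is `"solute"`).
#' @export
twoSiteModel <- function(fractionSolute) {
  stopifnot(fractionSolute > 0, fractionSolute < 1)
  pools <- data.frame(label = c("solute", "water"),
                      anomer = c("shared", "water"),
                      fraction = c(fractionSolute, 1 - fractionSolute),
                      stringsAsFactors = FALSE)
  spec <- new("ExchangeModelSpec", variant = "two_site", pools = pools,
              rateGroups = list(solute = "solute"), crossPairs = list(),
              glucoseMolar = NA_real_, waterProtonMolar = NA_real_)
  list(spec = spec)
}

#' Model parameter constructor
#'
#' @param spec the [ExchangeModelSpec-class] the parameters belong to.
#' @param deltas named ppm offsets per non-water pool.
#' @param rates named rates per rate group (1/s).
#' @param crossRates cross rates (1/s), if the model has cross pairs.
#' @param baselinePoly quadratic baseline coefficients (length 3).
#' @param integralScale integral scale in [0.8, 1.2].
#' @return a [ModelParameters-class].
#' @export
modelParameters <- function(spec, deltas, rates, crossRates = NULL,
                            baselinePoly = c(0, 0, 0), integralScale = 1) {
  if (is.null(crossRates)) crossRates <- rep(0, length(spec@crossPairs))
  new("ModelParameters", deltas = deltas, rates = rates,
      crossRates = crossRates, baselinePoly = baselinePoly,
      integralScale = integralScale)
}

#' Exchange relaxivity of dilute glucose from a virtual CPMG experiment
#'
#' Builds the dilute two-site model (solute fraction =
#' protonsPerGlucose * glucose_mM * 1e-3 / waterProtonMolar), runs
#' [simulateCpmgR2()] and divides by the millimolar concentration. A
#' linear-regime check compares the per-mM value at `glucoseMM` and at
#' 5 * `glucoseMM` and warns when they differ by more than 2%.
#'
#' @param deltaPpm solute offset from water, ppm.
#' @param kEx exchange rate of the solute protons, 1/s.
#' @param glucoseMM glucose concentration, mM.
#' @param protonsPerGlucose exchangeable protons per glucose molecule.
#' @param cpmg a [CPMGSpec-class] (its `spectrometerFreqMHz` sets the field).
#' @param waterProtonMolar water proton concentration, mol/L.
#' @param checkLinearity run the 5x concentration cross-check.
#' @return a [RelaxivityResult-class].
#' @export
#' @examples
#' relaxivity(1.44, 4600, cpmg = cpmgSpec(10, 0.010, "ideal",
#'   spectrometerFreqMHz = 499.9))
relaxivity <- function(deltaPpm, kEx, glucoseMM = 1, protonsPerGlucose = 5,
                       cpmg = cpmgSpec(), waterProtonMolar = 110.7,
                       checkLinearity = TRUE) {
  stopifnot(glucoseMM > 0)
  oneField <- function(mM) {
    fb <- protonsPerGlucose * mM * 1e-3 / waterProtonMolar
    if (fb >= 0.05)
      stop("solute fraction >= 0.05: dilute assumption broken")
    m <- twoSiteModel(fb)
    params <- modelParameters(m$spec, deltas = c(solute = deltaPpm),
                              rates = c(solute = kEx))
    if (kEx == 0) return(0)
    simulateCpmgR2(m$spec, params, cpmg) / mM
  }
  r <- oneField(glucoseMM)
  if (checkLinearity && kEx > 0) {
    r5 <- oneField(5 * glucoseMM)
    if (abs(r5 - r) > 0.02 * abs(r))
      warning(sprintf(paste0("relaxivity not linear in concentration: ",
                             "%.4g at %g mM vs %.4g at %g mM"),
                      r, glucoseMM, r5, 5 * glucoseMM))
  }
  fT <- cpmg@spectrometerFreqMHz / 42.577478518
  new("RelaxivityResult",
      fieldLabel = sprintf("%.1f T (%.1f MHz)", fT, cpmg@spectrometerFreqMHz),
      spectrometerFreqMHz = cpmg@spectrometerFreqMHz,
      R2ex = r * glucoseMM, glucoseMM = glucoseMM, relaxivity = r)
}

#' Exchange relaxivity of an arbitrary dilute exchange model
#'
#' Runs the CPMG simulation on a supplied multi-pool model (for example the
#' restricted glucose model built at millimolar concentration) and reports
#' R2ex per mM.
#'
#' @param spec an [ExchangeModelSpec-class] (dilute).
#' @param params a [ModelParameters-class].
#' @param glucoseMM solute concentration in mM.
#' @param cpmg a [CPMGSpec-class].
#' @return a [RelaxivityResult-class].
#' @export
relaxivityFromModel <- function(spec, params, glucoseMM, cpmg = cpmgSpec()) {
  r2 <- simulateCpmgR2(spec, params, cpmg)
  fT <- cpmg@spectrometerFreqMHz / 42.577478518
  new("RelaxivityResult",
      fieldLabel = sprintf("%.1f T (%.1f MHz)", fT, cpmg@spectrometerFreqMHz),
      spectrometerFreqMHz = cpmg@spectrometerFreqMHz,
      R2ex = r2, glucoseMM = glucoseMM, relaxivity = r2 / glucoseMM)
}

#' CPMG-filtered spectra
#'
#' Applies a CPMG train (default four echo inversions) with the given
#' half-echo delays before acquisition and processes the resulting FIDs as
#' in plain pulse-acquire simulation. The receiver phase is chosen so that
#' the zero-delay limit reproduces the plain spectrum; at longer half-echo
#' times exchange during the train imprints characteristic phase/amplitude
#' patterns on the hydroxyl lines.
#'
#' @param spec an [ExchangeModelSpec-class].
#' @param params a [ModelParameters-class].
#' @param acq an [AcquisitionConfig-class].
#' @param d20List numeric vector of half-echo delays, seconds (> 0).
#' @param nEchoes echo inversions before acquisition (default 4).
#' @param pulseMode `"ideal"` or `"rectangular"`.
#' @param pulseB1Hz B1 amplitude for rectangular pulses, Hz.
#' @return named list of [Spectrum-class], one per half-echo delay.
#' @export
cpmgFilteredSpectrum <- function(spec, params, acq, d20List, nEchoes = 4,
                                 pulseMode = c("ideal", "rectangular"),
                                 pulseB1Hz = 25000) {
  pulseMode <- match.arg(pulseMode)
  stopifnot(all(d20List > 0))
  n <- nrow(spec@pools)
  out <- vector("list", length(d20List))
  names(out) <- sprintf("d20=%gs", d20List)
  for (j in seq_along(d20List)) {
    cpmg <- new("CPMGSpec", nEchoes = as.integer(nEchoes),
                halfEchoS = d20List[j], pulseMode = pulseMode,
                pulseB1Hz = pulseB1Hz,
                spectrometerFreqMHz = acq@spectrometerFreqMHz)
    run <- .runCpmgTrain(spec, params, acq, cpmg)
    d <- numeric(4 * n)
    d[n + seq_len(n)] <- 1
    ## receiver phase: an ideal 90x turns unit Iz into -i/2 on the I- block
    fid <- .propagateDetect(run$G, run$state, d, acq@td, .dwell(acq)) * 2i
    out[[j]] <- processFid(fid, acq)
  }
  out
}
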