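#' @include AllClasses.R
NULL

## fraction of the alpha anomer in solution equilibrium (beta = 1 - alpha)
.alphaFraction <- 0.36

.variants <- c("split_anomeric", "split2", "split3", "restricted",
               "restricted_cross")

## Pool layout per model variant: label + anomer + protons relative to
## glucoseMolar (split sites contribute the anomer fraction each).
.poolLayout <- function(variant) {
  a <- .alphaFraction
  b <- 1 - .alphaFraction
  switch(variant,
    split_anomeric = data.frame(
      label = c("C1_alpha", "C1_beta", "C2", "C3", "C4", "C6"),
      anomer = c("alpha", "beta", "shared", "shared", "shared", "shared"),
      rel = c(a, b, 1, 1, 1, 1)),
    split2 = data.frame(
      label = c("C1_alpha", "C1_beta", "S1_alpha", "S1_beta", "U1", "U2",
                "C6"),
      anomer = c("alpha", "beta", "alpha", "beta", "shared", "shared",
                 "shared"),
      rel = c(a, b, a, b, 1, 1, 1)),
    split3 = data.frame(
      label = c("C1_alpha", "C1_beta", "S1_alpha", "S1_beta", "S2_alpha",
                "S2_beta", "U1", "C6"),
      anomer = c("alpha", "beta", "alpha", "beta", "alpha", "beta",
                 "shared", "shared"),
      rel = c(a, b, a, b, a, b, 1, 1)),
    restricted = ,
    restricted_cross = data.frame(
      label = c("C1_alpha", "C1_beta", "C2_alpha", "C2_beta", "C3_alpha",
                "C3_beta", "C4_alpha", "C4_beta", "C6"),
      anomer = c("alpha", "beta", "alpha", "beta", "alpha", "beta",
                 "alpha", "beta", "shared"),
      rel = c(a, b, a, b, a, b, a, b, 1)),
    stop("unknown model variant '", variant, "'; must be one of: ",
         paste(.variants, collapse = ", "))
  )
}

.rateGroupLayout <- function(variant) {
  switch(variant,
    split_anomeric = list(
      C1_alpha = "C1_alpha", C1_beta = "C1_beta", C2 = "C2", C3 = "C3",
      C4 = "C4", C6 = "C6"),
    split2 = list(
      C1_alpha = "C1_alpha", C1_beta = "C1_beta", S1_alpha = "S1_alpha",
      S1_beta = "S1_beta", U1 = "U1", U2 = "U2", C6 = "C6"),
    split3 = list(
      C1_alpha = "C1_alpha", C1_beta = "C1_beta", S1_alpha = "S1_alpha",
      S1_beta = "S1_beta", S2_alpha = "S2_alpha", S2_beta = "S2_beta",
      U1 = "U1", C6 = "C6"),
    restricted = ,
    restricted_cross = list(
      C1_alpha = "C1_alpha", C1_beta = "C1_beta",
      C2 = c("C2_alpha", "C2_beta"), C3 = c("C3_alpha", "C3_beta"),
      C4 = c("C4_alpha", "C4_beta"), C6 = "C6")
  )
}

.crossPairLayout <- function(variant) {
  if (variant != "restricted_cross") return(list())
  list(c("C1_alpha", "C2_alpha"), c("C2_alpha", "C3_alpha"),
       c("C3_alpha", "C4_alpha"),
       c("C1_beta", "C2_beta"), c("C2_beta", "C3_beta"),
       c("C3_beta", "C4_beta"))
}

#' Build a glucose hydroxyl exchange model
#'
#' Enumerates the exchangeable proton pools of a chosen model variant and
#' computes their population fractions from proton molarities: each
#' anomer-split hydroxyl site contributes `glucoseMolar * 0.36` (alpha) or
#' `glucoseMolar * 0.64` (beta) protons, the C6 hydroxyl (and any unsplit
#' site) contributes `glucoseMolar`, and water contributes
#' `waterProtonMolar`. Fractions are normalized to sum to one.
#'
#' Variants form a ladder of flexibility: `"split_anomeric"` splits only the
#' anomeric C1 site into alpha/beta pools; `"split2"`/`"split3"` additionally
#' split one/two of the C2-C4 sites into anomer pools with their own rates
#' (which of C2/C3/C4 actually splits is not asserted, hence the generic
#' `S`/`U` labels); `"restricted"` gives every site except C6 distinct
#' alpha/beta chemical shifts but ties the C2, C3 and C4 rates across
#' anomers (9 shifts, 6 rates); `"restricted_cross"` adds direct
#' hydroxyl-hydroxyl exchange along (C1,C2), (C2,C3), (C3,C4) in each anomer.
#'
#' @param variant model variant name.
#' @param glucoseMolar glucose concentration, mol/L (> 0).
#' @param waterProtonMolar water proton concentration, mol/L (> 0);
#'   the default 110.7 corresponds to 2 x 55.35 M water.
#' @return an [ExchangeModelSpec-class] object.
#' @export
#' @examples
#' buildModel("restricted", 1.0, 110.7)
buildModel <- function(variant, glucoseMolar = 1.0, waterProtonMolar = 110.7) {
  stopifnot(glucoseMolar > 0, waterProtonMolar > 0)
  lay <- .poolLayout(variant)
  protons <- c(lay$rel * glucoseMolar, waterProtonMolar)
  pools <- data.frame(
    label = c(lay$label, "water"),
    anomer = c(lay$anomer, "water"),
    fraction = protons / sum(protons),
    stringsAsFactors = FALSE
  )
  new("ExchangeModelSpec", variant = variant, pools = pools,
      rateGroups = .rateGroupLayout(variant),
      crossPairs = .crossPairLayout(variant),
      glucoseMolar = glucoseMolar, waterProtonMolar = waterProtonMolar)
}

#' Per-pool exchange rates implied by rate-group parameters
#'
#' @keywords internal
.poolRates <- function(spec, params) {
  groups <- spec@rateGroups
  if (length(params@rates) != length(groups))
    stop("expected ", length(groups), " rates (one per rate group), got ",
         length(params@rates))
  rates <- params@rates
  if (is.null(names(rates))) names(rates) <- names(groups)
  out <- numeric(0)
  for (g in names(groups)) out[groups[[g]]] <- rates[[g]]
  out
}

#' Assemble the first-order exchange matrix K
#'
#' Builds the N x N chemical exchange (reaction) matrix of first-order rate
#' constants in column convention: `K[i, j]` is the rate of transfer from
#' pool j to pool i (for i != j), and each diagonal entry is minus its column
#' sum, so columns sum to zero and total population is conserved. For each
#' non-water pool with rate k, transfer to water is `K[water, pool] = k` and
#' the back transfer is scaled by the stationary fractions,
#' `K[pool, water] = k * f_pool / f_water`, so that the pool fraction vector
#' is stationary (`K %*% f = 0`) by construction. Cross pairs (donor,
#' acceptor) add `K[acceptor, donor] = k_c` with the detailed-balance back
#' rate `K[donor, acceptor] = k_c * f_donor / f_acceptor`.
#'
#' @param spec an [ExchangeModelSpec-class].
#' @param params a [ModelParameters-class] consistent with `spec`.
#' @return numeric matrix with pool labels as dimnames.
#' @export
#' @examples
#' spec <- buildModel("restricted")
#' params <- glucoseModelParameters(spec, pH = 6.21, temperatureK = 270)
#' K <- assembleExchangeMatrix(spec, params)
#' max(abs(colSums(K)))                      # columns sum to zero
#' max(abs(K %*% poolTable(spec)$fraction))  # stationary fractions
assembleExchangeMatrix <- function(spec, params) {
  if (any(params@rates < 0)) stop("negative exchange rate")
  p <- spec@pools
  n <- nrow(p)
  f <- p$fraction
  labels <- p$label
  iw <- which(p$anomer == "water")
  K <- matrix(0, n, n, dimnames = list(labels, labels))
  k <- .poolRates(spec, params)
  for (lab in names(k)) {
    i <- match(lab, labels)
    K[iw, i] <- K[iw, i] + k[[lab]]
    K[i, iw] <- K[i, iw] + k[[lab]] * f[i] / f[iw]
  }
  if (length(spec@crossPairs)) {
    kc <- params@crossRates
    if (length(kc) != length(spec@crossPairs))
      stop("expected ", length(spec@crossPairs), " cross rates, got ",
           length(kc))
    for (m in seq_along(spec@crossPairs)) {
      d <- match(spec@crossPairs[[m]][1], labels)
      a <- match(spec@crossPairs[[m]][2], labels)
      K[a, d] <- K[a, d] + kc[m]
      K[d, a] <- K[d, a] + kc[m] * f[d] / f[a]
    }
  }
  diag(K) <- diag(K) - colSums(K)
  K
}

#' Fitting bounds for the parameters of an exchange model
#'
#' Returns one row per free parameter (chemical shifts, one rate per rate
#' group, cross rates if any, three baseline coefficients, integral scale).
#' At the `"initial"` stage the chemical-shift windows are broad and
#' overlapping except for the unambiguous anchors (C1 alpha/beta downfield
#' of 1.8 ppm, C6 below 1 ppm). At the `"assignment_fixed"` stage the shift
#' windows are non-overlapping intervals centered on supplied prior
#' assignments, which pins the peak assignment obtained at low temperature.
#' Exchange-rate bounds are wide and non-restrictive at both stages; the
#' integral scale is always limited to [0.8, 1.2].
#'
#' @param spec an [ExchangeModelSpec-class].
#' @param stage `"initial"` or `"assignment_fixed"`.
#' @param priors named numeric of prior chemical shifts (ppm) per non-water
#'   pool; required for `"assignment_fixed"`.
#' @param shiftWindow half-width (ppm) of the assignment-fixed windows
#'   before disjointness shrinking.
#' @param baselineScale scale of the symmetric baseline-coefficient bounds.
#' @param rateUpper upper edge of the exchange-rate windows (1/s). The
#'   default 2e4 is non-restrictive at any temperature studied; for
#'   low-temperature spectra a tighter (but still order-of-magnitude
#'   generous) ceiling avoids starting chains deep in the flat coalescence
#'   plateau of the error surface.
#' @return data.frame with columns `parameter`, `type`, `lower`, `upper`.
#' @export
parameterBounds <- function(spec, stage = c("initial", "assignment_fixed"),
                            priors = NULL, shiftWindow = 0.12,
                            baselineScale = 1, rateUpper = 2e4) {
  stage <- match.arg(stage)
  p <- spec@pools
  nonWater <- p$label[p$anomer != "water"]

  if (stage == "initial") {
    lo <- rep(0.3, length(nonWater))
    hi <- rep(1.8, length(nonWater))
    lo[nonWater == "C1_alpha"] <- 1.8; hi[nonWater == "C1_alpha"] <- 2.5
    lo[nonWater == "C1_beta"] <- 2.5;  hi[nonWater == "C1_beta"] <- 3.2
    lo[nonWater == "C6"] <- 0.5;       hi[nonWater == "C6"] <- 1.0
  } else {
    if (is.null(priors) || !all(nonWater %in% names(priors)))
      stop("assignment_fixed stage needs prior shifts for every non-water pool")
    centers <- priors[nonWater]
    ord <- order(centers)
    half <- rep(shiftWindow, length(centers))
    sorted <- centers[ord]
    if (length(sorted) > 1) {
      gaps <- diff(sorted)
      ## shrink neighbouring windows so the intervals stay pairwise disjoint
      for (i in seq_along(gaps)) {
        cap <- 0.45 * gaps[i]
        half[ord[i]] <- min(half[ord[i]], cap)
        half[ord[i + 1]] <- min(half[ord[i + 1]], cap)
      }
    }
    lo <- centers - half
    hi <- centers + half
  }

  out <- data.frame(
    parameter = paste0("delta.", nonWater),
    type = "delta", lower = as.numeric(lo), upper = as.numeric(hi),
    stringsAsFactors = FALSE
  )
  out <- rbind(out, data.frame(
    parameter = paste0("rate.", names(spec@rateGroups)),
    type = "rate", lower = 0, upper = rateUpper, stringsAsFactors = FALSE))
  if (length(spec@crossPairs))
    out <- rbind(out, data.frame(
      parameter = paste0("cross.", seq_along(spec@crossPairs)),
      type = "cross", lower = 0, upper = 5e3, stringsAsFactors = FALSE))
  out <- rbind(out, data.frame(
    parameter = paste0("baseline.", 0:2),
    type = "baseline", lower = -2 * baselineScale, upper = 2 * baselineScale,
    stringsAsFactors = FALSE))
  out <- rbind(out, data.frame(
    parameter = "integralScale", type = "scale", lower = 0.8, upper = 1.2,
    stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

## ---------------------------------------------------------------------------
## Published glucose parameter sets (1 M glucose in 1x PBS)
## ---------------------------------------------------------------------------

#' Chemical shifts of the glucose hydroxyl pools
#'
#' Fitted chemical-shift offsets from water (ppm, downfield positive) of the
#' nine hydroxyl pools of the restricted model for 1 M glucose in 1x PBS,
#' by sample pH (shifts were read at 295 K for pH 6.21 and 277 K for
#' pH 7.00).
#'
#' @param pH one of 6.21 or 7.00.
#' @return named numeric vector in restricted-model pool order.
#' @export
#' @examples
#' glucoseShiftTable(6.21)
glucoseShiftTable <- function(pH = 6.21) {
  key <- sprintf("%.2f", pH)
  tab <- list(
    "6.21" = c(C1_alpha = 2.116, C1_beta = 2.835,
               C2_alpha = 1.055, C2_beta = 1.252,
               C3_alpha = 1.230, C3_beta = 1.347,
               C4_alpha = 1.208, C4_beta = 1.415,
               C6 = 0.763),
    "7.00" = c(C1_alpha = 2.0726, C1_beta = 2.8231,
               C2_alpha = 1.0599, C2_beta = 1.2255,
               C3_alpha = 1.2361, C3_beta = 1.3004,
               C4_alpha = 1.2200, C4_beta = 1.4371,
               C6 = 0.77576)
  )
  if (is.null(tab[[key]]))
    stop("no shift table for pH ", pH, "; available: 6.21, 7.00")
  tab[[key]]
}

#' Eyring parameters of the glucose hydroxyl exchange rates
#'
#' Transmission coefficients and Gibbs activation energies (with 1-sigma
#' uncertainties) of the six rate groups of the restricted model, per sample
#' pH, for 1 M glucose in 1x PBS. The two C3/C4 groups are distinguished by
#' their chemical-shift pairs (see [glucoseShiftTable()]); which is
#' physically C3 and which C4 is a best-guess assignment. The pH 7.38 set
#' derives from only two measured temperatures (270 and 275 K) and is
#' flagged as unreliable for extrapolation beyond them.
#'
#' @param pH one of 6.21, 7.00 or 7.38.
#' @return named list of [EyringParams-class], one per rate group
#'   (C1_alpha, C1_beta, C2, C3, C4, C6).
#' @export
#' @examples
#' ey <- glucoseEyringTable(7.00)
#' eyringRate(ey$C1_alpha, 310)
glucoseEyringTable <- function(pH = 6.21) {
  key <- sprintf("%.2f", pH)
  mk <- function(kappa, skappa, dG, sdG, range, reliable = TRUE)
    eyringParams(kappa, dG, sigmaKappa = skappa, sigmaDG = sdG,
                 tempRangeK = range, reliableExtrapolation = reliable)
  tab <- switch(key,
    "6.21" = {
      r <- c(270, 295)
      list(
        C1_alpha = mk(0.0162, 0.0007, 4.617e4, 0.010e4, r),
        C1_beta = mk(0.00126, 0.00006, 3.852e4, 0.011e4, r),
        C2 = mk(8.2e-6, 0.6e-6, 2.793e4, 0.017e4, r),
        C3 = mk(1.54e-6, 0.34e-6, 2.38e4, 0.05e4, r),
        C4 = mk(2.5e-5, 0.4e-5, 3.054e4, 0.035e4, r),
        C6 = mk(1.37e-6, 0.08e-6, 2.227e4, 0.013e4, r))
    },
    "7.00" = {
      r <- c(268.5, 277.5)
      list(
        C1_alpha = mk(0.247, 0.024, 4.966e4, 0.022e4, r),
        C1_beta = mk(0.071, 0.005, 4.549e4, 0.017e4, r),
        C2 = mk(0.000231, 0.000021, 3.508e4, 0.021e4, r),
        C3 = mk(6.0e-5, 0.7e-5, 3.192e4, 0.025e4, r),
        C4 = mk(0.00228, 0.00027, 4.006e4, 0.027e4, r),
        C6 = mk(1.43e-5, 0.05e-5, 2.810e4, 0.008e4, r))
    },
    "7.38" = {
      r <- c(270, 275)
      list(
        C1_alpha = mk(5.7e2, 2.1e2, 6.54e4, 0.08e4, r, FALSE),
        C1_beta = mk(2.9, 0.9, 5.23e4, 0.07e4, r, FALSE),
        C2 = mk(2.1e3, 0.8e3, 7.00e4, 0.09e4, r, FALSE),
        C3 = mk(1.1e3, 0.6e3, 6.83e4, 0.13e4, r, FALSE),
        C4 = mk(0.00080, 0.00023, 3.68e4, 0.07e4, r, FALSE),
        C6 = mk(0.042, 0.005, 4.551e4, 0.028e4, r, FALSE))
    },
    stop("no Eyring table for pH ", pH, "; available: 6.21, 7.00, 7.38")
  )
  tab
}

#' Model parameters of glucose at a given pH and temperature
#'
#' Convenience constructor combining [glucoseShiftTable()] (chemical shifts)
#' with rates evaluated from [glucoseEyringTable()] at the requested
#' temperature, with a flat baseline and unit integral scale.
#'
#' @param spec an [ExchangeModelSpec-class] built from the `"restricted"` or
#'   `"restricted_cross"` variant.
#' @param pH sample pH (6.21 or 7.00).
#' @param temperatureK absolute temperature, K.
#' @return a [ModelParameters-class].
#' @export
glucoseModelParameters <- function(spec, pH = 6.21, temperatureK = 270) {
  if (!spec@variant %in% c("restricted", "restricted_cross"))
    stop("published parameter sets are for the restricted model")
  ey <- glucoseEyringTable(pH)
  rates <- vapply(names(spec@rateGroups),
                  function(g) unname(eyringRate(ey[[g]], temperatureK)$k),
                  numeric(1))
  new("ModelParameters",
      deltas = glucoseShiftTable(pH),
      rates = rates,
      crossRates = rep(0, length(spec@crossPairs)),
      baselinePoly = c(0, 0, 0), integralScale = 1)
}

#' Export the pool table (with shifts) as a data.frame / CSV
#'
#' @param spec an [ExchangeModelSpec-class].
#' @param params optional [ModelParameters-class]; if given, a `deltaPpm`
#'   column is added (NA for water).
#' @param file optional path; if given the table is written as CSV.
#' @return the data.frame, invisibly when writing to file.
#' @export
exportPoolTable <- function(spec, params = NULL, file = NULL) {
  out <- spec@pools
  if (!is.null(params)) {
    out$deltaPpm <- NA_real_
    idx <- match(names(params@deltas), out$label)
    out$deltaPpm[idx] <- unname(params@deltas)
  }
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE)
    return(invisible(out))
  }
  out
}
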