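# Shared fixtures: small hand-built exchange models and acquisition settings
# sized for fast tests. All synthetic inputs are generated in code.

# arbitrary multi-pool model; fractions include water's share (last element)
customSpec <- function(labels, fractions, rateGroups = NULL) {
  stopifnot(abs(sum(fractions) - 1) < 1e-12,
            length(fractions) == length(labels) + 1)
  n <- length(labels)
  pools <- data.frame(
    label = c(labels, "water"),
    anomer = c(rep("shared", n), "water"),
    fraction = fractions,
    stringsAsFactors = FALSE
  )
  if (is.null(rateGroups))
    rateGroups <- stats::setNames(as.list(labels), labels)
  new("ExchangeModelSpec", variant = "custom", pools = pools,
      rateGroups = rateGroups, crossPairs = list(),
      glucoseMolar = NA_real_, waterProtonMolar = NA_real_)
}

# two-pool symmetric or asymmetric model: solute pool(s) + water
poolModel <- function(fracSolute, deltaPpm, kEx) {
  labels <- paste0("s", seq_along(fracSolute))
  spec <- customSpec(labels, c(fracSolute, 1 - sum(fracSolute)))
  params <- modelParameters(spec,
                            deltas = stats::setNames(deltaPpm, labels),
                            rates = stats::setNames(kEx, labels))
  list(spec = spec, params = params)
}

# symmetric two-site system: equal populations at offsets delta and 0
# (identical, up to an overall frequency shift, to sites at +/- delta/2)
symmetricTwoSite <- function(deltaPpm, k)
  poolModel(0.5, deltaPpm, k)

smallAcq <- function(td = 4096, sw = 15, freq = 500, lb = 1, upper = 3.8)
  acquisitionConfig(spectrometerFreqMHz = freq, sweepWidthPpm = sw, td = td,
                    lbHz = lb, extractionUpperPpm = upper)

paperAcq <- function() acquisitionConfig()

# quick local-maxima count above a relative threshold
countPeaks <- function(y, relThreshold = 0.1) {
  thr <- relThreshold * max(y)
  n <- length(y)
  sum(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n] &
        y[2:(n - 1)] > thr)
}
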