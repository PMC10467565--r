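#' @include AllClasses.R
NULL

#' Pool table of an exchange model
#'
#' @param object an `ExchangeModelSpec`.
#' @return data.frame with columns `label`, `anomer`, `fraction`.
#' @export
setGeneric("poolTable", function(object) standardGeneric("poolTable"))

#' @rdname poolTable
#' @export
setMethod("poolTable", "ExchangeModelSpec", function(object) object@pools)

#' Rate-sharing topology of an exchange model
#'
#' @param object an `ExchangeModelSpec`.
#' @return named list mapping rate-group name to pool labels.
#' @export
setGeneric("rateGroups", function(object) standardGeneric("rateGroups"))

#' @rdname rateGroups
#' @export
setMethod("rateGroups", "ExchangeModelSpec", function(object) object@rateGroups)

#' Number of pools (including water)
#'
#' @param object an `ExchangeModelSpec`.
#' @export
setGeneric("nPools", function(object) standardGeneric("nPools"))

#' @rdname nPools
#' @export
setMethod("nPools", "ExchangeModelSpec", function(object) nrow(object@pools))

#' Spectrum axis (ppm offsets from water)
#'
#' @param object a `Spectrum` or `SpectrumSegment`.
#' @export
setGeneric("axisPpm", function(object) standardGeneric("axisPpm"))

#' @rdname axisPpm
#' @export
setMethod("axisPpm", "Spectrum", function(object) object@axisPpm)

#' Spectrum intensities
#'
#' @param object a `Spectrum` or `SpectrumSegment`.
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))

#' @rdname intensity
#' @export
setMethod("intensity", "Spectrum", function(object) object@intensity)

#' Production samples of an MCMC trace
#'
#' @param object an `MCMCTrace`.
#' @export
setGeneric("traceSamples", function(object) standardGeneric("traceSamples"))

#' @rdname traceSamples
#' @export
setMethod("traceSamples", "MCMCTrace", function(object) object@samples)

#' Best-fit parameter vector of a posterior summary
#'
#' @param object a `PosteriorSummary`.
#' @export
setGeneric("bestFit", function(object) standardGeneric("bestFit"))

#' @rdname bestFit
#' @export
setMethod("bestFit", "PosteriorSummary", function(object) object@best)

#' Symmetrized 95% credible half-widths
#'
#' @param object a `PosteriorSummary`.
#' @export
setGeneric("ci95Half", function(object) standardGeneric("ci95Half"))

#' @rdname ci95Half
#' @export
setMethod("ci95Half", "PosteriorSummary", function(object) object@ci95Half)

## show methods -------------------------------------------------------------

setMethod("show", "ExchangeModelSpec", function(object) {
  cat("ExchangeModelSpec '", object@variant, "': ", nrow(object@pools),
      " pools, ", length(object@rateGroups), " rate groups",
      if (length(object@crossPairs)) paste0(", ", length(object@crossPairs),
                                            " cross pairs") else "",
      "\n", sep = "")
  cat("  glucose ", object@glucoseMolar, " M, water protons ",
      object@waterProtonMolar, " M\n", sep = "")
  print(object@pools, row.names = FALSE)
})

setMethod("show", "Spectrum", function(object) {
  cat(class(object), ": ", length(object@axisPpm), " points, ",
      sprintf("%.3f to %.3f ppm (offsets from water)", min(object@axisPpm),
              max(object@axisPpm)), "\n", sep = "")
})

setMethod("show", "MCMCTrace", function(object) {
  cat("MCMCTrace: ", nrow(object@samples), " production sweeps x ",
      ncol(object@samples), " parameters\n", sep = "")
  cat("  mean acceptance ", sprintf("%.2f", mean(object@acceptance)),
      ", min error ", format(min(object@errors), digits = 6), "\n", sep = "")
})

setMethod("show", "PosteriorSummary", function(object) {
  cat("PosteriorSummary (", length(object@best), " parameters)\n", sep = "")
  df <- data.frame(best = object@best, ci95 = object@ci95Half)
  rownames(df) <- names(object@best)
  print(df)
})

setMethod("show", "EyringParams", function(object) {
  cat(sprintf("EyringParams: kappa = %.4g +/- %.2g, dG = %.5g +/- %.2g J/mol\n",
              object@kappa, object@sigmaKappa, object@dG, object@sigmaDG))
  if (length(object@tempRangeK))
    cat(sprintf("  fitted over %.2f-%.2f K%s\n", min(object@tempRangeK),
                max(object@tempRangeK),
                if (!object@reliableExtrapolation)
                  " (extrapolation beyond this range not recommended)" else ""))
})

setMethod("show", "RelaxivityResult", function(object) {
  cat(sprintf("RelaxivityResult: %s, R2ex = %.4g 1/s at %g mM -> %.4g 1/s/mM\n",
              object@fieldLabel, object@R2ex, object@glucoseMM,
              object@relaxivity))
})
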