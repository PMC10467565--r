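## Physical constants (CODATA 2018), SI units.
.kB <- 1.380649e-23    # Boltzmann constant, J/K
.hP <- 6.62607015e-34  # Planck constant, J s
.Rgas <- 8.31446       # molar gas constant, J/(mol K)

#' Physical constants used by the package
#'
#' Returns the CODATA-2018 values of the Boltzmann constant, the Planck
#' constant and the molar gas constant used throughout the Eyring
#' calculations.
#'
#' @return Named numeric vector with elements `kB` (J/K), `h` (J s) and
#'   `R` (J/(mol K)).
#' @export
#' @examples
#' physicalConstants()
physicalConstants <- function() {
  c(kB = .kB, h = .hP, R = .Rgas)
}
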