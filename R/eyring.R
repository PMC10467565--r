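#' @include AllClasses.R constants.R
NULL

#' Eyring parameter constructor
#'
#' When only marginal uncertainties are supplied, the covariance of the
#' linearized parameters (slope a = -dG/R, intercept b = ln(kappa*kB/h)) is
#' taken diagonal with var(b) = (sigmaKappa/kappa)^2 and
#' var(a) = (sigmaDG/R)^2.
#'
#' @param kappa transmission coefficient (> 0, dimensionless).
#' @param dG Gibbs activation energy (J/mol, > 0).
#' @param sigmaKappa,sigmaDG 1-sigma uncertainties.
#' @param cov optional 2x2 covariance of (slope, intercept); overrides the
#'   diagonal construction.
#' @param tempRangeK temperature range of the underlying data.
#' @param reliableExtrapolation logical extrapolation flag.
#' @return an [EyringParams-class].
#' @export
eyringParams <- function(kappa, dG, sigmaKappa = 0, sigmaDG = 0, cov = NULL,
                         tempRangeK = numeric(0),
                         reliableExtrapolation = TRUE) {
  if (is.null(cov))
    cov <- diag(c((sigmaDG / .Rgas)^2, (sigmaKappa / kappa)^2))
  new("EyringParams", kappa = kappa, dG = dG, sigmaKappa = sigmaKappa,
      sigmaDG = sigmaDG, cov = cov, tempRangeK = tempRangeK,
      reliableExtrapolation = reliableExtrapolation)
}

#' Evaluate the Eyring equation with propagated uncertainty
#'
#' k(T) = kappa * (kB * T / h) * exp(-dG / (R * T)). The 95% half-width is
#' propagated to first order through the linearized form
#' ln(k/T) = a / T + b using the stored covariance of (a, b):
#' var(ln k) = x^2 var(a) + var(b) + 2 x cov(a, b) with x = 1/T, and
#' ci95 = 1.96 * k * sd(ln k).
#'
#' @param params an [EyringParams-class].
#' @param T absolute temperature(s), K.
#' @return data.frame with columns `T_K`, `k` (1/s) and `ci95` (1/s).
#' @export
#' @examples
#' ey <- eyringParams(0.247, 4.966e4)
#' eyringRate(ey, 310)$k   # about 6.8e3 1/s
eyringRate <- function(params, T) {
  stopifnot(all(T > 0))
  k <- params@kappa * (.kB * T / .hP) * exp(-params@dG / (.Rgas * T))
  x <- 1 / T
  vlnk <- x^2 * params@cov[1, 1] + params@cov[2, 2] +
    2 * x * params@cov[1, 2]
  vlnk <- pmax(vlnk, 0)
  data.frame(T_K = T, k = k, ci95 = 1.96 * k * sqrt(vlnk))
}

#' Fit Eyring parameters by linearized pseudoinverse regression
#'
#' Regresses y = ln(k/T) on x = 1/T with design matrix [x, 1] solved by the
#' Moore-Penrose pseudoinverse: slope a = -dG/R, intercept
#' b = ln(kappa*kB/h). Supplied 95% half-widths are converted to 1-sigma
#' (divided by 1.96), propagated linearly through the logarithm and the
#' pseudoinverse into the covariance of (a, b), and back through the
#' exponential to (kappa, dG). No residual-based error inflation is added:
#' the reported uncertainties reflect only the uncertainties of the input
#' rates, taking the Eyring form as exact.
#'
#' @param points data.frame with columns `T_K`, `k` and optionally `ci95`
#'   (95% half-widths of k; zero/absent means exact points).
#' @param weighted logical; if TRUE, rows are weighted by inverse variance
#'   of ln k in the regression (default FALSE: plain pseudoinverse).
#' @return an [EyringParams-class] with propagated uncertainties.
#' @export
#' @examples
#' tt <- seq(270, 295, 5)
#' pts <- data.frame(T_K = tt, k = eyringRate(eyringParams(0.01, 4e4), tt)$k)
#' fitEyringLinearized(pts)
fitEyringLinearized <- function(points, weighted = FALSE) {
  T <- points$T_K
  k <- points$k
  if (length(T) < 2 || length(unique(T)) < 2)
    stop("insufficient temperatures: need at least 2 distinct points")
  if (any(k <= 0)) stop("non-positive rate")
  ci95 <- if (!is.null(points$ci95)) points$ci95 else rep(0, length(k))
  sigmaLnk <- (ci95 / 1.96) / k
  x <- 1 / T
  y <- log(k / T)
  X <- cbind(x, 1)
  if (weighted) {
    w <- ifelse(sigmaLnk > 0, 1 / sigmaLnk^2, max(1 / sigmaLnk[sigmaLnk > 0]^2,
                                                  1))
    A <- solve(t(X) %*% (w * X), t(X * w))
  } else {
    A <- pracma::pinv(X)
  }
  ab <- as.vector(A %*% y)
  covAB <- A %*% diag(sigmaLnk^2, nrow = length(y)) %*% t(A)
  a <- ab[1]
  b <- ab[2]
  dG <- -.Rgas * a
  kappa <- exp(b) * .hP / .kB
  eyringParams(kappa = kappa, dG = dG,
               sigmaKappa = kappa * sqrt(covAB[2, 2]),
               sigmaDG = .Rgas * sqrt(covAB[1, 1]),
               cov = covAB, tempRangeK = range(T))
}

#' Tabulate Eyring rates over a temperature grid
#'
#' @param params an [EyringParams-class].
#' @param Tmin,Tmax,step grid limits and spacing in K (defaults 260-310 K,
#'   0.25 K: 201 rows).
#' @return data.frame with columns `T_K`, `k`, `ci95` and (when the
#'   parameter set is flagged unreliable for extrapolation) a logical
#'   `extrapolationCaution` column marking rows outside the measured range.
#' @export
tabulateRates <- function(params, Tmin = 260, Tmax = 310, step = 0.25) {
  stopifnot(Tmin < Tmax, step > 0)
  grid <- seq(Tmin, Tmax, by = step)
  out <- eyringRate(params, grid)
  if (!params@reliableExtrapolation && length(params@tempRangeK))
    out$extrapolationCaution <- grid < min(params@tempRangeK) |
      grid > max(params@tempRangeK)
  out
}
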