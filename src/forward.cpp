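// Single-quantum Bloch-McConnell propagation of an exchanging multi-pool
// spin system, and the processed/extracted spectrum segment used inside the
// MCMC loop. The generator of the detected coherence block is
// A = i*diag(omega) + K, so the FID is a finite sum of complex exponential
// modes, FID[n] = sum_m c_m z_m^n. Its DFT therefore has an exact closed
// form per frequency bin (finite geometric series), which lets the fitting
// loop evaluate only the bins of the extraction window.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void bm_modes(const vec& omega, const mat& K, const vec& f,
                     cx_vec& lambda, cx_vec& weight) {
  const uword n = omega.n_elem;
  cx_mat A(n, n);
  A.set_real(K);
  A.set_imag(diagmat(omega));
  cx_mat V;
  if (!eig_gen(lambda, V, A))
    Rcpp::stop("eigendecomposition of the exchange generator failed");
  cx_vec w = solve(V, conv_to<cx_vec>::from(f));
  cx_rowvec colsum = sum(V, 0);
  weight = colsum.st() % w;
  if (!lambda.is_finite() || !weight.is_finite())
    Rcpp::stop("non-finite exchange generator modes (rates too large?)");
}

// Raw complex FID (no apodization): FID[n] = sum_j [exp(A n dwell) f]_j
// [[Rcpp::export(name = ".bmFidCpp")]]
arma::cx_vec bm_fid_cpp(const arma::vec& omega, const arma::mat& K,
                        const arma::vec& f, const int td,
                        const double dwell) {
  cx_vec lambda, weight;
  bm_modes(omega, K, f, lambda, weight);
  cx_vec z = exp(lambda * dwell);
  cx_vec zpow(z.n_elem, fill::ones);
  cx_vec fid(td);
  for (int n = 0; n < td; ++n) {
    fid(n) = accu(weight % zpow);
    zpow %= z;
  }
  if (!fid.is_finite())
    Rcpp::stop("propagator produced non-finite FID (exchange rates too large?)");
  return fid;
}

// Real part of the apodized DFT over fftshifted bins [j0, j1] (0-based,
// inclusive), evaluated mode-by-mode in closed form:
// S[k] = sum_m c_m (1 - (z_m)^td) / (1 - z_m w_k),  w_k = exp(-2*pi*i*k/td)
// where z_m already contains the exp(-pi*lb*dwell) apodization and the
// shifted bin j corresponds to k = j + td/2 (mod td), i.e. w = -exp(-2*pi*i*j/td).
static vec spectrum_bins(const vec& omega, const mat& K, const vec& f,
                         const int td, const double dwell, const double lb,
                         const int j0, const int j1) {
  cx_vec lambda, weight;
  bm_modes(omega, K, f, lambda, weight);
  const uword nm = lambda.n_elem;
  cx_vec logz = (lambda - datum::pi * lb) * dwell;
  cx_vec z = exp(logz);
  cx_vec num = weight % (1.0 - exp(double(td) * logz));
  // halving the first FID point (standard practice) removes the constant
  // Re[1/(1-e^{i theta})] = 1/2 baseline pedestal of the DFT
  cx_double halfFirst = 0.5 * accu(weight);
  vec out(j1 - j0 + 1);
  const double twopi = 2.0 * datum::pi;
  for (int j = j0; j <= j1; ++j) {
    double ang = -twopi * double(j) / double(td);
    cx_double w(-std::cos(ang), -std::sin(ang));
    cx_double s = -halfFirst;
    for (uword m = 0; m < nm; ++m) {
      cx_double denom = 1.0 - z(m) * w;
      if (std::abs(denom) < 1e-13)
        s += weight(m) * double(td);   // ratio 1: the series sums to td terms
      else
        s += num(m) / denom;
    }
    out(j - j0) = s.real();
  }
  if (!out.is_finite())
    Rcpp::stop("non-finite spectrum (exchange rates too large?)");
  // absorption-mode integral of the halved-first-point DFT is FID[0]/2;
  // scale by 2 so unit magnetization gives unit spectral integral
  return out * (2.0 / double(td));
}

// Processed real spectrum on the full fftshifted grid, scaled so that
// sum(intensity) * dppm = Re(FID[0]) (unit integral for unit magnetization).
// [[Rcpp::export(name = ".bmSpectrumCpp")]]
arma::vec bm_spectrum_cpp(const arma::vec& omega, const arma::mat& K,
                          const arma::vec& f, const int td,
                          const double dwell, const double lb,
                          const double dppm) {
  return spectrum_bins(omega, K, f, td, dwell, lb, 0, td - 1) / dppm;
}

// Full forward model for fitting: spectrum over the extraction window only,
// baseline polynomial, unit-integral normalization, integral scale.
// i0/i1 are 0-based inclusive indices of the window in the fftshifted grid.
// [[Rcpp::export(name = ".forwardSegmentCpp")]]
arma::vec forward_segment_cpp(const arma::vec& omega, const arma::mat& K,
                              const arma::vec& f, const int td,
                              const double dwell, const double lb,
                              const double dppm, const int i0, const int i1,
                              const arma::vec& segAxis,
                              const arma::vec& poly,
                              const double integralScale) {
  if (i0 < 0 || i1 >= td || i1 <= i0)
    Rcpp::stop("invalid extraction window");
  vec seg = spectrum_bins(omega, K, f, td, dwell, lb, i0, i1) / dppm;
  if ((int)segAxis.n_elem != (int)seg.n_elem)
    Rcpp::stop("segment axis length mismatch");
  seg += poly(0) + poly(1) * segAxis + poly(2) * square(segAxis);
  double integral = (accu(seg) - 0.5 * (seg(0) + seg(seg.n_elem - 1))) * dppm;
  if (!(integral > 0))
    Rcpp::stop("non-positive segment integral; cannot normalize");
  return seg * (integralScale / integral);
}
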