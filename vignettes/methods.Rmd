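---
title: "Models and methods: exchange-broadened lineshapes, MCMC fitting and Eyring extrapolation"
author: "glucoExchange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette describes the science inside `glucoExchange`: the exchange
models and their assumptions, the spectrum simulation, the fitting
machinery and its numerical choices, the temperature extrapolation, and
what the synthetic-data tests do and do not demonstrate.

## The physical model

Aqueous glucose is an equilibrium mixture of the alpha and beta anomers at
fractional concentrations 0.36 and 0.64. Each anomer carries five hydroxyl
protons (C1, C2, C3, C4, C6) that exchange with water protons at pseudo
first-order rates $k_\mathrm{ex}$ of order $10$–$10^4\,\mathrm{s^{-1}}$
depending on temperature, pH and buffer. Because the anomeric configuration
perturbs the other hydroxyls detectably, the most economical model that
still fits cold-temperature spectra — the *restricted* model — gives every
site except C6 distinct alpha/beta chemical shifts while sharing one
exchange rate per carbon across anomers: nine shifts, six rates, ten pools
including water.

`buildModel()` computes pool fractions from proton molarities: a split site
contributes $0.36\,c_\mathrm{glc}$ or $0.64\,c_\mathrm{glc}$ protons, C6
contributes $c_\mathrm{glc}$, water contributes $c_\mathrm{w}$ (default
$110.7$ M $= 2 \times 55.35$ M, pure-water protons; the exact value only
rescales the dilute pool fractions). The kinetic matrix $K$ is assembled in
column convention ($K_{ij}$ = rate from pool $j$ into pool $i$) with
$K_{\mathrm{w},i} = k_i$ and the detailed-balance back-rate
$K_{i,\mathrm{w}} = k_i f_i / f_\mathrm{w}$, so columns sum to zero and the
fraction vector is stationary by construction. The `restricted_cross`
variant adds direct OH–OH exchange along (C1,C2), (C2,C3), (C3,C4) within
each anomer with the same detailed-balance closure; with zero cross rates
it reproduces the restricted matrix exactly.

Mutarotation (alpha/beta interconversion) is deliberately not an exchange
pathway: it is orders of magnitude slower than proton exchange. pH enters
only as a label selecting a parameter set; no rate law in pH is modelled.

## Spectrum simulation

The density operator is expanded in the product of the single-spin
Liouville basis $\{E, I_-, I_+, I_z\}$ and the chemical configuration
space, giving a $4N \times 4N$ generator ($40 \times 40$ for the
restricted model): the chemical-shift Hamiltonian contributes
$\pm i\Omega_j$ on the single-quantum blocks and exchange contributes $K$
identically on every spin block. Only the chemical-shift term is kept —
isolated spins in exchanging pools — so the detected $I_-$ block obeys the
Bloch–McConnell equations
$\dot v = (i\,\mathrm{diag}(\Omega) + K)\,v$ exactly; the package
propagates either representation and the test suite asserts their
equality to $10^{-9}$.

No intrinsic relaxation terms are included: linewidths are exchange
broadening plus the processing apodization. For glucose hydroxyls this
neglects an intrinsic width of roughly 7–15 Hz (shrinking with
temperature), which biases fitted rates high by up to about one percent
at the warm end of the measured range — well inside the reported
uncertainties.

Numerical route: because the generator is time-independent, the FID is a
finite sum of complex exponential modes obtained by one eigendecomposition
of the $N \times N$ single-quantum matrix. The discrete Fourier transform
of such a signal has a closed form per frequency bin (a finite geometric
series), so the fitting loop evaluates only the bins of the extraction
window — a few thousand complex divisions per iteration, no FFT. The
closed form and the FFT of the propagated FID agree to machine precision.

Processing conventions, chosen once and used for both simulated and
synthetic "measured" spectra:

* apodization $\exp(-\pi\,\mathrm{lb}\,t)$ (a pure line acquires FWHM =
  lb, default 1 Hz), no zero filling;
* the first FID point is halved before the DFT — the standard correction
  that removes the constant $\tfrac12$ baseline pedestal of a sampled
  decay — and intensities are scaled so unit magnetization integrates to
  one over the ppm axis;
* axis in ppm offsets from water, downfield positive, ascending;
* ideal uniform excitation (equilibrium fractions placed on the
  transverse blocks), phased-real detection of the total $I_-$
  projection.

The hydroxyl window starts at the first local minimum downfield of the
water maximum, located on a 5-point moving-average smoothed copy (the
plain first-minimum rule is noise-fragile), and ends at a configurable
upper edge, default +3.8 ppm from water (8.5 ppm absolute for water at
4.7 ppm). Under the default acquisition (15 ppm sweep, 16384 points,
500 MHz) the window covers ~3600–3800 points. The window is normalized to
unit trapezoid integral; during fitting the model adds its quadratic
baseline polynomial *before* normalizing and multiplies by the integral
scale factor afterwards, so baseline and normalization interact exactly as
they do for the data. The three polynomial coefficients plus the scale
factor (bounded to 0.8–1.2) are the four baseline fitting parameters.

## Fitting: point estimate plus posterior

The error function is $E = T_\mathrm{inv}\,\mathrm{RSS}/Y_\mathrm{SEM}^2$.
With $Y_\mathrm{SEM}$ equal to the 1-sigma noise and
$T_\mathrm{inv} = 0.5$, $\exp(-E)$ is exactly the Gaussian likelihood, so
the sampled intervals are calibrated; all shipped analyses use
$T_\mathrm{inv} = 0.5$ for that reason ($E$ as defined lacks the
conventional $\tfrac12$). When not supplied, $Y_\mathrm{SEM}$ is the
detrended standard deviation of the most-downfield 0.2 ppm of the window,
which is free of hydroxyl signal.

The sampler is single-parameter-at-a-time Metropolis on a bounded box:
per sweep each parameter is perturbed by $\mathrm{unif}(-1,1)\,k_i$,
proposals crossing a bound are reflected at it, moves are accepted when
the error decreases and with probability $\exp(-\Delta E)$ otherwise.
During two adaptation phases the $k_i$ are rescaled every 50 sweeps by
$\exp(\mathrm{acc}_i - 0.5)$ toward 50% acceptance and then frozen for
the production phase (20000 sweeps by default), from which the best fit
(minimum-$E$ sample), 2.5/50/97.5% quantiles and symmetrized 95%
half-widths (half the interquantile range) are reported, along with
per-parameter acceptance fractions and step autocorrelations.

Three structural choices make the sampler usable on heavily overlapped
hydroxyl spectra, whose error surface is glassy (a coordinate chain from
a random start demonstrably stalls at 50–100 times the noise floor within
any practical number of sweeps):

1. **Log-scale rates.** Exchange rates are scale parameters; `fitSpectrum`
   samples $\log_{10} k$ (flat-in-log prior; a linear lower bound of 0
   becomes $0.05\,\mathrm{s^{-1}}$, i.e. no measurable exchange).
   Quantile summaries back-transform exactly.
2. **Mixture and block proposals.** 10% of proposals draw the parameter
   uniformly across its whole box (symmetric, hence Metropolis-exact),
   rescuing parameters stranded on the tilted near-flat plateau where a
   coalesced line's rate has almost no gradient. One coordinated move per
   sweep shifts all log-rates (and all shifts) by a common scalar — the
   valley direction induced by the window normalization, along which
   single-coordinate steps only zig-zag.
3. **Optimizer initialization.** By default the chain starts at a
   multi-start bounded Levenberg–Marquardt solution (centre of the box
   plus random starts) with step sizes seeded from the Gauss–Newton
   curvature, $k_i = 2.4/\sqrt{2 T_\mathrm{inv} (J^\top J)_{ii}}$. The
   chain's job is then measuring the posterior, not global search. An
   annealed burn-in (geometric inverse-temperature ramp, `annealStart`)
   is available for random-start runs.

Bounds policy: at the *initial* stage shift windows are broad and may
overlap except for the unambiguous anchors (anomeric C1 sites downfield,
C6 upfield); at the *assignment_fixed* stage windows are non-overlapping
intervals centred on prior assignments — this is what pins which alpha
peak pairs with which beta peak. Rate windows are wide at both stages;
their ceiling is configuration (`rateUpper`), and for a cold spectrum a
generous-but-sane ceiling (several times the largest expected rate) is
preferable to an astronomically large one, which only adds volume in the
fully coalesced regime.

## Temperature dependence

Each rate group's temperature series is fitted to the Eyring equation
$k = \kappa (k_B T/h) \exp(-\Delta G^\ddagger / RT)$ through its
linearized form $y = \ln(k/T) = a x + b$, $x = 1/T$, solved by the
Moore–Penrose pseudoinverse of the design matrix $[x\ 1]$;
$\Delta G^\ddagger = -Ra$, $\kappa = e^b h/k_B$. The 95% half-widths of
the fitted rates are converted to 1-sigma ($\div 1.96$), propagated
linearly through the logarithm and the pseudoinverse into the covariance
of $(a, b)$ and back out to any temperature; no residual-based inflation
is added, so the bands reflect only the rate uncertainties, taking the
Eyring form as exact. The two-parameter form treats
$\Delta G^\ddagger$ as temperature-independent, with entropy absorbed
into $\kappa$; $\kappa$ values far below unity for the slower sites are
therefore effective, not mechanistic, quantities. Rate tables span
260–310 K in 0.25 K steps (201 rows) with propagated intervals that widen
away from the measured-temperature centroid. Parameter sets derived from
too-sparse series (the pH 7.38 set, two temperatures) carry a caution
flag that marks extrapolated rows.

Constants are CODATA-2018. Note that evaluating rates from *tabulated*
$(\kappa, \Delta G^\ddagger)$ with only marginal errors overstates the
uncertainty badly, because the strong $a$–$b$ anticorrelation is lost;
rate values are unaffected, and `fitEyringLinearized` output carries the
full covariance.

## Virtual CPMG experiments

`simulateCpmgR2` runs $90_x - [\tau - 180_y - \tau]^n$ on the equilibrium
state, with either ideal rotations or finite rectangular pulses (default
B1 = 25 kHz: 10 us / 20 us pulses), detects the total transverse
magnitude through the $J_-$ projection and converts the end/start ratio
to $R_2 = -\ln(M_n/M_0)/(2 n \tau)$; with no other relaxation in the
model the decay is effectively single-exponential, so the two-point ratio
is sufficient. Relaxivity builds the dilute two-site model (solute
fraction $= n_\mathrm{H}\,c_\mathrm{mM}\,10^{-3}/c_\mathrm{w}$, rejected
above 0.05), simulates the published sequence (10 echo periods of 20 ms,
read as $\tau = 10$ ms) and divides by the millimolar concentration; a
5x-concentration cross-check warns if the linear regime is violated. In
the fast-exchange dilute limit the result reproduces the Swift–Connick
form $f_b\,\Delta\omega^2 k/(k^2 + \Delta\omega^2)$ to a few percent;
across fields it grows quadratically while $k \gg \Delta\omega$ and
saturates as $\Delta\omega$ approaches $k$. `cpmgFilteredSpectrum`
applies a short train (default four echo inversions) before acquisition;
the receiver phase is fixed so the zero-delay limit equals the plain
spectrum, and longer half-echo delays imprint the exchange-generated
phase/amplitude patterns useful for verifying fitted rates.

## Synthetic data: what the tests show

`generateTemperatureSeries` emulates the measured series: 1 M glucose in
1x PBS, 11.7 T, 15 ppm sweep, Gaussian noise with SD = (peak hydroxyl
intensity)/SNR added on the real spectrum, a quadratic truth baseline,
and rates following the Eyring law with the published pH-labelled
parameter sets as default truth. Chemical-shift temperature drift
defaults to zero (the real dependence is modest) but a linear drift is
supported for robustness studies. The noise model is i.i.d. on the
processed spectrum — adequate for well-phased post-FT data; correlated
baseline distortions, solvent-suppression artefacts, field drift and
$^{13}$C satellites are *not* emulated, so passing recovery tests
demonstrate correctness of the machinery, not robustness to every
instrumental pathology.

Problem sizes in the shipped tests are scaled for a single CPU: synthetic
fits use 4096-point acquisitions (the closed-form evaluator makes cost
proportional to the window length) with 300 + 200 adaptation and 4000
production sweeps for the coverage check (5 seeds, SNR 200, 270 K-like
truth, requiring on average 12 of 15 spectral parameters inside their
symmetrized 95% intervals) and 1500 production sweeps per spectrum for
the six-temperature pipeline check (activation energies within 5% for at
least 5 of 6 rate groups). The published-scale analysis — 16k points,
20000 production sweeps — is the package default outside the tests.

## Known limitations

* No intrinsic relaxation: rates carry the documented ~1% warm-end bias.
* The assignment of the two C3/C4 shift pairs (and hence which Eyring set
  is "C3") is a best guess; swapping the labels changes nothing but the
  names.
* Cross-exchange rates share the detailed-balance closure of the
  water pathways; their absolute scale is weakly identified by 1D
  lineshapes alone, and the model ladder tests only assert that the data
  give them no support.
* The coordinate sampler's intervals are trustworthy only when the chain
  mixes (check `stepAutocorrelation` and acceptance fractions); for
  strongly correlated posteriors the common-mode rate direction is the
  slowest to decorrelate.
* Concentration dependence of the rates (self-catalysis at molar glucose)
  is outside the model; the shipped parameter sets are for 1 M glucose
  in 1x PBS specifically.
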