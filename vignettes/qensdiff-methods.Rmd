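---
title: "Models and methods in qensdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in qensdiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qensdiff)
```

`qensdiff` implements the analysis chain of a quasi-elastic neutron
scattering (QENS) and molecular-simulation study of a small, self-crowding
intrinsically disordered protein (IDP): a 24-residue, 3.036 kDa cationic
peptide measured on a backscattering spectrometer and simulated as
multi-chain ensembles in periodic boxes.  This vignette documents the
models, the tunable parameters, the synthetic-data generators used as test
substrate, and the numerical choices; it states no empirical result that
the package's tests and acceptance script do not themselves compute.

## The scattering model

The measured scattering function on the (q, energy) grid is modeled as a
Gaussian resolution function `R` convolved with two protein Lorentzians and
a solvent Lorentzian,

    S(q, w) = R (*) { beta(q) [ A0(q) L(gamma) + (1 - A0(q)) L(gamma + Gamma) ]
                      + beta_s(q) L(gamma_s) },

where `L(w)` is a unit Lorentzian of half-width-at-half-maximum `w`.  The
center-of-mass (COM) line follows Fickian diffusion, `gamma = hbar D q^2`,
and the internal line follows the jump-diffusion law
`Gamma = hbar D_int q^2 / (1 + D_int q^2 tau)`, which plateaus at
`hbar / tau` at large q.  `A0(q)` is the elastic incoherent structure
factor (EISF) of the internal motion.  Widths are HWHM throughout: this
convention makes the COM law read `gamma = hbar D q^2` with D in
Angstrom^2/ns and widths in micro-eV (`hbar = 0.6582119569` micro-eV ns),
and is pinned by the consistency of the Stokes-Einstein chain
(`D = 16.8` Angstrom^2/ns at 298 K giving an effective radius near 11.8
Angstrom).

Two fit routes are implemented, mirroring the two-route experimental
analysis:

* **per-q** (`fit_per_q()`): every q slice fitted independently; the COM
  widths `gamma(q)` are then regressed against `hbar q^2` through the
  origin (`extract_D_from_gamma()`).  This is the route of choice for the
  EISF, since `A0(q)` is left completely free.  A caveat the tests
  document: a single slice's free two-Lorentzian decomposition is almost
  exactly degenerate (distinct parameter sets reproduce a slice to a small
  fraction of realistic noise), so per-q parameters are exact on noiseless
  data but scatter systematically at finite noise; slices whose internal
  width has no curvature support are flagged, and quantitative D and
  internal-motion inference should use the global route.
* **global jump-diffusion** (`fit_global()`): one simultaneous fit over the
  whole (q, w) grid with shared `D`, `D_int`, `tau` and per-q amplitudes.
  This is the route of choice for `D`.

### Optimization

Both routes are bounded weighted least squares (weights `1/sigma^2`).  The
decisive structural observation is that, at fixed line widths, the model is
*linear* in `beta A0`, `beta (1 - A0)` and the solvent amplitude, all
constrained non-negative.  The fits therefore profile these amplitudes out
exactly with a tiny non-negative least-squares solve per slice (variable
projection), which confines `A0` to `[0, 1]` by construction and leaves
only width-like parameters to the Levenberg-Marquardt search: two per slice
in the per-q route, and `(D, D_int, tau)` (log-parametrized) globally.
Deterministic multi-starts (width multipliers crossed with two EISF start
envelopes) guard against secondary minima; the lowest weighted SSE wins,
and the best exploration point is re-polished with all nonlinear parameters
free.

Two identifiability hazards of this model class are handled explicitly:

* In the `tau -> 0` limit the model degenerates to two Fickian Lorentzians
  and acquires an exact label-swap symmetry (`A0 <-> 1 - A0` with the two
  lines exchanged).  The global fit therefore constrains `A0(q)` to be
  non-increasing in q by default (`eisf_constraint = "monotone"`), which is
  true of any confined internal motion over this instrument window (the
  sphere EISF is monotone up to its first zero at `qa ~ 4.49`) and removes
  the swapped branch.  Set `eisf_constraint = "free"` for systems where
  this assumption is wrong.
* `D_int` and `tau` trade against each other along the high-q plateau
  (`Gamma ~ hbar/tau`); physical bounds (`D_int <= 500` Angstrom^2/ns,
  `tau` between 0.1 ps and 1 ns) keep this flat direction finite.  At
  realistic noise the internal-motion pair remains the least certain part
  of the fit, and its reported standard errors say so.

Slices whose fitted EISF sits at 1 carry no internal-line weight; `Gamma`
is then unidentifiable and flagged rather than reported.

### Solvent term

The paper-analysis convention for the solvent line is not uniquely
determined, so both options are supported through `solvent_policy()`:
width fixed at `hbar D_solvent q^2` from a known solvent diffusion
coefficient (default, `D_solvent = 187` Angstrom^2/ns for heavy water near
ambient temperature) with free amplitude, or amplitude and width both free.
Spectra are assumed already corrected for container scattering
(absorption corrections are upstream of this package; the spectrum reader
is the no-op hook where such a correction would enter).

## Synthetic spectra

`spectrum_truth()` + `generate_spectrum()` are the forward model of the
same equation, so fitter and generator agree exactly at zero noise (a round
trip the test suite asserts to machine precision).  Defaults emulate the
backscattering experiment: q from 0.2 to 1.8 1/A in 16 steps, energy window
+-30 micro-eV, Gaussian resolution of 0.9 micro-eV FWHM.  The omega step is
0.2 micro-eV, chosen to satisfy the generator's own resolvability rule
(step at most a quarter of the resolution FWHM, which the commonly quoted
0.25 step would narrowly violate).  The default internal-motion EISF is a
sphere-confinement shape with radius 1.2 Angstrom, giving the shallow,
featureless EISF decay (to about 0.4 at the highest q) characteristic of a
disordered chain's effective internal mean free path.

Noise emulates counting statistics on reduced data: zero-mean Gaussian with
standard deviation `noise_scale * sqrt(model)`, the reported uncertainty
equal to that standard deviation.  Each q slice is normalized to unit peak
by default (`normalization = "peak"`), emulating monitor-normalized
reduction; under this convention `noise_scale = 0.02` means 2% noise at the
elastic maximum of every spectrum.  The error bars of the real experiment
come from the instrument reduction chain; this model is a stated stand-in,
not a reconstruction.  A single integer seed expands into per-stream seeds
through a fixed documented scheme, so every generator is bitwise
reproducible.

## Scalar hydrodynamics

All conversions run in Angstrom / ns / micro-eV / K / mPa s units:

* **Viscosity.** Light- and heavy-water viscosities use the thermal-offset
  power law `eta = eta0 (T/Ts - 1)^(-g)` with the published singular
  temperatures (225.334 K for H2O, 231.832 K for D2O); the amplitude and
  exponent are calibrated against standard tabulations and reproduce them
  to better than 1% over 273-363 K.  NaCl corrections use the relative
  viscosity law `exp(XE)/(1 + XV)` on the salt mole fraction, calibrated at
  25 C; at 0.15 M the correction is near 1%.
* **Stokes-Einstein** (`stokes_einstein_radius()` and inverse) and
  **Einstein-Smoluchowski** sphere rotation (`sphere_Dr()`).
* **Empirical IDP relation** between the radius of gyration and the
  hydrodynamic radius for an N-residue disordered chain (`nygaard_rh()`),
  inverted by bracketed root finding.  For the 24-residue chain the
  implied `R_h / R_g` ratio is about 1.06.
* **Perrin factors** for spheroids: the translational friction uses the
  closed-form S-function result (`R_h = 2/S(a, b)`); rotational friction
  uses the general ellipsoid elliptic integrals evaluated by quadrature.
  The closed form and the quadrature agree to 1e-6 in the tests, and both
  collapse to the Stokes sphere exactly at `a = b`.
* **Apparent diffusion** of a rotating, translating scatterer
  (`apparent_diffusion()`): the quasi-elastic spectrum is the Lorentzian
  series with weights `B_l(q) = (2l+1) Int rho_H(r) j_l(qr)^2 dr` and
  widths `hbar (D_t q^2 + l(l+1) D_r)`, truncated when the cumulative
  weight passes `1 - 1e-4`.  The "apparent" width per q is defined as the
  half-width of the best-fitting single Lorentzian over the instrument
  window — matching how the experiment reads a single effective width —
  not an amplitude-weighted mean of widths; a brute-force grid fit pins
  this definition in the tests.  Radial hydrogen profiles are parametric
  (uniform sphere, point); the study's own P(r)-weighted variant used an
  external SAXS distance distribution, which is emulated rather than
  reproduced.
* **Volume fractions**: dry `phi = c nu_p` (concentration per solution
  volume; 50 mg/mL of a 0.7023 mL/g protein gives 0.035, commonly quoted
  rounded as 0.03) with the alternative `c nu_p / (1 + c nu_p)` convention
  selectable; hydrodynamic `phi_h = (R_h/R_g)^3 phi`.
* **Crowding scaling** (`crowding_scale()`): charged-sphere short-time
  laws, translational `1 - a_t phi^(4/3)` with `a_t = 2.5`, rotational
  `1 - a_r phi^2` with `a_r = 1.3`.
* **Fractal mass scaling** (`fractal_predict()`): `D = C M^(-1/d_F)` with
  the family constant C (default 10353, calibrated on an IDP reference
  system); `fractal_dimension_from_saxs()` extracts `d_F` as minus the
  log-log slope of the scattering curve over the fixed high-q window
  2.0-2.8 1/A.

One known inconsistency is handled by exclusion: the study's table of
sphere/ellipsoid diffusion values appears to carry a unit slip of one order
of magnitude, so those printed numbers are not asserted anywhere; the
package reports SI-consistent values.

## Trajectory analysis

`chain_ensemble_trajectory` holds frames x atoms x 3 coordinates in a
periodic cubic box with chain labels and masses; a plain-text XYZ-with-box
dialect provides round-trippable I/O.  The analysis conventions follow the
simulation side of the study:

* **Unwrap -> MSD -> fit** (`unwrap_trajectory()`, `msd()`,
  `fit_diffusion()`): minimum-image continuity, origin-averaged MSD by the
  FFT (Wiener-Khinchin) algorithm with a naive double-loop oracle in the
  tests, and a straight-line fit over the 0-4.6 ns window — the coherence
  time of a 0.9 micro-eV backscattering resolution — with `R^2` reported
  and low values flagged.  Ensemble averaging across chains and replicates
  reports the standard deviation across chains.
* **Finite-size correction** (`yeh_hummer_correct()`):
  `D0 = D_pbc + kB T xi / (6 pi eta L)` with `xi = 2.837297` for cubic
  boxes.  For rhombic-dodecahedral boxes the FCC lattice constant is used
  with L the edge of the enclosing cubic unit cell; no numeric FCC value is
  printed in the study, so the constant is derived from the FCC drag
  coefficient 1.7917 as `xi = 1.7917 (16 pi / 3)^(1/3) = 4.585` (four
  lattice points per conventional cell) and is overridable.  The effective-L
  convention is implemented as stated and flagged for sensitivity analysis.
* **Isotope rescaling** (`isotope_rescale()`): multiply by
  `eta_H2O(T)/eta_D2O(T)` (about 0.81 at 298 K).  Both corrections set
  provenance flags on the estimate and refuse double application.
* **Viscosity** (`viscosity_from_pressure()`): Einstein-Helfand slope of
  the squared time-integrated off-diagonal pressure, times `V/(2 kB T)`,
  averaged over independent components.  The slope window is 5-50
  integrated stress correlation times — past the ballistic bend yet short
  enough to keep many independent blocks; the estimator refuses series
  shorter than that.
* **Clustering** (`min_chain_distance()`, `cluster_chains()`): minimum
  inter-chain atom distances under minimum image (alpha-carbon selection
  when present, all particles for point-chain fixtures), connected
  components at 6 and 7 Angstrom cutoffs, singletons not counted;
  statistics (cluster count, chains participating, largest cluster) are
  reported as time averages.
* **EISF from trajectories** (`eisf_from_trajectory()`): squared modulus of
  the time-averaged `exp(i q . r)` per scatterer, averaged over scatterers
  and 64 (default) seeded uniform q directions, with per-chain COM removal
  on by default — the experimental EISF rides on a separate COM Lorentzian,
  so only internal motion belongs in `A0`.  The hydrogen selection is an
  argument (`selection`), since whether exchanged hydrogens were excluded
  in the study is a detail its supplement holds.
* **Per-snapshot size-to-diffusion distributions**
  (`rg_series()`, `dt_distribution_from_rg()`): per-frame mass-weighted
  radius of gyration, mapped through the IDP relation and Stokes-Einstein
  and divided by the mean, giving the reduced distribution whose width
  reflects size heterogeneity only — by construction narrower than any
  distribution carrying additional shape heterogeneity.
* **Diffusion autocorrelation** (`diffusion_autocorrelation()`): the
  variance-normalized estimator `C(k) = sum (D_i - Dbar)(D_{i+k} - Dbar) /
  sum (D_i - Dbar)^2`, so `C(0) = 1`, matching the 0-1 range of the
  study's autocorrelation figures.

## Synthetic trajectories and pressure series

* `generate_brownian_chains()`: independent Gaussian random walks of chain
  centers (per-component step variance `2 D_t dt`) wrapped into the box.
  Chains do not interact — cluster logic is tested on hand-placed
  configurations instead.
* `generate_confined_hydrogens()`: Brownian motion confined to spheres.
  The boundary is handled by a Metropolis-style reject-and-stay step, whose
  stationary distribution is exactly uniform in the ball; that makes the
  closed-form sphere EISF `[3 j1(qa)/(qa)]^2` an analytic oracle for the
  whole trajectory-EISF chain.  Atoms are initialized in equilibrium, and
  proposals larger than `a/5` rms are refused.
* `generate_pressure_series()`: a stationary Ornstein-Uhlenbeck process
  whose Green-Kubo integral `V Var tau_c / (kB T)` equals the target
  viscosity analytically, giving the viscosity estimator a known truth.

## What the synthetic data do and do not show

The generators reproduce the *statistical structure* the estimators assume:
Lorentzian lines under a Gaussian resolution with counting-like noise,
Gaussian COM displacements, uniform confined equilibrium, exponentially
correlated stress.  Passing tests therefore demonstrate correctness of the
estimators and conventions, not robustness to everything real data add:
non-Gaussian resolution wings, correlated detector noise, inter-chain
hydrodynamic interactions, conformational dynamics coupling size and shape,
and aggregation.  Conclusions about real systems should lean on the
reported uncertainties and flags, which are calibrated on these synthetic
conditions.

At the default study conditions (2% peak noise), the Monte-Carlo suite
runs the full global fit across 50 seeds and tests the reduced
goodness-of-fit distribution (centered at 1) and the bias of each recovered
parameter against the generator truth.  The COM diffusion comes back
accurate at the percent level with a small finite-noise curvature bias that
shrinks quadratically with the noise level.  The internal-motion pair is
the weak point of the model class: the residence time estimator is
positively skewed at this noise level (its plateau direction trades
`D_int` against `tau`), a genuine property of weighted least squares on a
+-30 micro-eV window that the bias test reports rather than hides; the
per-fit standard errors of `D_int` and `tau` are correspondingly large.

## Problem sizes and runtimes

The test suite and acceptance checks choose sizes that exercise every code
path at desk scale: 16-q default spectra (8-q reduced grids where many
replicate fits are needed), 50-seed Monte-Carlo for the global fit,
10-chain x 5-replicate Brownian ensembles, 1e5-sample equilibrium checks
for the confined generator, 2e5-step (1e6 for the acceptance property)
pressure series, and 200 random frames for the clustering oracle.  Each
suite runs in minutes on one core.
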