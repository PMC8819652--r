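#' Ground truth for a synthetic QENS spectrum
#'
#' Holds every generator-side parameter of the scattering model: apparent
#' center-of-mass diffusion, internal jump diffusion, EISF shape, per-q
#' amplitudes, solvent term, resolution, grids, noise level, and seed.
#' Defaults emulate a backscattering experiment on a small IDP:
#' q from 0.2 to 1.8 1/A in 16 steps, energy window +-30 micro-eV with a
#' 0.2 micro-eV step, Gaussian resolution of 0.9 micro-eV FWHM.
#'
#' @param D_apparent center-of-mass diffusion, A^2/ns (> 0)
#' @param D_int internal jump diffusion, A^2/ns (> 0)
#' @param tau residence time, ns (> 0)
#' @param eisf_model `"sphere"` (EISF `[3 j1(qa)/(qa)]^2`) or `"constant"`
#' @param eisf_radius confinement radius a, A (sphere model)
#' @param eisf_value constant EISF value (constant model)
#' @param beta_q per-q protein amplitude (scalar recycled or vector)
#' @param solvent_amplitude per-q solvent amplitude (scalar or vector)
#' @param solvent_width solvent Lorentzian HWHM, micro-eV
#' @param resolution_fwhm Gaussian resolution FWHM, micro-eV
#' @param q_grid momentum transfers, 1/A, strictly increasing in [0.05, 3]
#' @param omega_grid energy transfers, micro-eV, symmetric about 0
#' @param noise_scale counting-noise scale (sd = noise_scale * sqrt(model));
#'   under the default peak normalization this is the relative noise at the
#'   elastic maximum of every spectrum
#' @param normalization `"peak"` (default) rescales each q slice so its
#'   noiseless maximum is 1, emulating monitor-normalized reduced data;
#'   `"none"` keeps the raw amplitudes
#' @param seed integer RNG seed
#' @return object of class `"spectrum_truth"`
#' @export
spectrum_truth <- function(D_apparent = 17, D_int = 30, tau = 0.02,
                           eisf_model = c("sphere", "constant"),
                           eisf_radius = 1.2, eisf_value = 0.6,
                           beta_q = 1, solvent_amplitude = 0.05,
                           solvent_width = 80, resolution_fwhm = 0.9,
                           q_grid = seq(0.2, 1.8, length.out = 16),
                           omega_grid = seq(-30, 30, by = 0.2),
                           noise_scale = 0.02,
                           normalization = c("peak", "none"), seed = 1L) {
  eisf_model <- match.arg(eisf_model)
  normalization <- match.arg(normalization)
  stopifnot(D_apparent > 0, D_int > 0, tau > 0, resolution_fwhm > 0,
            all(solvent_width > 0), noise_scale >= 0,
            all(diff(q_grid) > 0), min(q_grid) >= 0.05, max(q_grid) <= 3)
  if (max(abs(sort(omega_grid) + rev(sort(omega_grid)))) > 1e-9) {
    stop("omega_grid must be symmetric about 0")
  }
  nq <- length(q_grid)
  structure(list(
    D_apparent = D_apparent, D_int = D_int, tau = tau,
    eisf_model = eisf_model, eisf_radius = eisf_radius,
    eisf_value = eisf_value,
    beta_q = rep_len(beta_q, nq),
    solvent_amplitude = rep_len(solvent_amplitude, nq),
    solvent_width = rep_len(solvent_width, nq),
    resolution_fwhm = resolution_fwhm,
    q_grid = q_grid, omega_grid = omega_grid,
    noise_scale = noise_scale, normalization = normalization,
    seed = as.integer(seed)),
    class = "spectrum_truth")
}

#' EISF of a spectrum truth record
#' @param truth a [spectrum_truth()]
#' @return per-q EISF values
#' @export
truth_eisf <- function(truth) {
  switch(truth$eisf_model,
         sphere   = eisf_sphere(truth$q_grid, truth$eisf_radius),
         constant = rep(truth$eisf_value, length(truth$q_grid)))
}

#' Noiseless forward model of a spectrum truth
#'
#' Evaluates the resolution-convolved scattering model at every (q, omega)
#' of the truth record, with widths `gamma = hbar*D*q^2` and
#' `Gamma = hbar*D_int*q^2/(1 + D_int*q^2*tau)`.
#'
#' @param truth a [spectrum_truth()]
#' @return intensity matrix `length(q_grid) x length(omega_grid)`
#' @export
spectrum_forward_model <- function(truth) {
  A0 <- truth_eisf(truth)
  gam <- fick_width(truth$D_apparent, truth$q_grid)
  Gam <- jump_width(truth$D_int, truth$tau, truth$q_grid)
  plan <- .conv_plan(truth$omega_grid, truth$resolution_fwhm)
  wp <- plan$omega_pad
  y_pad <- vapply(seq_along(truth$q_grid), function(i) {
    truth$beta_q[i] * (A0[i] * lorentzian(wp, gam[i]) +
                         (1 - A0[i]) * lorentzian(wp, gam[i] + Gam[i])) +
      truth$solvent_amplitude[i] * lorentzian(wp, truth$solvent_width[i])
  }, numeric(length(wp)))
  m <- t(.conv_apply(plan, y_pad))
  if (identical(truth$normalization, "peak")) {
    peaks <- apply(m, 1, max)
    m <- m / peaks
  }
  m
}

#' Generate a synthetic QENS spectrum
#'
#' Adds zero-mean Gaussian counting noise with standard deviation
#' `noise_scale * sqrt(model)` to the noiseless forward model; the reported
#' uncertainties equal that standard deviation.  Identical truth (including
#' seed) gives bitwise-identical output.  With `noise_scale = 0` the
#' intensities equal the forward model exactly and unit uncertainties are
#' reported (uniform weights).
#'
#' @param truth a [spectrum_truth()]
#' @return a [qens_spectrum()] carrying the truth record
#' @export
generate_spectrum <- function(truth) {
  model <- spectrum_forward_model(truth)
  if (truth$noise_scale > 0) {
    sigma <- truth$noise_scale * sqrt(pmax(model, 0))
    noise <- .with_stream_seed(truth$seed, "spectrum",
                               matrix(stats::rnorm(length(model)), nrow(model)))
    intensity <- model + sigma * noise
    sigma[sigma <= 0] <- min(sigma[sigma > 0])
  } else {
    intensity <- model
    sigma <- matrix(1, nrow(model), ncol(model))
  }
  qens_spectrum(truth$q_grid, truth$omega_grid, intensity, sigma,
                truth$resolution_fwhm, truth = truth)
}
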