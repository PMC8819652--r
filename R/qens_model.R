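#' Unit-normalized Lorentzian line shape
#'
#' `L(x; w) = w / (pi * (x^2 + w^2))` with half-width at half-maximum `w`.
#'
#' @param x energy transfer, micro-eV
#' @param hwhm half-width at half-maximum, micro-eV (> 0)
#' @return density values, 1/micro-eV
#' @export
lorentzian <- function(x, hwhm) {
  if (any(hwhm <= 0)) stop("Lorentzian half-width must be > 0")
  hwhm / (pi * (x^2 + hwhm^2))
}

#' Quasi-elastic line widths of the diffusion models
#'
#' `fick_width()` is the Fickian center-of-mass width `gamma = hbar*D*q^2`;
#' `jump_width()` the jump-diffusion internal width
#' `Gamma = hbar*D_int*q^2 / (1 + D_int*q^2*tau)`, which plateaus at
#' `hbar/tau` for large q.
#'
#' @param D,D_int diffusion coefficients, A^2/ns (>= 0)
#' @param tau residence time between jumps, ns (> 0)
#' @param q momentum transfer, 1/A
#' @return half-width, micro-eV
#' @examples
#' fick_width(16.8, 1.0)        # 11.058
#' jump_width(30, 0.02, 1.0)    # 12.34
#' @export
fick_width <- function(D, q) {
  stopifnot(all(D >= 0))
  physical_constants$hbar_ueV_ns * D * q^2
}

#' @rdname fick_width
#' @export
jump_width <- function(D_int, tau, q) {
  stopifnot(all(D_int >= 0))
  if (any(tau <= 0)) stop("residence time tau must be > 0")
  physical_constants$hbar_ueV_ns * D_int * q^2 / (1 + D_int * q^2 * tau)
}

#' EISF of diffusion confined to a sphere
#'
#' Closed form `A0(q) = [3 j1(qa) / (qa)]^2` for a scatterer diffusing
#' inside an impermeable sphere of radius `a`.
#'
#' @param q momentum transfer, 1/A
#' @param a confinement radius, A
#' @return elastic fraction in `[0, 1]`
#' @export
eisf_sphere <- function(q, a) {
  x <- q * a
  out <- rep(1, length(x))
  nz <- x > 1e-8
  out[nz] <- (3 * .sph_bessel_j(1L, x[nz]) / x[nz])^2
  out
}

# --- resolution convolution -------------------------------------------------

# Precompute a padded-grid convolution plan for a uniform omega grid and a
# Gaussian resolution of the given FWHM.  The model is evaluated directly on
# the padded grid (no zero padding of data), so edge behavior is correct,
# and convolved by FFT with the circularly shifted kernel.
.conv_plan <- function(omega, resolution_fwhm) {
  h <- diff(omega)
  if (max(h) - min(h) > 1e-8 * max(abs(h))) {
    stop("omega grid must be uniform for the resolution convolution")
  }
  h <- h[1]
  if (h > resolution_fwhm / 4) {
    stop("omega grid step ", signif(h, 3), " micro-eV is coarser than ",
         "resolution_fwhm/4 = ", signif(resolution_fwhm / 4, 3),
         "; the resolution function would be unresolvable")
  }
  sigma <- resolution_fwhm / (2 * sqrt(2 * log(2)))
  n <- length(omega)
  n_pad <- ceiling(6 * sigma / h) + 32L
  # round the padded length up to a highly composite size for the FFT
  n_tot <- stats::nextn(n + 2L * n_pad, c(2, 3, 5))
  n_left <- (n_tot - n) %/% 2L
  omega_pad <- seq(omega[1] - n_left * h, by = h, length.out = n_tot)
  # centered Gaussian kernel on the padded grid, circularly shifted to 0
  x <- (c(0:(n_tot %/% 2), -((n_tot - n_tot %/% 2 - 1):1))) * h
  kern <- exp(-x^2 / (2 * sigma^2))
  kern <- kern / sum(kern)                  # discrete flux conservation
  list(omega_pad = omega_pad, kern_fft = stats::fft(kern),
       keep = (n_left + 1L):(n_left + n), n_tot = n_tot, h = h)
}

# convolve columns of a matrix of model curves sampled on plan$omega_pad
.conv_apply <- function(plan, y_pad) {
  y_pad <- as.matrix(y_pad)
  out <- Re(stats::mvfft(stats::mvfft(y_pad) * plan$kern_fft,
                         inverse = TRUE)) / plan$n_tot
  out[plan$keep, , drop = FALSE]
}

#' Evaluate the scattering model at one q
#'
#' Computes the resolution-convolved model
#' `R (*) { beta * [A0 * L(gamma) + (1 - A0) * L(gamma + Gamma)] +
#'  beta_s * L(gamma_s) }` on an energy grid, where `L` is a unit Lorentzian,
#' `gamma` the center-of-mass width, `Gamma` the internal width, `A0` the
#' EISF, `beta_s`/`gamma_s` the solvent amplitude and width, and `R` a
#' Gaussian resolution function of the given FWHM.  The convolution is done
#' by FFT on a padded uniform grid and conserves integrated flux.
#'
#' @param omega energy-transfer grid, micro-eV (uniform)
#' @param beta protein amplitude scalar (>= 0)
#' @param A0 EISF value in `[0, 1]`
#' @param gamma center-of-mass Lorentzian HWHM, micro-eV (> 0)
#' @param Gamma_int internal Lorentzian HWHM added to `gamma`, micro-eV (>= 0)
#' @param solvent_amplitude solvent amplitude scalar (>= 0)
#' @param solvent_width solvent Lorentzian HWHM, micro-eV (> 0)
#' @param resolution_fwhm Gaussian resolution FWHM, micro-eV; `0` means a
#'   delta-function resolution (no convolution)
#' @return intensity values on `omega`
#' @export
model_spectrum <- function(omega, beta, A0, gamma, Gamma_int,
                           solvent_amplitude = 0, solvent_width = 1,
                           resolution_fwhm = 0.9) {
  stopifnot(beta >= 0, A0 >= 0, A0 <= 1, gamma > 0, Gamma_int >= 0,
            solvent_amplitude >= 0)
  unconv <- function(w) {
    y <- beta * (A0 * lorentzian(w, gamma) +
                   (1 - A0) * lorentzian(w, gamma + Gamma_int))
    if (solvent_amplitude > 0) {
      y <- y + solvent_amplitude * lorentzian(w, solvent_width)
    }
    y
  }
  if (resolution_fwhm == 0) return(unconv(omega))
  plan <- .conv_plan(omega, resolution_fwhm)
  drop(.conv_apply(plan, unconv(plan$omega_pad)))
}
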