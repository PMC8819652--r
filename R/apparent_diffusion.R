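#' Radial hydrogen density profiles
#'
#' A normalized radial density `rho_H(r)` of the incoherent scatterers
#' (hydrogens) about the molecular center, used to weight the rotational
#' Lorentzian series.  `profile_uniform_sphere()` gives the density of a
#' homogeneously filled sphere, `profile_point()` a point-like scatterer at
#' the center, and `hydrogen_radial_profile()` wraps an arbitrary tabulated
#' density (renormalized to unit integral).
#'
#' @param r_grid radii, A (strictly increasing, starting at or near 0)
#' @param rho_H density values on `r_grid` (>= 0)
#' @param a sphere radius, A
#' @param n number of grid points
#' @return object of class `"hydrogen_radial_profile"`
#' @export
hydrogen_radial_profile <- function(r_grid, rho_H) {
  stopifnot(length(r_grid) == length(rho_H), all(diff(r_grid) > 0),
            all(rho_H >= 0))
  z <- .trapz(r_grid, rho_H)
  if (z <= 0) stop("profile has zero integral")
  structure(list(r = r_grid, rho = rho_H / z),
            class = "hydrogen_radial_profile")
}

#' @rdname hydrogen_radial_profile
#' @export
profile_uniform_sphere <- function(a, n = 400L) {
  r <- seq(0, a, length.out = n)
  hydrogen_radial_profile(r, 3 * r^2 / a^3)
}

#' @rdname hydrogen_radial_profile
#' @export
profile_point <- function() {
  structure(list(r = 0, rho = NULL, point = TRUE),
            class = "hydrogen_radial_profile")
}

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

# spherical Bessel function of the first kind, vectorized in x, order l >= 0
.sph_bessel_j <- function(l, x) {
  out <- numeric(length(x))
  small <- x < 1e-8
  out[small] <- if (l == 0L) 1 else 0
  xs <- x[!small]
  if (length(xs)) out[!small] <- sqrt(pi / (2 * xs)) * besselJ(xs, l + 0.5)
  out
}

# rotational weights B_l(q) = (2l+1) * int rho_H(r) j_l(qr)^2 dr, truncated
# when the cumulative weight exceeds 1 - trunc_tol (identity sum_l B_l = 1)
.rotational_weights <- function(profile, q, l_max = 100L, trunc_tol = 1e-4) {
  if (isTRUE(profile$point)) return(1)
  B <- numeric(0)
  for (l in 0:l_max) {
    jl2 <- .sph_bessel_j(l, q * profile$r)^2
    B <- c(B, (2 * l + 1) * .trapz(profile$r, profile$rho * jl2))
    if (sum(B) > 1 - trunc_tol) return(B / sum(B))
  }
  stop("rotational Lorentzian series not converged by l = ", l_max,
       " at q = ", q)
}

# best single-Lorentzian (amplitude + HWHM) least-squares fit to a curve on
# a symmetric omega window; returns the HWHM
.single_lorentzian_hwhm <- function(omega, y, start_hwhm) {
  fit <- minpack.lm::nls.lm(
    par = c(log_A = log(max(sum(y) * mean(diff(omega)), 1e-12)),
            log_w = log(start_hwhm)),
    fn = function(p) {
      A <- exp(p[["log_A"]]); w <- exp(p[["log_w"]])
      A * lorentzian(omega, w) - y
    },
    control = minpack.lm::nls.lm.control(maxiter = 200))
  exp(fit$par[["log_w"]])
}

#' Apparent diffusion coefficient of a rotating and translating scatterer
#'
#' A quasi-elastic experiment analysed with a single Lorentzian sees a
#' superposition of Lorentzians of widths
#' `hbar*(D_t*q^2 + l*(l+1)*D_r)` weighted by
#' `B_l(q) = (2l+1) * int rho_H(r) j_l(qr)^2 dr`.  This function builds that
#' superposition on a dense energy grid over the instrument window, extracts
#' the apparent half-width per q as the half-width of the best-fitting single
#' Lorentzian, and converts the widths back to a diffusion coefficient by a
#' least-squares fit of `hbar*D*q^2` through the origin.  Rotation only
#' broadens, so the result is always `>= D_t`.
#'
#' @param D_t translational diffusion, A^2/ns
#' @param D_r rotational diffusion, 1/ns
#' @param profile a [hydrogen_radial_profile()]
#' @param q_range q values sampled across the instrument window, 1/A
#' @param omega_max half-width of the energy window, micro-eV
#' @param n_omega dense-grid size per spectrum
#' @return apparent diffusion coefficient, A^2/ns
#' @export
apparent_diffusion <- function(D_t, D_r, profile,
                               q_range = seq(0.2, 1.8, length.out = 9),
                               omega_max = 30, n_omega = 601L) {
  stopifnot(D_t > 0, D_r >= 0)
  if (D_r == 0) return(D_t)
  hbar <- physical_constants$hbar_ueV_ns
  omega <- seq(-omega_max, omega_max, length.out = n_omega)
  gamma_app <- vapply(q_range, function(q) {
    B <- .rotational_weights(profile, q)
    if (length(B) == 1L) return(hbar * D_t * q^2)
    widths <- hbar * (D_t * q^2 + (seq_along(B) - 1) * seq_along(B) * D_r)
    y <- colSums(B * t(vapply(widths, function(w) lorentzian(omega, w),
                              numeric(n_omega))))
    .single_lorentzian_hwhm(omega, y, start_hwhm = widths[1])
  }, numeric(1))
  # weighted (uniform) straight-line fit of gamma against hbar*q^2 through 0
  x <- hbar * q_range^2
  sum(x * gamma_app) / sum(x^2)
}
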