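#' Protein volume fractions
#'
#' `volume_fraction()` converts a protein concentration and partial specific
#' volume to the dry volume fraction.  Two conventions are supported: the
#' default `"solution"` convention `phi = c * nu_p` (concentration per
#' solution volume, the convention consistent with a 50 mg/mL system at
#' phi = 0.035, or 0.03 once rounded as commonly quoted) and the
#' `"solvent"` convention `phi = c*nu_p / (1 + c*nu_p)`.
#' `hydrodynamic_volume_fraction()` rescales the dry fraction by the cubed
#' ratio of hydrodynamic to gyration radius, `phi_h = (R_h/R_g)^3 * phi`,
#' accounting for the hydration shell dragged along by center-of-mass
#' diffusion.
#'
#' @param c_p protein concentration, mg/mL
#' @param nu_p partial specific volume, mL/g (default 0.7023, Histatin 5)
#' @param convention `"solution"` (default) or `"solvent"`
#' @param phi dry volume fraction
#' @param R_h hydrodynamic radius, A
#' @param R_g radius of gyration, A
#' @return a volume fraction in `[0, 1]`
#' @examples
#' volume_fraction(50)                      # 0.0351
#' hydrodynamic_volume_fraction(0.03, 14.61, 13.8)
#' @export
volume_fraction <- function(c_p, nu_p = 0.7023,
                            convention = c("solution", "solvent")) {
  convention <- match.arg(convention)
  stopifnot(c_p >= 0, nu_p > 0)
  x <- c_p / 1000 * nu_p                    # mg/mL -> g/mL times mL/g
  if (convention == "solution") x else x / (1 + x)
}

#' @rdname volume_fraction
#' @export
hydrodynamic_volume_fraction <- function(phi, R_h, R_g) {
  stopifnot(phi >= 0, R_h > 0, R_g > 0)
  phi_h <- (R_h / R_g)^3 * phi
  if (phi_h > 1) warning("phi_h = ", signif(phi_h, 4), " > 1 is unphysical")
  phi_h
}

#' Short-time crowding reduction of a dilute diffusion coefficient
#'
#' Charged-sphere short-time scaling laws: the translational branch applies
#' `D0 * (1 - a_t * phi_h^(4/3))`, the rotational branch
#' `D0 * (1 - a_r * phi_h^2)`, with defaults a_t = 2.5, a_r = 1.3.
#'
#' @param D0 dilute-limit diffusion coefficient (A^2/ns or 1/ns)
#' @param phi_h effective hydrodynamic volume fraction, in `[0, 1)`
#' @param params a [scaling_params()]
#' @param branch `"translational"` or `"rotational"`
#' @return the scaled diffusion coefficient
#' @examples
#' crowding_scale(22.4, 0.03)   # 21.9 A^2/ns
#' @export
crowding_scale <- function(D0, phi_h, params = scaling_params(),
                           branch = c("translational", "rotational")) {
  branch <- match.arg(branch)
  stopifnot(phi_h >= 0, phi_h < 1)
  factor <- if (branch == "translational") {
    1 - params$a_t * phi_h^(4 / 3)
  } else {
    1 - params$a_r * phi_h^2
  }
  if (factor <= 0) {
    stop("crowding reduction factor <= 0 at phi_h = ", phi_h,
         "; outside the validity of the short-time scaling law")
  }
  D0 * factor
}

#' Fractal-dimension mass-scaling model of diffusion
#'
#' Empirical relation `D = C * M^(-1/d_F)` between the diffusion coefficient,
#' the molecular mass M (Da) and the fractal (mass-scaling) dimension d_F of
#' the chain, with a family constant C.  `fractal_predict()` evaluates the
#' relation; `fractal_calibrate()` inverts the linearized form
#' `log D = log C - (1/d_F) log M` for C.
#'
#' @param model a [fractal_model()]
#' @param C family constant (default 10353, calibrated on an IDP reference)
#' @param d_F fractal dimension, in (1, 3]
#' @param M molecular mass, Da
#' @param D diffusion coefficient, A^2/ns
#' @return `fractal_predict()`: D in A^2/ns; `fractal_calibrate()`: C
#' @examples
#' fractal_predict(fractal_model(d_F = 1.45, M = 3036))
#' @export
fractal_model <- function(d_F, M, C = 10353) {
  stopifnot(d_F > 1, d_F <= 3, C > 0, M > 0)
  structure(list(C = C, d_F = d_F, M = M), class = "fractal_model")
}

#' @rdname fractal_model
#' @export
fractal_predict <- function(model) {
  model$C * model$M^(-1 / model$d_F)
}

#' @rdname fractal_model
#' @export
fractal_calibrate <- function(D, M, d_F) {
  stopifnot(D > 0, M > 0, d_F > 1)
  exp(log(D) + log(M) / d_F)
}

#' Fractal dimension from the high-q slope of a scattering curve
#'
#' Straight-line fit of `log I` against `log q` inside a fixed high-q window;
#' the fractal dimension is minus the slope.  The default window matches the
#' wide-angle region used for disordered-chain mass scaling.
#'
#' @param q scattering vector, 1/A
#' @param intensity intensities (> 0), arbitrary units
#' @param q_min,q_max fit window bounds, 1/A
#' @return fractal dimension d_F
#' @examples
#' q <- seq(1.8, 3.0, by = 0.02)
#' fractal_dimension_from_saxs(q, q^-1.5)   # 1.5
#' @export
fractal_dimension_from_saxs <- function(q, intensity,
                                        q_min = 2.0, q_max = 2.8) {
  keep <- q >= q_min & q <= q_max & is.finite(intensity)
  if (sum(keep) < 5) stop("fewer than 5 points in the fit window [",
                          q_min, ", ", q_max, "] 1/A")
  if (any(intensity[keep] <= 0)) stop("non-positive intensities in window")
  fit <- stats::lm(log(intensity[keep]) ~ log(q[keep]))
  -unname(stats::coef(fit)[2])
}

#' Rescale translational to apparent diffusion by a fixed ratio
#'
#' The apparent diffusion coefficient seen by a single-Lorentzian analysis
#' exceeds the purely translational one; when the full rotational
#' deconvolution is not warranted, a fixed literature ratio `D/D_t` can be
#' applied instead (e.g. 1.27 measured on an IDP of comparable class, or
#' ~1.7 from an ellipsoid model).
#'
#' @param D_t translational diffusion, A^2/ns
#' @param ratio apparent-to-translational ratio (> 0)
#' @return apparent diffusion, A^2/ns
#' @examples
#' apply_apparent_ratio(10.7, 1.27)   # 13.6
#' @export
apply_apparent_ratio <- function(D_t, ratio) {
  stopifnot(ratio > 0)
  D_t * ratio
}
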