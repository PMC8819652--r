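#' Empirical IDP relation between radius of gyration and hydrodynamic radius
#'
#' Forward relation
#' `Rh = Rg / (a1*(Rg - a2*N^0.33)/(N^0.60 - N^0.33) + a3)` for a disordered
#' chain of `N` residues; `nygaard_rg_inverse()` inverts it numerically on
#' the physical branch by bracketed root finding.
#'
#' @param R_g radius of gyration, A
#' @param R_h hydrodynamic radius, A
#' @param N number of residues (>= 2)
#' @param bracket search interval in A for the inverse
#' @return radius in A
#' @examples
#' nygaard_rh(13.8, 24)          # 14.61 A
#' nygaard_rg_inverse(11.8, 24)  # ~6.0 A
#' @export
nygaard_rh <- function(R_g, N) {
  stopifnot(all(R_g > 0), N >= 2)
  co <- .nygaard_coefficients
  denom <- N^0.60 - N^0.33
  ratio_inv <- co$alpha1 * (R_g - co$alpha2 * N^0.33) / denom + co$alpha3
  if (any(ratio_inv <= 0)) {
    stop("Rg outside the physical branch of the IDP Rg-Rh relation")
  }
  R_g / ratio_inv
}

#' @rdname nygaard_rh
#' @export
nygaard_rg_inverse <- function(R_h, N, bracket = c(0.1, 200)) {
  stopifnot(R_h > 0, N >= 2)
  f <- function(rg) nygaard_rh(rg, N) - R_h
  lo <- f(bracket[1]); hi <- f(bracket[2])
  if (is.na(lo) || is.na(hi) || lo * hi > 0) {
    stop("no root of the Rg-Rh relation in the bracket [",
         bracket[1], ", ", bracket[2], "] A")
  }
  stats::uniroot(f, bracket, tol = 1e-9)$root
}

#' Ellipsoid-of-revolution shape
#'
#' @param a polar semiaxis, A
#' @param b equatorial semiaxis, A (prolate when a > b, oblate when a < b)
#' @return object of class `"ellipsoid_shape"`
#' @export
ellipsoid_shape <- function(a, b) {
  stopifnot(a > 0, b > 0)
  structure(list(a = a, b = b), class = "ellipsoid_shape")
}

# Perrin S-function (units 1/length) for a spheroid with polar semiaxis a,
# equatorial semiaxis b; S -> 2/a for the sphere.
.perrin_S <- function(a, b) {
  if (abs(a - b) < 1e-9 * max(a, b)) return(2 / a)
  if (a > b) {
    xi <- sqrt(a^2 - b^2)
    2 / xi * log((a + xi) / b)
  } else {
    xi <- sqrt(b^2 - a^2)
    2 / xi * atan(xi / a)
  }
}

#' Perrin translational and rotational diffusion of a spheroid
#'
#' Translational friction uses the closed-form orientation-averaged Perrin
#' result; the equivalent hydrodynamic radius is `R_h = 2/S(a, b)` with the
#' Perrin S-function, so that `D_t = kB*T/(6*pi*eta*R_h)`.  Rotational
#' diffusion is computed from the general-ellipsoid friction tensor
#' (elliptic integrals, evaluated by quadrature) and returned as the
#' orientation average `(D_a + 2*D_b)/3` over the symmetry and equatorial
#' axes.
#'
#' @param shape an [ellipsoid_shape()]
#' @param ctx a [hydro_context()]
#' @return `perrin_translational()`: list with `D_t` (A^2/ns) and
#'   `R_h_equiv` (A); `perrin_rotational()`: list with the per-axis and
#'   mean rotational diffusion coefficients (1/ns)
#' @examples
#' ctx <- hydro_context(298, "D2O")
#' perrin_translational(ellipsoid_shape(32.9, 5), ctx)$R_h_equiv  # 12.65 A
#' @export
perrin_translational <- function(shape, ctx) {
  R_h <- 2 / .perrin_S(shape$a, shape$b)
  list(D_t = stokes_einstein_D(R_h, ctx), R_h_equiv = R_h)
}

# elliptic integrals chi = int dt/Delta and alpha_i = int dt/((a_i^2+t)Delta)
# for semiaxes (a, b, b); Delta = sqrt((a^2+t)(b^2+t)^2)
.ellipsoid_integrals <- function(a, b) {
  delta <- function(t) sqrt(a^2 + t) * (b^2 + t)
  # substitute t = s/(1-s) to map [0, Inf) to [0, 1)
  quad <- function(f) {
    stats::integrate(function(s) f(s / (1 - s)) / (1 - s)^2, 0, 1,
                     rel.tol = 1e-10, subdivisions = 500L)$value
  }
  list(chi     = quad(function(t) 1 / delta(t)),
       alpha_a = quad(function(t) 1 / ((a^2 + t) * delta(t))),
       alpha_b = quad(function(t) 1 / ((b^2 + t) * delta(t))))
}

#' @rdname perrin_translational
#' @export
perrin_rotational <- function(shape, ctx) {
  a <- shape$a; b <- shape$b
  ints <- .ellipsoid_integrals(a, b)
  kT6 <- .stokes_prefactor_A3_ns(ctx)          # kB*T/(6*pi*eta), A^3/ns
  # rotational friction about axis i: 16*pi*eta*(aj^2+ak^2)/(3*(aj^2 aj + ...))
  # expressed via kT6: D_r,i = kT * 3 (aj^2 alpha_j + ak^2 alpha_k) /
  #                            (16 pi eta (aj^2 + ak^2))
  pref <- kT6 * 6 / 16 * 3                      # = kB*T*3/(16*pi*eta)
  D_a <- pref * (2 * b^2 * ints$alpha_b) / (2 * b^2)
  D_b <- pref * (a^2 * ints$alpha_a + b^2 * ints$alpha_b) / (a^2 + b^2)
  list(D_r_polar = D_a, D_r_equatorial = D_b, D_r = (D_a + 2 * D_b) / 3)
}

#' Translational Perrin friction factor
#'
#' Ratio of the spheroid friction to that of the equal-volume sphere;
#' >= 1 with equality only for the sphere.
#'
#' @param shape an [ellipsoid_shape()]
#' @return dimensionless friction ratio
#' @export
perrin_friction_factor <- function(shape) {
  R_equiv_volume <- (shape$a * shape$b^2)^(1 / 3)
  (2 / .perrin_S(shape$a, shape$b)) / R_equiv_volume
}
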