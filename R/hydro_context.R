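#' Solvent viscosity of light or heavy water
#'
#' Thermal-offset power law `eta = eta0 * (T/Ts - 1)^(-g)` with the singular
#' temperatures of supercooled light/heavy water; coefficients reproduce
#' standard tabulations to better than 1% over the stated validity range.
#'
#' @param temperature temperature in K
#' @param isotope `"H2O"` or `"D2O"`
#' @return dynamic viscosity in mPa.s
#' @examples
#' viscosity_water(298.15, "D2O")   # ~1.10 mPa.s
#' @export
viscosity_water <- function(temperature, isotope = c("D2O", "H2O")) {
  isotope <- match.arg(isotope)
  co <- .viscosity_coefficients[[isotope]]
  if (any(temperature < co$T_min) || any(temperature > co$T_max)) {
    stop("temperature outside the validity range [", co$T_min, ", ",
         co$T_max, "] K of the ", isotope, " viscosity relation")
  }
  co$eta0 * (temperature / co$Ts - 1)^(-co$g)
}

#' Salt correction to the solvent viscosity
#'
#' Relative-viscosity law `eta_r = exp(X*E) / (1 + X*V)` on the salt mole
#' fraction X, with electrolyte-specific parameters E and V.
#'
#' @param eta0 pure-solvent viscosity, mPa.s
#' @param molarity salt concentration, mol/L
#' @param salt salt name; only `"NaCl"` is parametrized
#' @return corrected viscosity in mPa.s
#' @export
viscosity_with_salt <- function(eta0, molarity, salt = "NaCl") {
  stopifnot(eta0 > 0, molarity >= 0)
  co <- .salt_viscosity_coefficients[[salt]]
  if (is.null(co)) stop("no viscosity parameters for salt '", salt, "'")
  if (molarity > co$molarity_max) {
    stop("molarity ", molarity, " outside validity range (<= ",
         co$molarity_max, " mol/L) for ", salt)
  }
  # mole fraction, taking ~55.51 mol/L of water in the solution
  X <- molarity / (molarity + 55.51)
  eta0 * exp(X * co$E) / (1 + X * co$V)
}

#' Solvent context: temperature, isotope, salt, and the implied viscosity
#'
#' The conversion hub between diffusion coefficients and radii.  Viscosity is
#' computed from the water relation plus the salt correction unless
#' explicitly overridden.
#'
#' @param temperature K
#' @param isotope `"D2O"` (default, matching a neutron experiment) or `"H2O"`
#' @param salt_molarity mol/L NaCl (default 0)
#' @param viscosity optional override, mPa.s
#' @return object of class `"hydro_context"`
#' @examples
#' ctx <- hydro_context(298)          # D2O at 298 K
#' ctx$viscosity
#' @export
hydro_context <- function(temperature, isotope = c("D2O", "H2O"),
                          salt_molarity = 0, viscosity = NULL) {
  isotope <- match.arg(isotope)
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            salt_molarity >= 0)
  if (is.null(viscosity)) {
    viscosity <- viscosity_water(temperature, isotope)
    if (salt_molarity > 0) {
      viscosity <- viscosity_with_salt(viscosity, salt_molarity)
    }
  }
  stopifnot(viscosity > 0)
  structure(list(temperature = temperature, isotope = isotope,
                 salt_molarity = salt_molarity, viscosity = viscosity),
            class = "hydro_context")
}

#' @export
print.hydro_context <- function(x, ...) {
  cat(sprintf("<hydro_context> T = %g K, %s, %g M NaCl, eta = %.4f mPa.s\n",
              x$temperature, x$isotope, x$salt_molarity, x$viscosity))
  invisible(x)
}

# kB*T/(6*pi*eta) in units of A^3/ns: with eta in mPa.s, R in A, D in A^2/ns
.stokes_prefactor_A3_ns <- function(ctx) {
  # kB*T/(6*pi*eta) [m^3/s] -> A^2/ns * A: 1 m^3/s = 1e30 A^3 / 1e9 ns = 1e21
  physical_constants$kB_J_per_K * ctx$temperature /
    (6 * pi * ctx$viscosity * 1e-3) * 1e21
}

#' Stokes-Einstein conversions between diffusion coefficient and radius
#'
#' `stokes_einstein_radius()` maps an (apparent or translational) diffusion
#' coefficient to the friction-equivalent sphere radius
#' `R = kB*T / (6*pi*eta*D)`; `stokes_einstein_D()` is its exact inverse;
#' `sphere_Dr()` gives the Einstein-Smoluchowski rotational diffusion
#' coefficient `kB*T / (8*pi*eta*R^3)` of a sphere.
#'
#' @param D diffusion coefficient, A^2/ns
#' @param R radius, A
#' @param ctx a [hydro_context()]
#' @return radius in A, diffusion in A^2/ns, or rotational diffusion in 1/ns
#' @examples
#' ctx <- hydro_context(298, "D2O")
#' stokes_einstein_radius(16.8, ctx)   # ~11.8 A
#' @export
stokes_einstein_radius <- function(D, ctx) {
  stopifnot(all(D > 0))
  .stokes_prefactor_A3_ns(ctx) / D
}

#' @rdname stokes_einstein_radius
#' @export
stokes_einstein_D <- function(R, ctx) {
  stopifnot(all(R > 0))
  .stokes_prefactor_A3_ns(ctx) / R
}

#' @rdname stokes_einstein_radius
#' @export
sphere_Dr <- function(R, ctx) {
  stopifnot(all(R > 0))
  # kB*T/(8*pi*eta*R^3): 3/4 of the translational prefactor divided by R^3
  0.75 * .stokes_prefactor_A3_ns(ctx) / R^3
}
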