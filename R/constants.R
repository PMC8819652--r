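#' Physical constants and empirical coefficient tables
#'
#' All model physics in the package runs on a single unit system:
#' lengths in Angstrom, times in ns, energies in micro-eV, temperatures in K,
#' viscosities in mPa.s (= 1e-3 Pa.s).  In these units a diffusion
#' coefficient in A^2/ns converts to a quasi-elastic half-width through
#' `hbar_ueV_ns * D * q^2` with q in 1/A.
#'
#' @format A list with elements:
#' \describe{
#'   \item{hbar_ueV_ns}{Reduced Planck constant, 0.6582119569 micro-eV ns.}
#'   \item{kB_J_per_K}{Boltzmann constant, 1.380649e-23 J/K (exact).}
#'   \item{A2_per_ns_to_m2_per_s}{1 A^2/ns = 1e-11 m^2/s.}
#' }
#' @export
physical_constants <- list(
  hbar_ueV_ns = 0.6582119569,
  kB_J_per_K  = 1.380649e-23,
  A2_per_ns_to_m2_per_s = 1e-11
)

# Thermal-offset power law eta(T) = eta0 * (T/Ts - 1)^(-g)  [mPa.s]
# Singular temperatures are the published values for light and heavy water;
# eta0 and g calibrated against standard viscosity tabulations
# (max relative deviation < 1% over 273-363 K / 283-353 K).
.viscosity_coefficients <- list(
  H2O = list(eta0 = 0.1386973, Ts = 225.334, g = 1.6474848,
             T_min = 270, T_max = 370),
  D2O = list(eta0 = 0.1411226, Ts = 231.832, g = 1.6399320,
             T_min = 277, T_max = 370)
)

# Relative viscosity of aqueous electrolytes, eta_r = exp(X*E)/(1 + X*V)
# with X the salt mole fraction; E, V calibrated to 25 C NaCl tabulations.
.salt_viscosity_coefficients <- list(
  NaCl = list(E = 10.2458, V = 5.7466, molarity_max = 4)
)

# Empirical IDP Rg <-> Rh relation coefficients (alpha1 in 1/A, alpha2 in A):
# Rh = Rg / (alpha1 * (Rg - alpha2 * N^0.33) / (N^0.60 - N^0.33) + alpha3)
.nygaard_coefficients <- list(alpha1 = 0.216, alpha2 = 4.06, alpha3 = 0.821)

# Lattice self-interaction constants for the periodic-boundary finite-size
# correction D0 = D_pbc + kB*T*xi/(6*pi*eta*L).  The cubic value is the
# standard Ewald constant; the FCC value derives from the Hasimoto FCC drag
# constant 1.7917 via xi = 1.7917*(16*pi/3)^(1/3) (4 lattice points per
# conventional cubic cell of edge L), for rhombic-dodecahedral boxes with L
# the edge of the enclosing cubic unit cell.
.lattice_xi <- list(cubic = 2.837297, fcc = 4.584957)

#' Default short-time colloidal crowding scaling parameters
#'
#' Charged-sphere short-time self-diffusion reduction factors:
#' translational `1 - a_t * phi^(4/3)`, rotational `1 - a_r * phi^2`,
#' with the effective hydrodynamic volume fraction phi.
#'
#' @param a_t translational prefactor (default 2.5)
#' @param a_r rotational prefactor (default 1.3)
#' @return list with class `"scaling_params"`
#' @export
scaling_params <- function(a_t = 2.5, a_r = 1.3) {
  stopifnot(a_t > 0, a_r > 0)
  structure(list(a_t = a_t, a_r = a_r), class = "scaling_params")
}
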