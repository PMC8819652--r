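#' Ground truth for a synthetic off-diagonal pressure-tensor series
#'
#' Stationary Ornstein-Uhlenbeck construction: an exponentially correlated
#' Gaussian process whose analytic Green-Kubo integral
#' `eta = V/(kB*T) * Var * tau_c` equals the target viscosity exactly.
#' The variance is therefore set to
#' `Var = eta_target * kB * T / (V * tau_c)`.
#'
#' @param eta_target target shear viscosity, mPa.s
#' @param correlation_time OU correlation time, ps
#' @param volume system volume, nm^3
#' @param temperature K
#' @param dt sampling interval, ps (must be < correlation_time)
#' @param n_steps series length
#' @param n_components number of independent off-diagonal components
#' @param seed integer RNG seed
#' @return object of class `"pressure_series_truth"`
#' @export
pressure_series_truth <- function(eta_target = 0.85, correlation_time = 1,
                                  volume = 100, temperature = 300,
                                  dt = 0.1, n_steps = 1e5L,
                                  n_components = 3L, seed = 1L) {
  stopifnot(eta_target >= 0, correlation_time > 0, volume > 0,
            temperature > 0, n_steps >= 2)
  if (dt >= correlation_time) {
    stop("dt >= correlation_time: the pressure series would be undersampled")
  }
  structure(list(eta_target = eta_target,
                 correlation_time = correlation_time, volume = volume,
                 temperature = temperature, dt = dt,
                 n_steps = as.integer(n_steps),
                 n_components = as.integer(n_components),
                 seed = as.integer(seed)),
            class = "pressure_series_truth")
}

#' Generate an off-diagonal pressure-tensor time series
#'
#' Exact discrete OU recursion `P[k+1] = rho*P[k] + sqrt(Var*(1-rho^2))*eps`
#' with `rho = exp(-dt/tau_c)`, one column per independent off-diagonal
#' component, in bar.  The analytic Green-Kubo viscosity of the generated
#' process equals `eta_target`.
#'
#' @param truth a [pressure_series_truth()]
#' @return object of class `"pressure_series"`: matrix `n_steps x
#'   n_components` (bar) with time metadata
#' @export
generate_pressure_series <- function(truth) {
  stopifnot(inherits(truth, "pressure_series_truth"))
  kB <- physical_constants$kB_J_per_K
  V_m3 <- truth$volume * 1e-27
  tau_s <- truth$correlation_time * 1e-12
  # Var in Pa^2 from the Green-Kubo closed form, then to bar
  var_Pa2 <- truth$eta_target * 1e-3 * kB * truth$temperature / (V_m3 * tau_s)
  sd_bar <- sqrt(var_Pa2) / 1e5
  rho <- exp(-truth$dt / truth$correlation_time)
  P <- .with_stream_seed(truth$seed, "pressure", {
    x0 <- stats::rnorm(truth$n_components, 0, sd_bar)
    innov_sd <- sd_bar * sqrt(1 - rho^2)
    vapply(seq_len(truth$n_components), function(j) {
      eps <- stats::rnorm(truth$n_steps - 1, 0, innov_sd)
      c(x0[j], stats::filter(eps, rho, method = "recursive",
                             init = x0[j]))
    }, numeric(truth$n_steps))
  })
  structure(list(P = P, dt = truth$dt, volume = truth$volume,
                 temperature = truth$temperature, units = "bar",
                 truth = truth),
            class = "pressure_series")
}
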