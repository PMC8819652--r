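# Shared fixtures: small, fast synthetic inputs built in code.

ctx_d2o_298 <- function() hydro_context(298, "D2O")

# compact zero-noise spectrum truth used across fit tests
truth_small <- function(noise_scale = 0, seed = 1L, nq = 8L) {
  spectrum_truth(D_apparent = 17, D_int = 30, tau = 0.02,
                 noise_scale = noise_scale, seed = seed,
                 q_grid = seq(0.4, 1.8, length.out = nq))
}

# Voigt profile by direct adaptive quadrature of the Gaussian-Lorentzian
# convolution integral; slow but accurate, used only as an independent
# oracle
voigt_profile <- function(x, sigma, gamma) {
  vapply(x, function(xi) {
    stats::integrate(function(t) {
      stats::dnorm(t, 0, sigma) * gamma / (pi * ((xi - t)^2 + gamma^2))
    }, -Inf, Inf, rel.tol = 1e-10)$value
  }, numeric(1))
}

# brute-force MSD oracle: naive double loop over origins
msd_naive <- function(r, k_max) {
  n <- nrow(r)
  vapply(seq_len(k_max), function(k) {
    mean(rowSums((r[(1 + k):n, , drop = FALSE] -
                    r[1:(n - k), , drop = FALSE])^2))
  }, numeric(1))
}

# brute-force oracle: single-Lorentzian grid minimization of the explicitly
# summed rotational-translational multi-Lorentzian spectrum
apparent_D_bruteforce <- function(D_t, D_r, profile, q_range,
                                  omega_max = 30) {
  hbar <- physical_constants$hbar_ueV_ns
  omega <- seq(-omega_max, omega_max, length.out = 1201)
  gam <- vapply(q_range, function(q) {
    B <- qensdiff:::.rotational_weights(profile, q)
    widths <- hbar * (D_t * q^2 + (seq_along(B) - 1) * seq_along(B) * D_r)
    y <- colSums(B * t(sapply(widths, function(w) lorentzian(omega, w))))
    # grid search over width; amplitude solved in closed form per width
    ws <- seq(0.3 * widths[1], 3 * max(widths), length.out = 900)
    sse <- vapply(ws, function(w) {
      b <- lorentzian(omega, w)
      a <- sum(b * y) / sum(b * b)
      sum((a * b - y)^2)
    }, numeric(1))
    ws[which.min(sse)]
  }, numeric(1))
  x <- hbar * q_range^2
  sum(x * gam) / sum(x^2)
}

# brute-force connected components via label propagation
components_naive <- function(adj) {
  n <- nrow(adj)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && lab[j] < lab[i]) { lab[i] <- lab[j]; changed <- TRUE }
    }
    if (!changed) break
  }
  match(lab, unique(lab))
}
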