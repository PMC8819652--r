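#' Ground truth for a Brownian multi-chain system
#'
#' Each chain's center of mass performs an isotropic Gaussian random walk
#' with per-component step variance `2 * D_t * dt`, wrapped into a periodic
#' cubic box.  Defaults emulate the crowded-simulation conditions of a small
#' IDP study: 10 chains in a 100 A box.
#'
#' @param n_chains number of chains
#' @param D_t translational diffusion, A^2/ns (>= 0)
#' @param box_edge cubic box edge, A
#' @param dt frame spacing, ns
#' @param n_steps number of frames (>= 2)
#' @param seed integer RNG seed
#' @return object of class `"brownian_system_truth"`
#' @export
brownian_system_truth <- function(n_chains = 10L, D_t = 15, box_edge = 100,
                                  dt = 0.1, n_steps = 200L, seed = 1L) {
  stopifnot(n_chains >= 1, D_t >= 0, box_edge > 0, dt > 0)
  if (n_steps < 2) stop("n_steps must be >= 2")
  structure(list(n_chains = as.integer(n_chains), D_t = D_t,
                 box_edge = box_edge, dt = dt, n_steps = as.integer(n_steps),
                 seed = as.integer(seed)),
            class = "brownian_system_truth")
}

#' Generate a Brownian multi-chain trajectory
#'
#' Single-particle chains (each chain is its own center of mass) performing
#' independent Gaussian random walks at the truth's diffusion coefficient;
#' coordinates are returned wrapped into the periodic box.  Seeded and
#' bitwise reproducible.
#'
#' @param truth a [brownian_system_truth()]
#' @return a wrapped [chain_ensemble_trajectory()]
#' @export
generate_brownian_chains <- function(truth) {
  stopifnot(inherits(truth, "brownian_system_truth"))
  n <- truth$n_steps; m <- truth$n_chains
  sd_step <- sqrt(2 * truth$D_t * truth$dt)
  coords <- .with_stream_seed(truth$seed, "brownian", {
    start <- matrix(stats::runif(m * 3, 0, truth$box_edge), m, 3)
    steps <- array(stats::rnorm((n - 1) * m * 3, 0, sd_step), c(n - 1, m, 3))
    out <- array(0, c(n, m, 3))
    out[1, , ] <- start
    for (k in 2:n) out[k, , ] <- out[k - 1, , ] + steps[k - 1, , ]
    out
  })
  traj <- chain_ensemble_trajectory(
    times = (seq_len(n) - 1) * truth$dt, coords = coords,
    box_edge = truth$box_edge, chain_id = seq_len(m), wrapped = FALSE)
  wrap_trajectory(traj)
}

#' Generate sphere-confined hydrogen motion
#'
#' Each atom performs Brownian motion confined to a sphere of radius `a`
#' about its own fixed center: proposed Gaussian steps that would leave the
#' sphere are rejected (the atom keeps its position), a Metropolis-style
#' boundary whose stationary distribution is exactly uniform in the sphere.
#' Atoms are initialized uniformly in their spheres, so every frame samples
#' the equilibrium distribution.  Refused when the rms step exceeds `a/5`.
#'
#' @param n_atoms number of independent confined atoms
#' @param a confinement radius, A (> 0)
#' @param D_loc local diffusion coefficient, A^2/ns (>= 0)
#' @param dt frame spacing, ns
#' @param n_steps number of frames
#' @param seed integer RNG seed
#' @param centers optional `n_atoms x 3` matrix of sphere centers, A
#' @return an unwrapped [chain_ensemble_trajectory()] (one chain per atom;
#'   box chosen large enough to be irrelevant)
#' @export
generate_confined_hydrogens <- function(n_atoms, a, D_loc, dt, n_steps,
                                        seed = 1L, centers = NULL) {
  stopifnot(a > 0, D_loc >= 0, dt > 0, n_steps >= 1)
  sd_step <- sqrt(2 * D_loc * dt)
  if (sd_step > a / 5) {
    stop("rms step ", signif(sd_step, 3), " A exceeds a/5 = ", a / 5,
         " A; boundary scheme invalid at this time step")
  }
  if (is.null(centers)) {
    spacing <- 4 * a
    side <- ceiling(n_atoms^(1 / 3))
    g <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                               z = seq_len(side)))[seq_len(n_atoms), , drop = FALSE]
    centers <- g * spacing
  }
  coords <- .with_stream_seed(seed, "confined", {
    # uniform initial points in the unit ball, scaled to radius a
    u <- matrix(stats::rnorm(n_atoms * 3), n_atoms, 3)
    u <- u / sqrt(rowSums(u^2)) * a * stats::runif(n_atoms)^(1 / 3)
    out <- array(0, c(n_steps, n_atoms, 3))
    out[1, , ] <- u
    if (n_steps > 1) {
      for (k in 2:n_steps) {
        prop <- out[k - 1, , ] + matrix(stats::rnorm(n_atoms * 3, 0, sd_step),
                                        n_atoms, 3)
        outside <- rowSums(prop^2) > a^2
        if (any(outside)) prop[outside, ] <- out[k - 1, , ][outside, ]
        out[k, , ] <- prop
      }
    }
    out
  })
  for (ax in 1:3) coords[, , ax] <- coords[, , ax] +
      matrix(centers[, ax], dim(coords)[1], n_atoms, byrow = TRUE)
  chain_ensemble_trajectory(
    times = (seq_len(n_steps) - 1) * dt, coords = coords,
    box_edge = max(centers) + 10 * a, chain_id = seq_len(n_atoms),
    element = rep("H", n_atoms), wrapped = FALSE)
}
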