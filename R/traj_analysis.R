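#' Mean square displacement of a chain center of mass
#'
#' Time- and origin-averaged squared displacement of the (mass-weighted)
#' center of mass of one chain, at every lag up to `max_lag`, computed with
#' the FFT autocorrelation algorithm (all time origins).
#'
#' @param traj an unwrapped [chain_ensemble_trajectory()]
#' @param chain chain label (integer, as in `traj$chain_id`); `NULL` averages
#'   the per-chain MSD curves over all chains
#' @param max_lag maximum lag, ns (default: 40% of the trajectory length)
#' @return data frame with columns `lag` (ns) and `msd` (A^2)
#' @export
msd <- function(traj, chain = NULL, max_lag = NULL) {
  if (traj$wrapped) stop("msd() requires an unwrapped trajectory; call ",
                         "unwrap_trajectory() first")
  dt <- diff(traj$times)[1]
  n <- length(traj$times)
  t_total <- traj$times[n] - traj$times[1]
  if (is.null(max_lag)) max_lag <- 0.4 * t_total
  if (max_lag >= t_total + 1e-12) stop("max_lag must be below the ",
                                       "trajectory length")
  k_max <- max(1L, min(n - 1L, floor(max_lag / dt + 1e-9)))
  coms <- .chain_coms(traj)
  chains <- if (is.null(chain)) seq_len(dim(coms)[2]) else {
    j <- match(chain, sort(unique(traj$chain_id)))
    if (is.na(j)) stop("unknown chain label ", chain)
    j
  }
  curves <- vapply(chains, function(j) {
    .msd_fft(coms[, j, , drop = FALSE][, 1, ], k_max)
  }, numeric(k_max))
  data.frame(lag = dt * seq_len(k_max), msd = rowMeans(as.matrix(curves)))
}

# FFT (Wiener-Khinchin) origin-averaged MSD of a single n x 3 path
.msd_fft <- function(r, k_max) {
  n <- nrow(r)
  # S1 recursion term: sum over origins of |r(t+k)|^2 + |r(t)|^2
  sq <- rowSums(r^2)
  s1 <- numeric(k_max)
  ss <- 2 * sum(sq)
  for (k in seq_len(k_max)) {
    ss <- ss - sq[k] - sq[n - k + 1L]
    s1[k] <- ss
  }
  # S2: autocorrelation sum via zero-padded FFT, per component
  n_fft <- stats::nextn(2L * n, 2)
  s2 <- numeric(n)
  for (ax in 1:3) {
    f <- stats::fft(c(r[, ax], rep(0, n_fft - n)))
    ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / n_fft
    s2 <- s2 + ac
  }
  counts <- n - seq_len(k_max)
  (s1 - 2 * s2[1L + seq_len(k_max)]) / counts
}

#' Fit a diffusion coefficient to an MSD curve
#'
#' Straight line over a fixed lag window (default 0 to 4.6 ns, the coherence
#' window of a 0.9 micro-eV backscattering resolution); the diffusion
#' coefficient is slope/6 and the R^2 of the line is reported as a linearity
#' diagnostic, flagged when it falls below `r2_threshold`.
#'
#' @param msd_curve data frame with `lag` (ns) and `msd` (A^2)
#' @param window lag window in ns, default `c(0, 4.6)`
#' @param r2_threshold linearity warning threshold (default 0.99)
#' @return a [diffusion_estimate()] with method `"msd"`
#' @export
fit_diffusion <- function(msd_curve, window = c(0, 4.6), r2_threshold = 0.99) {
  keep <- msd_curve$lag >= window[1] & msd_curve$lag <= window[2]
  if (sum(keep) < 2) stop("empty or too-small MSD fit window")
  if (sum(keep) < 5) warning("fewer than 5 MSD points in the fit window")
  fit <- stats::lm(msd ~ lag, data = msd_curve[keep, ])
  slope <- unname(stats::coef(fit)[2])
  sm <- suppressWarnings(summary(fit))     # exact fits trip summary.lm
  r2 <- sm$r.squared
  if (r2 < r2_threshold) {
    warning(sprintf("MSD window nonlinear: R^2 = %.4f < %.2f", r2,
                    r2_threshold))
  }
  diffusion_estimate(max(slope, 0) / 6,
                     uncertainty = sm$coefficients[2, 2] / 6,
                     r_squared = r2, method = "msd")
}

#' Ensemble diffusion from a multi-chain trajectory
#'
#' Per-chain MSD fits averaged over chains (and, if several trajectories are
#' given, over replicates), with the standard deviation across chains as
#' uncertainty.
#'
#' @param trajs a [chain_ensemble_trajectory()] or list of them (replicates)
#' @param window MSD fit window, ns
#' @param max_lag maximum MSD lag, ns
#' @return list with the pooled [diffusion_estimate()] and the per-chain
#'   values
#' @export
diffusion_from_trajectories <- function(trajs, window = c(0, 4.6),
                                        max_lag = NULL) {
  if (inherits(trajs, "chain_ensemble_trajectory")) trajs <- list(trajs)
  per_chain <- unlist(lapply(trajs, function(tr) {
    if (tr$wrapped) tr <- unwrap_trajectory(tr)
    vapply(sort(unique(tr$chain_id)), function(ch) {
      suppressWarnings(
        fit_diffusion(msd(tr, chain = ch, max_lag = max_lag), window)$value)
    }, numeric(1))
  }))
  est <- diffusion_estimate(mean(per_chain),
                            uncertainty = stats::sd(per_chain) /
                              sqrt(length(per_chain)),
                            method = "msd_ensemble")
  list(estimate = est, per_chain = per_chain,
       sd_chains = stats::sd(per_chain))
}

#' Finite-size (periodic-boundary) correction of a diffusion coefficient
#'
#' Adds the hydrodynamic self-interaction term
#' `kB*T*xi / (6*pi*eta*L)` to a diffusion coefficient computed in a
#' periodic box of edge `L`.  `xi` is 2.837297 for a cubic box; for
#' rhombic-dodecahedral boxes use `lattice = "fcc"` with `L` the edge of the
#' enclosing cubic unit cell.
#'
#' @param D_pbc in-box diffusion coefficient, A^2/ns (number or
#'   [diffusion_estimate()])
#' @param L box edge, A
#' @param eta solvent viscosity, mPa.s
#' @param temperature K
#' @param lattice `"cubic"` or `"fcc"`
#' @param xi optional explicit lattice constant (overrides `lattice`)
#' @return corrected diffusion, same type as `D_pbc`
#' @export
yeh_hummer_correct <- function(D_pbc, L, eta, temperature,
                               lattice = c("cubic", "fcc"), xi = NULL) {
  lattice <- match.arg(lattice)
  if (is.null(xi)) xi <- .lattice_xi[[lattice]]
  stopifnot(xi > 0, L > 0, eta > 0)
  # kB*T*xi/(6*pi*eta*L): [m^2/s] -> A^2/ns via 1e11
  term <- physical_constants$kB_J_per_K * temperature * xi /
    (6 * pi * eta * 1e-3 * L * 1e-10) * 1e11
  if (inherits(D_pbc, "diffusion_estimate")) {
    if (isTRUE(D_pbc$corrections$finite_size)) {
      stop("finite-size correction already applied to this estimate")
    }
    D_pbc$value <- D_pbc$value + term
    D_pbc$corrections$finite_size <- TRUE
    D_pbc
  } else {
    D_pbc + term
  }
}

#' Isotope (light-to-heavy water) rescaling of a diffusion coefficient
#'
#' Multiplies a diffusion coefficient computed in light water by the
#' viscosity ratio `eta_H2O(T) / eta_D2O(T)` (< 1) to make it comparable
#' with a heavy-water experiment.  Guarded against double application via
#' the provenance flags of [diffusion_estimate()].
#'
#' @param D diffusion coefficient, A^2/ns (number or [diffusion_estimate()])
#' @param temperature K
#' @return rescaled diffusion, same type as `D`
#' @export
isotope_rescale <- function(D, temperature) {
  ratio <- viscosity_water(temperature, "H2O") /
    viscosity_water(temperature, "D2O")
  if (inherits(D, "diffusion_estimate")) {
    if (isTRUE(D$corrections$isotope_rescaled)) {
      stop("isotope rescaling already applied to this estimate")
    }
    D$value <- D$value * ratio
    if (!is.na(D$uncertainty)) D$uncertainty <- D$uncertainty * ratio
    D$corrections$isotope_rescaled <- TRUE
    D
  } else {
    D * ratio
  }
}

#' Shear viscosity from an off-diagonal pressure-tensor series
#'
#' Einstein-Helfand estimator: the mean squared displacement of the
#' time-integrated pressure, `G(t) = <(int_0^t P dt')^2>`, grows linearly at
#' times beyond the stress correlation time with slope `2*eta*kB*T/V`; the
#' estimate is the straight-line slope over `fit_window` (fractions of the
#' series length) times `V/(2*kB*T)`, averaged over the independent
#' components.  Invariant under sign flips of the series.
#'
#' @param series a `"pressure_series"` or a numeric vector/matrix in bar
#' @param volume system volume, nm^3 (taken from the series if present)
#' @param temperature K (taken from the series if present)
#' @param dt sampling interval, ps (taken from the series if present)
#' @param fit_window slope-fit window in multiples of the integrated stress
#'   correlation time (default 5 to 50; long enough to be past the ballistic
#'   bend, short enough to keep many independent blocks)
#' @return viscosity in mPa.s
#' @export
viscosity_from_pressure <- function(series, volume = NULL, temperature = NULL,
                                    dt = NULL, fit_window = c(5, 50)) {
  if (inherits(series, "pressure_series")) {
    if (is.null(volume)) volume <- series$volume
    if (is.null(temperature)) temperature <- series$temperature
    if (is.null(dt)) dt <- series$dt
    P <- series$P
  } else {
    P <- as.matrix(series)
  }
  stopifnot(!is.null(volume), !is.null(temperature), !is.null(dt))
  if (all(P == 0)) return(0)
  n <- nrow(P)
  # integrated correlation time (in steps) from the first component's ACF
  # (estimated on a leading subsample), summed to its first zero crossing
  n_ac <- min(n, 100000L)
  ac <- stats::acf(P[seq_len(n_ac), 1], lag.max = min(n_ac - 1L, 2000L),
                   plot = FALSE, demean = FALSE)$acf[, 1, 1]
  zc <- which(ac <= 0)[1]
  tau_steps <- max(sum(ac[seq_len(if (is.na(zc)) length(ac) else zc - 1L)]),
                   1)
  lag_lo <- max(2L, ceiling(fit_window[1] * tau_steps))
  lag_hi <- min(n %/% 5L, ceiling(fit_window[2] * tau_steps))
  if (lag_hi <= lag_lo) {
    stop("pressure series too short relative to its correlation time ",
         "for a converged Einstein-Helfand slope")
  }
  lags <- unique(round(seq(lag_lo, lag_hi, length.out = 30L)))
  slope_sum <- 0
  for (j in seq_len(ncol(P))) {
    A <- c(0, cumsum(P[, j])) * dt          # bar * ps
    G <- vapply(lags, function(k) {
      d <- A[(k + 1):(n + 1)] - A[1:(n + 1 - k)]
      mean(d^2)
    }, numeric(1))
    fit <- stats::lm(G ~ I(lags * dt))
    slope_sum <- slope_sum + unname(stats::coef(fit)[2])  # bar^2 ps
  }
  slope <- slope_sum / ncol(P)
  # bar^2*ps -> Pa^2*s: (1e5)^2 * 1e-12; times V[m^3]/(2 kB T) -> Pa.s
  eta_Pa_s <- slope * 1e10 * 1e-12 * (volume * 1e-27) /
    (2 * physical_constants$kB_J_per_K * temperature)
  eta_Pa_s * 1e3
}

#' Normalized autocorrelation of a per-snapshot diffusion series
#'
#' `C(k) = sum_i (D_i - Dbar)(D_{i+k} - Dbar) / sum_i (D_i - Dbar)^2`,
#' so `C(0) = 1` for any series with positive variance.
#'
#' @param series numeric vector of per-snapshot diffusion values
#' @param max_lag largest lag (default `length(series) - 1`)
#' @return data frame with columns `lag` (index) and `acf`
#' @export
diffusion_autocorrelation <- function(series, max_lag = NULL) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 2 || stats::var(series) == 0) {
    stop("autocorrelation undefined for a zero-variance series")
  }
  if (is.null(max_lag)) max_lag <- n - 1L
  x <- series - mean(series)
  denom <- sum(x^2)
  acf_k <- vapply(0:max_lag, function(k) {
    sum(x[1:(n - k)] * x[(1 + k):n]) / denom
  }, numeric(1))
  data.frame(lag = 0:max_lag, acf = acf_k)
}

#' Pairwise minimum inter-chain distances in one frame
#'
#' Symmetric matrix of the minimum atom-atom distance between every pair of
#' chains under the minimum-image convention.  With alpha-carbon flags
#' present (element `"CA"`), only those atoms are used; synthetic
#' point-chain fixtures fall back to all particles.
#'
#' @param traj a [chain_ensemble_trajectory()]
#' @param frame frame index
#' @param selection element label to select (default `"CA"` if present)
#' @return `n_chains x n_chains` matrix, A (diagonal 0)
#' @export
min_chain_distance <- function(traj, frame = 1L, selection = NULL) {
  ids <- sort(unique(traj$chain_id))
  if (length(ids) < 2) stop("need >= 2 chains for inter-chain distances")
  L <- traj$box_edge
  if (is.null(selection)) {
    selection <- if (any(traj$element == "CA")) "CA" else NULL
  }
  sel <- if (is.null(selection)) rep(TRUE, length(traj$chain_id))
         else traj$element == selection
  x <- traj$coords[frame, , , drop = FALSE]
  dim(x) <- dim(traj$coords)[2:3]
  out <- matrix(0, length(ids), length(ids))
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in (i + 1):length(ids)) {
      xi <- x[sel & traj$chain_id == ids[i], , drop = FALSE]
      xj <- x[sel & traj$chain_id == ids[j], , drop = FALSE]
      dmin <- Inf
      for (k in seq_len(nrow(xi))) {
        d <- sweep(xj, 2, xi[k, ])
        d <- d - L * round(d / L)
        dmin <- min(dmin, sqrt(min(rowSums(d^2))))
      }
      out[i, j] <- out[j, i] <- dmin
    }
  }
  out
}

#' Transient-cluster partition of chains
#'
#' Connected components of the graph whose edges join chain pairs with
#' minimum distance at or below the cutoff (6 or 7 A are the conventional
#' choices).  Singletons are not counted as clusters.
#'
#' @param dist_matrix symmetric matrix of minimum inter-chain distances, A
#' @param cutoff distance cutoff, A (default 6)
#' @return list: `membership` (component id per chain), `n_clusters`
#'   (components with >= 2 members), `chains_in_clusters`, `largest_cluster`
#' @export
cluster_chains <- function(dist_matrix, cutoff = 6) {
  stopifnot(isSymmetric(unname(as.matrix(dist_matrix))))
  adj <- (as.matrix(dist_matrix) <= cutoff)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  sizes <- comp$csize
  real <- sizes >= 2
  list(membership = comp$membership,
       n_clusters = sum(real),
       chains_in_clusters = sum(sizes[real]),
       largest_cluster = if (any(real)) max(sizes[real]) else 0L)
}

#' Time-averaged cluster statistics over a trajectory
#'
#' @param traj a [chain_ensemble_trajectory()]
#' @param cutoffs distance cutoffs, A
#' @param frames frame indices (default all)
#' @return data frame: per cutoff, mean number of clusters, mean chains
#'   participating, and mean largest-cluster size over frames
#' @export
cluster_statistics <- function(traj, cutoffs = c(6, 7), frames = NULL) {
  if (is.null(frames)) frames <- seq_along(traj$times)
  do.call(rbind, lapply(cutoffs, function(cut) {
    per_frame <- vapply(frames, function(f) {
      cl <- cluster_chains(min_chain_distance(traj, f), cut)
      c(cl$n_clusters, cl$chains_in_clusters, cl$largest_cluster)
    }, numeric(3))
    data.frame(cutoff = cut, n_clusters = mean(per_frame[1, ]),
               chains_in_clusters = mean(per_frame[2, ]),
               largest_cluster = mean(per_frame[3, ]))
  }))
}

#' Per-frame radius of gyration of a chain
#'
#' Mass-weighted root-mean-square distance of the chain's atoms from its
#' center of mass, per frame.
#'
#' @param traj a [chain_ensemble_trajectory()] (unwrapped, or with chains
#'   whole in the box)
#' @param chain chain label
#' @return numeric vector of R_g values per frame, A
#' @export
rg_series <- function(traj, chain = 1L) {
  sel <- traj$chain_id == chain
  if (!any(sel)) stop("unknown chain label ", chain)
  m <- traj$masses[sel]; mw <- m / sum(m)
  n_f <- dim(traj$coords)[1]
  vapply(seq_len(n_f), function(k) {
    x <- traj$coords[k, sel, , drop = FALSE]
    dim(x) <- c(sum(sel), 3)
    com <- colSums(x * mw)
    sqrt(sum(mw * rowSums(sweep(x, 2, com)^2)))
  }, numeric(1))
}

#' Reduced distribution of translational diffusion from an R_g series
#'
#' Maps each snapshot's radius of gyration to a hydrodynamic radius through
#' the empirical IDP relation, to a translational diffusion coefficient
#' through Stokes-Einstein, and divides by the series mean, giving a
#' dimensionless per-snapshot diffusion distribution of mean 1.
#'
#' @param rg per-snapshot radius of gyration, A
#' @param N chain length in residues
#' @param ctx a [hydro_context()]
#' @return list: `reduced` (mean-1 distribution), `D_t` (A^2/ns),
#'   `mean_D_t`
#' @export
dt_distribution_from_rg <- function(rg, N, ctx) {
  stopifnot(all(rg > 0))
  D <- stokes_einstein_D(nygaard_rh(rg, N), ctx)
  list(reduced = D / mean(D), D_t = D, mean_D_t = mean(D))
}

#' Elastic incoherent structure factor from a trajectory
#'
#' `A0(q)` is the squared modulus of the time-averaged phase factor
#' `exp(i q . r)`, averaged over the selected scatterers and over
#' isotropically sampled q directions (fixed-seed uniform sampling).  With
#' `remove_com = TRUE` (default) each chain's center-of-mass motion is
#' subtracted first, isolating internal motion.  A static structure gives
#' exactly 1 at all q; unbounded motion decays towards 0.
#'
#' @param traj a [chain_ensemble_trajectory()] (unwrapped)
#' @param q_values momentum transfers, 1/A
#' @param n_orientations number of q-direction samples (default 64)
#' @param remove_com subtract per-chain center-of-mass motion
#' @param selection element label of the scatterers (default `"H"`; falls
#'   back to all atoms if absent)
#' @param seed RNG seed for the direction sampling
#' @return data frame with columns `q` and `A0`
#' @export
eisf_from_trajectory <- function(traj, q_values, n_orientations = 64L,
                                 remove_com = TRUE, selection = "H",
                                 seed = 1L) {
  sel <- traj$element == selection
  if (!any(sel)) sel <- rep(TRUE, length(traj$element))
  if (!any(sel)) stop("empty scatterer selection")
  x <- traj$coords[, sel, , drop = FALSE]
  if (remove_com) {
    coms <- .chain_coms(traj)
    ids <- sort(unique(traj$chain_id))
    ci <- match(traj$chain_id[sel], ids)
    for (ax in 1:3) x[, , ax] <- x[, , ax] - coms[, ci, ax]
  }
  n_f <- dim(x)[1]; n_at <- dim(x)[2]
  dirs <- .with_stream_seed(seed, "eisf", {
    u <- matrix(stats::rnorm(n_orientations * 3), n_orientations, 3)
    u / sqrt(rowSums(u^2))
  })
  flat <- matrix(x, n_f * n_at, 3)           # (frame, atom) major in frame
  A0 <- vapply(q_values, function(q) {
    acc <- 0
    for (d in seq_len(n_orientations)) {
      phase <- flat %*% (q * dirs[d, ])
      dim(phase) <- c(n_f, n_at)
      z <- colMeans(exp(1i * phase))
      acc <- acc + mean(Mod(z)^2)
    }
    acc / n_orientations
  }, numeric(1))
  data.frame(q = q_values, A0 = A0)
}
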