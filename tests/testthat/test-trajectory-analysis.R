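make_point_traj <- function(pos_list, box = 50, dt = 0.1) {
  # pos_list: list of frames, each an n x 3 matrix
  arr <- array(NA_real_, c(length(pos_list), nrow(pos_list[[1]]), 3))
  for (k in seq_along(pos_list)) arr[k, , ] <- pos_list[[k]]
  chain_ensemble_trajectory((seq_along(pos_list) - 1) * dt, arr, box,
                            seq_len(nrow(pos_list[[1]])), wrapped = FALSE)
}

test_that("unwrap: continuous input unchanged; single crossing handled", {
  # chain drifting right, crossing the boundary once
  x <- seq(8, 12, by = 0.5) %% 10
  frames <- lapply(x, function(v) matrix(c(v, 1, 1), 1, 3))
  tr <- make_point_traj(frames, box = 10)
  tr$wrapped <- TRUE
  un <- unwrap_trajectory(tr)
  expect_equal(un$coords[, 1, 1], seq(8, 12, by = 0.5), tolerance = 1e-12)
  # already-continuous trajectory is unchanged
  tr2 <- make_point_traj(lapply(seq(1, 3, by = 0.5),
                                function(v) matrix(c(v, 1, 1), 1, 3)),
                         box = 10)
  expect_equal(unwrap_trajectory(tr2)$coords, tr2$coords, tolerance = 1e-12)
  # displacement of exactly half the box edge is ambiguous and refused
  tr3 <- make_point_traj(list(matrix(c(1, 1, 1), 1, 3),
                              matrix(c(6, 1, 1), 1, 3)), box = 10)
  expect_error(unwrap_trajectory(tr3), "undersampled")
})

test_that("MSD: ballistic and static closed forms; FFT equals naive oracle", {
  v <- c(1.5, -0.7, 0.3)
  frames <- lapply(0:20, function(k) matrix(k * 0.1 * v, 1, 3))
  tr <- make_point_traj(frames, box = 1e4)
  m <- msd(tr, max_lag = 1.0)
  expect_equal(m$msd, sum(v^2) * m$lag^2, tolerance = 1e-10)
  static <- make_point_traj(rep(list(matrix(1, 2, 3)), 10), box = 10)
  expect_lt(max(abs(msd(static, max_lag = 0.5)$msd)), 1e-10)
  tr2 <- unwrap_trajectory(generate_brownian_chains(
    brownian_system_truth(n_chains = 2, D_t = 12, n_steps = 80, seed = 6)))
  coms <- qensdiff:::.chain_coms(tr2)
  for (j in 1:2) {
    expect_equal(qensdiff:::.msd_fft(coms[, j, ], 30),
                 msd_naive(coms[, j, ], 30), tolerance = 1e-9)
  }
})

test_that("diffusion fit: exact line, and nonlinearity is flagged", {
  lag <- seq(0.1, 6, by = 0.1)
  exact <- data.frame(lag = lag, msd = 6 * 4.2 * lag)
  fd <- fit_diffusion(exact)
  expect_equal(fd$value, 4.2, tolerance = 1e-12)
  expect_equal(fd$r_squared, 1, tolerance = 1e-12)
  quad <- data.frame(lag = lag, msd = lag^2 * 10)
  expect_warning(fit_diffusion(quad), "nonlinear")
  expect_error(fit_diffusion(exact, window = c(100, 200)), "window")
})

test_that("finite-size correction: magnitude, decay, FCC mode, idempotence
           guard", {
  expect_equal(yeh_hummer_correct(0, L = 100, eta = 0.85, temperature = 300),
               7.33, tolerance = 1e-3)
  expect_lt(yeh_hummer_correct(0, L = 1e8, eta = 0.85, temperature = 300),
            1e-5)
  # FCC constant is larger than cubic; explicit xi override wins
  d_fcc <- yeh_hummer_correct(0, 100, 0.85, 300, lattice = "fcc")
  expect_gt(d_fcc, 7.33)
  expect_equal(yeh_hummer_correct(0, 100, 0.85, 300, xi = 2.837297), 7.33,
               tolerance = 1e-3)
  est <- diffusion_estimate(10, method = "msd")
  est <- yeh_hummer_correct(est, 100, 0.85, 300)
  expect_true(est$corrections$finite_size)
  expect_error(yeh_hummer_correct(est, 100, 0.85, 300), "already applied")
})

test_that("finite-size correction removes a designed 1/L bias", {
  # same truth, two box sizes, the analytic PBC bias injected by hand
  D_true <- 15; eta <- 0.85; Temp <- 300
  for (L in c(60, 120)) {
    bias <- yeh_hummer_correct(0, L, eta, Temp)
    D_pbc <- D_true - bias
    expect_equal(yeh_hummer_correct(D_pbc, L, eta, Temp), D_true,
                 tolerance = 1e-12)
  }
})

test_that("isotope rescaling ratio and double-application guard", {
  for (Temp in c(280, 298, 310)) {
    r <- isotope_rescale(1, Temp)
    expect_lt(r, 1)
  }
  expect_equal(isotope_rescale(1, 298), 0.815, tolerance = 0.01)
  est <- isotope_rescale(diffusion_estimate(10), 298)
  expect_true(est$corrections$isotope_rescaled)
  expect_error(isotope_rescale(est, 298), "already applied")
})

test_that("minimum-image chain distances match a brute-force oracle", {
  # two point chains, direct and across the boundary
  tr <- make_point_traj(list(rbind(c(1, 1, 1), c(5, 1, 1))), box = 20)
  expect_equal(min_chain_distance(tr, 1)[1, 2], 4)
  tr2 <- make_point_traj(list(rbind(c(0.5, 1, 1), c(19.5, 1, 1))), box = 20)
  expect_equal(min_chain_distance(tr2, 1)[1, 2], 1)
  # random 10-chain frames with several atoms per chain
  set.seed(31)
  L <- 30
  for (rep in 1:3) {
    n_chain <- 10; n_per <- 3
    coords <- array(runif(n_chain * n_per * 3, 0, L), c(1, n_chain * n_per, 3))
    tr3 <- chain_ensemble_trajectory(0, coords, L,
                                     rep(seq_len(n_chain), each = n_per))
    got <- min_chain_distance(tr3, 1)
    x <- coords[1, , ]
    want <- matrix(0, n_chain, n_chain)
    for (i in 1:(n_chain - 1)) for (j in (i + 1):n_chain) {
      dmin <- Inf
      for (ai in which(rep(seq_len(n_chain), each = n_per) == i)) {
        for (aj in which(rep(seq_len(n_chain), each = n_per) == j)) {
          d <- abs(x[ai, ] - x[aj, ])
          d <- pmin(d, L - d)
          dmin <- min(dmin, sqrt(sum(d^2)))
        }
      }
      want[i, j] <- want[j, i] <- dmin
    }
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("clustering: pairs, transitivity, and brute-force equivalence", {
  d <- matrix(20, 3, 3); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 5
  cl <- cluster_chains(d, 6)
  expect_equal(cl$n_clusters, 1)
  expect_equal(sort(which(cl$membership == cl$membership[1])), c(1, 2))
  # A-B 5, B-C 5, A-C 20 -> one transitive cluster of three
  d[2, 3] <- d[3, 2] <- 5
  cl2 <- cluster_chains(d, 6)
  expect_equal(cl2$n_clusters, 1)
  expect_equal(cl2$largest_cluster, 3)
  expect_equal(cl2$chains_in_clusters, 3)
  # random matrices vs label-propagation oracle, both cutoffs
  set.seed(8)
  for (rep in 1:20) {
    n <- 12
    d <- matrix(runif(n * n, 2, 12), n, n)
    d <- (d + t(d)) / 2; diag(d) <- 0
    for (cut in c(6, 7)) {
      got <- cluster_chains(d, cut)$membership
      want <- components_naive(d <= cut & diag(n) == 0)
      # same partition up to relabeling
      expect_equal(got[order(want)], want[order(want)],
                   ignore_attr = TRUE, tolerance = 0)
      expect_true(all(table(got) == table(want)))
    }
  }
})

test_that("cluster statistics are invariant under relabeling and rigid
           translation", {
  set.seed(12)
  coords <- array(runif(8 * 3, 0, 30), c(1, 8, 3))
  tr <- chain_ensemble_trajectory(0, coords, 30, 1:8)
  s1 <- cluster_statistics(tr, cutoffs = 7, frames = 1)
  # rigid translation (with wrap)
  tr2 <- tr; tr2$coords <- (tr2$coords + 11.3) %% 30
  s2 <- cluster_statistics(tr2, cutoffs = 7, frames = 1)
  expect_equal(s1, s2)
  # relabeled chains
  perm <- sample(8)
  tr3 <- chain_ensemble_trajectory(0, coords[, perm, , drop = FALSE], 30,
                                   (1:8)[perm][perm])
  tr3$coords <- coords[, order(perm), , drop = FALSE][, perm[order(perm)], ,
                                                      drop = FALSE]
  s3 <- cluster_statistics(tr, cutoffs = 7, frames = 1)
  expect_equal(s1$n_clusters, s3$n_clusters)
})

test_that("radius of gyration: closed forms and brute-force agreement", {
  # single particle
  tr1 <- chain_ensemble_trajectory(0, array(c(3, 4, 5), c(1, 1, 3)), 50, 1)
  expect_equal(rg_series(tr1, 1), 0)
  # two unit masses at separation d -> d/2
  tr2 <- chain_ensemble_trajectory(0, array(c(0, 6, 0, 0, 0, 0), c(1, 2, 3)),
                                   50, c(1, 1))
  expect_equal(rg_series(tr2, 1), 3)
  # mass-weighted random configuration vs direct definition
  set.seed(5)
  x <- matrix(rnorm(15), 5, 3)
  m <- runif(5, 0.5, 3)
  tr3 <- chain_ensemble_trajectory(0, array(x, c(1, 5, 3)), 50, rep(1, 5),
                                   masses = m)
  com <- colSums(x * m / sum(m))
  want <- sqrt(sum(m / sum(m) * rowSums(sweep(x, 2, com)^2)))
  expect_equal(rg_series(tr3, 1), want, tolerance = 1e-12)
})

test_that("reduced diffusion distribution has mean one and shape-noise
           ordering", {
  ctx <- ctx_d2o_298()
  rg <- rep(12, 10)
  d <- dt_distribution_from_rg(rg, 24, ctx)
  expect_equal(d$reduced, rep(1, 10))
  set.seed(3)
  rg2 <- rnorm(500, 12.5, 1.5)
  rg2 <- rg2[rg2 > 6]
  d2 <- dt_distribution_from_rg(rg2, 24, ctx)
  expect_equal(mean(d2$reduced), 1, tolerance = 1e-12)
  # a series carrying extra shape noise on top of the size-driven D is wider
  D_extra <- d2$D_t * exp(rnorm(length(d2$D_t), 0, 0.25))
  expect_gt(sd(D_extra / mean(D_extra)), sd(d2$reduced))
})

test_that("EISF bounds and monotone decay for the sphere fixture", {
  tr <- generate_confined_hydrogens(60, a = 2, D_loc = 5, dt = 0.01,
                                    n_steps = 400, seed = 13)
  q <- seq(0.3, 2.4, by = 0.3)
  ei <- eisf_from_trajectory(tr, q, n_orientations = 12, remove_com = FALSE,
                             seed = 2)
  expect_true(all(ei$A0 >= 0 & ei$A0 <= 1))
  expect_true(all(diff(ei$A0) < 0.02))   # non-increasing up to sampling noise
})
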