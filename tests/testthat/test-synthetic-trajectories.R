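test_that("Brownian generator: ensemble MSD slope recovers D_t within 3 SE", {
  ests <- unlist(lapply(1:5, function(s) {
    tr <- generate_brownian_chains(brownian_system_truth(
      n_chains = 10, D_t = 15, dt = 0.1, n_steps = 200, seed = s))
    diffusion_from_trajectories(tr)$per_chain
  }))
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 15), 3 * se)
})

test_that("zero-diffusion truth freezes all frames", {
  tr <- generate_brownian_chains(brownian_system_truth(
    n_chains = 3, D_t = 0, n_steps = 10, seed = 1))
  for (k in 2:10) expect_identical(tr$coords[k, , ], tr$coords[1, , ])
})

test_that("unwrap(wrap(x)) reproduces pre-wrap displacements exactly", {
  tr <- generate_brownian_chains(brownian_system_truth(
    n_chains = 4, D_t = 30, box_edge = 20, dt = 0.05, n_steps = 150,
    seed = 3))
  un <- unwrap_trajectory(tr)
  rewrapped <- wrap_trajectory(un)
  un2 <- unwrap_trajectory(rewrapped)
  d1 <- apply(un$coords, c(2, 3), diff)
  d2 <- apply(un2$coords, c(2, 3), diff)
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("per-component displacement variance matches 2*D*dt (chi-square)", {
  tr <- generate_brownian_chains(brownian_system_truth(
    n_chains = 100, D_t = 8, box_edge = 1e4, dt = 0.2, n_steps = 35,
    seed = 9))
  un <- unwrap_trajectory(wrap_trajectory(tr))
  steps <- apply(un$coords, c(2, 3), diff)        # (n-1) x atoms x 3
  z2 <- as.vector(steps)^2 / (2 * 8 * 0.2)
  n <- length(z2)                                  # ~ 10^4 draws
  expect_gt(n, 9000)
  # chi-square with n dof: sum within 3 sd of its expectation
  expect_lt(abs(sum(z2) - n), 3 * sqrt(2 * n))
})

test_that("generators are bitwise seed-reproducible", {
  t1 <- generate_brownian_chains(brownian_system_truth(seed = 5,
                                                       n_steps = 20))
  t2 <- generate_brownian_chains(brownian_system_truth(seed = 5,
                                                       n_steps = 20))
  expect_identical(t1$coords, t2$coords)
  c1 <- generate_confined_hydrogens(10, 2, 1, 0.01, 30, seed = 5)
  c2 <- generate_confined_hydrogens(10, 2, 1, 0.01, 30, seed = 5)
  expect_identical(c1$coords, c2$coords)
})

test_that("generator refusals: n_steps and confined step size", {
  expect_error(brownian_system_truth(n_steps = 1), "n_steps")
  expect_error(generate_confined_hydrogens(5, a = 1, D_loc = 10, dt = 0.1,
                                           n_steps = 10), "a/5")
})

test_that("confined motion stays in the sphere and equilibrates uniformly", {
  a <- 2
  tr <- generate_confined_hydrogens(100000, a = a, D_loc = 5, dt = 0.003,
                                    n_steps = 5, seed = 21)
  centers_free <- sweep_center <- NULL
  # radial distance of each atom from its own center in the last frame
  first <- tr$coords[1, , ]
  last <- tr$coords[5, , ]
  # reconstruct centers from the generator's grid layout
  spacing <- 4 * a
  centers <- round(first / spacing) * spacing
  r_last <- sqrt(rowSums((last - centers)^2))
  expect_true(all(r_last <= a + 1e-9))
  # Kolmogorov-Smirnov against the uniform-ball radial CDF (r/a)^3
  ks <- suppressWarnings(ks.test(r_last, function(r) pmin((r / a)^3, 1)))
  expect_gt(ks$p.value, 1e-3)
})

test_that("static confined atoms give unit EISF downstream", {
  tr <- generate_confined_hydrogens(30, a = 2, D_loc = 0, dt = 0.01,
                                    n_steps = 20, seed = 2)
  ei <- eisf_from_trajectory(tr, c(0.4, 1.1, 2.0), n_orientations = 8,
                             remove_com = FALSE)
  expect_equal(ei$A0, rep(1, 3), tolerance = 1e-12)
})

test_that("trajectories survive the XYZ-with-box round trip", {
  tr <- generate_brownian_chains(brownian_system_truth(
    n_chains = 3, D_t = 10, n_steps = 5, seed = 4))
  path <- file.path(tempdir(), "traj_roundtrip.xyz")
  write_xyz_trajectory(tr, path)
  tr2 <- read_xyz_trajectory(path)
  expect_equal(tr2$coords, tr$coords, tolerance = 1e-8)
  expect_identical(tr2$chain_id, tr$chain_id)
  expect_equal(tr2$box_edge, tr$box_edge)
  unlink(path)
})

test_that("corrupted trajectory files fail with a file-and-frame message", {
  path <- file.path(tempdir(), "traj_corrupt.xyz")
  writeLines(c("2", "time=0 box=10 wrapped=1", "H 1 1 0 0 0",
               "H 2 1 5 5 5", "2", "time=0.1 box=10 wrapped=1",
               "H 1 1 0 0 bogus", "H 2 1 5 5 5"), path)
  expect_error(read_xyz_trajectory(path), "frame 2")
  unlink(path)
})
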