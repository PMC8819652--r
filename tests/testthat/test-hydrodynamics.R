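test_that("water viscosity reproduces literature tabulations within 2%", {
  # CRC-style reference values, mPa.s
  ref_h2o <- data.frame(T = c(273.15, 298.15, 323.15, 353.15),
                        eta = c(1.791, 0.890, 0.5465, 0.3540))
  ref_d2o <- data.frame(T = c(293.15, 298.15, 313.15, 333.15),
                        eta = c(1.247, 1.095, 0.786, 0.5506))
  expect_lt(max(abs(viscosity_water(ref_h2o$T, "H2O") / ref_h2o$eta - 1)),
            0.02)
  expect_lt(max(abs(viscosity_water(ref_d2o$T, "D2O") / ref_d2o$eta - 1)),
            0.02)
})

test_that("viscosity is decreasing in T and heavier in D2O", {
  Ts <- seq(278, 360, by = 2)
  expect_true(all(diff(viscosity_water(Ts, "H2O")) < 0))
  expect_true(all(diff(viscosity_water(Ts, "D2O")) < 0))
  expect_true(all(viscosity_water(Ts, "D2O") > viscosity_water(Ts, "H2O")))
  expect_error(viscosity_water(200, "H2O"), "validity range")
})

test_that("salt correction is small at physiological strength and monotone", {
  eta0 <- viscosity_water(298, "D2O")
  expect_identical(viscosity_with_salt(eta0, 0), eta0)
  expect_lt(abs(viscosity_with_salt(eta0, 0.15) / eta0 - 1), 0.02)
  etas <- vapply(seq(0, 1, by = 0.05), viscosity_with_salt, numeric(1),
                 eta0 = eta0)
  expect_true(all(diff(etas) > 0))
  expect_error(viscosity_with_salt(eta0, 0.1, "KCl"), "no viscosity")
})

test_that("Stokes-Einstein chain reproduces the 298 K effective radius", {
  ctx <- ctx_d2o_298()
  expect_equal(stokes_einstein_radius(16.8, ctx), 11.8, tolerance = 0.02)
  # exact round trip and scaling
  expect_equal(stokes_einstein_D(stokes_einstein_radius(7.3, ctx), ctx), 7.3,
               tolerance = 1e-12)
  ctx2 <- hydro_context(298, "D2O", viscosity = 2 * ctx$viscosity)
  expect_equal(stokes_einstein_radius(16.8, ctx2),
               stokes_einstein_radius(16.8, ctx) / 2, tolerance = 1e-12)
  # sphere identity D_r * 4R^2/3 = D_t
  expect_equal(sphere_Dr(9, ctx) * 4 * 81 / 3, stokes_einstein_D(9, ctx),
               tolerance = 1e-12)
})

test_that("IDP Rg-Rh relation reproduces printed forward and inverse values", {
  expect_equal(nygaard_rh(13.8, 24), 14.61, tolerance = 5e-4)
  expect_equal(nygaard_rg_inverse(11.8, 24), 6.0, tolerance = 0.01)
  expect_equal(nygaard_rg_inverse(12.9, 24), 8.1, tolerance = 0.01)
  for (x in c(5, 9, 13.8, 21, 30)) {
    expect_equal(nygaard_rg_inverse(nygaard_rh(x, 24), 24), x,
                 tolerance = 1e-6)
  }
})

test_that("Perrin machinery: printed radius, sphere limit, friction bound", {
  ctx <- ctx_d2o_298()
  pe <- perrin_translational(ellipsoid_shape(32.9, 5), ctx)
  expect_equal(pe$R_h_equiv, 12.65, tolerance = 5e-4)
  # sphere limit is exactly Stokes
  sp <- perrin_translational(ellipsoid_shape(8, 8), ctx)
  expect_equal(sp$D_t, stokes_einstein_D(8, ctx), tolerance = 1e-9)
  expect_equal(perrin_rotational(ellipsoid_shape(8, 8), ctx)$D_r,
               sphere_Dr(8, ctx), tolerance = 1e-7)
  # friction factor >= 1, equality only for the sphere
  expect_equal(perrin_friction_factor(ellipsoid_shape(5, 5)), 1,
               tolerance = 1e-9)
  expect_gt(perrin_friction_factor(ellipsoid_shape(32.9, 5)), 1)
  expect_gt(perrin_friction_factor(ellipsoid_shape(5, 30)), 1)  # oblate too
})

test_that("closed-form Perrin translational radius matches the general
           elliptic-integral friction tensor", {
  ctx <- ctx_d2o_298()
  for (ab in list(c(32.9, 5), c(20, 8), c(4, 12))) {
    ints <- qensdiff:::.ellipsoid_integrals(ab[1], ab[2])
    # orientation-averaged mobility of the triaxial (a, b, b) ellipsoid
    zeta_terms <- c(ints$chi + ab[1]^2 * ints$alpha_a,
                    ints$chi + ab[2]^2 * ints$alpha_b,
                    ints$chi + ab[2]^2 * ints$alpha_b)
    D_oracle <- qensdiff:::.stokes_prefactor_A3_ns(ctx) * 6 / 16 *
      mean(zeta_terms)
    D_closed <- perrin_translational(ellipsoid_shape(ab[1], ab[2]), ctx)$D_t
    expect_equal(D_closed, D_oracle, tolerance = 1e-6)
  }
})

test_that("volume fractions follow both conventions and the cubic rescale", {
  expect_equal(volume_fraction(50), 0.0351, tolerance = 1e-3)
  expect_equal(volume_fraction(50, convention = "solvent"),
               0.0351 / 1.0351, tolerance = 1e-3)
  expect_identical(volume_fraction(0), 0)
  expect_equal(hydrodynamic_volume_fraction(0.03, 10, 10), 0.03)
  expect_equal(hydrodynamic_volume_fraction(0.03, 14.61, 13.8),
               (14.61 / 13.8)^3 * 0.03)
  expect_warning(hydrodynamic_volume_fraction(0.9, 30, 10), "unphysical")
})

test_that("crowding scaling law reproduces the crowded-column values", {
  expect_equal(round(crowding_scale(22.4, 0.03), 1), 21.9)
  expect_equal(crowding_scale(16.0, 0.03), 15.7, tolerance = 0.006)
  expect_equal(round(crowding_scale(59.8, 0.03), 1), 58.4)
  expect_identical(crowding_scale(10, 0), 10)
  # reduction factors in (0, 1], monotone decreasing in phi
  phis <- seq(0, 0.1, by = 0.005)
  f_t <- vapply(phis, crowding_scale, numeric(1), D0 = 1)
  f_r <- vapply(phis, crowding_scale, numeric(1), D0 = 1,
                branch = "rotational")
  expect_true(all(f_t > 0 & f_t <= 1) && all(diff(f_t) < 0))
  expect_true(all(f_r > 0 & f_r <= 1) && all(diff(f_r) <= 0))
  expect_error(crowding_scale(1, 0.9), "validity")
})

test_that("fractal mass-scaling model: round trip, printed-value inversion,
           monotonicity", {
  m <- fractal_model(d_F = 1.6, M = 3036, C = 10353)
  expect_equal(fractal_calibrate(fractal_predict(m), 3036, 1.6), 10353,
               tolerance = 1e-9)
  # the d_F implied by the printed prediction of 41 A^2/ns lies in (1, 2)
  f <- function(d) fractal_predict(fractal_model(d, 3036)) - 41
  d_F <- uniroot(f, c(1.05, 2.5))$root
  expect_gt(d_F, 1); expect_lt(d_F, 2)
  Ds <- vapply(c(1000, 3036, 10000, 1e5), function(M)
    fractal_predict(fractal_model(1.6, M)), numeric(1))
  expect_true(all(diff(Ds) < 0))
})

test_that("high-q scattering slope recovers the fractal dimension", {
  q <- seq(1.9, 2.9, by = 0.02)
  expect_equal(fractal_dimension_from_saxs(q, 7 * q^-1.5), 1.5,
               tolerance = 1e-10)
  # overall intensity scale drops out
  expect_equal(fractal_dimension_from_saxs(q, 1e4 * q^-2.2),
               fractal_dimension_from_saxs(q, q^-2.2), tolerance = 1e-10)
  # multiplicative-noise Monte Carlo stays within +-0.05 of truth
  set.seed(42)
  est <- replicate(100, {
    I <- q^-1.8 * exp(rnorm(length(q), 0, 0.05))
    fractal_dimension_from_saxs(q, I)
  })
  expect_lt(abs(mean(est) - 1.8), 0.05)
  expect_error(fractal_dimension_from_saxs(c(2.1, 2.2), c(1, 1)), "5 points")
})

test_that("apparent-to-translational ratio rescaling", {
  expect_equal(round(apply_apparent_ratio(10.7, 1.27), 1), 13.6)
  expect_identical(apply_apparent_ratio(12.3, 1), 12.3)
  expect_equal(apply_apparent_ratio(10.7, 1.7), 18.19, tolerance = 1e-9)
})

test_that("unit audit: Stokes prefactor at 298 K in D2O is consistent", {
  ctx <- ctx_d2o_298()
  expect_equal(qensdiff:::.stokes_prefactor_A3_ns(ctx),
               stokes_einstein_D(1, ctx) * 1, tolerance = 1e-12)
})
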