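test_that("Kratky transform flattens 1/q^2 decay and keeps the abscissa", {
  q <- seq(0.05, 1, length.out = 200)
  prof <- profile1d(q, 1 / q^2, kind = "q", wavelength = 0.0709)
  kr <- kratky_transform(prof)
  expect_equal(kr$intensity, rep(1, 200))
  expect_identical(kr$abscissa, q)
  tt <- profile1d(10:20, rep(1, 11), kind = "two_theta", wavelength = 0.15)
  expect_error(kratky_transform(tt), "q profile")
})

test_that("harmonic peak detection recovers the long period and order ratios", {
  g <- generate_saxs_meridional(lamellar_params(long_period = 38.5,
                                                phase1_fraction = 15.7 / 38.5))
  hp <- find_harmonic_peaks(kratky_transform(g$profile))
  expect_equal(hp$lp_1st, 38.5, tolerance = 0.1 / 38.5)
  expect_equal(hp$ratio_2nd_3rd, 1.5, tolerance = 0.01 / 1.5)
  # harmonic consistency invariant: |q_n/(n q_1) - 1| < 1e-3
  ok <- hp$peaks[!is.na(hp$peaks$order), ]
  q1 <- ok$q[ok$order == 1]
  expect_true(all(abs(ok$q / (ok$order * q1) - 1) < 1e-3))
})

test_that("single-peak profile yields the first-order period and no higher orders", {
  q <- saxs_q_grid()
  prof <- profile1d(q, 2 + 500 * dnorm(q, 2 * pi / 10, 0.01), kind = "q",
                    wavelength = 0.0709)
  hp <- find_harmonic_peaks(kratky_transform(prof))
  expect_equal(hp$lp_1st, 10, tolerance = 0.05 / 10)
  expect_true(is.na(hp$lp_2nd) && is.na(hp$lp_3rd))
  flat <- profile1d(q, rep(1, length(q)), kind = "q", wavelength = 0.0709)
  expect_error(find_harmonic_peaks(kratky_transform(flat)), "no resolvable")
})

test_that("correlation function matches the real-space autocorrelation oracle", {
  # the target geometry
  g <- generate_saxs_meridional(lamellar_params(long_period = 38.5,
                                                phase1_fraction = 15.7 / 38.5))
  cf <- correlation_function(g$profile)
  expect_equal(cf$Lp, 38.5, tolerance = 0.5 / 38.5)
  expect_equal(cf$Q, max(cf$K))
  expect_equal(cf$d_pI_mean, 15.7, tolerance = 0.05)  # nm, approx phi1*Lp
  expect_true(cf$d_pI <= cf$d_pI_mean + 0.5 && cf$d_pI_mean < cf$Lp)

  # route agreement across phase fractions (high-fidelity harmonics: 8
  # orders, sharp peaks -- truncation bias of the 5-order default is a
  # property of the input, not of the transform)
  for (phi in c(0.3, 0.41, 0.5)) {
    gg <- suppressWarnings(generate_saxs_meridional(
      lamellar_params(long_period = 38.5, phase1_fraction = phi,
                      n_orders = 8, peak_width_sigma = 0.004)))
    cc <- correlation_function(gg$profile)
    lp_oracle <- oracle_K_long_period(38.5, phi)
    expect_equal(cc$Lp, lp_oracle, tolerance = 0.02)
    expect_lt(abs(cc$phase1_fraction - min(phi, 1 - phi)), 0.03)
  }
})

test_that("symmetric lamella: first zero of K at Lp/4", {
  g <- suppressWarnings(generate_saxs_meridional(
    lamellar_params(phase1_fraction = 0.5)))
  cf <- correlation_function(g$profile)
  expect_equal(cf$first_zero, cf$Lp / 4, tolerance = 0.01)
  # closed-form check on the oracle too
  zf <- seq(5, 15, by = 0.01)
  Ko <- oracle_square_wave_K(38.5, 0.5, zf)
  z0 <- zf[which(diff(sign(Ko)) < 0)[1]]
  expect_equal(z0, 38.5 / 4, tolerance = 0.02 / 9.6)
})

test_that("long-period strain reproduces the printed worked examples", {
  expect_equal(long_period_strain(c(37.5, 44.7))[2], 19.2,
               tolerance = 1e-3)
  expect_equal(long_period_strain(c(37.5, 38.1))[2], 1.6, tolerance = 1e-3)
  expect_equal(long_period_strain(rep(40, 5)), rep(0, 5))
  expect_error(long_period_strain(c(0, 38)), "zero reference")
})

test_that("phase decomposition closure", {
  expect_equal(phase2_thickness(38.5, 15.7), 22.8)
  expect_error(phase2_thickness(38.5, 40), "phase1_thickness")
})

test_that("Scherrer size recovery across the relevant size range", {
  instr <- 0.005
  for (d_true in c(50, 100, 150, 220, 300)) {
    g <- generate_saxs_equatorial(bundle_thickness = d_true,
                                  instrumental_fwhm = instr)
    pk <- fit_equatorial_peak(g$profile)
    sc <- scherrer_thickness(pk$center_q, pk$fwhm_q, instr, 0.15418)
    expect_lt(abs(sc$d - d_true) / d_true, 0.05)
  }
  # the modelled silk's bundle: 150 +/- 7 nm
  g <- generate_saxs_equatorial(bundle_thickness = 150,
                                instrumental_fwhm = instr)
  pk <- fit_equatorial_peak(g$profile)
  expect_equal(scherrer_thickness(pk$center_q, pk$fwhm_q, instr,
                                  0.15418)$d,
               150, tolerance = 7 / 150)
  # no instrumental broadening: beta = beta_obs
  s0 <- scherrer_thickness(1.337, 0.04, 0, 0.15418)
  expect_equal(s0$beta, s0$beta_obs)
  # doubling the true size halves the corrected beta
  g1 <- generate_saxs_equatorial(bundle_thickness = 100,
                                 instrumental_fwhm = instr)
  g2 <- generate_saxs_equatorial(bundle_thickness = 200,
                                 instrumental_fwhm = instr)
  b <- function(g) {
    pk <- fit_equatorial_peak(g$profile)
    scherrer_thickness(pk$center_q, pk$fwhm_q, instr, 0.15418)$beta
  }
  expect_equal(b(g1) / b(g2), 2, tolerance = 1e-3)
  expect_error(scherrer_thickness(1.337, 0.004, 0.005, 0.15418),
               "not resolvable")
})

test_that("deformation series assembly aligns, strains and stages correctly", {
  log_t <- seq(0, 330, by = 1)
  curve <- generate_stress_strain(tensile_params(fracture_strain = 0.22,
                                                 hardening_slope = 2.5))
  strain_of_t <- 0.22 * log_t / 330
  tl <- data.frame(time = log_t, displacement = 15 * strain_of_t,
                   stress = approx(curve$curve$strain, curve$curve$stress,
                                   strain_of_t)$y)
  ft <- c(seq(0, 324, by = 9), 330)
  lp1 <- 37.5 + (44.7 - 37.5) * ft / 330
  frames <- data.frame(time = ft,
                       d002 = 3.52 + 0.05 * ft / 330,
                       lp_2nd = lp1 / 2, lp_3rd = lp1 / 3)
  ds <- assemble_deformation_series(frames, tl)
  expect_s3_class(ds, "deformation_series")
  expect_equal(nrow(ds), length(ft))
  expect_equal(ds$bulk_strain[1], 0)
  expect_equal(max(ds$bulk_strain), 22, tolerance = 1e-6)
  expect_equal(ds$lp_1st, lp1, tolerance = 1e-9)   # 3 * lp_3rd reconstruction
  expect_equal(ds$crystal_strain[1], 0)
  expect_equal(ds$lp_strain[length(ft)], 19.2, tolerance = 1e-3)
  st <- attr(ds, "stages")
  expect_false(is.null(st))
  expect_equal(st$yield_strain * 100, 3.3, tolerance = 0.2 / 3.3)

  # single frame: degenerate series, zero strains
  one <- assemble_deformation_series(frames[1, , drop = FALSE], tl)
  expect_equal(nrow(one), 1L)
  expect_equal(one$crystal_strain, 0)
  expect_equal(one$lp_strain, 0)

  # misaligned clock: error naming the frame
  bad <- frames
  bad$time[3] <- bad$time[3] + 400
  expect_error(assemble_deformation_series(bad, tl), "misaligned")
})
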