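paper_cell <- unit_cell(9.39, 9.50, 6.98)

test_that("radial scan of a synthetic diagram round-trips the generating profile", {
  p <- beta_sheet_waxd_params(0.44, orientation_fwhm = 18)
  d <- generate_fiber_diagram(p, image_shape = c(1024L, 1024L),
                              geometry = fine_geometry())
  prof <- scan_two_theta_profile(d, two_theta_range = c(10, 37),
                                 azimuth_range = c(0, -180))
  model <- generate_waxd_profile(p, two_theta = prof$abscissa)$profile
  rms <- sqrt(mean((prof$intensity - model$intensity)^2))
  expect_lt(rms / max(model$intensity), 0.01)
})

test_that("uniform image scans to a flat profile", {
  d <- fiber_diagram(matrix(7, 256L, 256L),
                     detector_geometry(beam_center = c(128.5, 128.5),
                                       pixel_size = 0.3))
  prof <- scan_two_theta_profile(d, two_theta_range = c(10, 37))
  expect_equal(max(prof$intensity) - min(prof$intensity), 0)
})

test_that("crystallinity fitting recovers the generating truth", {
  g <- generate_waxd_profile(beta_sheet_waxd_params(0.44))
  fit <- fit_crystallinity(g$profile, paper_cell)
  expect_equal(fit$Xc, 44, tolerance = 2 / 44)
  expect_equal(fit$Xc, 100 * fit$Ic / (fit$Ic + fit$Ia))

  # zero crystalline area
  g0 <- generate_waxd_profile(beta_sheet_waxd_params(0))
  expect_lt(fit_crystallinity(g0$profile, paper_cell)$Xc, 0.01)

  # equal-area crystalline + amorphous pair: Xc = 50 +/- 1 by symmetry
  pos <- beta_sheet_positions(paper_cell, 0.15418)
  two <- waxd_params(
    data.frame(two_theta = pos$two_theta[1], sigma = 0.45, area = 60,
               label = "200"),
    list(two_theta = 20.5, sigma = 3.2, area = 60))
  fit2 <- fit_crystallinity(generate_waxd_profile(two)$profile, paper_cell)
  expect_equal(fit2$Xc, 50, tolerance = 1 / 50)
})

test_that("crystallinity recovery property holds over random noiseless profiles", {
  set.seed(101)
  for (i in 1:20) {
    xc <- runif(1, 0.2, 0.7)
    g <- generate_waxd_profile(
      beta_sheet_waxd_params(xc, rel_areas = runif(6, 0.1, 1)))
    fit <- fit_crystallinity(g$profile, paper_cell)
    expect_lt(abs(fit$Xc - 100 * xc), 1)
  }
})

test_that("unit-cell solving inverts the forward d-spacing oracle", {
  # the silk cell, forward then inverted
  sol <- solve_unit_cell(oracle_d(9.39, 9.50, 6.98, 2, 0, 0),
                         oracle_d(9.39, 9.50, 6.98, 2, 1, 0),
                         oracle_d(9.39, 9.50, 6.98, 0, 0, 2))
  expect_equal(c(sol$a, sol$b, sol$c), c(9.39, 9.50, 6.98),
               tolerance = 0.01 / 9.39)
  # the reference silkworm cell round-trips identically
  ref <- solve_unit_cell(oracle_d(9.38, 9.49, 6.98, 2, 0, 0),
                         oracle_d(9.38, 9.49, 6.98, 2, 1, 0),
                         oracle_d(9.38, 9.49, 6.98, 0, 0, 2))
  expect_equal(c(ref$a, ref$b, ref$c), c(9.38, 9.49, 6.98),
               tolerance = 1e-9)
  # square basal cell: d210 = a / sqrt(5)
  expect_equal(d_spacing(unit_cell(9, 9, 7), 2, 1, 0), 9 / sqrt(5),
               tolerance = 1e-12)
  expect_error(solve_unit_cell(4.2, 4.7, 3.5), "d210")
  # property: random orthorhombic cells invert to 1e-3 Angstrom
  set.seed(7)
  for (i in 1:25) {
    a <- runif(1, 8, 11); b <- runif(1, a / 2 + 0.6, 12)
    cc <- runif(1, 6, 8)
    s <- solve_unit_cell(oracle_d(a, b, cc, 2, 0, 0),
                         oracle_d(a, b, cc, 2, 1, 0),
                         oracle_d(a, b, cc, 0, 0, 2))
    expect_lt(max(abs(c(s$a - a, s$b - b, s$c - cc))), 1e-3)
  }
})

test_that("crystal strain is the stated relative d002 change", {
  expect_equal(crystal_strain(c(3.52, 3.54))[2], 0.568, tolerance = 1e-3)
  expect_equal(crystal_strain(c(3.52, 3.57))[2], 1.420, tolerance = 1e-3)
  expect_equal(crystal_strain(rep(3.5, 6)), rep(0, 6))
  # invariant under uniform rescaling
  d <- c(3.52, 3.54, 3.57)
  expect_equal(crystal_strain(d), crystal_strain(10 * d))
  expect_error(crystal_strain(c(0, 3.5)), "zero reference")
})

test_that("orientation index tracks the generated azimuthal spread", {
  geom <- detector_geometry()
  d18 <- generate_fiber_diagram(
    beta_sheet_waxd_params(0.44, orientation_fwhm = 18), geometry = geom)
  o18 <- orientation_index(d18)
  expect_equal(o18$fwhm, 18, tolerance = 0.3 / 18)
  expect_equal(o18$index, 0.90, tolerance = 0.005 / 0.9)
  # near-perfect orientation
  o1 <- orientation_index(generate_fiber_diagram(
    beta_sheet_waxd_params(0.44, orientation_fwhm = 1), geometry = geom))
  expect_equal(o1$index, (180 - 1) / 180, tolerance = 0.01)
  # monotone decreasing in the generated FWHM
  idx <- vapply(c(9, 18, 45, 90, 150), function(fw)
    orientation_index(generate_fiber_diagram(
      beta_sheet_waxd_params(0.44, orientation_fwhm = fw),
      geometry = geom))$index, numeric(1))
  expect_true(all(diff(idx) < 0))
  # flat profile -> index 0 with a warning
  flat <- fiber_diagram(matrix(5, 512L, 512L), geom)
  expect_warning(of <- orientation_index(flat), "flat|discernible")
  expect_equal(of$index, 0)
})

test_that("002 centre fitting reaches sub-bin precision", {
  tt <- seq(10, 14, length.out = 300)
  d002 <- 3.524
  tt0 <- d_to_two_theta(d002, 0.0709)
  prof <- profile1d(tt, 2 + 40 * dnorm(tt, tt0, 0.12),
                    kind = "two_theta", wavelength = 0.0709)
  fit <- fit_002_center(prof, tt0 + 0.2)
  expect_equal(fit$d, d002, tolerance = 1e-5)
})
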