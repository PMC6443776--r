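test_that("meridional generator places exact harmonic peaks with the stated envelope", {
  g <- generate_saxs_meridional(lamellar_params(
    long_period = 38.5, phase1_fraction = 15.7 / 38.5, n_orders = 5))
  # q_n = 2*pi*n/L_p, computed by hand: 0.1632 * n
  expect_equal(g$truth$peak_positions_q, 0.1632 * (1:5),
               tolerance = 1e-4)
  expect_equal(g$truth$peak_positions_q / g$truth$peak_positions_q[1],
               1:5, tolerance = 1e-6)
  # argmax-scan oracle recovers the positions from the trace itself
  # (flat background subtracted first; the 5th-order envelope is tiny)
  bgsub <- profile1d(g$profile$abscissa,
                     g$profile$intensity - min(g$profile$intensity),
                     kind = "q", wavelength = g$profile$wavelength)
  kr <- kratky_transform(bgsub)
  found <- oracle_peak_positions(kr, 5)
  expect_equal(found, g$truth$peak_positions_q, tolerance = 5e-3)
  expect_equal(g$truth$phase1_thickness, 15.7)
  expect_equal(g$truth$phase2_thickness, 22.8)
})

test_that("symmetric lamella suppresses even orders (with a warning, not an error)", {
  expect_warning(
    g <- generate_saxs_meridional(lamellar_params(phase1_fraction = 0.5,
                                                  n_orders = 2)),
    "envelope vanishes")
  expect_equal(g$truth$suppressed_orders, 2L)
  expect_equal(g$truth$peak_areas[2], 0, tolerance = 1e-20)
})

test_that("seeded generation is bit-reproducible and seeds change only noise", {
  noise <- list(type = "poisson", mean_counts = 1e4)
  g1 <- generate_saxs_meridional(lamellar_params(noise = noise, seed = 11))
  g2 <- generate_saxs_meridional(lamellar_params(noise = noise, seed = 11))
  g3 <- generate_saxs_meridional(lamellar_params(noise = noise, seed = 12))
  expect_identical(g1$profile$intensity, g2$profile$intensity)
  expect_false(identical(g1$profile$intensity, g3$profile$intensity))
  expect_identical(g1$truth, g3$truth)

  w1 <- generate_stress_strain(tensile_params(noise_sd = 0.02, seed = 4))
  w2 <- generate_stress_strain(tensile_params(noise_sd = 0.02, seed = 4))
  expect_identical(w1$curve$stress, w2$curve$stress)

  s1 <- generate_sequences(sequence_params(seed = 9))
  s2 <- generate_sequences(sequence_params(seed = 9))
  expect_identical(s1$sequence, s2$sequence)
})

test_that("equatorial generator follows the Scherrer/quadrature width model", {
  g <- generate_saxs_equatorial(bundle_thickness = 150,
                                fibril_spacing = 4.7,
                                instrumental_fwhm = 0)
  expect_equal(g$truth$peak_q, 2 * pi / 4.7, tolerance = 1e-12)
  expect_equal(g$truth$peak_q, 1.337, tolerance = 1e-3)
  # infinite-crystal limit: FWHM -> instrumental only
  g_inf <- generate_saxs_equatorial(bundle_thickness = 1e9,
                                    instrumental_fwhm = 0)
  expect_lt(g_inf$truth$fwhm_obs_q, 1e-8)
  expect_error(generate_saxs_equatorial(wavelength = 0), "wavelength")
  expect_error(generate_saxs_equatorial(bundle_thickness = 2,
                                        fibril_spacing = 4.7),
               "bundle_thickness")
})

test_that("WAXD generator records the exact area-ratio crystallinity", {
  pos <- beta_sheet_positions(unit_cell(9.39, 9.50, 6.98), 0.15418)
  one <- waxd_params(
    data.frame(two_theta = pos$two_theta[1], sigma = 0.4, area = 50),
    list(two_theta = 20.5, sigma = 3, area = 50))
  expect_equal(one$crystallinity_true, 0.5)
  zero <- waxd_params(
    data.frame(two_theta = pos$two_theta[1], sigma = 0.4, area = 0),
    list(two_theta = 20.5, sigma = 3, area = 50))
  expect_equal(zero$crystallinity_true, 0)
  expect_error(waxd_params(
    data.frame(two_theta = 20, sigma = 0.4, area = -1),
    list(two_theta = 20.5, sigma = 3, area = 50)), "non-negative")
  # numeric-integration oracle agrees with the recorded truth (< 0.5%)
  g <- generate_waxd_profile(beta_sheet_waxd_params(0.44))
  expect_equal(oracle_crystallinity(g$truth), 0.44, tolerance = 5e-3)
})

test_that("tensile generator ground truth matches closed forms and the trapezoid oracle", {
  # the modelled silk's averages: E 28.1 GPa, strength 2.0 GPa at 0.32
  g <- generate_stress_strain(tensile_params())
  expect_equal(g$truth$modulus, 28.1)
  expect_equal(g$truth$strength, 2.0, tolerance = 1e-12)
  expect_equal(g$truth$extensibility, 0.32)
  expect_equal(g$truth$toughness, oracle_toughness(g$curve),
               tolerance = 1e-9)
  # pure elastic: toughness = E eps^2 / 2
  pe <- generate_stress_strain(tensile_params(modulus = 10,
                                              yield_strain = 0.1,
                                              fracture_strain = 0.1))
  expect_equal(pe$truth$toughness, 1000 * 10 * 0.1^2 / 2,
               tolerance = 1e-12)
  expect_error(tensile_params(yield_strain = 0.5, fracture_strain = 0.3),
               "yield_strain")
})

test_that("sequence generator emits the stated repeat architecture", {
  g <- generate_sequences(sequence_params(seed = 21))
  expect_equal(nchar(g$sequence), 5 * 160)
  blocks <- find_polyalanine_blocks(g$sequence)
  expect_equal(nrow(blocks), 5L)
  expect_true(all(blocks$length == 22L))
  # Gly+Ala molar fraction about 80%
  chars <- strsplit(g$sequence, "")[[1]]
  expect_equal(mean(chars %in% c("G", "A")), 0.80, tolerance = 0.03)
  expect_error(sequence_params(n_motifs = 0), "n_motifs")
  one <- generate_sequences(sequence_params(n_motifs = 1, seed = 3))
  b1 <- find_polyalanine_blocks(one$sequence)
  expect_equal(nrow(b1), 1L)
  expect_equal(b1$length, 22L)
})

test_that("profile and fibre-diagram text round trips preserve the data", {
  g <- generate_saxs_meridional(lamellar_params())
  p <- withr::local_tempfile(fileext = ".dat")
  write_profile(g$profile, p)
  back <- read_profile(p)
  expect_equal(back$abscissa, g$profile$abscissa)
  expect_equal(back$intensity, g$profile$intensity)
  expect_identical(back$kind, "q")
  expect_equal(back$wavelength, g$profile$wavelength)

  d <- generate_fiber_diagram(beta_sheet_waxd_params(0.3),
                              image_shape = c(128L, 128L),
                              geometry = detector_geometry(
                                beam_center = c(64.5, 64.5),
                                pixel_size = 0.6))
  ip <- withr::local_tempfile(fileext = ".txt")
  write_fiber_diagram(d, ip)
  back2 <- read_fiber_diagram(ip)
  expect_equal(back2$image, d$image, tolerance = 1e-10)
  expect_equal(back2$geometry$camera_distance,
               d$geometry$camera_distance)
  expect_error(fiber_diagram(matrix(0, 10, 10),
                             detector_geometry(beam_center = c(50, 5))),
               "beam center")
})
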