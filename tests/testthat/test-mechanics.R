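test_that("cross-section area follows the tilt-corrected ellipse formula", {
  cs0 <- cross_section_area(4.42, tilt_theta = 0, axial_ratio = 1.70)
  expect_equal(cs0$area, pi * 4.42^2 / (4 * 1.70), tolerance = 1e-12)
  expect_equal(cs0$area, 9.03, tolerance = 1e-3)
  # tilt 10.37 degrees inflates the area by 1/cos^2 = 1.0333
  cs <- cross_section_area(4.42)
  expect_equal(cs$area / cs0$area, 1 / cos(10.37 * pi / 180)^2,
               tolerance = 1e-12)
  expect_equal(cs$area / cs0$area, 1.0333, tolerance = 3e-4)
  expect_equal(cs$n_filaments, 2L)        # a fibre is a pair of filaments
  expect_equal(axial_ratio(4.42, 2.55), 1.73, tolerance = 0.005 / 1.73)
  expect_error(cross_section_area(4.42, tilt_theta = 90), "tilt")
  # strictly increasing in tilt
  areas <- vapply(seq(0, 80, by = 10),
                  function(t) cross_section_area(4.42, t)$area, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("force-to-stress conversion is unit-consistent", {
  cs <- cross_section_area(4.42, tilt_theta = 0, axial_ratio = 1.70)
  cs$area <- 5; cs$n_filaments <- 2L          # total 10 um^2
  expect_equal(force_to_stress(1e-3, cs), 0.1)
  expect_equal(force_to_stress(0, cs), 0)
  cs$area <- 0
  expect_error(force_to_stress(1, cs), "zero total")
})

test_that("bundle-mode area estimator is dimensionally correct", {
  # 1 mg over 10 mm at 1 g/cm^3: V = 1e-3 cm^3, A = 1e-3 cm^2 = 1e5 um^2
  expect_equal(area_from_mass(1, 10, 1), 1e5)
  expect_equal(area_from_mass(2, 10, 1.35), 2e5 / 1.35, tolerance = 1e-12)
})

test_that("tensile properties recover the generating truth", {
  g <- generate_stress_strain(tensile_params())
  tp <- tensile_properties(g$curve)
  expect_equal(tp$modulus, 28.1, tolerance = 0.1 / 28.1)
  expect_equal(tp$strength, g$truth$strength, tolerance = 1e-9)
  expect_equal(tp$extensibility, 0.32, tolerance = 1e-9)
  expect_equal(tp$toughness, g$truth$toughness, tolerance = 1e-6)
  # linear curve to 0.1 at 10 GPa: toughness = 50 MJ m^-3
  lin <- generate_stress_strain(tensile_params(modulus = 10,
                                               yield_strain = 0.1,
                                               fracture_strain = 0.1))
  expect_equal(tensile_properties(lin$curve)$toughness, 50,
               tolerance = 1e-9)
})

test_that("property recovery stays below 0.5% over random noiseless curves", {
  set.seed(33)
  worst <- 0
  for (i in 1:100) {
    p <- tensile_params(modulus = runif(1, 5, 60),
                        yield_strain = runif(1, 0.02, 0.05),
                        hardening_slope = runif(1, 0.5, 8),
                        fracture_strain = runif(1, 0.1, 0.5))
    g <- generate_stress_strain(p)
    tp <- tensile_properties(g$curve)
    rel <- abs(c(tp$modulus / g$truth$modulus,
                 tp$strength / g$truth$strength,
                 tp$extensibility / g$truth$extensibility,
                 tp$toughness / g$truth$toughness) - 1)
    worst <- max(worst, rel)
  }
  expect_lt(worst, 0.005)
})

test_that("toughness is additive over stages", {
  g <- generate_stress_strain(tensile_params())
  st <- stage_segmentation(g$curve)
  e <- g$curve$strain; s <- g$curve$stress
  cut <- st$yield_strain
  e1 <- c(e[e <= cut], cut); s1 <- approx(e, s, e1)$y
  e2 <- c(cut, e[e > cut]); s2 <- approx(e, s, e2)$y
  total <- trapz(e, s)
  expect_equal(trapz(e1, s1) + trapz(e2, s2), total,
               tolerance = 1e-6)
})

test_that("crystal modulus regression recovers slope and flags saturation", {
  set.seed(5)
  ec <- seq(0, 1.4, length.out = 30)            # percent
  stress <- 106 * ec / 100 + rnorm(30, 0, 0.02)
  cm <- crystal_modulus(stress, ec)
  expect_equal(cm$slope, 106, tolerance = 2 / 106)
  expect_false(cm$nonlinear)
  # exact line: exact slope, zero residual
  exact <- suppressWarnings(crystal_modulus(42 * ec / 100, ec))
  expect_equal(exact$slope, 42, tolerance = 1e-9)
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)
  # saturating series (crystal strain levels off at high stress)
  sat_stress <- seq(0, 0.7, length.out = 30)
  sat_ec <- 100 * 0.004 * (1 - exp(-sat_stress / 0.15))
  expect_true(crystal_modulus(sat_stress, sat_ec)$nonlinear)
  expect_error(crystal_modulus(c(1, 2, 3), c(0.5, 0.5, 0.5)), "degenerate")
})

test_that("stage segmentation finds the 0.2%-offset yield and the fracture", {
  g <- generate_stress_strain(tensile_params())
  st <- stage_segmentation(g$curve)
  expect_equal(st$yield_strain * 100, 3.3, tolerance = 0.3 / 3.3)
  expect_equal(st$fracture_strain, 0.32, tolerance = 1e-6)
  expect_identical(st$stages$stage[1:2], c("I", "II"))
  # purely elastic curve: single stage with a warning
  pe <- generate_stress_strain(tensile_params(modulus = 20,
                                              yield_strain = 0.2,
                                              fracture_strain = 0.2))
  expect_warning(st1 <- stage_segmentation(pe$curve), "single-stage")
  expect_identical(st1$stages$stage, "I")
})
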