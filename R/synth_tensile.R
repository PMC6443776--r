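#' Parameters of the three-stage tensile model
#'
#' Piecewise-linear engineering stress–strain law: elastic loading at slope
#' `modulus` up to `yield_strain`, then linear strain hardening at slope
#' `hardening_slope` up to `fracture_strain`. Defaults reproduce the average
#' single-fibre mechanics of the modelled silk (modulus 28.1 GPa, strength
#' 2.0 GPa at extensibility 0.32, yield at the stage-I bulk strain 3.3%), the
#' hardening slope following from those four numbers.
#'
#' @param modulus Young's modulus E in GPa (> 0).
#' @param yield_strain engineering strain at yield, in (0, fracture_strain).
#' @param hardening_slope stage-II slope in GPa.
#' @param fracture_strain engineering strain at fracture.
#' @param noise_sd Gaussian stress noise s.d. in GPa (0 = noiseless).
#' @param seed integer RNG seed for the noise.
#' @return object of class `tensile_params`.
#' @export
tensile_params <- function(modulus = 28.1,
                           yield_strain = 0.033,
                           hardening_slope = (2.0 - 28.1 * 0.033) /
                             (0.32 - 0.033),
                           fracture_strain = 0.32,
                           noise_sd = 0,
                           seed = NULL) {
  if (modulus <= 0) stop("modulus must be positive")
  if (yield_strain <= 0 || yield_strain > fracture_strain)
    stop("need 0 < yield_strain <= fracture_strain")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(modulus = modulus, yield_strain = yield_strain,
                 hardening_slope = hardening_slope,
                 fracture_strain = fracture_strain,
                 noise_sd = noise_sd, seed = seed),
            class = "tensile_params")
}

#' Engineering stress–strain curve
#'
#' @param strain engineering strain, starting at 0 and non-decreasing.
#' @param stress stress in GPa, finite.
#' @return object of class `stress_strain_curve`.
#' @export
stress_strain_curve <- function(strain, stress) {
  strain <- as.numeric(strain); stress <- as.numeric(stress)
  if (length(strain) != length(stress)) stop("length mismatch")
  if (strain[1] != 0) stop("strain must start at 0")
  if (any(diff(strain) < 0)) stop("strain must be non-decreasing")
  if (!all(is.finite(stress))) stop("stress must be finite")
  structure(list(strain = strain, stress = stress),
            class = "stress_strain_curve")
}

## closed-form noiseless stress law
tensile_law <- function(params, strain) {
  ey <- params$yield_strain
  ifelse(strain <= ey,
         params$modulus * strain,
         params$modulus * ey + params$hardening_slope * (strain - ey))
}

#' Simulate a stress–strain curve with known tensile properties
#'
#' Samples the piecewise-linear law of [tensile_params()] on a strain grid
#' that always contains the yield breakpoint (so the recorded closed-form
#' toughness matches trapezoidal integration of the noiseless samples
#' exactly), adds optional Gaussian stress noise, and records the ground
#' truth: modulus, strength, extensibility, and toughness (MJ m\eqn{^{-3}},
#' closed-form area under the noiseless curve, 1 GPa strain = 1000 MJ
#' m\eqn{^{-3}}).
#'
#' @param params a [tensile_params].
#' @param n_points number of strain samples (breakpoints appended).
#' @return list of class `synth_curve` with `curve` (a
#'   [stress_strain_curve]) and `truth`.
#' @export
generate_stress_strain <- function(params, n_points = 500L) {
  stopifnot(inherits(params, "tensile_params"))
  strain <- sort(unique(c(seq(0, params$fracture_strain,
                              length.out = n_points),
                          params$yield_strain)))
  stress <- tensile_law(params, strain)
  if (params$noise_sd > 0)
    stress <- with_seed(params$seed,
                        stress + stats::rnorm(length(stress), 0,
                                              params$noise_sd))
  ey <- params$yield_strain; ef <- params$fracture_strain
  sy <- params$modulus * ey
  sf <- tensile_law(params, ef)
  toughness_gpa <- params$modulus * ey^2 / 2 +
    (sy + sf) / 2 * (ef - ey)
  structure(list(
    curve = stress_strain_curve(strain, stress),
    truth = list(modulus = params$modulus,
                 strength = sf,
                 extensibility = ef,
                 yield_strain = ey,
                 yield_stress = sy,
                 toughness = 1000 * toughness_gpa)),
    class = "synth_curve")
}
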