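#' Tilt-corrected elliptical cross-section of a silk filament
#'
#' The filament cross-section is modelled as an ellipse of axial ratio
#' \eqn{R = L_a/L_b}. When the pair of conjugated filaments is tilted by
#' \eqn{\theta}, the optically measured major axis is the projection
#' \eqn{L'_a = L_a\cos\theta}, so the true per-filament area is
#' \deqn{A = \frac{\pi}{4 R \cos^2\theta}\,L'^2_a .}
#'
#' @param L_a_apparent measured (projected) major axis \eqn{L'_a} in \eqn{\mu}m.
#' @param tilt_theta tilt angle in degrees (default 10.37, the average tilt);
#'   must be < 90.
#' @param axial_ratio \eqn{L_a/L_b} (default 1.70).
#' @param n_filaments filaments per fibre (default 2: each fibre is a pair).
#' @return object of class `cross_section`: `L_a`, `L_b`, `L_a_apparent`
#'   (\eqn{\mu}m), `tilt_theta` (deg), `axial_ratio`, `area` (per filament,
#'   \eqn{\mu m^2}), `n_filaments`.
#' @export
cross_section_area <- function(L_a_apparent, tilt_theta = 10.37,
                               axial_ratio = 1.70, n_filaments = 2L) {
  if (L_a_apparent <= 0 || axial_ratio <= 0) stop("inputs must be positive")
  if (tilt_theta < 0 || tilt_theta >= 90)
    stop("tilt angle must lie in [0, 90) degrees")
  ct <- cos(tilt_theta * pi / 180)
  L_a <- L_a_apparent / ct
  structure(list(L_a = L_a, L_b = L_a / axial_ratio,
                 L_a_apparent = L_a_apparent,
                 tilt_theta = tilt_theta, axial_ratio = axial_ratio,
                 area = pi / (4 * axial_ratio * ct^2) * L_a_apparent^2,
                 n_filaments = as.integer(n_filaments)),
            class = "cross_section")
}

#' Axial ratio of measured ellipse axes
#'
#' @param L_a,L_b major and minor axes (same units).
#' @return \eqn{L_a/L_b}.
#' @export
axial_ratio <- function(L_a, L_b) {
  if (any(c(L_a, L_b) <= 0)) stop("axes must be positive")
  L_a / L_b
}

#' Cross-sectional area of a fibre bundle from mass and length
#'
#' Alternative estimator for bundle-mode tests: \eqn{A = m/(\rho l)}.
#'
#' @param mass_mg bundle mass in mg.
#' @param length_mm bundle length in mm.
#' @param density_g_cm3 fibre density in g cm\eqn{^{-3}} (e.g. 1.35 for
#'   *B. mori*, 1.31 for *A. assama*).
#' @return area in \eqn{\mu m^2}.
#' @export
area_from_mass <- function(mass_mg, length_mm, density_g_cm3) {
  if (any(c(mass_mg, length_mm, density_g_cm3) <= 0))
    stop("inputs must be positive")
  # A [cm^2] = (m [g]) / (rho [g cm^-3] * l [cm]); 1 cm^2 = 1e8 um^2
  (mass_mg * 1e-3) / (density_g_cm3 * length_mm * 0.1) * 1e8
}

#' Convert tensile force to engineering stress
#'
#' Stress = force / (n_filaments \eqn{\times} per-filament area); 1 N over
#' 1 \eqn{\mu m^2} is 1000 GPa.
#'
#' @param force_N force series in N.
#' @param cross_section a [cross_section_area()] result.
#' @return stress in GPa.
#' @export
force_to_stress <- function(force_N, cross_section) {
  stopifnot(inherits(cross_section, "cross_section"))
  total <- cross_section$n_filaments * cross_section$area
  if (total <= 0) stop("zero total cross-sectional area")
  force_N / total * 1000
}

## fracture point: last sample at >= 95% of the global stress maximum
## (handles the gradual post-peak decay of fibre bundles)
fracture_index <- function(stress, frac = 0.95) {
  max(which(stress >= frac * max(stress)))
}

#' Tensile properties of a stress–strain curve
#'
#' Modulus = least-squares slope over the elastic window (default strain
#' 0.2%–1.5%); strength and extensibility at the fracture point (last sample
#' at \eqn{\ge} 95% of the global stress maximum); toughness by trapezoidal
#' integration to fracture, converted to MJ m\eqn{^{-3}} (1 GPa strain =
#' 1000 MJ m\eqn{^{-3}}).
#'
#' @param curve a [stress_strain_curve].
#' @param elastic_fit_window strain window for the modulus fit.
#' @param mode `"window"` (least squares over the window) or `"tangent"`
#'   (secant slope at the origin over the first points).
#' @return object of class `tensile_properties`: `modulus` (GPa),
#'   `strength` (GPa), `extensibility`, `toughness` (MJ m\eqn{^{-3}}).
#' @export
tensile_properties <- function(curve,
                               elastic_fit_window = c(0.002, 0.015),
                               mode = c("window", "tangent")) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  mode <- match.arg(mode)
  e <- curve$strain; s <- curve$stress
  if (any(diff(e) < 0)) stop("non-monotone strain")
  if (mode == "window") {
    keep <- e >= elastic_fit_window[1] & e <= elastic_fit_window[2]
    if (sum(keep) < 2) stop("elastic window outside the data")
    modulus <- unname(stats::coef(stats::lm(s[keep] ~ e[keep]))[2])
  } else {
    keep <- seq_len(max(3L, min(10L, length(e))))
    modulus <- unname(stats::coef(stats::lm(s[keep] ~ e[keep]))[2])
  }
  i_f <- fracture_index(s)
  structure(list(modulus = modulus,
                 strength = s[i_f],
                 extensibility = e[i_f],
                 toughness = 1000 * trapz(e[seq_len(i_f)], s[seq_len(i_f)])),
            class = "tensile_properties")
}

#' @export
print.tensile_properties <- function(x, ...) {
  cat(sprintf(
    "<tensile_properties> E = %.2f GPa, strength = %.3f GPa, extensibility = %.3f, toughness = %.1f MJ m^-3\n",
    x$modulus, x$strength, x$extensibility, x$toughness))
  invisible(x)
}

#' Crystal modulus by stress vs crystal-strain regression
#'
#' Ordinary least squares of tensile stress (GPa) against crystal strain
#' (supplied in percent, regressed as a fraction); the slope is the apparent
#' crystal modulus. A linearity diagnostic flags saturating behaviour
#' (\eqn{R^2} below `r2_threshold`).
#'
#' @param stress stress series, GPa.
#' @param crystal_strain_pct crystal strain series in percent.
#' @param r2_threshold nonlinearity flag threshold (default 0.98).
#' @return list: `slope` (GPa), `slope_se`, `intercept`, `r_squared`,
#'   `nonlinear` (logical).
#' @export
crystal_modulus <- function(stress, crystal_strain_pct,
                            r2_threshold = 0.98) {
  ec <- crystal_strain_pct / 100
  if (length(stress) < 3 || length(ec) != length(stress))
    stop("need >= 3 paired points")
  if (stats::sd(ec) == 0) stop("degenerate: constant crystal strain")
  fit <- stats::lm(stress ~ ec)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       slope_se = sm$coefficients[2, 2],
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       nonlinear = sm$r.squared < r2_threshold)
}

#' Deformation-stage segmentation of a stress–strain curve
#'
#' Stage I is the initial elastic region up to the 0.2%-offset yield point
#' (intersection of the curve with a line of the elastic slope offset by
#' 0.2% strain); stage II runs from yield to the fracture point; stage III
#' is the post-fracture tail if present. A curve that never crosses the
#' offset line is reported as single-stage with a warning.
#'
#' @param curve a [stress_strain_curve].
#' @param elastic_fit_window window for the elastic slope (strain).
#' @param offset strain offset of the yield construction (default 0.002).
#' @return list: `yield_strain`, `yield_stress`, `fracture_strain`,
#'   `fracture_stress`, `stages` (data.frame stage/strain_from/strain_to).
#' @export
stage_segmentation <- function(curve,
                               elastic_fit_window = c(0.002, 0.015),
                               offset = 0.002) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  e <- curve$strain; s <- curve$stress
  keep <- e >= elastic_fit_window[1] & e <= elastic_fit_window[2]
  if (sum(keep) < 2) stop("elastic window outside the data")
  E <- unname(stats::coef(stats::lm(s[keep] ~ e[keep]))[2])
  i_f <- fracture_index(s)
  line <- E * (e - offset)
  below <- which(line >= s & e > offset)
  below <- below[below <= i_f]
  if (!length(below)) {
    warning("no yield point detectable: single-stage (elastic) curve",
            call. = FALSE)
    return(list(yield_strain = NA_real_, yield_stress = NA_real_,
                fracture_strain = e[i_f], fracture_stress = s[i_f],
                stages = data.frame(stage = "I", strain_from = 0,
                                    strain_to = e[i_f])))
  }
  i <- below[1]
  # interpolate the crossing between i-1 and i
  if (i > 1) {
    g <- (line[i - 1] - s[i - 1]) / ((line[i - 1] - s[i - 1]) -
                                       (line[i] - s[i]))
    ey <- e[i - 1] + g * (e[i] - e[i - 1])
    sy <- s[i - 1] + g * (s[i] - s[i - 1])
  } else {
    ey <- e[i]; sy <- s[i]
  }
  stages <- data.frame(
    stage = c("I", "II", if (i_f < length(e)) "III"),
    strain_from = c(0, ey, if (i_f < length(e)) e[i_f]),
    strain_to = c(ey, e[i_f], if (i_f < length(e)) e[length(e)]))
  list(yield_strain = ey, yield_stress = sy,
       fracture_strain = e[i_f], fracture_stress = s[i_f],
       stages = stages)
}
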