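#' Parameters of the WAXD fibre-pattern model
#'
#' A set of Gaussian crystalline reflections plus one broad amorphous halo on
#' a 2\eqn{\theta} axis. The recorded ground-truth crystallinity equals, by
#' construction, the total crystalline Gaussian area over the total peak area
#' (background excluded).
#'
#' @param crystalline_peaks data.frame with columns `two_theta` (degrees),
#'   `sigma` (degrees), `area` (>= 0) and optionally `label`, `axis`
#'   (`"equator"`/`"meridian"`, used by the 2D generator).
#' @param amorphous_peak list/row with `two_theta`, `sigma`, `area`.
#' @param wavelength wavelength in nm.
#' @param orientation_fwhm azimuthal FWHM of the crystalline arcs in degrees
#'   (used only by [generate_fiber_diagram()]).
#' @param background_level flat background (arbitrary units).
#' @param noise,seed as in [lamellar_params()].
#' @return object of class `waxd_params`; `$crystallinity_true` is the
#'   area-ratio crystallinity in \[0, 1\].
#' @export
waxd_params <- function(crystalline_peaks, amorphous_peak,
                        wavelength = 0.15418,
                        orientation_fwhm = 18,
                        background_level = 0,
                        noise = NULL, seed = NULL) {
  cp <- as.data.frame(crystalline_peaks)
  stopifnot(all(c("two_theta", "sigma", "area") %in% names(cp)))
  if (any(cp$area < 0) || amorphous_peak$area < 0)
    stop("peak areas must be non-negative")
  if (any(cp$sigma <= 0) || amorphous_peak$sigma <= 0)
    stop("peak sigmas must be positive")
  if (any(cp$two_theta < 10 | cp$two_theta > 37))
    stop("crystalline peak centers must lie inside the 10-37 degree window")
  if (!"label" %in% names(cp)) cp$label <- sprintf("c%d", seq_len(nrow(cp)))
  if (!"axis" %in% names(cp)) cp$axis <- "equator"
  check_noise(noise)
  Ic <- sum(cp$area)
  Ia <- amorphous_peak$area
  structure(list(crystalline_peaks = cp,
                 amorphous_peak = amorphous_peak,
                 crystallinity_true = if (Ic + Ia > 0) Ic / (Ic + Ia) else 0,
                 wavelength = wavelength,
                 orientation_fwhm = orientation_fwhm,
                 background_level = background_level,
                 noise = noise, seed = seed),
            class = "waxd_params")
}

#' \eqn{\beta}-sheet WAXD model with a stated crystallinity
#'
#' Convenience constructor: places the six crystalline reflections at the
#' positions dictated by `cell` with a plausible fixed pattern of relative
#' areas, and scales the amorphous halo so that the exact area-ratio
#' crystallinity equals `crystallinity`.
#'
#' @param crystallinity target crystallinity in \[0, 1\] (default 0.44).
#' @param cell a [unit_cell] (default a = 9.39, b = 9.50, c = 6.98 Angstrom).
#' @param wavelength wavelength nm (default Cu-K\eqn{\alpha} so all peaks fall
#'   in the 10–37 degree window).
#' @param rel_areas relative areas of the six crystalline peaks.
#' @param sigma_cryst,sigma_amorph Gaussian sigmas in degrees.
#' @param amorphous_center amorphous halo centre in degrees (default 20.5 at
#'   Cu; rescaled via Bragg if another wavelength is given).
#' @param ... passed on to [waxd_params()].
#' @return a `waxd_params`.
#' @export
beta_sheet_waxd_params <- function(crystallinity = 0.44,
                                   cell = unit_cell(9.39, 9.50, 6.98),
                                   wavelength = 0.15418,
                                   rel_areas = c(1, 0.85, 0.25, 0.35,
                                                 0.2, 0.15),
                                   sigma_cryst = 0.45,
                                   sigma_amorph = 3.2,
                                   amorphous_center = NULL, ...) {
  if (crystallinity < 0 || crystallinity >= 1)
    stop("crystallinity must lie in [0, 1)")
  pos <- beta_sheet_positions(cell, wavelength)
  if (is.null(amorphous_center))
    amorphous_center <- d_to_two_theta(two_theta_to_d(20.5, 0.15418),
                                       wavelength)
  cp <- data.frame(two_theta = pos$two_theta,
                   sigma = sigma_cryst,
                   area = 100 * rel_areas / sum(rel_areas),
                   label = pos$label,
                   axis = ifelse(pos$label %in% c("002"),
                                 "meridian", "equator"),
                   stringsAsFactors = FALSE)
  Ic <- sum(cp$area)
  Ia <- if (crystallinity > 0) Ic * (1 - crystallinity) / crystallinity
        else 100
  if (crystallinity == 0) cp$area <- 0
  waxd_params(cp, list(two_theta = amorphous_center, sigma = sigma_amorph,
                       area = Ia),
              wavelength = wavelength, ...)
}

#' Simulate a 1D WAXD 2\eqn{\theta} profile
#'
#' Sum of the crystalline Gaussians, the amorphous halo and a flat background
#' on the 10–37 degree grid, with optional Poisson noise.
#'
#' @param params a [waxd_params].
#' @param two_theta optional 2\eqn{\theta} grid (default 10–37 deg, 1350 pts).
#' @return `synth_profile` list (`profile` of kind `"two_theta"`, `truth`
#'   carrying the exact crystallinity and component inventory).
#' @export
generate_waxd_profile <- function(params, two_theta = waxd_tt_grid()) {
  stopifnot(inherits(params, "waxd_params"))
  cp <- params$crystalline_peaks
  am <- params$amorphous_peak
  I <- params$background_level + rep(0, length(two_theta))
  for (i in seq_len(nrow(cp)))
    I <- I + cp$area[i] * stats::dnorm(two_theta, cp$two_theta[i], cp$sigma[i])
  I <- I + am$area * stats::dnorm(two_theta, am$two_theta, am$sigma)
  I <- apply_poisson_noise(I, params$noise, params$seed)
  structure(list(
    profile = profile1d(two_theta, I, kind = "two_theta",
                        wavelength = params$wavelength),
    truth = list(crystallinity = params$crystallinity_true,
                 crystalline_peaks = cp,
                 amorphous_peak = am,
                 background_level = params$background_level)),
    class = "synth_profile")
}

#' Detector geometry of a flat 2D detector
#'
#' @param beam_center pixel coordinates (x, y) of the direct beam, 1-based.
#' @param pixel_size pixel edge in mm.
#' @param camera_distance sample-to-detector distance in mm (> 0).
#' @param wavelength wavelength in nm.
#' @param fibre_axis `"vertical"` (meridian up) or `"horizontal"`.
#' @return object of class `detector_geometry`.
#' @export
detector_geometry <- function(beam_center = c(256.5, 256.5),
                              pixel_size = 0.15,
                              camera_distance = 40,
                              wavelength = 0.15418,
                              fibre_axis = c("vertical", "horizontal")) {
  fibre_axis <- match.arg(fibre_axis)
  if (camera_distance <= 0) stop("camera_distance must be positive")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  structure(list(beam_center = beam_center, pixel_size = pixel_size,
                 camera_distance = camera_distance, wavelength = wavelength,
                 fibre_axis = fibre_axis),
            class = "detector_geometry")
}

## per-pixel polar coordinates: 2theta (deg) and azimuth (deg, (-180, 180],
## measured from the +x axis, y up)
pixel_polar <- function(dim, geometry) {
  px <- matrix(seq_len(dim[2]), nrow = dim[1], ncol = dim[2], byrow = TRUE)
  py <- matrix(seq_len(dim[1]), nrow = dim[1], ncol = dim[2])
  dx <- (px - geometry$beam_center[1]) * geometry$pixel_size
  dy <- -(py - geometry$beam_center[2]) * geometry$pixel_size  # row 1 = top
  r <- sqrt(dx^2 + dy^2)
  list(two_theta = atan(r / geometry$camera_distance) * 180 / pi,
       azimuth = atan2(dy, dx) * 180 / pi)
}

## azimuthal Gaussian arc profile about `center_deg`, periodic, normalised to
## unit mean over the full circle so azimuthal-mean scans preserve the 1D
## radial profile
azimuthal_arc <- function(azimuth_deg, center_deg, fwhm_deg) {
  if (fwhm_deg <= 0) stop("orientation FWHM must be positive")
  s <- fwhm_deg / (2 * sqrt(2 * log(2)))
  d <- (azimuth_deg - center_deg + 180) %% 360 - 180
  # wrap a few periods so broad arcs stay periodic
  g <- exp(-d^2 / (2 * s^2)) + exp(-(d - 360)^2 / (2 * s^2)) +
    exp(-(d + 360)^2 / (2 * s^2))
  norm <- (stats::integrate(function(u)
    exp(-u^2 / (2 * s^2)) + exp(-(u - 360)^2 / (2 * s^2)) +
      exp(-(u + 360)^2 / (2 * s^2)), -180, 180)$value) / 360
  g / norm
}

#' Fibre diagram container
#'
#' @param image numeric intensity matrix (rows = detector rows, row 1 = top).
#' @param geometry a [detector_geometry]; the beam centre must fall inside
#'   the image.
#' @return object of class `fiber_diagram`.
#' @export
fiber_diagram <- function(image, geometry) {
  stopifnot(is.matrix(image), inherits(geometry, "detector_geometry"))
  bc <- geometry$beam_center
  if (bc[1] < 1 || bc[1] > ncol(image) || bc[2] < 1 || bc[2] > nrow(image))
    stop("beam center lies outside the image")
  structure(list(image = image, geometry = geometry), class = "fiber_diagram")
}

#' Simulate a 2D WAXD fibre diagram
#'
#' Renders each reflection of `params` on its 2\eqn{\theta} ring with a
#' Gaussian radial profile (sigma in degrees, evaluated in per-pixel
#' 2\eqn{\theta}) and a periodic Gaussian azimuthal arc of FWHM
#' `orientation_fwhm` centred on the equator or meridian according to the
#' peak's `axis`; arcs appear on both sides of the pattern. The amorphous
#' halo is isotropic. Azimuthal arcs are normalised to unit circular mean, so
#' an azimuthal-mean radial scan reproduces the generating 1D profile.
#'
#' @param params a [waxd_params].
#' @param image_shape `c(nrow, ncol)` in pixels.
#' @param geometry a [detector_geometry].
#' @return a [fiber_diagram] with the generating truth attached as
#'   `attr(, "truth")`.
#' @export
generate_fiber_diagram <- function(params,
                                   image_shape = c(512L, 512L),
                                   geometry = detector_geometry()) {
  stopifnot(inherits(params, "waxd_params"),
            inherits(geometry, "detector_geometry"))
  bc <- geometry$beam_center
  if (bc[1] < 1 || bc[1] > image_shape[2] ||
      bc[2] < 1 || bc[2] > image_shape[1])
    stop("beam center lies outside the image")
  pol <- pixel_polar(image_shape, geometry)
  equator_deg <- if (geometry$fibre_axis == "vertical") 0 else 90
  meridian_deg <- equator_deg + 90
  img <- matrix(params$background_level, image_shape[1], image_shape[2])
  cp <- params$crystalline_peaks
  for (i in seq_len(nrow(cp))) {
    center <- if (identical(cp$axis[i], "meridian")) meridian_deg
              else equator_deg
    arc <- azimuthal_arc(pol$azimuth, center, params$orientation_fwhm) / 2 +
      azimuthal_arc(pol$azimuth, center + 180, params$orientation_fwhm) / 2
    img <- img + cp$area[i] *
      stats::dnorm(pol$two_theta, cp$two_theta[i], cp$sigma[i]) * arc
  }
  am <- params$amorphous_peak
  img <- img + am$area * stats::dnorm(pol$two_theta, am$two_theta, am$sigma)
  img <- apply_poisson_noise(img, params$noise, params$seed)
  out <- fiber_diagram(img, geometry)
  attr(out, "truth") <- list(
    crystallinity = params$crystallinity_true,
    orientation_fwhm = params$orientation_fwhm,
    two_theta_200 = cp$two_theta[match("200", cp$label)])
  out
}

#' Read / write fibre diagrams as delimited text plus a JSON geometry sidecar
#'
#' The image is a whitespace-delimited numeric matrix at `path`; the geometry
#' is stored at `paste0(path, ".json")`.
#'
#' @param diagram a [fiber_diagram].
#' @param path image file path.
#' @return `read_fiber_diagram` returns a [fiber_diagram];
#'   `write_fiber_diagram` returns `path` invisibly.
#' @export
write_fiber_diagram <- function(diagram, path) {
  stopifnot(inherits(diagram, "fiber_diagram"))
  utils::write.table(diagram$image, path, row.names = FALSE,
                     col.names = FALSE)
  g <- diagram$geometry
  jsonlite::write_json(unclass(g), paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_fiber_diagram
#' @export
read_fiber_diagram <- function(path) {
  img <- as.matrix(utils::read.table(path))
  dimnames(img) <- NULL
  g <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  fiber_diagram(img, detector_geometry(
    beam_center = g$beam_center, pixel_size = g$pixel_size,
    camera_distance = g$camera_distance, wavelength = g$wavelength,
    fibre_axis = g$fibre_axis))
}
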