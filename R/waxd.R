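## bilinear image interpolation; x = column, y = row coordinates (1-based,
## row 1 at the top), points outside the frame return NA
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  ok <- x >= 1 & x <= nc & y >= 1 & y <= nr
  x0 <- pmin(pmax(floor(x), 1L), nc - 1L)
  y0 <- pmin(pmax(floor(y), 1L), nr - 1L)
  fx <- x - x0; fy <- y - y0
  v <- img[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    img[cbind(y0, x0 + 1L)] * fx * (1 - fy) +
    img[cbind(y0 + 1L, x0)] * (1 - fx) * fy +
    img[cbind(y0 + 1L, x0 + 1L)] * fx * fy
  v[!ok] <- NA_real_
  v
}

#' Azimuthally averaged radial 2\eqn{\theta} profile of a fibre diagram
#'
#' Bins every pixel whose azimuth falls inside `azimuth_range` by its
#' 2\eqn{\theta} (computed from the detector geometry) and takes the mean
#' intensity per bin; empty bins are flagged and filled by linear
#' interpolation.
#'
#' @param diagram a [fiber_diagram].
#' @param two_theta_range degrees, default the 10–37 scan window.
#' @param azimuth_range degrees, default `c(0, -180)` (one half of the
#'   pattern); order-insensitive.
#' @param n_bins number of 2\eqn{\theta} bins.
#' @return a [profile1d] of kind `"two_theta"`.
#' @export
scan_two_theta_profile <- function(diagram,
                                   two_theta_range = c(10, 37),
                                   azimuth_range = c(0, -180),
                                   n_bins = 270L) {
  stopifnot(inherits(diagram, "fiber_diagram"))
  pol <- pixel_polar(dim(diagram$image), diagram$geometry)
  if (max(pol$two_theta) < max(two_theta_range))
    stop("requested two_theta range exceeds detector coverage")
  az_lo <- min(azimuth_range); az_hi <- max(azimuth_range)
  # map azimuths so that -180 is representable on either convention
  az <- pol$azimuth
  in_az <- (az >= az_lo & az <= az_hi) |
    (az_lo <= -180 & az >= 180 + (az_lo + 180))  # degenerate guard
  sel <- in_az & pol$two_theta >= two_theta_range[1] &
    pol$two_theta <= two_theta_range[2]
  edges <- seq(two_theta_range[1], two_theta_range[2],
               length.out = n_bins + 1L)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  tt_sel <- pol$two_theta[sel]
  bin <- findInterval(tt_sel, edges, rightmost.closed = TRUE)
  means <- vapply(seq_len(n_bins), function(b) {
    v <- diagram$image[sel][bin == b]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  # report the mean pixel 2theta per bin, not the geometric bin centre:
  # pixel quantisation makes the within-bin 2theta distribution lopsided,
  # and on steep peak flanks the centre convention aliases badly
  tt_mean <- vapply(seq_len(n_bins), function(b) {
    v <- tt_sel[bin == b]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  tt_mean[is.na(tt_mean)] <- centers[is.na(tt_mean)]
  if (anyNA(means)) {
    warning(sum(is.na(means)), " empty 2theta bin(s) interpolated",
            call. = FALSE)
    means <- stats::approx(tt_mean[!is.na(means)], means[!is.na(means)],
                           tt_mean, rule = 2)$y
  }
  keep_inc <- c(TRUE, diff(tt_mean) > 0)
  profile1d(tt_mean[keep_inc], means[keep_inc], kind = "two_theta",
            wavelength = diagram$geometry$wavelength)
}

## ordinary least squares with non-negativity enforced on selected columns by
## active-set column dropping
nonneg_lm <- function(X, y, nonneg_cols) {
  active <- rep(TRUE, ncol(X))
  repeat {
    fit <- stats::lm.fit(X[, active, drop = FALSE], y)
    co <- rep(0, ncol(X))
    co[active] <- fit$coefficients
    co[is.na(co)] <- 0
    bad <- which(active & seq_len(ncol(X)) %in% nonneg_cols & co < 0)
    if (!length(bad)) {
      return(list(coef = co, rss = sum(fit$residuals^2)))
    }
    active[bad] <- FALSE
    if (!any(active)) return(list(coef = rep(0, ncol(X)), rss = sum(y^2)))
  }
}

## amorphous-halo centre window, stored as a d-spacing window (Angstrom) so
## it transfers across wavelengths; 5.91-3.56 A is 15-25 deg at Cu-K-alpha
AMORPHOUS_D_WINDOW <- c(5.91, 3.56)

#' Crystallinity by Gaussian peak deconvolution
#'
#' Fits the 1D WAXD profile with six crystalline Gaussians whose centres are
#' FIXED at the positions computed from the unit cell ((200), (210), (211),
#' (002), (102)+(300) composite, (202)), one amorphous Gaussian whose centre
#' floats inside a stated d-spacing window, and a background (linear by
#' default). Widths are optimised by bounded quasi-Newton iteration with the
#' areas solved linearly (non-negative) at every step. The crystallinity is
#' \eqn{X_c = 100\, I_c/(I_c + I_a)} with \eqn{I_c} the summed crystalline
#' areas and \eqn{I_a} the amorphous area.
#'
#' @param profile a [profile1d] of kind `"two_theta"` covering all six
#'   crystalline positions.
#' @param cell a [unit_cell].
#' @param wavelength wavelength nm; defaults to the profile's own.
#' @param background `"linear"`, `"constant"` or `"none"`.
#' @param amorphous_d_window centre window for the amorphous halo as
#'   d-spacings in Angstrom.
#' @return object of class `crystallinity_result`: fields `Xc` (percent),
#'   `Ic`, `Ia`, `fitted_peaks` (centre, sigma, area, label), `background`,
#'   `rss`, `convergence`.
#' @export
fit_crystallinity <- function(profile, cell,
                              wavelength = profile$wavelength,
                              background = c("linear", "constant", "none"),
                              amorphous_d_window = AMORPHOUS_D_WINDOW) {
  stopifnot(inherits(profile, "profile1d"), profile$kind == "two_theta",
            inherits(cell, "unit_cell"))
  background <- match.arg(background)
  tt <- profile$abscissa; y <- profile$intensity
  pos <- beta_sheet_positions(cell, wavelength)
  if (min(tt) > min(pos$two_theta) || max(tt) < max(pos$two_theta))
    stop("profile does not cover all six crystalline reflections")
  am_win <- sort(d_to_two_theta(sort(amorphous_d_window), wavelength))
  n_cryst <- nrow(pos)
  # widths scale roughly with the angular compression of the pattern
  wscale <- wavelength / 0.15418
  lower <- c(rep(0.05 * wscale, n_cryst), 1.0 * wscale, am_win[1])
  upper <- c(rep(1.5 * wscale, n_cryst), 8.0 * wscale, am_win[2])
  c_am0 <- tt[which.max(y)]
  c_am0 <- min(max(c_am0, am_win[1]), am_win[2])
  par0 <- c(rep(0.5 * wscale, n_cryst), 3.0 * wscale, c_am0)

  bg_cols <- switch(background,
                    none = NULL,
                    constant = cbind(rep(1, length(tt))),
                    linear = cbind(1, tt))
  design <- function(par) {
    X <- vapply(seq_len(n_cryst),
                function(j) stats::dnorm(tt, pos$two_theta[j], par[j]),
                numeric(length(tt)))
    X <- cbind(X, stats::dnorm(tt, par[n_cryst + 2], par[n_cryst + 1]))
    if (!is.null(bg_cols)) X <- cbind(X, bg_cols)
    X
  }
  obj <- function(par) nonneg_lm(design(par), y,
                                 seq_len(n_cryst + 1))$rss
  opt <- stats::optim(par0, obj, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 300, factr = 1e4))
  if (!opt$convergence %in% c(0, 1) && opt$value > stats::var(y))
    stop("crystallinity fit failed to converge: ", opt$message)
  sol <- nonneg_lm(design(opt$par), y, seq_len(n_cryst + 1))
  areas <- sol$coef[seq_len(n_cryst + 1)]
  Ic <- sum(areas[seq_len(n_cryst)])
  Ia <- areas[n_cryst + 1]
  fitted <- data.frame(
    center = c(pos$two_theta, opt$par[n_cryst + 2]),
    sigma = opt$par[seq_len(n_cryst + 1)],
    area = areas,
    label = c(pos$label, "amorphous"),
    stringsAsFactors = FALSE)
  structure(list(Xc = if (Ic + Ia > 0) 100 * Ic / (Ic + Ia) else 0,
                 Ic = Ic, Ia = Ia,
                 fitted_peaks = fitted,
                 background = if (is.null(bg_cols)) numeric(0)
                              else sol$coef[-seq_len(n_cryst + 1)],
                 rss = sol$rss,
                 convergence = opt$convergence),
            class = "crystallinity_result")
}

#' @export
print.crystallinity_result <- function(x, ...) {
  cat(sprintf("<crystallinity_result> Xc = %.1f%% (Ic = %.3g, Ia = %.3g)\n",
              x$Xc, x$Ic, x$Ia))
  invisible(x)
}

#' Crystal strain from a d002 series
#'
#' \eqn{\varepsilon_c(i) = (d_{002}(i) - d_{002}(0))/d_{002}(0) \times 100},
#' with the first element taken as the unloaded reference.
#'
#' @param d002_series numeric vector of 002 lattice spacings (Angstrom); the
#'   first element is the reference.
#' @return percent strain vector, same length (first element 0).
#' @export
crystal_strain <- function(d002_series) {
  d002_series <- as.numeric(d002_series)
  if (!length(d002_series)) stop("empty d002 series")
  if (d002_series[1] == 0) stop("zero reference d002")
  (d002_series - d002_series[1]) / d002_series[1] * 100
}

#' Azimuthal orientation of the equatorial 200 reflection
#'
#' Samples the diagram on the 200 ring radius over a fine azimuth grid
#' (bilinear interpolation, averaged over a small radial band), measures the
#' FWHM of the azimuthal distribution about the equator by linear
#' interpolation at half maximum, and reports the orientation index
#' \eqn{(180 - \mathrm{FWHM})/180}.
#'
#' @param diagram a [fiber_diagram].
#' @param two_theta_200 2\eqn{\theta} of the 200 ring in degrees; default
#'   computed from the standard silk \eqn{\beta}-sheet cell (a = 9.39
#'   Angstrom) at the diagram's wavelength.
#' @param ring_halfwidth half-width of the radial averaging band (degrees
#'   2\eqn{\theta}).
#' @return object of class `orientation_result` with `fwhm` (degrees) and
#'   `index`; a flat azimuthal profile yields index 0 with a warning.
#' @export
orientation_index <- function(diagram, two_theta_200 = NULL,
                              ring_halfwidth = 0.5) {
  stopifnot(inherits(diagram, "fiber_diagram"))
  g <- diagram$geometry
  if (is.null(two_theta_200))
    two_theta_200 <- d_to_two_theta(9.39 / 2, g$wavelength)
  az <- seq(-180, 180, by = 0.25)
  tt_band <- two_theta_200 + seq(-ring_halfwidth, ring_halfwidth,
                                 length.out = 5)
  prof <- rowMeans(vapply(tt_band, function(tt) {
    r_mm <- g$camera_distance * tan(tt * pi / 180)
    x <- g$beam_center[1] + r_mm * cos(az * pi / 180) / g$pixel_size
    y <- g$beam_center[2] - r_mm * sin(az * pi / 180) / g$pixel_size
    bilinear_sample(diagram$image, x, y)
  }, numeric(length(az))), na.rm = TRUE)
  if (anyNA(prof)) stop("200 ring not fully inside the detector")
  equator <- if (g$fibre_axis == "vertical") 0 else 90
  # window of +/-90 degrees about the equatorial arc
  keep <- abs((az - equator + 180) %% 360 - 180) <= 90
  azw <- az[keep]; pw <- prof[keep]
  rng <- max(pw) - min(pw)
  if (rng <= 1e-9 * max(abs(pw), 1e-12)) {
    warning("flat azimuthal profile: orientation index set to 0",
            call. = FALSE)
    return(structure(list(fwhm = 180, index = 0),
                     class = "orientation_result"))
  }
  fw <- fwhm_interp(azw, pw, baseline = min(pw))
  if (is.na(fw) || fw >= 180) {
    warning("no discernible azimuthal peak: orientation index set to 0",
            call. = FALSE)
    return(structure(list(fwhm = 180, index = 0),
                     class = "orientation_result"))
  }
  structure(list(fwhm = fw, index = (180 - fw) / 180),
            class = "orientation_result")
}

#' @export
print.orientation_result <- function(x, ...) {
  cat(sprintf("<orientation_result> FWHM = %.2f deg, index = %.3f\n",
              x$fwhm, x$index))
  invisible(x)
}

#' Fit the centre of the 002 reflection in a narrow window
#'
#' Gaussian fit (log-quadratic regression on the top of the peak) restricted
#' to a \eqn{\pm}`halfwidth` window about the expected position; used to
#' track d002 with sub-bin precision during deformation.
#'
#' @param profile a [profile1d] of kind `"two_theta"`.
#' @param expected_two_theta expected peak position in degrees.
#' @param halfwidth window half-width in degrees (default 1).
#' @return list with `two_theta` (fitted centre) and `d` (Angstrom).
#' @export
fit_002_center <- function(profile, expected_two_theta, halfwidth = 1) {
  stopifnot(inherits(profile, "profile1d"), profile$kind == "two_theta")
  keep <- abs(profile$abscissa - expected_two_theta) <= halfwidth
  if (sum(keep) < 5) stop("002 window contains too few samples")
  x <- profile$abscissa[keep]; y <- profile$intensity[keep]
  fit <- gaussian_log_fit(x, y, baseline = min(y) * 0.999)
  list(two_theta = fit$center,
       d = two_theta_to_d(fit$center, profile$wavelength))
}
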