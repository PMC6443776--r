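#' Kratky transform
#'
#' Replaces the intensity by \eqn{q^2 I(q)}, enhancing periodic peaks over
#' the power-law decay; the abscissa is unchanged.
#'
#' @param profile a [profile1d] of kind `"q"`.
#' @return a [profile1d] of kind `"q"`.
#' @export
kratky_transform <- function(profile) {
  stopifnot(inherits(profile, "profile1d"))
  if (profile$kind != "q") stop("Kratky transform requires a q profile")
  profile1d(profile$abscissa, profile$abscissa^2 * profile$intensity,
            kind = "q", wavelength = profile$wavelength)
}

## local maxima above a prominence threshold of k x MAD over the running
## background (here: the median of the trace), refined parabolically
find_peaks_1d <- function(x, y, prominence_mad = 3) {
  idx <- local_maxima_idx(y)
  thr <- stats::median(y) + prominence_mad * stats::mad(y)
  idx <- idx[y[idx] > thr]
  if (!length(idx)) return(data.frame(x = numeric(0), y = numeric(0)))
  data.frame(x = vapply(idx, function(i) parabolic_refine(x, y, i),
                        numeric(1)),
             y = y[idx])
}

#' Harmonic long-period analysis of a meridional Kratky profile
#'
#' Detects local maxima above a prominence threshold, assigns harmonic
#' orders by the nearest-integer ratio of each peak position to the first
#' peak, and reports the true (first-order) long period
#' \eqn{L_p = 2\pi n/q_n} averaged over the assigned orders \eqn{n \ge 2}
#' when present (falling back to order 1), together with the apparent
#' second- and third-order spacings \eqn{2\pi/q_2}, \eqn{2\pi/q_3} and their
#' ratio (1.5 for ideal harmonics).
#'
#' @param kratky a Kratky-transformed [profile1d] (see
#'   [kratky_transform()]).
#' @param max_order largest order considered.
#' @param prominence_mad peak threshold in MADs above the median.
#' @param ratio_tol relative deviation from integer ratio above which a peak
#'   is left unassigned (with a warning).
#' @return object of class `long_period_result`: `peaks` (data.frame q,
#'   order), `lp_1st`, `lp_2nd`, `lp_3rd`, `ratio_2nd_3rd`.
#' @export
find_harmonic_peaks <- function(kratky, max_order = 5L,
                                prominence_mad = 3, ratio_tol = 0.1) {
  stopifnot(inherits(kratky, "profile1d"), kratky$kind == "q")
  pk <- find_peaks_1d(kratky$abscissa, kratky$intensity, prominence_mad)
  if (!nrow(pk)) stop("no resolvable peak in the Kratky profile")
  q1 <- pk$x[1]
  ratio <- pk$x / q1
  order <- as.integer(round(ratio))
  dev <- abs(ratio / order - 1)
  bad <- dev > ratio_tol | order > max_order | order < 1L
  if (any(bad)) {
    warning(sum(bad), " peak(s) inconsistent with integer order assignment",
            call. = FALSE)
    order[bad] <- NA_integer_
  }
  peaks <- data.frame(q = pk$x, intensity = pk$y, order = order)
  ok <- peaks[!is.na(peaks$order), , drop = FALSE]
  ok <- ok[!duplicated(ok$order), , drop = FALSE]
  use <- if (any(ok$order >= 2)) ok[ok$order >= 2, ] else ok
  lp_1st <- mean(2 * pi * use$order / use$q)
  q_of <- function(n) if (n %in% ok$order) ok$q[match(n, ok$order)]
                      else NA_real_
  lp_2nd <- 2 * pi / q_of(2L)
  lp_3rd <- 2 * pi / q_of(3L)
  structure(list(peaks = peaks, lp_1st = lp_1st,
                 lp_2nd = lp_2nd, lp_3rd = lp_3rd,
                 ratio_2nd_3rd = lp_2nd / lp_3rd),
            class = "long_period_result")
}

#' @export
print.long_period_result <- function(x, ...) {
  cat(sprintf(
    "<long_period_result> Lp(1st) = %.2f nm; 2nd/3rd apparent = %.2f/%.2f nm (ratio %.3f); %d peak(s)\n",
    x$lp_1st, x$lp_2nd, x$lp_3rd, x$ratio_2nd_3rd, nrow(x$peaks)))
  invisible(x)
}

#' One-dimensional electron-density correlation function
#'
#' Computes \eqn{K(z) \propto \int_0^\infty q^2 I(q) \cos(zq)\,dq} by
#' trapezoidal quadrature after (i) subtracting a flat background (the
#' profile minimum, switchable), (ii) extrapolating the intensity to q = 0
#' with a quadratic through the first points, and (iii) damping the high-q
#' tail with a cosine taper to suppress truncation ripple. From K(z) it
#' extracts the invariant \eqn{Q = K(0)}, the long period \eqn{L_p} (first
#' local maximum at z > 0), and the phase-I thicknesses via the standard
#' self-correlation-triangle construction: a line is fitted over the 20–80%
#' portion of the drop from Q to the first minimum; its intersection with
#' the first-minimum baseline gives the core thickness \eqn{d_{pI}}, and its
#' zero crossing, divided by the majority-phase fraction obtained from the
#' two-phase baseline relation \eqn{K_{min}/Q = -\phi_1/\phi_2}, gives the
#' mean thickness \eqn{\langle d_{pI}\rangle}.
#'
#' @param profile a background-subtracted (or subtractable) [profile1d] of
#'   kind `"q"`.
#' @param z_max largest z evaluated, nm.
#' @param dz z step, nm.
#' @param background `"min"` subtracts the profile minimum; `"none"` uses
#'   the intensities as given.
#' @param n_extrap number of low-q points used for the q\eqn{\to}0
#'   quadratic.
#' @param damp_frac fraction of the high-q end tapered.
#' @return object of class `correlation_result`: `z`, `K`, `Q`, `Lp`,
#'   `d_pI`, `d_pI_mean`, `phase1_fraction`, `phase2_thickness`,
#'   `first_zero`.
#' @export
correlation_function <- function(profile, z_max = 100, dz = 0.05,
                                 background = c("min", "none"),
                                 n_extrap = 10L, damp_frac = 0.15) {
  stopifnot(inherits(profile, "profile1d"))
  if (profile$kind != "q") stop("correlation function requires a q profile")
  background <- match.arg(background)
  q <- profile$abscissa
  I <- profile$intensity
  if (background == "min") I <- I - min(I)
  # low-q extrapolation: quadratic through the first points, clamped >= 0
  if (q[1] > 0) {
    nfit <- min(n_extrap, length(q))
    co <- stats::coef(stats::lm(I[seq_len(nfit)] ~
                                  poly(q[seq_len(nfit)], 2, raw = TRUE)))
    q_lo <- seq(0, q[1], by = q[2] - q[1])
    q_lo <- q_lo[q_lo < q[1]]
    I_lo <- pmax(co[1] + co[2] * q_lo + co[3] * q_lo^2, 0)
    q <- c(q_lo, q); I <- c(I_lo, I)
  }
  # high-q taper (Hann half-window over the last damp_frac of the range)
  w <- rep(1, length(q))
  qd <- max(q) - damp_frac * (max(q) - min(q))
  tail_idx <- q > qd
  w[tail_idx] <- 0.5 * (1 + cos(pi * (q[tail_idx] - qd) / (max(q) - qd)))
  integrand <- q^2 * I * w
  if (integrand[length(integrand)] > 0.05 * max(integrand))
    stop("non-decaying high-q tail: background/Porod treatment failed")
  z <- seq(0, z_max, by = dz)
  dq <- diff(q)
  wts <- c(dq / 2, 0) + c(0, dq / 2)   # trapezoid weights
  K <- as.numeric(cos(outer(z, q)) %*% (integrand * wts))
  Q <- K[1]
  if (Q <= 0) stop("non-positive invariant: empty profile?")

  # first substantive local minimum: truncated-harmonic K(z) carries small
  # ripples, so require the minimum to reach the negative self-correlation
  # baseline (fall back to the deepest early minimum if K never goes
  # negative)
  mins <- local_minima_idx(K)
  if (!length(mins)) stop("no correlation minimum found within z_max")
  neg <- mins[K[mins] < 0]
  imin <- if (length(neg)) neg[1] else mins[which.min(K[mins])]
  # flat baseline: average K over a small neighbourhood of the minimum
  nb <- max(2L, round(0.05 * z[imin] / dz))
  baseline <- mean(K[max(1, imin - nb):min(length(K), imin + nb)])

  # linear fit over the 20-80% portion of the drop from Q to the baseline
  drop <- Q - baseline
  lin <- which(z < z[imin] & K < Q - 0.2 * drop & K > Q - 0.8 * drop)
  if (length(lin) < 3) stop("too few points in the linear region of K(z)")
  lf <- stats::lm(K[lin] ~ z[lin])
  c0 <- stats::coef(lf)[1]; m <- stats::coef(lf)[2]
  if (m >= 0) stop("non-decreasing linear region in K(z)")
  d_pI <- as.numeric((baseline - c0) / m)
  z0 <- as.numeric(-c0 / m)
  r <- -baseline / Q
  if (r <= 0) stop("non-negative correlation baseline: not two-phase-like")
  phi1 <- r / (1 + r)
  d_pI_mean <- z0 / (1 - phi1)

  # long period: dominant (highest) local maximum after the first minimum,
  # again guarding against truncation ripple
  maxs <- local_maxima_idx(K)
  maxs <- maxs[maxs > imin]
  if (!length(maxs)) stop("first correlation maximum not found within z_max")
  Lp <- parabolic_refine(z, K, maxs[which.max(K[maxs])])

  # first zero crossing of K
  sgn <- which(K[-1] < 0 & K[-length(K)] >= 0)
  first_zero <- if (length(sgn)) {
    i <- sgn[1]
    z[i] + K[i] / (K[i] - K[i + 1]) * dz
  } else NA_real_

  structure(list(z = z, K = K, Q = Q, Lp = Lp,
                 d_pI = d_pI, d_pI_mean = d_pI_mean,
                 phase1_fraction = phi1,
                 phase2_thickness = Lp - d_pI_mean,
                 first_zero = first_zero,
                 baseline = baseline),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "<correlation_result> Q = %.4g, Lp = %.2f nm, d_pI = %.2f nm, <d_pI> = %.2f nm, phase II = %.2f nm\n",
    x$Q, x$Lp, x$d_pI, x$d_pI_mean, x$phase2_thickness))
  invisible(x)
}

#' Two-phase decomposition closure
#'
#' Thickness of the complementary phase of a two-phase stack:
#' `long_period - phase1_thickness`.
#'
#' @param long_period lamellar long period, nm.
#' @param phase1_thickness (mean) thickness of phase I, nm; must be smaller
#'   than the long period.
#' @return phase-II thickness in nm.
#' @export
phase2_thickness <- function(long_period, phase1_thickness) {
  if (any(phase1_thickness >= long_period) || any(phase1_thickness <= 0))
    stop("need 0 < phase1_thickness < long_period")
  long_period - phase1_thickness
}

#' Long-period strain series
#'
#' \eqn{\varepsilon_L(i) = (L_p(i) - L_p(0))/L_p(0) \times 100} against the
#' first (unloaded) element.
#'
#' @param lp_series numeric vector of first-order long periods (nm).
#' @return percent strain vector.
#' @export
long_period_strain <- function(lp_series) {
  lp_series <- as.numeric(lp_series)
  if (!length(lp_series)) stop("empty long-period series")
  if (lp_series[1] == 0) stop("zero reference long period")
  (lp_series - lp_series[1]) / lp_series[1] * 100
}

#' Gaussian fit of an equatorial SAXS peak
#'
#' @param profile a [profile1d] of kind `"q"`.
#' @return list with `center_q`, `fwhm_q` (both nm\eqn{^{-1}}).
#' @export
fit_equatorial_peak <- function(profile) {
  stopifnot(inherits(profile, "profile1d"), profile$kind == "q")
  fit <- gaussian_log_fit(profile$abscissa, profile$intensity,
                          baseline = min(profile$intensity))
  if (is.na(fit$sigma)) stop("equatorial peak fit failed")
  list(center_q = fit$center, fwhm_q = fit$sigma * 2 * sqrt(2 * log(2)))
}

#' Scherrer size from an equatorial peak width
#'
#' Converts the observed and instrumental FWHMs from q units to radians of
#' scattering angle at the peak position, corrects the observed broadening
#' in quadrature (\eqn{\beta = \sqrt{\beta_{obs}^2 - \beta_{instr}^2}}), and
#' applies \eqn{d = K\lambda/(\beta\cos\theta)} with \eqn{\theta} half the
#' scattering angle.
#'
#' @param center_q peak centre in nm\eqn{^{-1}}.
#' @param fwhm_obs_q observed FWHM in nm\eqn{^{-1}}.
#' @param instrumental_fwhm_q instrumental FWHM in nm\eqn{^{-1}}; must be
#'   smaller than `fwhm_obs_q`.
#' @param wavelength wavelength nm.
#' @param K_factor Scherrer shape factor (default 0.9).
#' @return object of class `scherrer_result`: `beta_obs`, `beta_instr`,
#'   `beta` (radians), `theta` (radians), `wavelength`, `K_factor`, `d`
#'   (nm).
#' @export
scherrer_thickness <- function(center_q, fwhm_obs_q, instrumental_fwhm_q,
                               wavelength, K_factor = 0.9) {
  if (wavelength <= 0) stop("wavelength must be positive")
  if (fwhm_obs_q <= instrumental_fwhm_q)
    stop("observed width <= instrumental width: size not resolvable")
  theta <- asin(center_q * wavelength / (4 * pi))
  q_to_rad <- wavelength / (2 * pi * cos(theta))   # d(2theta)/dq
  beta_obs <- fwhm_obs_q * q_to_rad
  beta_instr <- instrumental_fwhm_q * q_to_rad
  beta <- sqrt(beta_obs^2 - beta_instr^2)
  structure(list(beta_obs = beta_obs, beta_instr = beta_instr, beta = beta,
                 theta = theta, wavelength = wavelength,
                 K_factor = K_factor,
                 d = K_factor * wavelength / (beta * cos(theta))),
            class = "scherrer_result")
}

#' @export
print.scherrer_result <- function(x, ...) {
  cat(sprintf("<scherrer_result> d = %.1f nm (beta = %.4g rad)\n",
              x$d, x$beta))
  invisible(x)
}

#' Join per-frame structure metrics with the tensile log
#'
#' Aligns each scattering frame with the tensile log by time stamp (error if
#' any frame is further than half a frame interval from the log), computes
#' bulk strain \eqn{\Delta l/l_0 \times 100}, crystal strain and long-period
#' strain against frame 1, derives the true long period from the third-order
#' apparent spacing (\eqn{L_p^{1st} = 3 L_p^{3rd}}) when not supplied, and
#' annotates deformation stages from the stress trace (stage I up to the
#' 0.2%-offset yield, stage II to fracture, stage III beyond).
#'
#' @param frames data.frame with columns `time` (s), `d002` (Angstrom), and
#'   `lp_2nd`, `lp_3rd` (apparent spacings, nm) and/or `lp_1st`; optionally
#'   `orientation_index`.
#' @param tensile_log data.frame with columns `time` (s), `displacement`
#'   (mm) and either `stress` (GPa) or `force` (N, converted via
#'   `cross_section`).
#' @param gauge_length_mm initial sample length \eqn{l_0} (default 15 mm).
#' @param cross_section optional [cross_section_area()] result for
#'   force-to-stress conversion.
#' @param frame_interval nominal frame spacing in s (default 9).
#' @return a data.frame of class `deformation_series` with one row per
#'   frame and the stage boundaries in `attr(, "stages")`.
#' @export
assemble_deformation_series <- function(frames, tensile_log,
                                        gauge_length_mm = 15,
                                        cross_section = NULL,
                                        frame_interval = 9) {
  frames <- as.data.frame(frames)
  tensile_log <- as.data.frame(tensile_log)
  stopifnot("time" %in% names(frames), "time" %in% names(tensile_log))
  if (!"stress" %in% names(tensile_log)) {
    if (is.null(cross_section) || !"force" %in% names(tensile_log))
      stop("tensile log needs a stress column, or force + cross_section")
    tensile_log$stress <- force_to_stress(tensile_log$force, cross_section)
  }
  dt <- vapply(frames$time,
               function(t) min(abs(t - tensile_log$time)), numeric(1))
  bad <- which(dt > frame_interval / 2)
  if (length(bad))
    stop("frame(s) misaligned with the tensile log beyond half a frame ",
         "interval: ", paste(bad, collapse = ", "))
  interp <- function(v) stats::approx(tensile_log$time, v, frames$time,
                                      rule = 2)$y
  out <- data.frame(time = frames$time)
  out$bulk_strain <- interp(tensile_log$displacement) / gauge_length_mm * 100
  out$stress <- interp(tensile_log$stress)
  out$d002 <- frames$d002
  out$crystal_strain <- crystal_strain(frames$d002)
  if ("orientation_index" %in% names(frames))
    out$orientation_index <- frames$orientation_index
  out$lp_2nd <- frames$lp_2nd %||% rep(NA_real_, nrow(frames))
  out$lp_3rd <- frames$lp_3rd %||% rep(NA_real_, nrow(frames))
  out$lp_1st <- if ("lp_1st" %in% names(frames)) frames$lp_1st
                else 3 * out$lp_3rd
  out$lp_strain <- long_period_strain(out$lp_1st)
  if (nrow(out) > 1) {
    curve <- stress_strain_curve(out$bulk_strain / 100 -
                                   out$bulk_strain[1] / 100,
                                 out$stress)
    stages <- tryCatch(stage_segmentation(curve),
                       error = function(e) NULL, warning = function(w) NULL)
  } else stages <- NULL
  structure(out, stages = stages, class = c("deformation_series",
                                            "data.frame"))
}
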