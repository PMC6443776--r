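#' Parameters of the two-phase lamellar stack model
#'
#' Describes an ideal one-dimensional alternating stack of two phases along
#' the fibre axis: phase I of thickness `phase1_fraction * long_period` and
#' phase II making up the rest of each period. The meridional SAXS of this
#' stack has harmonic peaks at \eqn{q_n = 2\pi n / L_p} whose integrated
#' intensities follow the square-wave Fourier envelope
#' \eqn{[\sin(n\pi\phi_1)/(n\pi)]^2}.
#'
#' @param long_period lamellar long period \eqn{L_p} in nm (> 0). Default
#'   38.5 nm, the stated period of the modelled silk.
#' @param phase1_fraction volume fraction of phase I in (0,1). Default
#'   15.7/38.5.
#' @param n_orders number of harmonic orders generated (1..8). Default 5.
#' @param peak_width_sigma Gaussian sigma of each peak in nm\eqn{^{-1}}.
#'   Default 0.008 (resolves five orders cleanly).
#' @param background_level flat background intensity (arbitrary units).
#' @param noise `NULL` for noiseless data, or `list(type = "poisson",
#'   mean_counts = <positive>)` to scale the trace to the stated mean count
#'   and draw Poisson counts.
#' @param seed integer RNG seed used only when noise is requested.
#' @return object of class `lamellar_params`.
#' @export
lamellar_params <- function(long_period = 38.5,
                            phase1_fraction = 15.7 / 38.5,
                            n_orders = 5L,
                            peak_width_sigma = 0.008,
                            background_level = 5,
                            noise = NULL,
                            seed = NULL) {
  if (long_period <= 0) stop("long_period must be positive")
  if (phase1_fraction <= 0 || phase1_fraction >= 1)
    stop("phase1_fraction must lie in (0, 1)")
  n_orders <- as.integer(n_orders)
  if (n_orders < 1L || n_orders > 8L) stop("n_orders must be in 1..8")
  if (peak_width_sigma <= 0) stop("peak_width_sigma must be positive")
  if (background_level < 0) stop("background_level must be >= 0")
  check_noise(noise)
  structure(list(long_period = long_period,
                 phase1_fraction = phase1_fraction,
                 n_orders = n_orders,
                 peak_width_sigma = peak_width_sigma,
                 background_level = background_level,
                 noise = noise, seed = seed),
            class = "lamellar_params")
}

check_noise <- function(noise) {
  if (is.null(noise)) return(invisible(NULL))
  if (!is.list(noise) || !identical(noise$type, "poisson") ||
      !is.numeric(noise$mean_counts) || noise$mean_counts <= 0)
    stop("noise must be NULL or list(type = 'poisson', mean_counts = <pos>)")
  invisible(NULL)
}

## default instrument grids (cover the stated scan windows)
saxs_q_grid <- function() seq(0.02, 2.0, length.out = 2000L)
waxd_tt_grid <- function() seq(10, 37, length.out = 1350L)

apply_poisson_noise <- function(intensity, noise, seed) {
  if (is.null(noise)) return(intensity)
  scale <- noise$mean_counts / mean(intensity)
  with_seed(seed, stats::rpois(length(intensity), intensity * scale) / scale)
}

#' Simulate the meridional SAXS profile of a lamellar stack
#'
#' Places `n_orders` Gaussian peaks at \eqn{q_n = 2\pi n/L_p} whose
#' Lorentz-corrected (Kratky, \eqn{q^2 I}) integrated intensities are
#' proportional to the ideal two-phase square-wave Fourier envelope
#' \eqn{[\sin(n\pi\phi_1)/(n\pi)]^2} — i.e. \eqn{I(q)} carries a \eqn{1/q^2}
#' factor, so that the correlation function
#' \eqn{K(z) \propto \int q^2 I \cos(zq) dq} of the noiseless profile is the
#' self-correlation triangle of the generating square-wave density. A flat
#' background and optional Poisson noise are added. Orders whose envelope
#' vanishes (e.g. even orders of a symmetric stack) are flagged in the
#' ground truth, not treated as an error.
#'
#' @param params a [lamellar_params].
#' @param q optional q grid in nm\eqn{^{-1}} (default 0.02–2.0, 2000 points).
#' @return a list of class `synth_profile` with elements `profile` (a
#'   [profile1d] of kind `"q"`) and `truth` (peak positions, envelope areas,
#'   the generating parameters, and `suppressed_orders`).
#' @export
generate_saxs_meridional <- function(params, q = saxs_q_grid()) {
  stopifnot(inherits(params, "lamellar_params"))
  n <- seq_len(params$n_orders)
  qn <- 2 * pi * n / params$long_period
  env <- (sin(n * pi * params$phase1_fraction) / (n * pi))^2
  suppressed <- n[env < 1e-12 * max(env)]
  if (length(suppressed))
    warning("envelope vanishes for order(s) ",
            paste(suppressed, collapse = ", "),
            " at this phase1_fraction", call. = FALSE)
  area <- 1000 * env
  s <- params$peak_width_sigma
  # Gaussian peaks in the Kratky representation, mapped back through 1/q^2
  I <- params$background_level +
    rowSums(vapply(seq_along(n),
                   function(i) area[i] * stats::dnorm(q, qn[i], s),
                   numeric(length(q)))) / q^2
  I <- apply_poisson_noise(I, params$noise, params$seed)
  structure(list(
    profile = profile1d(q, I, kind = "q", wavelength = 0.0709),
    truth = list(long_period = params$long_period,
                 phase1_fraction = params$phase1_fraction,
                 phase1_thickness = params$phase1_fraction * params$long_period,
                 phase2_thickness = (1 - params$phase1_fraction) *
                   params$long_period,
                 peak_positions_q = qn,
                 peak_areas = area,
                 peak_sigma = s,
                 suppressed_orders = suppressed,
                 background_level = params$background_level)),
    class = "synth_profile")
}

#' Simulate the equatorial SAXS peak of a finite nanofibril bundle
#'
#' A single Gaussian peak at \eqn{q = 2\pi/\mathrm{fibril\_spacing}} whose
#' FWHM is the quadrature sum of the Scherrer size broadening of a bundle of
#' the stated thickness (expressed in q: \eqn{\Delta q = 2\pi K/d}) and the
#' instrumental FWHM.
#'
#' @param bundle_thickness true bundle size d in nm; must be >=
#'   `fibril_spacing`.
#' @param fibril_spacing centre-to-centre fibril distance in nm (default 4.7).
#' @param wavelength wavelength in nm (default Cu-K\eqn{\alpha} 0.15418);
#'   must be positive.
#' @param instrumental_fwhm instrumental broadening FWHM in nm\eqn{^{-1}}.
#' @param K_factor Scherrer shape factor (default 0.9).
#' @param background_level,noise,seed as in [lamellar_params()].
#' @param q optional q grid.
#' @return `synth_profile` list; truth records the bundle size, peak centre
#'   and the size/instrumental/observed FWHMs in q units.
#' @export
generate_saxs_equatorial <- function(bundle_thickness = 150,
                                     fibril_spacing = 4.7,
                                     wavelength = 0.15418,
                                     instrumental_fwhm = 0.005,
                                     K_factor = 0.9,
                                     background_level = 5,
                                     noise = NULL, seed = NULL,
                                     q = saxs_q_grid()) {
  if (wavelength <= 0) stop("wavelength must be positive")
  if (bundle_thickness < fibril_spacing)
    stop("bundle_thickness must be >= fibril_spacing")
  if (instrumental_fwhm < 0) stop("instrumental_fwhm must be >= 0")
  check_noise(noise)
  q0 <- 2 * pi / fibril_spacing
  fwhm_size <- 2 * pi * K_factor / bundle_thickness
  fwhm_obs <- sqrt(fwhm_size^2 + instrumental_fwhm^2)
  sigma <- fwhm_obs / (2 * sqrt(2 * log(2)))
  I <- background_level + 1000 * stats::dnorm(q, q0, sigma)
  I <- apply_poisson_noise(I, noise, seed)
  structure(list(
    profile = profile1d(q, I, kind = "q", wavelength = wavelength),
    truth = list(bundle_thickness = bundle_thickness,
                 fibril_spacing = fibril_spacing,
                 peak_q = q0,
                 fwhm_size_q = fwhm_size,
                 fwhm_instr_q = instrumental_fwhm,
                 fwhm_obs_q = fwhm_obs,
                 K_factor = K_factor)),
    class = "synth_profile")
}
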