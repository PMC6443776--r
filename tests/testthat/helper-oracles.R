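# Independent oracles used across tests. These deliberately avoid the
# package's own analysis code paths.

# direct real-space autocorrelation of the ideal two-phase square-wave
# density: eta = 1 on [0, phi*L), 0 on [phi*L, L), mean-centred, periodic
oracle_square_wave_K <- function(long_period, phi, z, n_grid = 20000L) {
  u <- seq(0, long_period, length.out = n_grid + 1L)[-(n_grid + 1L)]
  eta <- as.numeric(u < phi * long_period) - phi
  vapply(z, function(zz) {
    shifted <- (u + zz) %% long_period
    mean(eta * (as.numeric(shifted < phi * long_period) - phi))
  }, numeric(1))
}

# oracle long period: position of the dominant maximum of K beyond the first
# negative minimum, by plain grid scan
oracle_K_long_period <- function(long_period, phi,
                                 z = seq(0.5, 1.5 * long_period,
                                         by = 0.02)) {
  K <- oracle_square_wave_K(long_period, phi, z)
  imin <- which(K < 0)[1]
  z[imin - 1 + which.max(K[imin:length(z)])]
}

# numeric-integration oracle for the crystallinity of a synthetic WAXD
# truth: integrates each Gaussian component on a fine grid
oracle_crystallinity <- function(truth, lo = -50, hi = 100) {
  x <- seq(lo, hi, length.out = 40000L)
  area_num <- function(center, sigma, area)
    sum(area * dnorm(x, center, sigma)) * (x[2] - x[1])
  cp <- truth$crystalline_peaks
  Ic <- sum(mapply(area_num, cp$two_theta, cp$sigma, cp$area))
  Ia <- area_num(truth$amorphous_peak$two_theta,
                 truth$amorphous_peak$sigma, truth$amorphous_peak$area)
  Ic / (Ic + Ia)
}

# trapezoid oracle for toughness (MJ m^-3) of a noiseless curve
oracle_toughness <- function(curve) {
  e <- curve$strain; s <- curve$stress
  1000 * sum(diff(e) * (s[-length(s)] + s[-1]) / 2)
}

# forward Bragg oracle: d-spacings of an orthorhombic cell
oracle_d <- function(a, b, cc, h, k, l) 1 / sqrt(h^2 / a^2 + k^2 / b^2 +
                                                   l^2 / cc^2)

# argmax-scan oracle for peak positions of a noiseless profile
oracle_peak_positions <- function(profile, n_peaks) {
  x <- profile$abscissa; y <- profile$intensity
  found <- numeric(0)
  yy <- y
  for (i in seq_len(n_peaks)) {
    j <- which.max(yy)
    found <- c(found, x[j])
    yy[abs(x - x[j]) < 0.05] <- -Inf
  }
  sort(found)
}

# fine-geometry instrument used where the round-trip fidelity of the 2D
# render matters (pixel pitch below the radial bin width)
fine_geometry <- function() {
  detector_geometry(beam_center = c(512.5, 512.5), pixel_size = 0.075,
                    camera_distance = 40)
}
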