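#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trapezoidal integration
#'
#' @param x,y numeric vectors of equal length, `x` strictly increasing.
#' @return the trapezoid-rule integral of `y` over `x`.
#' @export
trapz <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

## parabolic (3-point) refinement of a local extremum at index i
parabolic_refine <- function(x, y, i) {
  if (i <= 1L || i >= length(x)) return(x[i])
  y1 <- y[i - 1L]; y2 <- y[i]; y3 <- y[i + 1L]
  denom <- y1 - 2 * y2 + y3
  if (denom == 0) return(x[i])
  # uniform-grid vertex offset in units of the local spacing
  delta <- 0.5 * (y1 - y3) / denom
  h <- (x[i + 1L] - x[i - 1L]) / 2
  x[i] + delta * h
}

## indices of strict local maxima (plateaus resolved to their first sample)
local_maxima_idx <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  which(diff(sign(diff(y))) < 0) + 1L
}

local_minima_idx <- function(y) local_maxima_idx(-y)

#' Full width at half maximum by linear interpolation
#'
#' Width of the main peak of `y` at half of its maximum above `baseline`.
#' Crossings are located by linear interpolation between bracketing samples;
#' when several candidate crossings tie, the outermost (wider) pair is used.
#'
#' @param x abscissa, strictly increasing.
#' @param y ordinate.
#' @param baseline value subtracted before halving (default `min(y)`).
#' @return FWHM in units of `x`, or `NA` if no crossing brackets the peak.
#' @export
fwhm_interp <- function(x, y, baseline = min(y)) {
  yy <- y - baseline
  ipk <- which.max(yy)
  half <- yy[ipk] / 2
  if (half <= 0) return(NA_real_)
  # left crossing: outermost sample left of the peak below half
  left <- NA_real_
  for (i in seq(ipk, 2L)) {
    if (yy[i - 1L] < half && yy[i] >= half) {
      left <- x[i - 1L] + (half - yy[i - 1L]) / (yy[i] - yy[i - 1L]) *
        (x[i] - x[i - 1L])
      break
    }
  }
  right <- NA_real_
  if (ipk < length(x)) {
    for (i in seq(ipk, length(x) - 1L)) {
      if (yy[i] >= half && yy[i + 1L] < half) {
        right <- x[i] + (yy[i] - half) / (yy[i] - yy[i + 1L]) *
          (x[i + 1L] - x[i])
        break
      }
    }
  }
  if (is.na(left) || is.na(right)) return(NA_real_)
  right - left
}

#' Half-up display rounding
#'
#' Rounds half away from zero at the stated number of decimals (so 23.45 nm
#' displays as 23.5, not banker's 23.4), guarding against binary
#' representation of values like 67 * 0.35.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

## deterministic seeded evaluation that does not disturb the caller's RNG
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

## moment-free Gaussian peak fit: quadratic regression on log-intensity of the
## samples above `frac` of the peak (exact for a noiseless Gaussian).
## Returns center, sigma, height, area.
gaussian_log_fit <- function(x, y, frac = 0.2, baseline = 0) {
  yy <- y - baseline
  ipk <- which.max(yy)
  keep <- which(yy > frac * yy[ipk])
  # restrict to the contiguous block around the main peak
  block <- split(keep, cumsum(c(1L, diff(keep) != 1L)))
  keep <- block[[which(vapply(block, function(b) ipk %in% b, logical(1)))]]
  if (length(keep) < 3L) {
    return(list(center = x[ipk], sigma = NA_real_, height = yy[ipk],
                area = NA_real_))
  }
  fit <- stats::lm(log(yy[keep]) ~ poly(x[keep], 2, raw = TRUE))
  co <- stats::coef(fit)
  if (!is.finite(co[3]) || co[3] >= 0) {
    return(list(center = x[ipk], sigma = NA_real_, height = yy[ipk],
                area = NA_real_))
  }
  sigma <- sqrt(-1 / (2 * co[3]))
  center <- -co[2] / (2 * co[3])
  height <- exp(co[1] - co[2]^2 / (4 * co[3]))
  list(center = unname(center), sigma = unname(sigma),
       height = unname(height), area = unname(height * sigma * sqrt(2 * pi)))
}
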