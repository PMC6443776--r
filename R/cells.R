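#' Rectangular (orthorhombic) unit cell
#'
#' The \eqn{\beta}-sheet crystal of silks is conventionally indexed on a
#' rectangular cell with the c axis along the fibre.
#'
#' @param a,b,c cell edges in Angstrom; all positive.
#' @return object of class `unit_cell`.
#' @export
unit_cell <- function(a, b, c) {
  if (any(c(a, b, c) <= 0)) stop("unit cell edges must be positive")
  structure(list(a = a, b = b, c = c), class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> a = %.3f, b = %.3f, c = %.3f Angstrom\n",
              x$a, x$b, x$c))
  invisible(x)
}

#' d-spacing of an (hkl) plane in a rectangular cell
#'
#' \eqn{1/d^2 = h^2/a^2 + k^2/b^2 + l^2/c^2}.
#'
#' @param cell a [unit_cell].
#' @param h,k,l Miller indices (vectors recycle).
#' @return d in Angstrom.
#' @export
d_spacing <- function(cell, h, k, l) {
  stopifnot(inherits(cell, "unit_cell"))
  1 / sqrt(h^2 / cell$a^2 + k^2 / cell$b^2 + l^2 / cell$c^2)
}

#' Convert between d-spacing and scattering angle
#'
#' Bragg's law \eqn{\lambda = 2 d \sin\theta} with d in Angstrom and the
#' wavelength in nm (converted internally).
#'
#' @param d d-spacing in Angstrom.
#' @param two_theta scattering angle 2\eqn{\theta} in degrees.
#' @param wavelength wavelength in nm.
#' @return the other quantity.
#' @export
d_to_two_theta <- function(d, wavelength) {
  s <- (wavelength * 10) / (2 * d)
  if (any(s >= 1)) stop("d-spacing unreachable at this wavelength")
  2 * asin(s) * 180 / pi
}

#' @rdname d_to_two_theta
#' @export
two_theta_to_d <- function(two_theta, wavelength) {
  (wavelength * 10) / (2 * sin(two_theta / 2 * pi / 180))
}

## reflection inventory of the silk beta-sheet fibre pattern; the (102) and
## (300) reflections overlap and are treated as one composite peak by default
beta_sheet_reflections <- function() {
  data.frame(
    label = c("200", "210", "211", "002", "102+300", "202"),
    stringsAsFactors = FALSE)
}

#' 2\eqn{\theta} positions of the \eqn{\beta}-sheet reflections
#'
#' Computes the six crystalline peak positions (200), (210), (211), (002),
#' (102)+(300) composite, (202) from a rectangular cell. The composite is
#' placed at the midpoint of its two component angles.
#'
#' @param cell a [unit_cell].
#' @param wavelength wavelength in nm.
#' @return data.frame with columns `label`, `two_theta` (degrees), `d`
#'   (Angstrom, of the composite: intensity-agnostic midpoint in angle).
#' @export
beta_sheet_positions <- function(cell, wavelength) {
  tt <- function(h, k, l) d_to_two_theta(d_spacing(cell, h, k, l), wavelength)
  two_theta <- c(tt(2, 0, 0), tt(2, 1, 0), tt(2, 1, 1), tt(0, 0, 2),
                 (tt(1, 0, 2) + tt(3, 0, 0)) / 2, tt(2, 0, 2))
  data.frame(label = beta_sheet_reflections()$label,
             two_theta = two_theta,
             d = two_theta_to_d(two_theta, wavelength),
             stringsAsFactors = FALSE)
}

#' Solve the rectangular cell from three reflections
#'
#' Inverts the d-spacings of the 200, 210 and 002 reflections under the
#' rectangular-cell assumption: \eqn{a = 2 d_{200}}, \eqn{c = 2 d_{002}}, and
#' b from \eqn{1/d_{210}^2 = 4/a^2 + 1/b^2}.
#'
#' @param d200,d210,d002 d-spacings in Angstrom; requires `d210 < d200`.
#' @return a [unit_cell].
#' @export
solve_unit_cell <- function(d200, d210, d002) {
  if (any(c(d200, d210, d002) <= 0)) stop("d-spacings must be positive")
  if (d210 >= d200) stop("inconsistent spacings: d210 must be < d200")
  a <- 2 * d200
  cc <- 2 * d002
  inv_b2 <- 1 / d210^2 - 4 / a^2
  if (inv_b2 <= 0)
    stop("inconsistent spacings: 1/d210^2 <= 4/a^2 admits no real b")
  unit_cell(a = a, b = 1 / sqrt(inv_b2), c = cc)
}
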