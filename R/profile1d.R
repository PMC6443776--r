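#' One-dimensional scattering profile
#'
#' Container for a 1D scattering trace: either a wide-angle 2\eqn{\theta}
#' profile (degrees) or a small-angle q profile (nm\eqn{^{-1}}), with the
#' wavelength of the radiation carried as metadata so that Bragg arithmetic is
#' always done with the profile's own wavelength.
#'
#' @param abscissa numeric, strictly increasing; 2\eqn{\theta} in degrees or q
#'   in nm\eqn{^{-1}} according to `kind`.
#' @param intensity numeric, finite, same length as `abscissa`.
#' @param kind `"two_theta"` or `"q"`.
#' @param wavelength X-ray wavelength in nm.
#' @return object of class `profile1d` (list with the four fields).
#' @export
profile1d <- function(abscissa, intensity, kind = c("two_theta", "q"),
                      wavelength) {
  kind <- match.arg(kind)
  abscissa <- as.numeric(abscissa)
  intensity <- as.numeric(intensity)
  if (length(abscissa) != length(intensity))
    stop("abscissa and intensity must have equal length")
  if (any(diff(abscissa) <= 0))
    stop("abscissa must be strictly increasing")
  if (!all(is.finite(intensity)))
    stop("intensity must be finite")
  if (!is.numeric(wavelength) || wavelength <= 0)
    stop("wavelength must be a positive number (nm)")
  structure(list(abscissa = abscissa, intensity = intensity, kind = kind,
                 wavelength = wavelength),
            class = "profile1d")
}

#' @export
print.profile1d <- function(x, ...) {
  unit <- if (x$kind == "q") "nm^-1" else "deg 2theta"
  cat(sprintf("<profile1d> %d points, %s in [%.4g, %.4g] %s, lambda = %g nm\n",
              length(x$abscissa), x$kind, min(x$abscissa), max(x$abscissa),
              unit, x$wavelength))
  invisible(x)
}

#' Read / write 1D profiles as two-column delimited text
#'
#' The text format is two whitespace-separated numeric columns preceded by
#' `#`-prefixed header lines carrying `kind` and `wavelength_nm`.
#'
#' @param path file path.
#' @return `read_profile` returns a [profile1d]; `write_profile` returns
#'   `path` invisibly.
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    m <- grep(paste0("^#\\s*", key, "\\s*:"), hdr, value = TRUE)
    if (!length(m)) return(NA_character_)
    trimws(sub(paste0("^#\\s*", key, "\\s*:"), "", m[1]))
  }
  kind <- get_field("kind")
  wl <- as.numeric(get_field("wavelength_nm"))
  if (is.na(kind) || is.na(wl))
    stop("profile header must carry 'kind' and 'wavelength_nm'")
  dat <- utils::read.table(text = lines[!grepl("^#", lines)])
  profile1d(dat[[1]], dat[[2]], kind = kind, wavelength = wl)
}

#' @param profile a [profile1d].
#' @rdname read_profile
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "profile1d"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# kind: %s", profile$kind),
               sprintf("# wavelength_nm: %.10g", profile$wavelength)), con)
  utils::write.table(
    data.frame(x = profile$abscissa, y = profile$intensity),
    con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
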