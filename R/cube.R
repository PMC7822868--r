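#' Hyperspectral radiance or reflectance cube
#'
#' A `radiance_cube` holds a wavelength-indexed image: an array with
#' dimensions `height x width x bands`, a strictly increasing wavelength
#' grid in nanometres, and optional acquisition metadata. Pixel coordinates
#' follow the `(u, v) = (column, row)` convention, 0-based with the origin
#' at the top-left.
#'
#' @param values numeric array `height x width x n_wavelengths`, all values
#'   finite and `>= 0`.
#' @param wavelengths strictly increasing wavelength grid (nm).
#' @param unit `"relative"` or `"absolute"` (W m^-2 sr^-1 nm^-1).
#' @param kind `"radiance"` or `"reflectance"`.
#' @param timestamp optional acquisition time, minutes since session start.
#' @param angular_subtense optional `c(horizontal, vertical)` in degrees.
#' @return An object of class `radiance_cube`.
#' @export
radiance_cube <- function(values, wavelengths, unit = "relative",
                          kind = "radiance", timestamp = NULL,
                          angular_subtense = NULL) {
  if (!is.array(values) || length(dim(values)) != 3) {
    abort("`values` must be a 3-d array (height x width x bands).",
          class = "surfid_format_error")
  }
  wavelengths <- as.numeric(wavelengths)
  if (dim(values)[3] != length(wavelengths)) {
    abort("third array dimension must match the wavelength grid.",
          class = "surfid_format_error")
  }
  if (any(diff(wavelengths) <= 0)) {
    abort("wavelength grid must be strictly increasing.",
          class = "surfid_format_error")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    abort("cube values must be finite.", class = "surfid_data_error")
  }
  if (any(values < 0)) {
    abort("cube values must be non-negative.", class = "surfid_data_error")
  }
  structure(
    list(values = values, wavelengths = wavelengths, unit = unit,
         kind = kind, timestamp = timestamp,
         angular_subtense = angular_subtense),
    class = "radiance_cube"
  )
}

#' @export
dim.radiance_cube <- function(x) dim(x$values)

cube_height <- function(cube) dim(cube$values)[1]
cube_width <- function(cube) dim(cube$values)[2]

#' @export
print.radiance_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<radiance_cube> %s, %d x %d px, %d bands %g-%g nm (%s)\n",
              x$kind, d[2], d[1], d[3], min(x$wavelengths),
              max(x$wavelengths), x$unit))
  cat(sprintf("  value range [%.4g, %.4g]", min(x$values), max(x$values)))
  if (!is.null(x$timestamp)) cat(sprintf(", t = %g min", x$timestamp))
  cat("\n")
  invisible(x)
}

# spectra matrix (n_pixels x bands) for 0-based coordinates u (col), v (row)
cube_spectra_at <- function(cube, u, v) {
  h <- cube_height(cube)
  w <- cube_width(cube)
  if (any(u < 0 | u >= w | v < 0 | v >= h)) {
    abort("pixel coordinates out of bounds.", class = "surfid_domain_error")
  }
  nb <- length(cube$wavelengths)
  flat <- matrix(cube$values, nrow = h * w, ncol = nb)
  flat[v + 1 + u * h, , drop = FALSE]
}

check_same_grid <- function(a, b) {
  if (length(a$wavelengths) != length(b$wavelengths) ||
      any(a$wavelengths != b$wavelengths)) {
    abort("wavelength grids do not match.", class = "surfid_format_error")
  }
  if (any(dim(a$values)[1:2] != dim(b$values)[1:2])) {
    abort("cube dimensions do not match.", class = "surfid_pairing_error")
  }
  invisible(TRUE)
}
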