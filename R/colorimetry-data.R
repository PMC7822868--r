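# Pinned colorimetric tables ----------------------------------------------
#
# The CIE 1931 2-degree colour-matching functions and the CIE daylight
# eigenvector components are shipped as plain columnar text under
# inst/extdata with an md5 manifest; they are read once per session and
# cached. Cone fundamentals are derived from the pinned CMF table through
# the Hunt-Pointer-Estevez transformation, so a single primary table
# anchors both the tristimulus and the cone-excitation paths.

the <- new.env(parent = emptyenv())

read_asset <- function(file) {
  path <- system.file("extdata", file, package = "surfid", mustWork = TRUE)
  manifest <- system.file("extdata", "CHECKSUMS", package = "surfid")
  if (nzchar(manifest)) {
    want <- utils::read.table(manifest, col.names = c("md5", "file"),
                              stringsAsFactors = FALSE)
    expected <- want$md5[want$file == file]
    if (length(expected) == 1 && !identical(unname(tools::md5sum(path)), expected)) {
      abort(sprintf("data asset '%s' failed its checksum.", file),
            class = "surfid_data_error")
    }
  }
  utils::read.table(path, header = TRUE)
}

cie_cmf <- function() {
  if (is.null(the$cmf)) the$cmf <- read_asset("cie_xyz_cmf_2deg_10nm.tsv")
  the$cmf
}

daylight_components <- function() {
  if (is.null(the$daylight)) {
    the$daylight <- read_asset("cie_daylight_components_10nm.tsv")
  }
  the$daylight
}

# Hunt-Pointer-Estevez cone matrix (D65-normalised), rows L, M, S
M_HPE <- matrix(c(0.38971, 0.68898, -0.07868,
                  -0.22981, 1.18340, 0.04641,
                  0.00000, 0.00000, 1.00000),
                nrow = 3, byrow = TRUE)

# CAT02 chromatic-adaptation matrix used by CIECAM02
M_CAT02 <- matrix(c(0.7328, 0.4296, -0.1624,
                    -0.7036, 1.6975, 0.0061,
                    0.0030, 0.0136, 0.9834),
                  nrow = 3, byrow = TRUE)

#' Cone fundamentals table
#'
#' 2-degree L, M, S cone spectral sensitivities on the 400-720 nm, 10-nm
#' grid, derived from the pinned CIE 1931 colour-matching functions by the
#' Hunt-Pointer-Estevez transformation.
#'
#' @return A tibble with columns `wavelength`, `L`, `M`, `S`.
#' @export
cone_fundamentals <- function() {
  if (is.null(the$fundamentals)) {
    cmf <- cie_cmf()
    lms <- as.matrix(cmf[, c("xbar", "ybar", "zbar")]) %*% t(M_HPE)
    the$fundamentals <- tibble(wavelength = cmf$wavelength,
                               L = lms[, 1], M = lms[, 2], S = lms[, 3])
  }
  the$fundamentals
}

# linear interpolation of a tabulated function onto a target grid;
# extrapolation is forbidden
interp_table <- function(wl_from, values, wl_to) {
  if (min(wl_to) < min(wl_from) || max(wl_to) > max(wl_from)) {
    abort("wavelength grid extends beyond the tabulated range; extrapolation is not supported.",
          class = "surfid_format_error")
  }
  if (length(wl_from) == length(wl_to) && all(wl_from == wl_to)) return(values)
  apply(as.matrix(values), 2, function(col)
    approx(wl_from, col, xout = wl_to)$y)
}
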