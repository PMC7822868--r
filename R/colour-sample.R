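# Colour codes for pixel samples ------------------------------------------

new_colour_sample <- function(coords, space, u = NULL, v = NULL) {
  out <- as_tibble(coords)
  if (!is.null(u)) {
    out <- dplyr::bind_cols(tibble(u = u, v = v), out)
  }
  attr(out, "space") <- space
  attr(out, "coord_cols") <- utils::tail(setdiff(names(out), c("u", "v")), 3)[1:3]
  class(out) <- c("colour_sample", class(out))
  out
}

#' Coordinate matrix of a colour sample
#'
#' @param sample a `colour_sample`.
#' @return `n x 3` numeric matrix of the colour coordinates.
#' @export
colour_coords <- function(sample) {
  cols <- attr(sample, "coord_cols")
  if (is.null(cols)) cols <- utils::tail(names(sample), 3)
  as.matrix(sample[, cols])
}

# white spectrum for relative colorimetry: the illuminant if known, else
# the spatial mean radiance spectrum of the sample
white_spectrum_of <- function(sample, white_spectrum, wavelengths) {
  if (!is.null(white_spectrum)) {
    if (inherits(white_spectrum, "illuminant_spectrum")) {
      return(illuminant_power_on_grid(white_spectrum, wavelengths))
    }
    return(as.numeric(white_spectrum))
  }
  colMeans(sample$spectrum)
}

#' Colour codes of a pixel sample
#'
#' Converts a [sample_pixels()] / [extract_strip()] sample to 3-d colour
#' coordinates in the requested uniform colour space. Tristimulus values
#' are normalised so the adopted white (the illuminant spectrum when known,
#' otherwise the sample's mean radiance spectrum) has `Y = 100`; the same
#' white drives the CIECAM02 viewing conditions and the CIELAB reference.
#'
#' For `space = "S-CIELAB"` the spatial filtering must precede the random
#' draw, so the full source cube is required: the whole image is filtered
#' at `ppd` pixels per degree and the sample positions are then read from
#' the filtered image.
#'
#' @param sample a `pixel_sample`.
#' @param space `"CIECAM02"`, `"CIELAB"` or `"S-CIELAB"`.
#' @param white_spectrum optional [illuminant_spectrum()] (or numeric
#'   spectrum on the sample grid) defining the adopted white.
#' @param vc optional [viewing_conditions()]; by default derived from the
#'   white (average surround, `Y_b` 20, `L_A` 20).
#' @param cube the source `radiance_cube`; required for S-CIELAB.
#' @param ppd pixels per degree for S-CIELAB filtering (source scenes: 200).
#' @return A `colour_sample` tibble: `u`, `v` and three coordinate columns
#'   (`J`, `a_C`, `b_C` for CIECAM02; `L_star`, `a_star`, `b_star`
#'   otherwise).
#' @export
colour_codes <- function(sample, space = c("CIECAM02", "CIELAB", "S-CIELAB"),
                         white_spectrum = NULL, vc = NULL, cube = NULL,
                         ppd = 200) {
  space <- match.arg(space)
  stopifnot(inherits(sample, "pixel_sample"))
  wl <- attr(sample, "wavelengths")
  white_sp <- white_spectrum_of(sample, white_spectrum, wl)
  white_xyz <- as.numeric(as.matrix(tristimulus(white_sp, wl)))
  if (white_xyz[2] <= 0) {
    abort("white spectrum has zero luminance.",
          class = "surfid_degenerate_error")
  }
  scale <- 100 / white_xyz[2]
  white_xyz <- white_xyz * scale

  if (space == "S-CIELAB") {
    if (is.null(cube)) {
      abort("S-CIELAB filtering applies to the full image; supply `cube`.",
            class = "surfid_config_error")
    }
    d <- dim(cube$values)
    flat <- matrix(cube$values, nrow = d[1] * d[2], ncol = d[3])
    xyz_img <- array(as.matrix(tristimulus(flat, cube$wavelengths)) * scale,
                     dim = c(d[1], d[2], 3))
    lab_img <- scielab_transform(xyz_img, pixels_per_degree = ppd,
                                 white_point = white_xyz)
    lin <- sample$v + 1 + sample$u * d[1]
    coords <- tibble(L_star = lab_img[, , 1][lin],
                     a_star = lab_img[, , 2][lin],
                     b_star = lab_img[, , 3][lin])
    return(new_colour_sample(coords, "S-CIELAB", sample$u, sample$v))
  }

  xyz <- as.matrix(tristimulus(sample$spectrum, wl)) * scale
  if (space == "CIECAM02") {
    if (is.null(vc)) {
      vc <- viewing_conditions(white_point = white_xyz)
    }
    coords <- ciecam02_coords(xyz, vc)[, c("J", "a_C", "b_C")]
    new_colour_sample(coords, "CIECAM02", sample$u, sample$v)
  } else {
    coords <- cielab_coords(xyz, white_xyz)
    new_colour_sample(coords, "CIELAB", sample$u, sample$v)
  }
}
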