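# Reading, writing and sampling hyperspectral cubes ------------------------

#' Write a radiance cube to disk
#'
#' Two dialects are supported: `"envi"` (band-sequential binary payload
#' with a standard ENVI text header carrying `samples`, `lines`, `bands`
#' and the wavelength list) and `"flat"` (band-sequential binary with a
#' JSON sidecar `<path>.json`). Doubles are written by default so the round
#' trip through [read_radiance_cube()] is bit-exact; `precision = "single"`
#' halves the file at float32 resolution.
#'
#' @param cube a `radiance_cube`.
#' @param path output path (payload file).
#' @param dialect `"envi"` or `"flat"`.
#' @param precision `"double"` or `"single"`.
#' @return `path`, invisibly.
#' @export
write_radiance_cube <- function(cube, path, dialect = c("envi", "flat"),
                                precision = c("double", "single")) {
  stopifnot(inherits(cube, "radiance_cube"))
  dialect <- match.arg(dialect)
  precision <- match.arg(precision)
  h <- cube_height(cube)
  w <- cube_width(cube)
  nb <- length(cube$wavelengths)
  size <- if (precision == "double") 8L else 4L
  # BSQ layout: sample (column) fastest, then line, then band
  flat <- as.numeric(aperm(cube$values, c(2, 1, 3)))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) abort(sprintf("cannot write '%s'.", path),
                                            class = "surfid_io_error"))
  on.exit(close(con), add = TRUE)
  writeBin(flat, con, size = size, endian = "little")
  if (dialect == "envi") {
    hdr <- c(
      "ENVI",
      sprintf("samples = %d", w),
      sprintf("lines = %d", h),
      sprintf("bands = %d", nb),
      "header offset = 0",
      "file type = ENVI Standard",
      sprintf("data type = %d", if (size == 8L) 5L else 4L),
      "interleave = bsq",
      "byte order = 0",
      "wavelength units = Nanometers",
      sprintf("wavelength = {%s}",
              paste(format(cube$wavelengths, trim = TRUE), collapse = ", "))
    )
    writeLines(hdr, paste0(path, ".hdr"))
  } else {
    meta <- list(width = w, height = h, bands = nb,
                 wavelengths = cube$wavelengths, precision = precision,
                 interleave = "bsq", unit = cube$unit, kind = cube$kind,
                 timestamp = cube$timestamp,
                 angular_subtense = cube$angular_subtense)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  get_scalar <- function(key) {
    m <- regmatches(txt, regexpr(sprintf("%s\\s*=\\s*[0-9.]+", key), txt))
    if (!length(m)) return(NULL)
    as.numeric(sub(".*=\\s*", "", m))
  }
  get_list <- function(key) {
    m <- regmatches(txt, regexpr(sprintf("%s\\s*=\\s*\\{[^}]*\\}", key), txt))
    if (!length(m)) return(NULL)
    as.numeric(strsplit(gsub(".*\\{|\\}", "", m), ",")[[1]])
  }
  list(samples = get_scalar("samples"), lines = get_scalar("lines"),
       bands = get_scalar("bands"), data_type = get_scalar("data type"),
       wavelength = get_list("wavelength"))
}

#' Read a radiance cube
#'
#' @param path payload path written by [write_radiance_cube()].
#' @param dialect `"auto"` (default: header sniffing), `"envi"` or
#'   `"flat"`. An `"hdf5"` request raises an unsupported-dialect error: no
#'   HDF5 reader is available to this package.
#' @param negative_tolerance small negative radiances down to
#'   `-negative_tolerance * max(value)` are clipped to zero with a message;
#'   more than 1% negative pixels is a data error.
#' @return A `radiance_cube` with bands sorted ascending in wavelength.
#' @export
read_radiance_cube <- function(path, dialect = c("auto", "envi", "flat", "hdf5"),
                               negative_tolerance = 1e-3) {
  dialect <- match.arg(dialect)
  if (dialect == "hdf5") {
    abort("the hdf5 dialect is not supported by this build.",
          class = "surfid_format_error")
  }
  if (!file.exists(path)) {
    abort(sprintf("file '%s' does not exist.", path),
          class = "surfid_io_error")
  }
  if (dialect == "auto") {
    dialect <- if (file.exists(paste0(path, ".hdr"))) "envi"
    else if (file.exists(paste0(path, ".json"))) "flat"
    else abort("cannot autodetect dialect: no .hdr or .json sidecar.",
               class = "surfid_format_error")
  }
  meta <- list(unit = "relative", kind = "radiance", timestamp = NULL,
               angular_subtense = NULL)
  if (dialect == "envi") {
    hdr <- parse_envi_header(paste0(path, ".hdr"))
    if (is.null(hdr$wavelength)) {
      abort("ENVI header has no wavelength list.",
            class = "surfid_format_error")
    }
    w <- hdr$samples; h <- hdr$lines; nb <- hdr$bands
    size <- if (identical(hdr$data_type, 5)) 8L else 4L
    wavelengths <- hdr$wavelength
  } else {
    side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    w <- side$width; h <- side$height; nb <- side$bands
    size <- if (identical(side$precision, "single")) 4L else 8L
    wavelengths <- side$wavelengths
    meta$unit <- side$unit %||% "relative"
    meta$kind <- side$kind %||% "radiance"
    meta$timestamp <- side$timestamp
    meta$angular_subtense <- side$angular_subtense
  }
  if (length(wavelengths) != nb) {
    abort("wavelength metadata does not match the band count.",
          class = "surfid_format_error")
  }
  n <- as.integer(w * h * nb)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  flat <- readBin(con, "double", n = n, size = size, endian = "little")
  if (length(flat) != n) {
    abort("payload shorter than the declared layout.",
          class = "surfid_format_error")
  }
  vals <- aperm(array(flat, dim = c(w, h, nb)), c(2, 1, 3))
  neg <- vals < 0
  if (any(neg)) {
    frac <- mean(neg)
    floor_ok <- vals >= -negative_tolerance * max(vals, 0)
    if (frac > 0.01 || !all(floor_ok | !neg)) {
      abort(sprintf("%.2f%% of values are negative beyond tolerance.",
                    100 * frac), class = "surfid_data_error")
    }
    inform(sprintf("clipped %d small negative values (%.3f%%) to zero.",
                   sum(neg), 100 * frac))
    vals[neg] <- 0
  }
  ord <- order(wavelengths)
  if (any(diff(ord) != 1)) {
    vals <- vals[, , ord, drop = FALSE]
    wavelengths <- wavelengths[ord]
  }
  radiance_cube(vals, wavelengths, unit = meta$unit, kind = meta$kind,
                timestamp = meta$timestamp,
                angular_subtense = meta$angular_subtense)
}

#' Summarise a cube
#'
#' Prints dimensions, wavelength grid and radiance range; returns the
#' summary as a one-row tibble, invisibly.
#'
#' @param x a `radiance_cube` or a path readable by [read_radiance_cube()].
#' @return Tibble with `width`, `height`, `bands`, `wl_min`, `wl_max`,
#'   `value_min`, `value_max`.
#' @export
cube_info <- function(x) {
  cube <- if (inherits(x, "radiance_cube")) x else read_radiance_cube(x)
  print(cube)
  invisible(tibble(width = cube_width(cube), height = cube_height(cube),
                   bands = length(cube$wavelengths),
                   wl_min = min(cube$wavelengths),
                   wl_max = max(cube$wavelengths),
                   value_min = min(cube$values),
                   value_max = max(cube$values)))
}

# Pixel samples ------------------------------------------------------------

new_pixel_sample <- function(u, v, spectra, cube) {
  out <- tibble(u = as.integer(u), v = as.integer(v))
  out$spectrum <- spectra
  attr(out, "wavelengths") <- cube$wavelengths
  attr(out, "source_timestamp") <- cube$timestamp
  class(out) <- c("pixel_sample", class(out))
  out
}

#' Extract a horizontal strip of pixels
#'
#' Strips are addressed by their top row (0-based); pixels come back in
#' row-major order. The canonical strip used for variation profiles on the
#' source scenes is 896 x 30 pixels.
#'
#' @param cube a `radiance_cube`.
#' @param top_row 0-based top row of the strip.
#' @param strip_height,strip_width strip size in pixels.
#' @param left_col 0-based leftmost column, default 0.
#' @return A `pixel_sample` tibble with columns `u`, `v` and a matrix
#'   column `spectrum`.
#' @export
extract_strip <- function(cube, top_row, strip_height = 30,
                          strip_width = cube_width(cube), left_col = 0) {
  stopifnot(inherits(cube, "radiance_cube"))
  h <- cube_height(cube)
  w <- cube_width(cube)
  if (top_row < 0 || top_row + strip_height > h ||
      left_col < 0 || left_col + strip_width > w) {
    abort("strip does not fit within the image.",
          class = "surfid_domain_error")
  }
  v <- rep(top_row:(top_row + strip_height - 1), each = strip_width)
  u <- rep(left_col:(left_col + strip_width - 1), times = strip_height)
  new_pixel_sample(u, v, cube_spectra_at(cube, u, v), cube)
}

#' Draw a random pixel sample
#'
#' Uniform positions without replacement, deterministic given the seed.
#' Positions, not values, define the draw: apply the same sample to the
#' paired cube with [pixels_at()] to obtain pixel-paired colour codes.
#'
#' @param cube a `radiance_cube`.
#' @param n sample size (`<= width * height`).
#' @param seed integer seed.
#' @return A `pixel_sample` tibble.
#' @export
sample_pixels <- function(cube, n, seed = 1L) {
  stopifnot(inherits(cube, "radiance_cube"))
  h <- cube_height(cube)
  w <- cube_width(cube)
  if (n > h * w) {
    abort("sample size exceeds the number of pixels.",
          class = "surfid_domain_error")
  }
  lin <- with_seed_(seed, sample.int(h * w, n))
  u <- (lin - 1) %/% h
  v <- (lin - 1) %% h
  new_pixel_sample(u, v, cube_spectra_at(cube, u, v), cube)
}

#' Re-read a pixel sample's positions from another cube
#'
#' @param cube a `radiance_cube` (e.g. the second member of a pair).
#' @param sample a `pixel_sample` drawn from the paired cube.
#' @return A `pixel_sample` at the same positions, with this cube's values.
#' @export
pixels_at <- function(cube, sample) {
  stopifnot(inherits(sample, "pixel_sample"))
  new_pixel_sample(sample$u, sample$v,
                   cube_spectra_at(cube, sample$u, sample$v), cube)
}
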