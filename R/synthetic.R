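#' Configuration for the synthetic hyperspectral scene generator
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: a fixed, spatially correlated effective reflectance field
#' `R(u,v;lambda)` lit by a daylight-like illuminant, with illumination
#' change modelled either as a global spectral (correlated-colour-
#' temperature) shift or as a spatially correlated multiplicative gain
#' field whose pixel standard deviation grows as
#' `gain_amplitude * log(1 + dt)` for a nominal interval `dt` in minutes.
#'
#' @param width,height image size in pixels (`>= 8`).
#' @param wavelengths wavelength grid in nm, strictly increasing within
#'   `[400, 720]`; default 400-720 nm in 10-nm steps.
#' @param n_basis number of smooth spectral basis functions mixed to make
#'   per-pixel reflectances. The default 3 mirrors the effective
#'   dimensionality of natural surface reflectances, which keeps metameric
#'   scatter under daylight changes realistically small.
#' @param spatial_corr_length autocorrelation length (pixels) of the
#'   reflectance mixing-weight fields: the lag at which spatial
#'   autocorrelation falls to 1/e.
#' @param palette_size optional integer `M`. When set, the scene is a
#'   discrete palette: exactly `M` distinct reflectance spectra arranged in
#'   `M` equal horizontal blocks (`height` must be divisible by `M`).
#' @param gain_amplitude dimensionless gain-field amplitude per unit
#'   `log(1 + dt_minutes)`.
#' @param gain_corr_length autocorrelation length (pixels) of the gain field.
#' @param sensor_noise_sd multiplicative sensor noise, as a fraction of the
#'   signal; default 0.1%, negligible against illumination change.
#' @param direct_fraction fraction of the illuminant carried by the direct
#'   (solar-beam) component; the remainder is diffuse sky light. Default
#'   0.85, a clear-sky midday direct/global ratio. Geometric illumination
#'   change redistributes the two components independently, so shadowed
#'   regions turn bluer and directly lit ones warmer.
#' @param sky_cct correlated colour temperature (kelvin) of the diffuse sky
#'   component, default 20000 (clear blue sky).
#' @param seed integer seed; every stochastic stage derives its own stream
#'   from it via a fixed splitter, so stages re-run independently.
#' @return A `scene_config` list.
#' @export
scene_config <- function(width = 128, height = 128,
                         wavelengths = seq(400, 720, by = 10),
                         n_basis = 3, spatial_corr_length = 8,
                         palette_size = NULL, gain_amplitude = 0.05,
                         gain_corr_length = 8, sensor_noise_sd = 0.001,
                         direct_fraction = 0.85, sky_cct = 20000,
                         seed = 1L) {
  check_number(width, "width", lower = 8)
  check_number(height, "height", lower = 8)
  wavelengths <- as.numeric(wavelengths)
  if (any(diff(wavelengths) <= 0) || min(wavelengths) < 400 ||
      max(wavelengths) > 720) {
    abort("wavelengths must be strictly increasing within [400, 720].",
          class = "surfid_config_error")
  }
  check_number(n_basis, "n_basis", lower = 1)
  check_number(spatial_corr_length, "spatial_corr_length", lower = 1)
  check_number(gain_amplitude, "gain_amplitude", lower = 0)
  check_number(gain_corr_length, "gain_corr_length", lower = 1)
  check_number(sensor_noise_sd, "sensor_noise_sd", lower = 0)
  check_number(direct_fraction, "direct_fraction", lower = 0, upper = 1)
  check_number(sky_cct, "sky_cct", lower = 4000, upper = 25000)
  if (!is.null(palette_size)) {
    check_number(palette_size, "palette_size", lower = 1)
    if (as.integer(height) %% as.integer(palette_size) != 0) {
      abort("in palette mode `height` must be divisible by `palette_size`.",
            class = "surfid_config_error")
    }
  }
  structure(
    list(width = as.integer(width), height = as.integer(height),
         wavelengths = wavelengths, n_basis = as.integer(n_basis),
         spatial_corr_length = spatial_corr_length,
         palette_size = if (is.null(palette_size)) NULL else as.integer(palette_size),
         gain_amplitude = gain_amplitude,
         gain_corr_length = gain_corr_length,
         sensor_noise_sd = sensor_noise_sd,
         direct_fraction = direct_fraction, sky_cct = sky_cct,
         seed = as.integer(seed)),
    class = "scene_config"
  )
}

# Gaussian-correlated random field via spectral synthesis (periodic).
# Autocorrelation is exp(-r^2 / corr_length^2) in the ensemble, i.e. it
# decays to 1/e at lag = corr_length. Returned field has zero mean and
# unit variance empirically.
smooth_field <- function(n_row, n_col, corr_length) {
  z <- matrix(rnorm(n_row * n_col), n_row, n_col)
  sigma <- corr_length / 2
  fr <- c(0:(floor(n_row / 2)), -((ceiling(n_row / 2) - 1):1)) / n_row
  fc <- c(0:(floor(n_col / 2)), -((ceiling(n_col / 2) - 1):1)) / n_col
  h <- exp(-2 * pi^2 * sigma^2 * outer(fr^2, fc^2, `+`))
  f <- Re(fft(fft(z) * h, inverse = TRUE)) / (n_row * n_col)
  f <- f - mean(f)
  f / sd(f)
}

# Gaussian bumps spanning the visible range; columns are basis spectra.
spectral_basis <- function(wavelengths, n_basis, fwhm = 80) {
  centres <- seq(min(wavelengths), max(wavelengths), length.out = n_basis)
  s <- fwhm / (2 * sqrt(2 * log(2)))
  vapply(centres, function(c0) exp(-(wavelengths - c0)^2 / (2 * s^2)),
         numeric(length(wavelengths)))
}

#' Generate a synthetic reflectance cube
#'
#' Per-pixel reflectance spectra are smooth mixtures of `n_basis` Gaussian
#' spectral bumps; mixing weights are spatially correlated Gaussian random
#' fields with autocorrelation length `spatial_corr_length`, and the result
#' is clipped to `[0, 1]`. In palette mode the image is `palette_size`
#' equal horizontal blocks, each a single spectrum.
#'
#' @param config a [scene_config()].
#' @return A `radiance_cube` with `kind = "reflectance"`.
#' @export
generate_reflectance_cube <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  wl <- config$wavelengths
  basis <- spectral_basis(wl, config$n_basis)
  h <- config$height
  w <- config$width
  amp <- 0.35 / sqrt(config$n_basis)

  if (!is.null(config$palette_size)) {
    m <- config$palette_size
    weights <- with_seed_(split_seed(config$seed, "palette"),
                          matrix(rnorm(m * config$n_basis), m, config$n_basis))
    spectra <- 0.4 + amp * weights %*% t(basis)   # m x n_wl
    spectra <- pmin(pmax(spectra, 0), 1)
    block <- h / m
    vals <- array(0, dim = c(h, w, length(wl)))
    for (i in seq_len(m)) {
      rows <- ((i - 1) * block + 1):(i * block)
      vals[rows, , ] <- rep(spectra[i, ], each = length(rows) * w)
    }
  } else {
    fields <- with_seed_(
      split_seed(config$seed, "reflectance"),
      lapply(seq_len(config$n_basis), function(b)
        smooth_field(h, w, config$spatial_corr_length))
    )
    vals <- array(0.4, dim = c(h, w, length(wl)))
    for (b in seq_len(config$n_basis)) {
      contrib <- outer(fields[[b]], basis[, b])
      vals <- vals + amp * contrib
    }
    vals <- pmin(pmax(vals, 0), 1)
  }
  radiance_cube(vals, wl, unit = "relative", kind = "reflectance")
}

#' Generate a spatially correlated illumination gain field
#'
#' Models the geometric component of an illumination change -- a
#' redistribution of light over the scene. The field is smooth, strictly
#' positive, has mean exactly 1 over pixels (change is redistribution, not
#' net gain), and pixel standard deviation
#' `gain_amplitude * log(1 + dt_minutes)`.
#'
#' @param config a [scene_config()].
#' @param dt_minutes nominal interval in minutes (`> 0`).
#' @param seed integer seed; defaults to a stream split from `config$seed`.
#' @return A `gain_field` object with elements `values` (height x width
#'   matrix), `corr_length`, `amplitude`, `nominal_dt`.
#' @export
generate_gain_field <- function(config, dt_minutes,
                                seed = split_seed(config$seed, paste0("gain", dt_minutes))) {
  stopifnot(inherits(config, "scene_config"))
  if (!is.numeric(dt_minutes) || length(dt_minutes) != 1 || dt_minutes <= 0) {
    abort("`dt_minutes` must be a single positive number.",
          class = "surfid_domain_error")
  }
  s <- config$gain_amplitude * log(1 + dt_minutes)
  if (s == 0) {
    g <- matrix(1, config$height, config$width)
  } else {
    z <- with_seed_(seed, smooth_field(config$height, config$width,
                                       config$gain_corr_length))
    g <- 1 + s * z
    g <- pmax(g, 0.05)   # keep strictly positive under large excursions
    g <- g / mean(g)     # redistribution: mean exactly 1
  }
  structure(
    list(values = g, corr_length = config$gain_corr_length,
         amplitude = config$gain_amplitude, nominal_dt = dt_minutes),
    class = "gain_field"
  )
}

unity_gain <- function(height, width) {
  structure(list(values = matrix(1, height, width), corr_length = Inf,
                 amplitude = 0, nominal_dt = 0), class = "gain_field")
}

#' Render a pair of radiance cubes from one reflectance field
#'
#' With a single gain field per member, each output pixel spectrum is
#' `gain(u,v) * E(lambda) * R(u,v;lambda) * (1 + sensor noise)`. A member's
#' gain may instead be a list `list(direct =, sky =)` of two gain fields:
#' the illuminant is then split into a direct (solar-beam) component
#' carrying `direct_fraction` of the power and a diffuse sky component with
#' the spectrum of `sky_illuminant`, and the two components are
#' redistributed independently -- so a darkened (shadowed) pixel also turns
#' bluer, as under real skies. Radiance is clipped at zero. The two members
#' share the reflectance field, so all differences between them come from
#' illumination and sensor noise.
#'
#' @param reflectance a reflectance `radiance_cube`.
#' @param illuminant1,illuminant2 [illuminant_spectrum()] objects on the
#'   cube's wavelength grid.
#' @param gain1,gain2 `gain_field` objects, or two-element lists
#'   `list(direct =, sky =)` of gain fields (default: unity).
#' @param sensor_noise_sd fraction of signal; independent multiplicative
#'   Gaussian noise per pixel and band in each member.
#' @param seed integer seed for the sensor noise.
#' @param timestamps optional length-2 acquisition times (minutes).
#' @param direct_fraction fraction of illuminant power in the direct
#'   component (used only with two-component gains).
#' @param sky_illuminant [illuminant_spectrum()] of the diffuse component
#'   (used only with two-component gains).
#' @return A list of two `radiance_cube`s.
#' @export
render_radiance_pair <- function(reflectance, illuminant1, illuminant2,
                                 gain1 = NULL, gain2 = NULL,
                                 sensor_noise_sd = 0, seed = 1L,
                                 timestamps = NULL, direct_fraction = 0.85,
                                 sky_illuminant = NULL) {
  stopifnot(inherits(reflectance, "radiance_cube"))
  h <- cube_height(reflectance)
  w <- cube_width(reflectance)
  if (is.null(gain1)) gain1 <- unity_gain(h, w)
  if (is.null(gain2)) gain2 <- unity_gain(h, w)
  # per-band spectral weight of the direct component in the illuminant
  direct_weight <- function(e) {
    if (is.null(sky_illuminant)) return(rep(1, length(e)))
    sky <- illuminant_power_on_grid(sky_illuminant, reflectance$wavelengths)
    pmax(1 - (1 - direct_fraction) * sky / mean(sky) / e, 0)
  }
  render_one <- function(ill, gain, stream, t) {
    e <- illuminant_power_on_grid(ill, reflectance$wavelengths)
    vals <- sweep(reflectance$values, 3, e, `*`)
    if (inherits(gain, "gain_field")) {
      vals <- sweep(vals, 1:2, gain$values, `*`)
    } else {
      stopifnot(is.list(gain), inherits(gain$direct, "gain_field"),
                inherits(gain$sky, "gain_field"))
      wd <- direct_weight(e)
      for (b in seq_along(e)) {
        vals[, , b] <- vals[, , b] *
          (gain$direct$values * wd[b] + gain$sky$values * (1 - wd[b]))
      }
    }
    if (sensor_noise_sd > 0) {
      noise <- with_seed_(split_seed(seed, stream),
                          array(rnorm(length(vals), 0, sensor_noise_sd),
                                dim = dim(vals)))
      vals <- vals * (1 + noise)
    }
    radiance_cube(pmax(vals, 0), reflectance$wavelengths, unit = "relative",
                  kind = "radiance", timestamp = t,
                  angular_subtense = reflectance$angular_subtense)
  }
  list(render_one(illuminant1, gain1, "noise1", timestamps[1]),
       render_one(illuminant2, gain2, "noise2", timestamps[2]))
}
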