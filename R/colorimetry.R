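# Radiance -> cone excitations -> appearance coordinates -------------------

#' Illuminant spectral power distribution
#'
#' @param wavelengths wavelength grid (nm), strictly increasing.
#' @param power relative spectral power, `>= 0`.
#' @param cct optional correlated colour temperature (kelvin).
#' @return An `illuminant_spectrum` object.
#' @export
illuminant_spectrum <- function(wavelengths, power, cct = NULL) {
  wavelengths <- as.numeric(wavelengths)
  power <- as.numeric(power)
  if (length(wavelengths) != length(power) || any(diff(wavelengths) <= 0)) {
    abort("wavelengths must be strictly increasing and match `power`.",
          class = "surfid_format_error")
  }
  if (any(power < 0)) {
    abort("illuminant power must be non-negative.",
          class = "surfid_domain_error")
  }
  structure(list(wavelengths = wavelengths, power = power, cct = cct),
            class = "illuminant_spectrum")
}

illuminant_power_on_grid <- function(ill, grid) {
  stopifnot(inherits(ill, "illuminant_spectrum"))
  as.numeric(interp_table(ill$wavelengths, matrix(ill$power), grid))
}

#' CIE daylight-series illuminant for a correlated colour temperature
#'
#' Builds the daylight spectral power distribution from the standard
#' daylight chromaticity locus and the S0/S1/S2 eigenvector components,
#' resampled to the requested grid and normalised to unit mean power.
#' The classic reciprocal-megakelvin formulation is used as published; set
#' `c2_rescale = TRUE` to apply the 1.4388/1.4380 radiation-constant
#' rescaling of the nominal temperature.
#'
#' @param cct correlated colour temperature in kelvin, 4000-25000.
#' @param wavelengths target grid (nm), default 400-720 at 10 nm.
#' @param c2_rescale logical; rescale `cct` by 1.4388/1.4380.
#' @return An [illuminant_spectrum()].
#' @export
daylight_spd <- function(cct, wavelengths = seq(400, 720, by = 10),
                         c2_rescale = FALSE) {
  check_number(cct, "cct", lower = 4000, upper = 25000)
  t <- if (c2_rescale) cct * 1.4388 / 1.4380 else cct
  xd <- if (t <= 7000) {
    -4.6070e9 / t^3 + 2.9678e6 / t^2 + 0.09911e3 / t + 0.244063
  } else {
    -2.0064e9 / t^3 + 1.9018e6 / t^2 + 0.24748e3 / t + 0.237040
  }
  yd <- -3.000 * xd^2 + 2.870 * xd - 0.275
  m0 <- 0.0241 + 0.2562 * xd - 0.7341 * yd
  m1 <- (-1.3515 - 1.7703 * xd + 5.9114 * yd) / m0
  m2 <- (0.0300 - 31.4424 * xd + 30.0717 * yd) / m0
  comp <- daylight_components()
  spd <- comp$s0 + m1 * comp$s1 + m2 * comp$s2
  power <- as.numeric(interp_table(comp$wavelength, matrix(spd), wavelengths))
  power <- pmax(power, 0)
  illuminant_spectrum(wavelengths, power / mean(power), cct = cct)
}

#' Globally re-illuminate a radiance cube
#'
#' Given the illuminant `e0` under which the cube was recorded, replaces it
#' by `e_target` through the pixelwise spectral ratio
#' `L'(u,v;lambda) = (E_target(lambda) / E0(lambda)) L(u,v;lambda)`, i.e.
#' the cube's effective reflectance is held fixed while the global
#' illuminant spectrum changes.
#'
#' @param cube a `radiance_cube`.
#' @param e0,e_target [illuminant_spectrum()] objects; `e0` must be strictly
#'   positive on the cube grid.
#' @return The re-illuminated `radiance_cube`.
#' @export
reilluminate <- function(cube, e0, e_target) {
  stopifnot(inherits(cube, "radiance_cube"))
  p0 <- illuminant_power_on_grid(e0, cube$wavelengths)
  pt <- illuminant_power_on_grid(e_target, cube$wavelengths)
  if (any(p0 <= 0)) {
    abort("`e0` must be strictly positive at every band.",
          class = "surfid_domain_error")
  }
  out <- cube
  out$values <- sweep(cube$values, 3, pt / p0, `*`)
  out
}

# Cone excitations ---------------------------------------------------------

spectra_matrix <- function(spectrum) {
  if (is.matrix(spectrum)) spectrum else matrix(spectrum, nrow = 1)
}

#' Cone excitations from spectral radiance
#'
#' Numerically integrates radiance against the pinned L, M, S cone
#' fundamentals over the 400-720 nm range:
#' `q_k = sum_lambda fundamental_k(lambda) L(lambda) dlambda`. The map is
#' linear in radiance. Spectra on a different (interior) grid are linearly
#' resampled onto the fundamentals' grid first.
#'
#' @param spectrum radiance spectrum (vector) or matrix of spectra, one row
#'   per pixel.
#' @param wavelengths grid of the spectra (nm).
#' @return A tibble with columns `qL`, `qM`, `qS`.
#' @export
cone_excitations <- function(spectrum, wavelengths = seq(400, 720, by = 10)) {
  sp <- spectra_matrix(spectrum)
  if (ncol(sp) != length(wavelengths)) {
    abort("spectra and wavelength grid have different lengths.",
          class = "surfid_format_error")
  }
  fund <- cone_fundamentals()
  if (!(length(wavelengths) == nrow(fund) &&
        all(wavelengths == fund$wavelength))) {
    inform("resampling spectra onto the cone-fundamentals grid.")
    sp <- t(apply(sp, 1, function(row)
      as.numeric(interp_table(wavelengths, matrix(row), fund$wavelength))))
    wavelengths <- fund$wavelength
  }
  dl <- mean(diff(wavelengths))
  q <- sp %*% as.matrix(fund[, c("L", "M", "S")]) * dl
  tibble(qL = q[, 1], qM = q[, 2], qS = q[, 3])
}

#' von Kries scaling of cone excitations
#'
#' Divides each cone class by its spatial mean over the sample,
#' `q'_k = q_k / mean(q_k)`, the classical model of chromatic adaptation.
#' Post-scaling class means are exactly 1, so the result is invariant to a
#' global radiance scale.
#'
#' @param excitations tibble with columns `qL`, `qM`, `qS`.
#' @return Tibble of scaled excitations with the same columns.
#' @export
von_kries_scale <- function(excitations) {
  m <- as.matrix(excitations[, c("qL", "qM", "qS")])
  if (nrow(m) == 0) {
    abort("empty sample.", class = "surfid_degenerate_error")
  }
  mu <- colMeans(m)
  if (any(mu <= 0)) {
    abort("a cone class has non-positive mean; cannot von Kries scale.",
          class = "surfid_degenerate_error")
  }
  out <- sweep(m, 2, mu, `/`)
  tibble(qL = out[, 1], qM = out[, 2], qS = out[, 3])
}

#' Euclidean norm of cone-excitation differences
#'
#' The unweighted norm `delta_e = sqrt(sum_k (q'_k2 - q'_k1)^2)` between
#' paired von Kries-scaled triplets.
#'
#' @param t1,t2 tibbles of scaled excitations, row-paired.
#' @return Numeric vector of magnitudes.
#' @export
delta_e_cones <- function(t1, t2) {
  m1 <- as.matrix(t1[, c("qL", "qM", "qS")])
  m2 <- as.matrix(t2[, c("qL", "qM", "qS")])
  if (nrow(m1) != nrow(m2)) {
    abort("samples are not paired.", class = "surfid_pairing_error")
  }
  sqrt(rowSums((m2 - m1)^2))
}

# Tristimulus and appearance spaces ----------------------------------------

#' Tristimulus values from spectral radiance
#'
#' Standard colour-matching integration on the tabulated 10-nm grid. Values
#' are raw integrals; relative colorimetry (scaling the adopted white to
#' `Y = 100`) is applied by the callers that know the white.
#'
#' @inheritParams cone_excitations
#' @return Tibble with columns `X`, `Y`, `Z`.
#' @export
tristimulus <- function(spectrum, wavelengths = seq(400, 720, by = 10)) {
  sp <- spectra_matrix(spectrum)
  if (ncol(sp) != length(wavelengths)) {
    abort("spectra and wavelength grid have different lengths.",
          class = "surfid_format_error")
  }
  cmf <- cie_cmf()
  if (!(length(wavelengths) == nrow(cmf) &&
        all(wavelengths == cmf$wavelength))) {
    sp <- t(apply(sp, 1, function(row)
      as.numeric(interp_table(wavelengths, matrix(row), cmf$wavelength))))
    wavelengths <- cmf$wavelength
  }
  dl <- mean(diff(wavelengths))
  xyz <- sp %*% as.matrix(cmf[, c("xbar", "ybar", "zbar")]) * dl
  tibble(X = xyz[, 1], Y = xyz[, 2], Z = xyz[, 3])
}

chromaticity_xy <- function(xyz) {
  m <- as.matrix(xyz)
  s <- rowSums(m)
  cbind(x = m[, 1] / s, y = m[, 2] / s)
}

#' CIECAM02 viewing conditions
#'
#' Defaults follow relative colorimetry with the adopted white at
#' `Y = 100`: average surround, background relative luminance 20%, adapting
#' luminance 20% of the white luminance. These settings are echoed in every
#' run log and can be overridden per call.
#'
#' @param white_point tristimulus triplet of the adopted white (`Y = 100`).
#' @param adapting_luminance `L_A` in cd m^-2 (`> 0`).
#' @param background_relative_luminance `Y_b / Y_w` as a percentage of 100.
#' @param surround `"average"`, `"dim"` or `"dark"`.
#' @return A `viewing_conditions` list.
#' @export
viewing_conditions <- function(white_point = c(95.05, 100, 108.88),
                               adapting_luminance = 20,
                               background_relative_luminance = 20,
                               surround = c("average", "dim", "dark")) {
  surround <- match.arg(surround)
  check_number(adapting_luminance, "adapting_luminance", lower = 0,
               strict_lower = TRUE)
  structure(list(white_point = as.numeric(white_point),
                 adapting_luminance = adapting_luminance,
                 yb = background_relative_luminance,
                 surround = surround),
            class = "viewing_conditions")
}

surround_params <- function(surround) {
  switch(surround,
         average = list(f = 1.0, c = 0.69, nc = 1.0),
         dim = list(f = 0.9, c = 0.59, nc = 0.9),
         dark = list(f = 0.8, c = 0.525, nc = 0.8))
}

cam02_response <- function(rgb_p, fl) {
  x <- (fl * abs(rgb_p) / 100)^0.42
  sign(rgb_p) * 400 * x / (27.13 + x) + 0.1
}

#' CIECAM02 appearance coordinates
#'
#' Forward CIECAM02 model returning the lightness correlate `J` (0-100) and
#' the rectangular chromatic correlates `a_C = C cos h`, `b_C = C sin h`
#' (redness-greenness and yellowness-blueness). Relative-colorimetry
#' invariant: scaling sample and white tristimulus together leaves the
#' output unchanged.
#'
#' @param xyz tibble/matrix of tristimulus values, one row per pixel, on the
#'   scale where the adopted white has `Y = 100`.
#' @param vc a [viewing_conditions()] object.
#' @return Tibble with columns `J`, `a_C`, `b_C` (plus `C` and `h`).
#' @export
ciecam02_coords <- function(xyz, vc = viewing_conditions()) {
  stopifnot(inherits(vc, "viewing_conditions"))
  m <- as.matrix(xyz)
  if (any(!is.finite(m)) || any(m < -1e-9)) {
    abort("tristimulus values must be finite and non-negative.",
          class = "surfid_domain_error")
  }
  m[m < 0] <- 0
  sr <- surround_params(vc$surround)
  la <- vc$adapting_luminance
  # relative colorimetry: the model is defined with the white at Y = 100
  white <- vc$white_point * 100 / vc$white_point[2]
  m <- m * 100 / vc$white_point[2]
  yw <- white[2]

  rgb_w <- as.numeric(M_CAT02 %*% white)
  d <- sr$f * (1 - (1 / 3.6) * exp((-la - 42) / 92))
  d <- min(max(d, 0), 1)
  d_fac <- yw * d / rgb_w + 1 - d

  k <- 1 / (5 * la + 1)
  fl <- 0.2 * k^4 * (5 * la) + 0.1 * (1 - k^4)^2 * (5 * la)^(1 / 3)
  n <- vc$yb / 100   # background luminance is relative to the white
  nbb <- 0.725 * (1 / n)^0.2
  ncb <- nbb
  z <- 1.48 + sqrt(n)

  m_h <- M_HPE %*% solve(M_CAT02)
  to_adapted <- function(xyz_rows) {
    rgb <- xyz_rows %*% t(M_CAT02)
    rgb_c <- sweep(rgb, 2, d_fac, `*`)
    rgb_c %*% t(m_h)
  }
  resp_w <- cam02_response(as.numeric(to_adapted(matrix(white, nrow = 1))), fl)
  aw <- (2 * resp_w[1] + resp_w[2] + resp_w[3] / 20 - 0.305) * nbb

  resp <- cam02_response(to_adapted(m), fl)
  ra <- resp[, 1]; ga <- resp[, 2]; ba <- resp[, 3]
  a <- ra - 12 * ga / 11 + ba / 11
  b <- (ra + ga - 2 * ba) / 9
  h <- (atan2(b, a) * 180 / pi) %% 360
  et <- (cos(h * pi / 180 + 2) + 3.8) / 4
  achrom <- (2 * ra + ga + ba / 20 - 0.305) * nbb
  j <- 100 * (pmax(achrom, 0) / aw)^(sr$c * z)
  t_ <- (50000 / 13) * sr$nc * ncb * et * sqrt(a^2 + b^2) /
    (ra + ga + 21 / 20 * ba)
  cc <- t_^0.9 * sqrt(j / 100) * (1.64 - 0.29^n)^0.73
  tibble(J = j, a_C = cc * cos(h * pi / 180), b_C = cc * sin(h * pi / 180),
         C = cc, h = h)
}

#' CIELAB coordinates
#'
#' Standard CIE 1976 `L* a* b*` formulas including the low-ratio linear
#' segment.
#'
#' @param xyz tibble/matrix of tristimulus values, one row per pixel.
#' @param white_point tristimulus triplet of the reference white.
#' @return Tibble with columns `L_star`, `a_star`, `b_star`.
#' @export
cielab_coords <- function(xyz, white_point = c(95.05, 100, 108.88)) {
  if (any(white_point <= 0)) {
    abort("white point must be strictly positive.",
          class = "surfid_domain_error")
  }
  m <- as.matrix(xyz)
  f <- function(t) {
    ifelse(t > (6 / 29)^3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  }
  fx <- f(m[, 1] / white_point[1])
  fy <- f(m[, 2] / white_point[2])
  fz <- f(m[, 3] / white_point[3])
  tibble(L_star = 116 * fy - 16,
         a_star = 500 * (fx - fy),
         b_star = 200 * (fy - fz))
}

# S-CIELAB -----------------------------------------------------------------

# Poirson-Wandell opponent transform (from XYZ) and its inverse
M_OPP <- matrix(c(0.2787, 0.7218, -0.1066,
                  -0.4488, 0.2898, -0.0772,
                  0.0860, -0.5900, 0.5011),
                nrow = 3, byrow = TRUE)

# published sum-of-Gaussian spatial filters: weights and spreads (degrees)
# in the form w * exp(-(x^2 + y^2) / sigma^2)
SCIELAB_FILTERS <- list(
  lum = list(w = c(0.921, 0.105, -0.108), sigma = c(0.0283, 0.133, 4.336)),
  rg  = list(w = c(0.531, 0.330), sigma = c(0.0392, 0.494)),
  by  = list(w = c(0.488, 0.371), sigma = c(0.0536, 0.386))
)

# separable convolution of `img` with the 1-d kernel `g` along rows then
# columns, replicate padding (preserves constants exactly)
conv_sep <- function(img, g) {
  r <- (length(g) - 1) / 2
  pad_conv <- function(m) {
    n <- ncol(m)
    idx <- c(rep(1, r), seq_len(n), rep(n, r))
    mp <- m[, idx, drop = FALSE]
    out <- matrix(0, nrow(m), n)
    for (j in seq_along(g)) {
      out <- out + g[j] * mp[, j:(j + n - 1), drop = FALSE]
    }
    out
  }
  t(pad_conv(t(pad_conv(img))))
}

scielab_kernel_1d <- function(sigma_deg, ppd) {
  s <- sigma_deg * ppd           # spread in pixels
  r <- max(1, ceiling(3 * s))
  x <- (-r):r
  exp(-x^2 / s^2)
}

filter_plane <- function(img, filt, ppd) {
  acc <- matrix(0, nrow(img), ncol(img))
  norm <- 0
  kernels <- lapply(filt$sigma, scielab_kernel_1d, ppd = ppd)
  for (i in seq_along(filt$w)) {
    g <- kernels[[i]]
    norm <- norm + filt$w[i] * sum(g)^2
  }
  for (i in seq_along(filt$w)) {
    g <- kernels[[i]] / sqrt(abs(norm))   # fold normalisation into kernels
    acc <- acc + sign(norm) * filt$w[i] * conv_sep(img, g)
  }
  acc
}

#' S-CIELAB transform of a tristimulus image
#'
#' Applies the pattern-separable spatial filtering of S-CIELAB -- a
#' sum-of-Gaussians filter per opponent channel (luminance, red-green,
#' blue-yellow), scaled by the pixels-per-degree of the viewing geometry --
#' and then converts each pixel to CIELAB. Filtering precedes any pixel
#' sampling. Each filter is normalised to unit DC gain, so a spatially
#' uniform image is returned identical to its per-pixel CIELAB rendering.
#'
#' @param xyz_image numeric array `height x width x 3` of tristimulus
#'   values.
#' @param pixels_per_degree pixels per degree of visual angle (`> 0`); the
#'   source scenes correspond to 200 (0.3 arcmin per pixel).
#' @param white_point reference white for the CIELAB stage.
#' @return Array `height x width x 3` of `L*`, `a*`, `b*` planes.
#' @export
scielab_transform <- function(xyz_image, pixels_per_degree = 200,
                              white_point = c(95.05, 100, 108.88)) {
  if (!is.array(xyz_image) || length(dim(xyz_image)) != 3 ||
      dim(xyz_image)[3] != 3) {
    abort("`xyz_image` must be a height x width x 3 array.",
          class = "surfid_format_error")
  }
  check_number(pixels_per_degree, "pixels_per_degree", lower = 0,
               strict_lower = TRUE)
  d <- dim(xyz_image)
  flat <- matrix(xyz_image, ncol = 3)
  opp <- flat %*% t(M_OPP)
  planes <- list(matrix(opp[, 1], d[1], d[2]),
                 matrix(opp[, 2], d[1], d[2]),
                 matrix(opp[, 3], d[1], d[2]))
  filts <- SCIELAB_FILTERS
  planes[[1]] <- filter_plane(planes[[1]], filts$lum, pixels_per_degree)
  planes[[2]] <- filter_plane(planes[[2]], filts$rg, pixels_per_degree)
  planes[[3]] <- filter_plane(planes[[3]], filts$by, pixels_per_degree)
  opp_f <- cbind(as.numeric(planes[[1]]), as.numeric(planes[[2]]),
                 as.numeric(planes[[3]]))
  xyz_f <- opp_f %*% t(solve(M_OPP))
  xyz_f[xyz_f < 0] <- 0
  lab <- cielab_coords(xyz_f, white_point)
  array(c(lab$L_star, lab$a_star, lab$b_star), dim = d)
}
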