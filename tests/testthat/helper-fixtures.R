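# Shared fixtures, all generated in code.

# small continuous synthetic scene
small_scene <- function(seed = 1, ...) {
  scene_config(width = 64, height = 64,
               spatial_corr_length = 6, gain_corr_length = 4,
               sensor_noise_sd = 0, seed = seed, ...)
}

# a baseline radiance cube for a scene config under 6500 K daylight
baseline_cube <- function(sc, cct = 6500) {
  refl <- generate_reflectance_cube(sc)
  e <- daylight_spd(cct, sc$wavelengths)
  render_radiance_pair(refl, e, e, sensor_noise_sd = sc$sensor_noise_sd,
                       seed = sc$seed)[[1]]
}

# well-separated random palette in a 3-d colour-like space
palette_sample <- function(m, n, centre_spread = 100, seed = 1) {
  withr::with_seed(seed, {
    centres <- matrix(runif(m * 3, 0, centre_spread), m, 3)
    labels <- sample.int(m, n, replace = TRUE)
    list(labels = labels, centres = centres, coords = centres[labels, ])
  })
}

# wrap a coordinate matrix as a colour_sample the analysis functions accept
as_colour_sample <- function(coords,
                             cols = c("J", "a_C", "b_C"),
                             space = "CIECAM02") {
  out <- tibble::as_tibble(as.data.frame(coords))
  names(out) <- cols
  attr(out, "space") <- space
  attr(out, "coord_cols") <- cols
  class(out) <- c("colour_sample", class(out))
  out
}

# brute-force discrete mutual information from two label vectors (bits)
label_mi <- function(la, lb) {
  tab <- table(la, lb) / length(la)
  pa <- rowSums(tab)
  pb <- colSums(tab)
  nz <- tab > 0
  sum(tab[nz] * log2(tab[nz] / outer(pa, pb)[nz]))
}

# histogram plug-in mutual information for two 1-d variables (bits)
hist_mi_1d <- function(a, b, bins = 40) {
  cut2 <- function(x) as.integer(cut(x, breaks = bins))
  label_mi(cut2(a), cut2(b))
}

gauss_entropy_bits <- function(d, sigma = 1) {
  (d / 2) * log2(2 * pi * exp(1) * sigma^2)
}
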