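test_that("zero-interval identifiability reduces exactly to distinguishability", {
  set.seed(201)
  smp <- as_colour_sample(matrix(rnorm(3000 * 3, 50, 8), ncol = 3))
  noise <- noise_model(0.5, "gaussian")
  ident <- n_identifiable(smp, smp, noise, interval_dt = 0, seed = 77)
  disting <- n_distinguishable(smp, noise, seed = 77)
  expect_identical(ident$mi$bits, disting$mi$bits)
  expect_identical(ident$n_surfaces, disting$n_surfaces)
  expect_equal(disting$n_surfaces, 2^disting$mi$bits)
})

test_that("a well-separated palette counts its own size", {
  pal <- palette_sample(64, 2e4, seed = 301)
  smp <- as_colour_sample(pal$coords)
  est <- n_distinguishable(smp, noise_model(0.5, "gaussian"),
                           n_noise_reps = 3, seed = 5)
  expect_lt(abs(est$n_surfaces - 64) / 64, 0.1)
})

test_that("a collapsed or reshuffled partner carries no identity information", {
  one <- as_colour_sample(matrix(rep(c(50, 0, 0), each = 500), ncol = 3))
  est_one <- n_distinguishable(one, noise_model(0.5, "gaussian"), seed = 1)
  expect_equal(est_one$n_surfaces, 1, tolerance = 0.05)

  set.seed(202)
  coords <- matrix(rnorm(4e3 * 3, 50, 8), ncol = 3)
  smp <- as_colour_sample(coords)
  shuffled <- as_colour_sample(coords[sample(nrow(coords)), ])
  est <- n_identifiable(smp, shuffled, noise_model(0.5, "gaussian"),
                        n_noise_reps = 3, interval_dt = 5, seed = 2)
  expect_lt(est$mi$bits, 0.1)
})

test_that("identifiability drops with gain-field amplitude and never beats distinguishability", {
  noise <- noise_model(0.5, "gaussian")
  e0 <- daylight_spd(6500)
  counts <- vapply(c(0.02, 0.04, 0.08), function(amp) {
    sc <- scene_config(width = 64, height = 64, gain_amplitude = amp,
                       gain_corr_length = 4, sensor_noise_sd = 0, seed = 31)
    refl <- generate_reflectance_cube(sc)
    g2 <- generate_gain_field(sc, 10, seed = 99)
    pair <- render_radiance_pair(refl, e0, e0, gain2 = g2)
    px1 <- sample_pixels(pair[[1]], 4000, seed = 4)
    s1 <- colour_codes(px1, white_spectrum = e0)
    s2 <- colour_codes(pixels_at(pair[[2]], px1), white_spectrum = e0)
    n_identifiable(s1, s2, noise, n_noise_reps = 3, interval_dt = 10,
                   seed = 8)$mi$bits
  }, numeric(1))
  expect_true(all(diff(counts) < 0.1))
  expect_lt(counts[3], counts[1])

  # distinguishability of the unchanged member bounds identifiability
  sc <- scene_config(width = 64, height = 64, gain_amplitude = 0.04,
                     gain_corr_length = 4, sensor_noise_sd = 0, seed = 31)
  refl <- generate_reflectance_cube(sc)
  g2 <- generate_gain_field(sc, 10, seed = 99)
  pair <- render_radiance_pair(refl, e0, e0, gain2 = g2)
  px1 <- sample_pixels(pair[[1]], 4000, seed = 4)
  s1 <- colour_codes(px1, white_spectrum = e0)
  s2 <- colour_codes(pixels_at(pair[[2]], px1), white_spectrum = e0)
  ident <- n_identifiable(s1, s2, noise, n_noise_reps = 3,
                          interval_dt = 10, seed = 8)
  disting <- n_distinguishable(s1, noise, n_noise_reps = 3, seed = 8)
  expect_lt(ident$mi$bits, disting$mi$bits + 0.1)
})

test_that("surface counts are stable once the pixel sample is large enough", {
  sc <- scene_config(width = 160, height = 160, gain_corr_length = 4,
                     sensor_noise_sd = 0, seed = 41)
  cube <- baseline_cube(sc)
  e0 <- daylight_spd(6500, sc$wavelengths)
  noise <- noise_model(0.5, "gaussian")
  px <- sample_pixels(cube, 2e4, seed = 11)
  smp <- colour_codes(px, white_spectrum = e0)
  half <- as_colour_sample(colour_coords(smp)[1:1e4, ])
  n1 <- n_distinguishable(half, noise, n_noise_reps = 5,
                          seed = 12)$n_surfaces
  n2 <- n_distinguishable(smp, noise, n_noise_reps = 5,
                          seed = 12)$n_surfaces
  expect_lt(abs(n2 - n1) / n1, 0.05)
})

test_that("Gaussian and uniform noise of equal width give matching identifiability", {
  # when the illumination change dominates the internal noise, the two
  # matched-variance noise families give near-identical counts
  sc <- small_scene(seed = 51)
  refl <- generate_reflectance_cube(sc)
  e0 <- daylight_spd(6500, sc$wavelengths)
  g2 <- generate_gain_field(sc, 10)
  pair <- render_radiance_pair(refl, e0, e0, gain2 = g2)
  px <- sample_pixels(pair[[1]], 4000, seed = 13)
  s1 <- colour_codes(px, white_spectrum = e0)
  s2 <- colour_codes(pixels_at(pair[[2]], px), white_spectrum = e0)
  n_g <- n_identifiable(s1, s2, noise_model(0.5, "gaussian"),
                        n_noise_reps = 3, interval_dt = 10,
                        seed = 14)$n_surfaces
  n_u <- n_identifiable(s1, s2, noise_model(0.5, "uniform"),
                        n_noise_reps = 3, interval_dt = 10,
                        seed = 14)$n_surfaces
  expect_lt(abs(n_g - n_u) / n_g, 0.15)
})

test_that("time-course regression is exact on power-law inputs", {
  dts <- c(1, 2, 5, 15, 60, 240)
  obs <- tibble::tibble(interval_dt = dts, n_surfaces = 800 * dts^-0.6)
  fit <- time_course_fit(obs)
  expect_equal(fit$slope, -0.6, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$predictions$n_surfaces, 800 * c(2, 10, 60)^-0.6,
               tolerance = 1e-10)
  expect_equal(fit$predictions$n_surfaces,
               2^(fit$intercept + fit$slope * log2(c(2, 10, 60))))

  flat <- tibble::tibble(interval_dt = dts, n_surfaces = rep(500, 6))
  expect_equal(time_course_fit(flat)$slope, 0, tolerance = 1e-12)

  expect_error(time_course_fit(obs[1:2, ]),
               class = "surfid_insufficient_data_error")

  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "slope"], -0.6, tolerance = 1e-12)
  expect_equal(glance(fit)$r_squared, 1, tolerance = 1e-12)
})

test_that("relative-SD profiles vanish without change and localise injected change", {
  sc <- small_scene(seed = 61)
  cube <- baseline_cube(sc)
  prof0 <- relative_sd_profile(cube, cube, strip_height = 8, strip_step = 8)
  expect_true(all(prof0$rel_sd_pct == 0))

  scaled <- cube
  scaled$values <- cube$values * 3.7
  prof_scale <- relative_sd_profile(cube, scaled, strip_height = 8,
                                    strip_step = 8)
  expect_lt(max(prof_scale$rel_sd_pct), 1e-10)

  # inject a 5% gain contrast in the lower half only
  sc2 <- scene_config(width = 96, height = 96, gain_amplitude = 0.05,
                      gain_corr_length = 3, sensor_noise_sd = 0, seed = 62)
  cube2 <- baseline_cube(sc2)
  gain <- generate_gain_field(sc2, exp(1) - 1, seed = 63)$values
  gain[1:48, ] <- 1
  pert <- cube2
  pert$values <- sweep(cube2$values, 1:2, gain, `*`)
  prof <- relative_sd_profile(cube2, pert, strip_height = 16,
                              strip_step = 16)
  upper <- prof$rel_sd_pct[prof$top_row + 16 <= 48]
  lower <- prof$rel_sd_pct[prof$top_row >= 48]
  expect_lt(max(upper), 0.5)
  expect_equal(mean(lower), 5, tolerance = 0.2)
})

test_that("the Rice estimator recovers residual noise and suppresses trends", {
  expect_equal(rice_sd(rep(3, 100))$sd, 0)

  y <- withr::with_seed(71, 10 + rnorm(1e4, 0, 0.25))
  est <- rice_sd(y)
  expect_equal(est$sd, 0.25, tolerance = 0.03)
  expect_equal(est$rel_sd, est$sd / mean(y), tolerance = 1e-12)
  expect_equal(est$rel_sd_pct, 100 * est$rel_sd)

  t <- seq(0, 2 * pi, length.out = 1e4)
  y2 <- withr::with_seed(72, 10 + 2 * sin(t) + rnorm(1e4, 0, 0.25))
  expect_equal(rice_sd(y2)$sd, 0.25, tolerance = 0.05)

  expect_error(rice_sd(c(1, 2)), class = "surfid_domain_error")
  expect_error(rice_sd(rnorm(100, -5)), class = "surfid_domain_error")
})

test_that("scene aggregation works on the bits scale with BCa limits", {
  same <- suppressMessages(aggregate_ci(rep(8.1, 5), bootstrap_reps = 500))
  expect_equal(same$ci_low, same$mean_n)
  expect_equal(same$ci_high, same$mean_n)

  bits <- c(7.2, 8.1, 8.9, 9.4)
  agg <- aggregate_ci(bits, bootstrap_reps = 2000, seed = 3)
  expect_equal(agg$mean_n, 2^mean(bits), tolerance = 1e-12)  # geometric-type mean
  expect_lte(agg$ci_low, agg$mean_n)
  expect_gte(agg$ci_high, agg$mean_n)
})

test_that("BCa intervals cover the true mean at about the nominal rate", {
  reps <- 150
  covered <- vapply(seq_len(reps), function(r) {
    bits <- withr::with_seed(9000 + r, rnorm(12, mean = 8, sd = 0.6))
    agg <- aggregate_ci(bits, bootstrap_reps = 999, seed = r)
    agg$ci_low <= 2^8 && 2^8 <= agg$ci_high
  }, logical(1))
  expect_gt(mean(covered), 0.85)
})
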