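wl10 <- seq(400, 720, 10)

test_that("cone excitations are linear lookups of the fundamentals", {
  zero <- cone_excitations(rep(0, 33))
  expect_equal(as.numeric(unlist(zero)), c(0, 0, 0))

  a <- withr::with_seed(1, runif(33))
  b <- withr::with_seed(2, runif(33))
  qa <- as.matrix(cone_excitations(a))
  qb <- as.matrix(cone_excitations(b))
  qab <- as.matrix(cone_excitations(a + b))
  expect_equal(qab, qa + qb, tolerance = 1e-12)

  spike <- rep(0, 33)
  spike[which(wl10 == 550)] <- 1
  q <- as.matrix(cone_excitations(spike))
  fund <- cone_fundamentals()
  expect_equal(as.numeric(q),
               10 * unlist(fund[fund$wavelength == 550, c("L", "M", "S")]),
               ignore_attr = TRUE)
})

test_that("von Kries scaling normalises class means and drops global scale", {
  q <- cone_excitations(matrix(withr::with_seed(3, runif(50 * 33)), 50),
                        wl10)
  s <- von_kries_scale(q)
  expect_equal(colMeans(as.matrix(s)), c(qL = 1, qM = 1, qS = 1),
               tolerance = 1e-12)

  same <- von_kries_scale(tibble::tibble(qL = rep(2, 5), qM = rep(3, 5),
                                         qS = rep(0.5, 5)))
  expect_equal(as.matrix(same), matrix(1, 5, 3), ignore_attr = TRUE)

  s_scaled <- von_kries_scale(dplyr::mutate(q, dplyr::across(
    dplyr::everything(), ~ .x * 7.3)))
  expect_equal(as.matrix(s_scaled), as.matrix(s), tolerance = 1e-12)

  expect_error(von_kries_scale(tibble::tibble(qL = 0, qM = 1, qS = 1)[0, ]),
               class = "surfid_degenerate_error")
})

test_that("delta-e is the plain Euclidean norm of scaled differences", {
  t1 <- tibble::tibble(qL = 1, qM = 1, qS = 1)
  expect_equal(delta_e_cones(t1, t1), 0)
  t2 <- tibble::tibble(qL = 1.3, qM = 1.4, qS = 1)
  expect_equal(delta_e_cones(t1, t2), 0.5)

  m1 <- withr::with_seed(4, matrix(runif(30), 10, 3))
  m2 <- withr::with_seed(5, matrix(runif(30), 10, 3))
  tb <- function(m) tibble::tibble(qL = m[, 1], qM = m[, 2], qS = m[, 3])
  expect_equal(delta_e_cones(tb(m1), tb(m2)),
               sqrt(rowSums((m1 - m2)^2)))
  expect_equal(delta_e_cones(tb(m1), tb(m2)), delta_e_cones(tb(m2), tb(m1)))
})

test_that("tristimulus integration behaves like the 2-degree CMFs", {
  expect_equal(as.numeric(unlist(tristimulus(rep(0, 33)))), c(0, 0, 0))
  ee <- tristimulus(rep(1, 33))
  xyz <- as.numeric(as.matrix(ee))
  expect_lt(max(abs(xyz / xyz[2] - 1)), 0.02)  # X ~ Y ~ Z for equal energy
})

test_that("CIECAM02 reproduces the published worked example", {
  vc <- viewing_conditions(white_point = c(95.05, 100, 108.88),
                           adapting_luminance = 318.31,
                           background_relative_luminance = 20,
                           surround = "average")
  out <- ciecam02_coords(matrix(c(19.01, 20.00, 21.78), 1), vc)
  expect_equal(out$J, 41.73, tolerance = 0.01)
  expect_equal(out$C, 0.1047, tolerance = 0.01)
  expect_equal(out$h, 219.0, tolerance = 0.005)
})

test_that("CIECAM02 maps the white to J = 100 and is relative-colorimetry invariant", {
  white <- c(95.05, 100, 108.88)
  vc <- viewing_conditions(white_point = white)
  at_white <- ciecam02_coords(matrix(white, 1), vc)
  expect_equal(at_white$J, 100, tolerance = 1e-6)
  # under near-complete adaptation the white is nearly achromatic
  vc_hi <- viewing_conditions(white_point = white,
                              adapting_luminance = 318.31)
  at_white_hi <- ciecam02_coords(matrix(white, 1), vc_hi)
  expect_lt(abs(at_white_hi$a_C) + abs(at_white_hi$b_C), 0.5)

  xyz <- withr::with_seed(6, matrix(runif(30, 5, 95), 10, 3))
  base <- ciecam02_coords(xyz, vc)
  scaled <- ciecam02_coords(
    xyz * 3, viewing_conditions(white_point = white * 3))
  expect_equal(as.matrix(scaled), as.matrix(base), tolerance = 1e-9)

  expect_error(ciecam02_coords(matrix(c(-5, 20, 20), 1), vc),
               class = "surfid_domain_error")
})

test_that("CIELAB formulas including the linear segment are exact", {
  white <- c(95.05, 100, 108.88)
  expect_equal(unlist(cielab_coords(matrix(white, 1), white)),
               c(L_star = 100, a_star = 0, b_star = 0), tolerance = 1e-9)
  expect_equal(unlist(cielab_coords(matrix(0, 1, 3), white)),
               c(L_star = 0, a_star = 0, b_star = 0), tolerance = 1e-9)
  grey <- cielab_coords(matrix(0.18 * white, 1), white)
  expect_equal(grey$L_star, 49.5, tolerance = 0.1)
  expect_error(cielab_coords(matrix(white, 1), c(0, 0, 0)),
               class = "surfid_domain_error")
})

test_that("J and L* are co-monotone on a neutral lightness ramp", {
  white <- c(95.05, 100, 108.88)
  ramp <- outer(seq(0.05, 1, length.out = 12), white)
  j <- ciecam02_coords(ramp, viewing_conditions(white_point = white))$J
  l <- cielab_coords(ramp, white)$L_star
  expect_true(all(diff(j) > 0))
  expect_true(all(diff(l) > 0))
})

test_that("S-CIELAB of a uniform field equals per-pixel CIELAB", {
  white <- c(95.05, 100, 108.88)
  xyz_px <- c(30, 34, 20)
  img <- array(rep(xyz_px, each = 24 * 20), dim = c(24, 20, 3))
  out <- scielab_transform(img, pixels_per_degree = 200, white_point = white)
  direct <- unlist(cielab_coords(matrix(xyz_px, 1), white))
  for (k in 1:3) {
    expect_lt(max(abs(out[, , k] - direct[k])), 1e-6)
  }
})

test_that("S-CIELAB impulse response narrows as ppd grows", {
  white <- c(95.05, 100, 108.88)
  base <- c(30, 34, 20)
  img <- array(rep(base, each = 41 * 41), dim = c(41, 41, 3))
  img[21, 21, ] <- img[21, 21, ] * 3
  spread_at <- function(ppd) {
    out <- scielab_transform(img, ppd, white)
    resp <- abs(out[, , 1] - stats::median(out[, , 1]))
    sum(resp > max(resp) / 10)
  }
  expect_gt(spread_at(20), spread_at(100))
})

test_that("daylight spectra sit on the D-series locus and behave physically", {
  for (cct in c(4000, 6500, 10000)) {
    spd <- daylight_spd(cct)
    expect_true(all(spd$power >= 0))
    xyz <- as.numeric(as.matrix(tristimulus(spd$power, spd$wavelengths)))
    x <- xyz[1] / sum(xyz)
    y <- xyz[2] / sum(xyz)
    t <- cct
    xd <- if (t <= 7000) {
      -4.6070e9 / t^3 + 2.9678e6 / t^2 + 0.09911e3 / t + 0.244063
    } else {
      -2.0064e9 / t^3 + 1.9018e6 / t^2 + 0.24748e3 / t + 0.237040
    }
    yd <- -3 * xd^2 + 2.87 * xd - 0.275
    expect_lt(abs(x - xd), 1e-3)
    expect_lt(abs(y - yd), 1e-3)
  }
  warm <- daylight_spd(4000)
  expect_gt(warm$power[warm$wavelengths == 700],
            warm$power[warm$wavelengths == 450])
  expect_error(daylight_spd(3000), class = "surfid_config_error")
})

test_that("re-illumination is exact multiplicative spectral replacement", {
  sc <- small_scene(seed = 8)
  cube <- baseline_cube(sc)
  e65 <- daylight_spd(6500, sc$wavelengths)
  e40 <- daylight_spd(4000, sc$wavelengths)
  expect_equal(reilluminate(cube, e65, e65)$values, cube$values)
  doubled <- reilluminate(cube, e65,
                          illuminant_spectrum(e65$wavelengths, 2 * e65$power))
  expect_equal(doubled$values, 2 * cube$values, tolerance = 1e-12)
  round_trip <- reilluminate(reilluminate(cube, e65, e40), e40, e65)
  expect_equal(round_trip$values, cube$values, tolerance = 1e-10)
})
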