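test_that("noise widths are referred to the discrimination threshold", {
  u <- noise_model(0.5, "uniform")
  expect_equal(u$width_w, 1.0)
  g <- noise_model(0.5, "gaussian")
  expect_equal(g$sd, 1 / sqrt(12), tolerance = 1e-12)
  expect_equal(u$width_w^2 / 12, g$sd^2, tolerance = 1e-12)
  expect_error(noise_model(0), class = "surfid_config_error")
})

test_that("noise draws match the w^2/12 variance for both families", {
  n <- 1e5
  for (family in c("uniform", "gaussian")) {
    w <- draw_noise(n, noise_model(0.5, family), seed = 42)
    expect_equal(dim(w), c(n, 3))
    expect_equal(apply(w, 2, var), rep(1 / 12, 3), tolerance = 0.03)
  }
  u <- draw_noise(n, noise_model(0.5, "uniform"), seed = 1)
  expect_true(all(abs(u) <= 0.5))
  expect_identical(draw_noise(100, noise_model(0.5), seed = 9),
                   draw_noise(100, noise_model(0.5), seed = 9))
})

test_that("KL entropy recovers closed-form values", {
  set.seed(101)
  cube1 <- matrix(runif(3e5), ncol = 3)
  expect_lt(abs(kl_entropy(cube1)), 0.05)
  cube2 <- matrix(runif(3e5, 0, 2), ncol = 3)
  expect_lt(abs(kl_entropy(cube2) - 3), 0.05)
  gauss <- matrix(rnorm(3e5), ncol = 3)
  expect_lt(abs(kl_entropy(gauss) - gauss_entropy_bits(3)), 0.1)
})

test_that("KL entropy bias shrinks with sample size", {
  set.seed(102)
  target <- gauss_entropy_bits(3)
  err_small <- abs(kl_entropy(matrix(rnorm(3e3), ncol = 3)) - target)
  err_large <- abs(kl_entropy(matrix(rnorm(3e5), ncol = 3)) - target)
  expect_lt(err_large, err_small)
})

test_that("KL entropy is translation invariant and rejects degenerate samples", {
  set.seed(103)
  x <- matrix(rnorm(3e3), ncol = 3)
  expect_lt(abs(kl_entropy(x + 1000) - kl_entropy(x)), 1e-9)
  expect_error(kl_entropy(matrix(1, 50, 3)),
               class = "surfid_degenerate_error")
  expect_error(kl_entropy(matrix(rnorm(9), 3, 3), k_neighbour = 5),
               class = "surfid_domain_error")
})

test_that("independent samples carry no mutual information", {
  set.seed(104)
  a <- matrix(rnorm(3e4), ncol = 3)
  b <- matrix(rnorm(3e4), ncol = 3)
  expect_lt(abs(mutual_information(a, b)$bits), 0.05)
})

test_that("correlated-Gaussian mutual information matches the closed form", {
  set.seed(105)
  rho <- 0.9
  n <- 1e5
  a <- matrix(rnorm(n), ncol = 1)
  b <- rho * a + sqrt(1 - rho^2) * matrix(rnorm(n), ncol = 1)
  target <- -0.5 * log2(1 - rho^2)
  expect_lt(abs(mutual_information(a, b)$bits - target), 0.05)
})

test_that("discrete palettes recover log2 M against the label-MI oracle", {
  for (m in c(4, 16, 64)) {
    pal <- palette_sample(m, 2e4, seed = m)
    noise <- withr::with_seed(m + 1, matrix(rnorm(2e4 * 3, 0, 0.5), ncol = 3))
    b <- pal$coords + noise
    est <- mutual_information(pal$coords, b)$bits
    # independent oracle: label confusion matrix of true vs nearest centre
    lb <- apply(b, 1, function(p)
      which.min(colSums((t(pal$centres) - p)^2)))
    oracle <- label_mi(pal$labels, lb)
    expect_lt(abs(est - oracle), 0.1)
    expect_lt(abs(est - log2(m)), 0.1)
  }
})

test_that("the Eq.-2 combination agrees with a histogram oracle in 2-d", {
  set.seed(106)
  n <- 1e5
  rho <- 0.6
  a <- rnorm(n)
  b <- rho * a + sqrt(1 - rho^2) * rnorm(n)
  est <- mutual_information(matrix(a), matrix(b))$bits
  oracle <- hist_mi_1d(a, b, bins = 40)
  expect_lt(abs(est - oracle), 0.1)
})

test_that("estimated information is non-increasing in noise width", {
  set.seed(107)
  a <- matrix(rnorm(4e3 * 3, 0, 10), ncol = 3)
  widths <- c(0.5, 1, 2, 4, 8)
  bits <- vapply(widths, function(w) {
    noise <- noise_model(w / 2, "gaussian")
    mutual_information(a, a, noise = noise, n_noise_reps = 3,
                       seed = 500)$bits
  }, numeric(1))
  expect_true(all(diff(bits) < 0.05))   # estimator jitter allowance
  expect_lt(bits[length(bits)], bits[1])
})

test_that("degenerate and malformed inputs raise typed errors", {
  set.seed(108)
  a <- matrix(rnorm(300), ncol = 3)
  expect_error(mutual_information(a, a),
               class = "surfid_degenerate_error")
  expect_error(mutual_information(a, a[1:50, ]),
               class = "surfid_pairing_error")
})

test_that("negative estimates are clamped to zero with a message", {
  set.seed(109)
  # tiny independent samples make small negative estimates likely
  found <- FALSE
  for (s in 1:20) {
    a <- matrix(rnorm(150), ncol = 3)
    b <- matrix(rnorm(150), ncol = 3)
    res <- suppressMessages(mutual_information(a, b))
    expect_gte(res$bits, 0)
    if (res$clamped) found <- TRUE
  }
  expect_true(found)
})
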