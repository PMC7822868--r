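# Surface counts, time courses, variation profiles, aggregation -----------

new_surface_count <- function(mi, interval_dt, space, noise) {
  structure(list(n_surfaces = 2^mi$bits, mi = mi,
                 interval_dt = interval_dt, colour_space = space,
                 noise = noise),
            class = "surface_count_estimate")
}

#' @export
print.surface_count_estimate <- function(x, ...) {
  what <- if (x$interval_dt == 0) "distinguishable" else
    sprintf("identifiable over %g min", x$interval_dt)
  cat(sprintf("<surface_count> N = %.1f surfaces %s (%.3f bits, %s, %s noise)\n",
              x$n_surfaces, what, x$mi$bits, x$colour_space %||% "?",
              x$noise$family))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.surface_count_estimate <- function(x, ...) {
  tibble(n_surfaces = x$n_surfaces, bits = x$mi$bits,
         interval_dt = x$interval_dt,
         colour_space = x$colour_space %||% NA_character_,
         noise_family = x$noise$family, delta_e_thr = x$noise$delta_e_thr,
         k_neighbour = x$mi$k_neighbour, n_points = x$mi$n_points,
         n_noise_reps = x$mi$n_noise_reps)
}

#' Number of surfaces identifiable by colour across an interval
#'
#' The least upper bound on the average number of surfaces that an
#' observer with internal noise `W` can identify as the same across the
#' interval separating two pixel-paired colour samples:
#' `N = 2^I(A1; A2 + W)`. With `sample_t2 = sample_t1` (zero interval) this
#' reduces exactly to the number of distinguishable surfaces.
#'
#' @param sample_t1,sample_t2 `colour_sample` objects at the two times,
#'   pixel-paired (same positions, same length).
#' @param noise a [noise_model()].
#' @param k_neighbour neighbour order of the entropy estimator.
#' @param n_noise_reps independent noise draws averaged.
#' @param interval_dt interval in minutes (0 for distinguishability).
#' @param seed integer seed for the noise draws.
#' @return A `surface_count_estimate`.
#' @export
n_identifiable <- function(sample_t1, sample_t2, noise, k_neighbour = 3,
                           n_noise_reps = 5, interval_dt = NA_real_,
                           seed = 1L) {
  stopifnot(inherits(noise, "noise_model"))
  a <- colour_coords(sample_t1)
  b <- colour_coords(sample_t2)
  if (nrow(a) != nrow(b)) {
    abort("samples are not pixel-paired (different lengths).",
          class = "surfid_pairing_error")
  }
  if (!is.null(sample_t1[["u"]]) && !is.null(sample_t2[["u"]]) &&
      !(all(sample_t1$u == sample_t2$u) && all(sample_t1$v == sample_t2$v))) {
    abort("samples are not pixel-paired (different positions).",
          class = "surfid_pairing_error")
  }
  mi <- mutual_information(a, b, k_neighbour = k_neighbour,
                           n_noise_reps = n_noise_reps, noise = noise,
                           seed = seed)
  space <- attr(sample_t1, "space")
  new_surface_count(mi, interval_dt, space, noise)
}

#' Number of surfaces distinguishable by colour at one instant
#'
#' `N = 2^I(A; A + W)`: the zero-interval special case of
#' [n_identifiable()], computed through the identical code path so the two
#' agree bit-for-bit under shared seeds.
#'
#' @param sample a `colour_sample`.
#' @inheritParams n_identifiable
#' @return A `surface_count_estimate` with `interval_dt = 0`.
#' @export
n_distinguishable <- function(sample, noise, k_neighbour = 3,
                              n_noise_reps = 5, seed = 1L) {
  if (noise$width_w <= 0) {
    abort("zero-width noise makes the joint density singular.",
          class = "surfid_degenerate_error")
  }
  n_identifiable(sample, sample, noise, k_neighbour = k_neighbour,
                 n_noise_reps = n_noise_reps, interval_dt = 0, seed = seed)
}

# Time-course regression ---------------------------------------------------

#' Log-log regression of surface counts against interval
#'
#' Ordinary least squares of `log2 N` on `log2 dt` (dt in minutes), with
#' predictions at the reference intervals 2 min, 10 min and 1 h.
#' Logarithmic scales stabilise variance and linearise the decline of the
#' number of identifiable surfaces with interval.
#'
#' @param observations a data frame with columns `interval_dt` (minutes)
#'   and `n_surfaces`, or a list of `surface_count_estimate`s.
#' @param reference_intervals intervals (minutes) at which to predict.
#' @return A `timecourse_fit` with `slope`, `intercept` (log2 scale),
#'   `r_squared`, `predictions` (tibble) and the underlying `lm`.
#' @export
time_course_fit <- function(observations,
                            reference_intervals = c(2, 10, 60)) {
  if (is.list(observations) && !is.data.frame(observations) &&
      all(vapply(observations, inherits, logical(1),
                 "surface_count_estimate"))) {
    observations <- dplyr::bind_rows(lapply(observations, tidy))
  }
  obs <- as_tibble(observations)
  if (!all(c("interval_dt", "n_surfaces") %in% names(obs))) {
    abort("`observations` needs columns `interval_dt` and `n_surfaces`.",
          class = "surfid_config_error")
  }
  obs <- dplyr::filter(obs, .data$interval_dt > 0)
  if (length(unique(obs$interval_dt)) < 3) {
    abort("need at least 3 distinct positive intervals.",
          class = "surfid_insufficient_data_error")
  }
  dat <- tibble(log2_dt = log2_(obs$interval_dt),
                log2_n = log2_(obs$n_surfaces))
  fit <- lm(log2_n ~ log2_dt, data = dat)
  preds <- tibble(
    interval_dt = reference_intervals,
    log2_n = as.numeric(predict(fit, tibble(log2_dt = log2_(reference_intervals)))),
    n_surfaces = 2^as.numeric(predict(fit, tibble(log2_dt = log2_(reference_intervals))))
  )
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 predictions = preds, model = fit,
                 data = dat, observations = obs),
            class = "timecourse_fit")
}

#' @export
print.timecourse_fit <- function(x, ...) {
  cat(sprintf("<timecourse_fit> log2 N = %.3f %+.3f log2 dt, R^2 = %.3f\n",
              x$intercept, x$slope, x$r_squared))
  print(x$predictions)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.timecourse_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @exportS3Method generics::glance
glance.timecourse_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, slope = x$slope, intercept = x$intercept,
         n_obs = nrow(x$data))
}

# Strip variation profiles -------------------------------------------------

#' Relative-SD profile of cone-excitation differences
#'
#' For each vertical strip position: radiances of both cubes are converted
#' to cone excitations, each cube's strip sample is von Kries scaled by its
#' own class means, the per-pixel difference magnitude
#' `delta_e = ||q'_2 - q'_1||` is formed, and its SD over the strip is
#' reported in per cent. von Kries scaling makes the SD relative to the
#' sample mean, and removes any global radiance scale.
#'
#' @param cube_t1,cube_t2 registered `radiance_cube`s of the same scene.
#' @param strip_height,strip_width strip size in pixels (width is clamped
#'   to the image width).
#' @param strip_step step between strip top rows, default 10.
#' @return A tibble (class `sd_profile`) with `top_row`, `centre_row`,
#'   `centre_deg` (when the cube carries an angular subtense) and
#'   `rel_sd_pct`.
#' @export
relative_sd_profile <- function(cube_t1, cube_t2, strip_height = 30,
                                strip_width = NULL, strip_step = 10) {
  check_same_grid(cube_t1, cube_t2)
  h <- cube_height(cube_t1)
  w <- cube_width(cube_t1)
  strip_width <- min(strip_width %||% w, w)
  tops <- seq(0, h - strip_height, by = strip_step)
  left <- (w - strip_width) %/% 2
  rows <- purrr::map_dfr(tops, function(top) {
    s1 <- extract_strip(cube_t1, top, strip_height, strip_width, left)
    s2 <- extract_strip(cube_t2, top, strip_height, strip_width, left)
    q1 <- von_kries_scale(cone_excitations(s1$spectrum,
                                           attr(s1, "wavelengths")))
    q2 <- von_kries_scale(cone_excitations(s2$spectrum,
                                           attr(s2, "wavelengths")))
    de <- delta_e_cones(q1, q2)
    tibble(top_row = top, centre_row = top + strip_height / 2,
           rel_sd_pct = 100 * sd(de))
  })
  if (!is.null(cube_t1$angular_subtense) &&
      length(cube_t1$angular_subtense) == 2) {
    rows$centre_deg <- rows$centre_row * cube_t1$angular_subtense[2] / h
  }
  class(rows) <- c("sd_profile", class(rows))
  rows
}

# Rice residual-SD estimator -----------------------------------------------

#' Nonparametric residual SD of a time series (Rice estimator)
#'
#' Estimates the SD of the noise about a slowly varying trend from squared
#' successive differences: `sigma^2 = sum (y[i+1] - y[i])^2 / (2 (n - 1))`.
#' Slow trends contribute negligibly because successive differences
#' suppress them.
#'
#' @param series numeric vector, length `>= 3`.
#' @param relative if `TRUE`, also divide by the series mean (which must be
#'   positive) to give a relative SD.
#' @return A tibble with `sd` and, when requested, `rel_sd` (fraction) and
#'   `rel_sd_pct`.
#' @export
rice_sd <- function(series, relative = TRUE) {
  y <- as.numeric(series)
  if (length(y) < 3) {
    abort("series must have length >= 3.", class = "surfid_domain_error")
  }
  s2 <- sum(diff(y)^2) / (2 * (length(y) - 1))
  out <- tibble(sd = sqrt(s2))
  if (relative) {
    m <- mean(y)
    if (m <= 0) {
      abort("series mean must be positive for the relative form.",
            class = "surfid_domain_error")
    }
    out$rel_sd <- out$sd / m
    out$rel_sd_pct <- 100 * out$rel_sd
  }
  out
}

# Aggregation over scenes ---------------------------------------------------

#' Mean and BCa confidence limits of surface counts over scenes
#'
#' Means and 95% bias-corrected and accelerated (BCa) bootstrap limits are
#' computed on the mutual-information (bits) scale, where the log transform
#' linearises the estimates, and then mapped to the count scale by
#' `2^x` -- so the reported mean is the geometric-type mean of the counts.
#'
#' @param mi_values numeric vector of per-scene mutual informations in
#'   bits, or a list of `mi_estimate` / `surface_count_estimate` objects.
#' @param bootstrap_reps bootstrap replicates (default 2000).
#' @param seed integer seed for the resampling.
#' @param conf confidence level, default 0.95.
#' @return An `aggregate_estimate` with `mean_n`, `ci_low`, `ci_high`,
#'   `mean_bits`, `n_scenes`, `bootstrap_reps`, `seed`.
#' @export
aggregate_ci <- function(mi_values, bootstrap_reps = 2000, seed = 1L,
                         conf = 0.95) {
  bits <- extract_bits(mi_values)
  if (length(bits) < 2) {
    abort("need at least 2 scenes.", class = "surfid_domain_error")
  }
  mean_bits <- mean(bits)
  if (stats::sd(bits) == 0) {
    inform("all scene values equal; interval collapses to a point.")
    ci_bits <- c(mean_bits, mean_bits)
  } else {
    bt <- with_seed_(seed,
                     boot::boot(bits, function(x, idx) mean(x[idx]),
                                R = bootstrap_reps))
    ci <- boot::boot.ci(bt, conf = conf, type = "bca")
    ci_bits <- ci$bca[1, 4:5]
  }
  structure(list(mean_n = 2^mean_bits, ci_low = 2^ci_bits[1],
                 ci_high = 2^ci_bits[2], mean_bits = mean_bits,
                 n_scenes = length(bits),
                 bootstrap_reps = as.integer(bootstrap_reps),
                 seed = seed),
            class = "aggregate_estimate")
}

extract_bits <- function(mi_values) {
  if (is.numeric(mi_values)) return(as.numeric(mi_values))
  vapply(mi_values, function(x) {
    if (inherits(x, "mi_estimate")) x$bits
    else if (inherits(x, "surface_count_estimate")) x$mi$bits
    else abort("cannot extract bits from `mi_values`.",
               class = "surfid_config_error")
  }, numeric(1))
}

#' @export
print.aggregate_estimate <- function(x, ...) {
  cat(sprintf("<aggregate> mean N = %.1f, 95%% BCa [%.1f, %.1f] over %d scenes\n",
              x$mean_n, x$ci_low, x$ci_high, x$n_scenes))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.aggregate_estimate <- function(x, ...) {
  tibble(mean_n = x$mean_n, ci_low = x$ci_low, ci_high = x$ci_high,
         mean_bits = x$mean_bits, n_scenes = x$n_scenes,
         bootstrap_reps = x$bootstrap_reps)
}
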