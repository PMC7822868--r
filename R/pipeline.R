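# End-to-end runs ----------------------------------------------------------

#' Configuration for an end-to-end run
#'
#' @param mode `"synthetic"` (scenes generated on the fly from
#'   `scene_config`) or `"deposited"` (paired cube files on disk).
#' @param scenes synthetic mode: number of scenes, or a list of
#'   [scene_config()]s; deposited mode: a list of scene entries, each a
#'   list with `name` and either `path` (single cube) or `path_t1`,
#'   `path_t2`.
#' @param colour_space `"CIECAM02"` (default) or `"S-CIELAB"`.
#' @param noise_family `"gaussian"` or `"uniform"`.
#' @param delta_e_thr hard discrimination threshold (0.5 or 1.0 in
#'   CIECAM02 space; 1.0 in S-CIELAB space).
#' @param k_neighbour entropy-estimator neighbour order.
#' @param n_pixels pixels sampled per scene.
#' @param n_noise_reps noise draws averaged per estimate.
#' @param bootstrap_reps bootstrap replicates for scene aggregation.
#' @param intervals minutes separating pair members in identifiability runs.
#' @param cct_pair correlated colour temperatures (kelvin) for the
#'   spectral-change control, default `c(6500, 4000)`.
#' @param seed master seed; all stages split their own streams from it.
#' @param ppd pixels per degree for S-CIELAB.
#' @return A `run_config` list (echoed into every output row via its hash).
#' @export
run_config <- function(mode = c("synthetic", "deposited"), scenes = 4,
                       colour_space = c("CIECAM02", "S-CIELAB"),
                       noise_family = c("gaussian", "uniform"),
                       delta_e_thr = 0.5, k_neighbour = 3, n_pixels = 4000,
                       n_noise_reps = 5, bootstrap_reps = 2000,
                       intervals = c(1, 2, 5, 15, 60, 150, 276),
                       cct_pair = c(6500, 4000), seed = 1L, ppd = 200) {
  mode <- match.arg(mode)
  colour_space <- match.arg(colour_space)
  noise_family <- match.arg(noise_family)
  check_number(delta_e_thr, "delta_e_thr", lower = 0, strict_lower = TRUE)
  if (mode == "synthetic" && is.numeric(scenes)) {
    scenes <- lapply(seq_len(scenes), function(i)
      scene_config(seed = split_seed(seed, paste0("scene", i))))
  }
  if (mode == "deposited") {
    for (sc in scenes) {
      paths <- unlist(sc[grep("^path", names(sc))])
      if (!all(file.exists(paths))) {
        abort("a deposited scene path does not exist.",
              class = "surfid_config_error")
      }
    }
  }
  cfg <- list(mode = mode, scenes = scenes, colour_space = colour_space,
              noise_family = noise_family, delta_e_thr = delta_e_thr,
              k_neighbour = k_neighbour, n_pixels = n_pixels,
              n_noise_reps = n_noise_reps, bootstrap_reps = bootstrap_reps,
              intervals = intervals, cct_pair = cct_pair,
              seed = as.integer(seed), ppd = ppd)
  cfg$hash <- rlang::hash(cfg)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a flat JSON or YAML file
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are an error.
#'
#' @param path a `.json` or `.yaml`/`.yml` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    abort(sprintf("unknown config keys: %s.", paste(bad, collapse = ", ")),
          class = "surfid_config_error")
  }
  do.call(run_config, vals)
}

scene_names <- function(config) {
  if (config$mode == "synthetic") {
    sprintf("synthetic-%02d", seq_along(config$scenes))
  } else {
    vapply(config$scenes, function(s) s$name %||% s$path %||% s$path_t1,
           character(1))
  }
}

# the noise model a run config implies
config_noise <- function(config) {
  noise_model(config$delta_e_thr, config$noise_family)
}

# render the baseline radiance cube of synthetic scene i under the run's
# reference daylight
synthetic_baseline <- function(config, i) {
  sc <- config$scenes[[i]]
  refl <- generate_reflectance_cube(sc)
  e0 <- daylight_spd(config$cct_pair[1], sc$wavelengths)
  render_radiance_pair(refl, e0, e0, sensor_noise_sd = sc$sensor_noise_sd,
                       seed = split_seed(sc$seed, "baseline"))[[1]]
}

log_stage <- function(config, stage, scene, detail = "") {
  inform(sprintf("[%s] %s %s %s (hash %s, seed %d)", stage, scene,
                 detail, config$colour_space, config$hash, config$seed))
}

scene_sample <- function(config, cube, stream, e_white = NULL) {
  px <- sample_pixels(cube, min(config$n_pixels,
                                cube_width(cube) * cube_height(cube)),
                      seed = split_seed(config$seed, stream))
  colour_codes(px, space = config$colour_space, white_spectrum = e_white,
               cube = cube, ppd = config$ppd)
}

run_row <- function(config, scene, est) {
  dplyr::bind_cols(tibble(scene = scene), tidy(est),
                   tibble(config_hash = config$hash, seed = config$seed,
                          surfid_version =
                            as.character(utils::packageVersion("surfid"))))
}

#' Distinguishability run
#'
#' For each scene: sample pixels from a single radiance image, convert to
#' the configured colour space, and estimate the number of surfaces
#' distinguishable by colour under the configured observer noise;
#' per-scene results are aggregated over scenes with BCa limits.
#'
#' @param config a [run_config()].
#' @return List with `per_scene` (tibble, one row per scene, carrying the
#'   config hash and seed) and `aggregate` (an `aggregate_estimate`).
#' @export
run_distinguishability <- function(config) {
  stopifnot(inherits(config, "run_config"))
  noise <- config_noise(config)
  names_ <- scene_names(config)
  rows <- list()
  ests <- list()
  for (i in seq_along(config$scenes)) {
    log_stage(config, "distinguish", names_[i])
    res <- tryCatch({
      if (config$mode == "synthetic") {
        cube <- synthetic_baseline(config, i)
        e0 <- daylight_spd(config$cct_pair[1], cube$wavelengths)
      } else {
        cube <- read_radiance_cube(config$scenes[[i]]$path %||%
                                     config$scenes[[i]]$path_t1)
        e0 <- NULL
      }
      smp <- scene_sample(config, cube, paste0("pixels", i), e0)
      n_distinguishable(smp, noise, k_neighbour = config$k_neighbour,
                        n_noise_reps = config$n_noise_reps,
                        seed = split_seed(config$seed, paste0("mi", i)))
    }, error = function(e) {
      abort(sprintf("scene '%s' failed: %s", names_[i], conditionMessage(e)),
            class = "surfid_scene_error", parent = e)
    })
    ests[[i]] <- res
    rows[[i]] <- run_row(config, names_[i], res)
  }
  list(per_scene = dplyr::bind_rows(rows),
       aggregate = aggregate_ci(ests, config$bootstrap_reps,
                                seed = split_seed(config$seed, "boot")))
}

#' Identifiability run with time-course fits
#'
#' For each scene and interval: render (or read) the pixel-paired cubes,
#' estimate the number of surfaces identifiable across the interval, fit
#' `log2 N` against `log2 dt` per scene, and aggregate the predictions at
#' the reference intervals (2, 10 and 60 min) over scenes.
#'
#' @param config a [run_config()]; synthetic mode pairs a baseline image
#'   with a re-rendering whose gain-field SD grows with the interval.
#' @param reference_intervals minutes at which fitted counts are compared
#'   across scenes.
#' @return List with `per_pair` (tibble), `fits` (per-scene
#'   `timecourse_fit`s), and `predictions` (tibble of per-scene and
#'   aggregated counts at the reference intervals).
#' @export
run_identifiability <- function(config, reference_intervals = c(2, 10, 60)) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode != "synthetic") {
    abort("deposited-mode identifiability needs per-interval cube pairs; supply them per scene and call `n_identifiable()` directly.",
          class = "surfid_config_error")
  }
  noise <- config_noise(config)
  names_ <- scene_names(config)
  rows <- list()
  fits <- list()
  for (i in seq_along(config$scenes)) {
    sc <- config$scenes[[i]]
    refl <- generate_reflectance_cube(sc)
    e0 <- daylight_spd(config$cct_pair[1], sc$wavelengths)
    ests <- list()
    sky <- daylight_spd(sc$sky_cct, sc$wavelengths)
    # one gain pattern per component per scene, with amplitude growing with
    # the interval: the scene evolves, it is not redrawn at every dt.
    # Direct and diffuse components are redistributed independently, so the
    # geometric change is spectrally selective (shadowed pixels turn bluer).
    seed_direct <- split_seed(sc$seed, "gain-direct")
    seed_sky <- split_seed(sc$seed, "gain-sky")
    for (j in seq_along(config$intervals)) {
      dt <- config$intervals[j]
      log_stage(config, "identify", names_[i], sprintf("dt=%g", dt))
      g2 <- list(direct = generate_gain_field(sc, dt, seed = seed_direct),
                 sky = generate_gain_field(sc, dt, seed = seed_sky))
      pair <- render_radiance_pair(refl, e0, e0, gain2 = g2,
                                   sensor_noise_sd = sc$sensor_noise_sd,
                                   seed = split_seed(sc$seed, paste0("pair", dt)),
                                   timestamps = c(0, dt),
                                   direct_fraction = sc$direct_fraction,
                                   sky_illuminant = sky)
      px1 <- sample_pixels(pair[[1]], min(config$n_pixels,
                                          sc$width * sc$height),
                           seed = split_seed(config$seed, paste0("pixels", i)))
      px2 <- pixels_at(pair[[2]], px1)
      s1 <- colour_codes(px1, space = config$colour_space,
                         white_spectrum = e0, cube = pair[[1]],
                         ppd = config$ppd)
      s2 <- colour_codes(px2, space = config$colour_space,
                         white_spectrum = e0, cube = pair[[2]],
                         ppd = config$ppd)
      est <- n_identifiable(s1, s2, noise, k_neighbour = config$k_neighbour,
                            n_noise_reps = config$n_noise_reps,
                            interval_dt = dt,
                            seed = split_seed(config$seed,
                                              paste0("mi", i, "-", dt)))
      ests[[j]] <- est
      rows[[length(rows) + 1]] <- run_row(config, names_[i], est)
    }
    fits[[names_[i]]] <- time_course_fit(ests, reference_intervals)
  }
  pred_rows <- purrr::imap_dfr(fits, function(f, nm)
    dplyr::mutate(f$predictions, scene = nm, .before = 1))
  agg <- purrr::map_dfr(reference_intervals, function(dt) {
    bits <- pred_rows$log2_n[pred_rows$interval_dt == dt]
    est <- aggregate_ci(bits, config$bootstrap_reps,
                        seed = split_seed(config$seed, paste0("boot", dt)))
    dplyr::mutate(tidy(est), interval_dt = dt, .before = 1)
  })
  list(per_pair = dplyr::bind_rows(rows), fits = fits,
       predictions = list(per_scene = pred_rows, aggregate = agg))
}

#' Spectral-change control run
#'
#' Estimates the number of surfaces identifiable under a purely spectral
#' illumination change: a global daylight shift between the configured
#' correlated colour temperatures (default 6500 K, typical daylight, to
#' 4000 K, the setting sun), with the scene's effective reflectance held
#' fixed.
#'
#' @param config a [run_config()] (synthetic mode; deposited mode requires
#'   a known reference illuminant per scene via `scenes[[i]]$cct0`).
#' @return List with `per_scene` and `aggregate`, as in
#'   [run_distinguishability()].
#' @export
run_spectral_control <- function(config) {
  stopifnot(inherits(config, "run_config"))
  noise <- config_noise(config)
  names_ <- scene_names(config)
  rows <- list()
  ests <- list()
  for (i in seq_along(config$scenes)) {
    log_stage(config, "spectral-control", names_[i])
    if (config$mode == "synthetic") {
      sc <- config$scenes[[i]]
      refl <- generate_reflectance_cube(sc)
      e1 <- daylight_spd(config$cct_pair[1], sc$wavelengths)
      e2 <- daylight_spd(config$cct_pair[2], sc$wavelengths)
      pair <- render_radiance_pair(refl, e1, e2,
                                   sensor_noise_sd = sc$sensor_noise_sd,
                                   seed = split_seed(sc$seed, "spectral"))
    } else {
      sc <- config$scenes[[i]]
      if (is.null(sc$cct0)) {
        abort("deposited mode needs the reference illuminant CCT (`cct0`) per scene.",
              class = "surfid_config_error")
      }
      cube <- read_radiance_cube(sc$path %||% sc$path_t1)
      e0 <- daylight_spd(sc$cct0, cube$wavelengths)
      e1 <- daylight_spd(config$cct_pair[1], cube$wavelengths)
      e2 <- daylight_spd(config$cct_pair[2], cube$wavelengths)
      pair <- list(reilluminate(cube, e0, e1), reilluminate(cube, e0, e2))
    }
    px1 <- sample_pixels(pair[[1]],
                         min(config$n_pixels,
                             cube_width(pair[[1]]) * cube_height(pair[[1]])),
                         seed = split_seed(config$seed, paste0("pixels", i)))
    px2 <- pixels_at(pair[[2]], px1)
    s1 <- colour_codes(px1, space = config$colour_space, white_spectrum = e1,
                       cube = pair[[1]], ppd = config$ppd)
    s2 <- colour_codes(px2, space = config$colour_space, white_spectrum = e2,
                       cube = pair[[2]], ppd = config$ppd)
    est <- n_identifiable(s1, s2, noise, k_neighbour = config$k_neighbour,
                          n_noise_reps = config$n_noise_reps,
                          interval_dt = NA_real_,
                          seed = split_seed(config$seed, paste0("mi", i)))
    ests[[i]] <- est
    rows[[i]] <- run_row(config, names_[i], est)
  }
  list(per_scene = dplyr::bind_rows(rows),
       aggregate = aggregate_ci(ests, config$bootstrap_reps,
                                seed = split_seed(config$seed, "boot")))
}
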