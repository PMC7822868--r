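# ggplot2 displays for result types ---------------------------------------

#' Plot a strip variation profile
#'
#' Relative SD of cone-excitation differences (per cent, horizontal axis)
#' against vertical strip position (pixels, top of image uppermost), the
#' conventional orientation for these profiles.
#'
#' @param object an `sd_profile` from [relative_sd_profile()].
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sd_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$rel_sd_pct, y = .data$centre_row)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "relative SD of Δe (%)",
                  y = "vertical position (pixels)") +
    ggplot2::theme_minimal()
}

#' Plot a surface-count time course
#'
#' Estimated number of identifiable surfaces against interval on log-log
#' axes, with the fitted regression dashed and the 2-min and 1-h reference
#' intervals marked.
#'
#' @param object a `timecourse_fit` from [time_course_fit()].
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.timecourse_fit <- function(object, ...) {
  obs <- object$observations
  line <- tibble(
    interval_dt = exp(seq(log(min(obs$interval_dt)),
                          log(max(obs$interval_dt)), length.out = 50))
  )
  line$n_surfaces <- 2^(object$intercept +
                          object$slope * log2_(line$interval_dt))
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$interval_dt,
                                    y = .data$n_surfaces)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = line, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(2, 60), colour = "grey70") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "interval Δt (min)",
                  y = "number of identifiable surfaces N") +
    ggplot2::theme_minimal()
}
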