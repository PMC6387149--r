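#' Plot an eye-movement trial
#'
#' Position (degrees of horizontal rotation) against time.
#'
#' @param object An `eye_trace` tibble from [generate_trial()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eye_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_ms, .data$position_deg)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time [ms]", y = "position [deg]")
}

#' Plot a mutual-information profile
#'
#' The selected delay (first local minimum) is marked.
#'
#' @param object An `mi_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mi_profile <- function(object, ...) {
  sel <- select_delay(object)
  ggplot2::ggplot(object, ggplot2::aes(.data$lag, .data$mi)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = sel$tau, linetype = 2, colour = "red") +
    ggplot2::labs(x = expression(tau ~ "[samples]"),
                  y = "mutual information [bits]")
}

#' Plot a false-nearest-neighbour profile
#' @param object An `fnn_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fnn_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$m, .data$fnn_fraction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "embedding dimension m", y = "FNN fraction")
}

#' Plot a divergence curve
#' @param object A `divergence_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.divergence_curve <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$time, .data$mean_log_div)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time", y = expression("<ln d(i)/d(0)>"))
}

#' Log-log DFA plot
#'
#' Fluctuation versus box size on log axes with the fitted power law.
#'
#' @param object A `dfa_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dfa_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$scale, .data$fluctuation)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "interval length n",
      y = "F(n)",
      title = sprintf("alpha = %.3f (r^2 = %.3f)", object$alpha,
                      object$r_squared)
    )
}
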