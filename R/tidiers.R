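#' Tidy a DFA result
#'
#' One row per box size, with the fitted power law for plotting.
#'
#' @param x A `dfa_result`.
#' @param ... Unused.
#' @return A tibble with columns `scale`, `fluctuation`, `log_scale`,
#'   `log_fluctuation`, `fitted`.
#' @export
tidy.dfa_result <- function(x, ...) {
  fit <- lm(log(fluctuation) ~ log(scale), data = x$table)
  x$table %>%
    mutate(
      log_scale = log(.data$scale),
      log_fluctuation = log(.data$fluctuation),
      fitted = exp(stats::fitted(fit))
    )
}

#' @rdname tidy.dfa_result
#' @return `glance()` returns a one-row tibble with `alpha`, `hurst`,
#'   `r_squared`, `n_scales`, `detrend`, `max_scale`.
#' @export
glance.dfa_result <- function(x, ...) {
  tibble(
    alpha = x$alpha,
    hurst = x$hurst,
    r_squared = x$r_squared,
    n_scales = x$n_scales,
    detrend = x$params$detrend %||% NA_character_,
    max_scale = x$params$max_scale %||% NA_integer_
  )
}

#' Tidy a divergence curve
#' @param x A `divergence_curve`.
#' @param ... Unused.
#' @return The curve as a plain tibble.
#' @export
tidy.divergence_curve <- function(x, ...) {
  as_tibble(unclass(x)[c("step", "time", "mean_log_div", "n_pairs")])
}

#' Glance at a Lyapunov-exponent fit
#' @param x An `lle_result`.
#' @param ... Unused.
#' @return One-row tibble with `lambda`, `r_squared`, `n_pairs`, `feasible`,
#'   `reason`.
#' @export
glance.lle_result <- function(x, ...) {
  tibble(
    lambda = x$lambda,
    r_squared = x$r_squared,
    n_pairs = x$n_pairs,
    feasible = x$feasible,
    reason = x$reason
  )
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("DFA (%s, scales %s): alpha = %.4f, H = %.4f, r^2 = %.4f\n",
              x$params$detrend %||% "?",
              paste(range(x$table$scale), collapse = "-"),
              x$alpha, x$hurst, x$r_squared))
  invisible(x)
}

#' @export
print.lle_result <- function(x, ...) {
  if (!x$feasible) {
    cat(sprintf("LLE: infeasible (%s)\n", x$reason))
  } else {
    cat(sprintf("LLE: lambda = %.5f per time unit (dt = %g), r^2 = %.3f, %d pairs\n",
                x$lambda, x$dt, x$r_squared, x$n_pairs))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
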