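#' Mean log-divergence curve of nearest-neighbour pairs
#'
#' The nearest-neighbour divergence construction behind the largest-Lyapunov
#' -exponent estimate: every reconstructed state is paired with its nearest
#' neighbour outside the Theiler window and with positive initial separation,
#' and both points are followed forward in time. The curve value at step `i`
#' is the mean over pairs of `log(d_j(i) / d_j(0))`; for chaotic dynamics it
#' grows linearly (slope = LLE) before saturating at the attractor size.
#'
#' Pairs whose initial separation is exactly zero cannot be used; when more
#' than half of the candidate pairs are like that (typical of heavily
#' median-filtered, constant-rich traces) the curve is marked infeasible.
#'
#' @param embedding A `delay_embedding` matrix from [delay_embed()].
#' @param theiler Theiler window in samples; defaults to `tau * m` of the
#'   embedding.
#' @param max_steps Steps each pair is followed (capped at `M - 2`).
#' @param dt Time per step in the output units (default 1; use 1 ms at
#'   1000 Hz so exponents are per millisecond).
#' @param zero_frac_limit Infeasibility threshold on the fraction of
#'   zero-initial-distance pairs (default 0.5).
#' @return A tibble of class `divergence_curve` with columns `step`, `time`,
#'   `mean_log_div`, `n_pairs`, plus attributes `dt`, `n_pairs`, `zero_frac`,
#'   `feasible`, `reason`.
#' @export
divergence_curve <- function(embedding, theiler = NULL, max_steps = 20,
                             dt = 1, zero_frac_limit = 0.5) {
  stopifnot(inherits(embedding, "delay_embedding"))
  M <- nrow(embedding)
  tau <- attr(embedding, "tau")
  m <- attr(embedding, "m")
  if (is.null(theiler)) theiler <- tau * m
  theiler <- as.integer(theiler)

  infeasible <- function(reason) {
    out <- tibble(step = integer(), time = numeric(),
                  mean_log_div = numeric(), n_pairs = integer())
    attr(out, "dt") <- dt
    attr(out, "n_pairs") <- 0L
    attr(out, "zero_frac") <- NA_real_
    attr(out, "feasible") <- FALSE
    attr(out, "reason") <- reason
    class(out) <- c("divergence_curve", class(out))
    out
  }
  if (M < max(theiler + 2L, 4L)) return(infeasible("too_short"))
  max_steps <- min(as.integer(max_steps), M - 2L)

  res <- divergence_cpp(unclass(embedding), theiler, max_steps)
  if (res$n_admissible == 0) return(infeasible("no_neighbors"))
  zero_frac <- res$n_zero / res$n_admissible
  if (zero_frac > zero_frac_limit) return(infeasible("zero_distance_pairs"))
  n_pairs <- res$n_admissible - res$n_zero
  if (n_pairs == 0) return(infeasible("no_neighbors"))

  keep <- res$count > 0
  out <- tibble(
    step = (0:max_steps)[keep],
    time = (0:max_steps)[keep] * dt,
    mean_log_div = (res$sum_log / pmax(res$count, 1L))[keep],
    n_pairs = res$count[keep]
  )
  attr(out, "dt") <- dt
  attr(out, "n_pairs") <- n_pairs
  attr(out, "zero_frac") <- zero_frac
  attr(out, "feasible") <- TRUE
  attr(out, "reason") <- "none"
  class(out) <- c("divergence_curve", class(out))
  out
}

#' Largest Lyapunov exponent from a divergence curve
#'
#' Least-squares slope of the mean log-divergence against time over the fit
#' range. With `dt` in milliseconds the exponent is reported per millisecond,
#' the natural scale for 1000 Hz eye-movement recordings; for map data use
#' `dt = 1` to obtain nats per iteration.
#'
#' @param curve A `divergence_curve`.
#' @param fit_range Integer vector of steps used in the fit; default
#'   `1:min(20, floor(max step / 4))` clipped to the available steps (step 0
#'   is excluded because stochastic noise jumps to saturation there).
#' @return A list of class `lle_result` with fields `lambda`, `r_squared`,
#'   `fit_range`, `dt`, `n_pairs`, `feasible`, `reason`.
#' @export
estimate_lle <- function(curve, fit_range = NULL) {
  stopifnot(inherits(curve, "divergence_curve"))
  dt <- attr(curve, "dt")
  if (!attr(curve, "feasible")) {
    out <- list(lambda = NA_real_, r_squared = NA_real_, fit_range = NULL,
                dt = dt, n_pairs = 0L, feasible = FALSE,
                reason = attr(curve, "reason"))
    class(out) <- "lle_result"
    return(out)
  }
  max_step <- max(curve$step)
  if (is.null(fit_range)) {
    upper <- max(1L, min(20L, as.integer(floor(max_step / 4))))
    fit_range <- seq_len(upper)
  }
  pts <- dplyr::filter(curve, .data$step %in% fit_range)
  if (nrow(pts) < 2) {
    out <- list(lambda = NA_real_, r_squared = NA_real_, fit_range = fit_range,
                dt = dt, n_pairs = attr(curve, "n_pairs"), feasible = FALSE,
                reason = "too_short")
    class(out) <- "lle_result"
    return(out)
  }
  fit <- lm(mean_log_div ~ time, data = pts)
  out <- list(
    lambda = unname(coef(fit)[2]),
    # suppressed: summary.lm warns on numerically perfect fits, which are
    # legitimate here (exact contraction maps, noise-free lines)
    r_squared = suppressWarnings(summary(fit)$r.squared),
    fit_range = range(pts$step),
    dt = dt,
    n_pairs = attr(curve, "n_pairs"),
    feasible = TRUE,
    reason = "none"
  )
  class(out) <- "lle_result"
  out
}

#' Classify dynamics by the sign of the largest Lyapunov exponent
#'
#' Positive exponents indicate exponential divergence of nearby states
#' (chaos), negative exponents convergence towards a stable point or orbit,
#' and exponents within `tol` of zero neutral dynamics.
#'
#' @param result An `lle_result`.
#' @param tol Half-width of the neutral band, in the exponent's units.
#' @return One of `"chaotic"`, `"convergent"`, `"neutral"`, `"infeasible"`.
#' @export
#' @examples
#' curve <- divergence_curve(delay_embed(generate_canonical("logistic", 1500,
#'   x0 = 0.2), 1, 2), theiler = 5)
#' classify_dynamics(estimate_lle(curve, 1:4))
classify_dynamics <- function(result, tol = 1e-4) {
  stopifnot(inherits(result, "lle_result"))
  if (!result$feasible || is.na(result$lambda)) return("infeasible")
  if (result$lambda > tol) return("chaotic")
  if (result$lambda < -tol) return("convergent")
  "neutral"
}
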