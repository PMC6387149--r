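#' Mean-centred cumulative sum (profile) of a series
#'
#' The integration step preceding detrended fluctuation analysis:
#' `y(k) = sum_{i<=k} (x_i - mean(x))`. The final value is zero by
#' construction.
#'
#' @param x Numeric series.
#' @return Integrated series of the same length.
#' @export
dfa_integrate <- function(x) {
  if (length(x) == 0) abort("empty series")
  cumsum(x - mean(x))
}

#' Dyadic DFA box-size grid
#'
#' Box sizes `min_scale * 2^k` not exceeding `max_scale`. With the default
#' minimum of 30 this yields 5 scales up to 500 and 6 up to 1000.
#'
#' @param min_scale Smallest box size (samples, >= 4).
#' @param max_scale Largest allowed box size.
#' @return Integer vector of box sizes.
#' @export
#' @examples
#' dfa_scales(30, 500)   # 30 60 120 240 480
#' dfa_scales(30, 1000)  # ... 960
dfa_scales <- function(min_scale = 30, max_scale = 500) {
  if (min_scale < 4) abort("`min_scale` must be >= 4")
  if (max_scale < min_scale) abort("`max_scale` must be >= `min_scale`")
  k <- 0:floor(log2(max_scale / min_scale))
  as.integer(min_scale * 2^k)
}

#' Detrended fluctuation at one box size
#'
#' Partitions the integrated series into `floor(N/n)` non-overlapping boxes
#' from the start (any trailing remainder is dropped), removes the per-box
#' trend -- the least-squares line (`poly1`) or the chord joining the box's
#' first and last points (`bridge`) -- and returns the root-mean-square
#' residual over all covered points.
#'
#' @param y Integrated series (see [dfa_integrate()]).
#' @param n Box size, `4 <= n <= length(y)`.
#' @param detrend `"poly1"` or `"bridge"`.
#' @return The fluctuation `F(n)` (nonnegative scalar).
#' @export
dfa_fluctuation <- function(y, n, detrend = c("poly1", "bridge")) {
  detrend <- match.arg(detrend)
  n <- as.integer(n)
  N <- length(y)
  if (n > N) abort("box size exceeds the series length")
  if (n < 2) abort("box size must be >= 2")
  nbox <- N %/% n
  Y <- matrix(y[seq_len(nbox * n)], nrow = n, ncol = nbox)
  t <- seq_len(n)
  if (detrend == "poly1") {
    tc <- t - mean(t)
    sxx <- sum(tc^2)
    slopes <- as.numeric(crossprod(tc, Y)) / sxx
    means <- colMeans(Y)
    res <- Y - outer(tc, slopes) - rep(means, each = n)
  } else {
    first <- Y[1, ]
    last <- Y[n, ]
    u <- (t - 1) / (n - 1)
    res <- Y - outer(1 - u, first) - outer(u, last)
  }
  sqrt(mean(res^2))
}

#' DFA parameter grid of the standard analysis
#'
#' The four detrending/scale-range combinations applied to every trial:
#' first-degree polynomial or bridge detrending crossed with maximum box
#' sizes 500 and 1000 (minimum 30 in both cases).
#'
#' @return A tibble with columns `label`, `detrend`, `min_scale`, `max_scale`.
#' @export
dfa_param_grid <- function() {
  tibble(
    label = c("poly:500", "poly:1000", "bridge:500", "bridge:1000"),
    detrend = c("poly1", "poly1", "bridge", "bridge"),
    min_scale = 30L,
    max_scale = c(500L, 1000L, 500L, 1000L)
  )
}

#' Scaling exponent from a fluctuation table
#'
#' Unweighted least-squares slope of `log F(n)` versus `log n`. Scales with
#' zero fluctuation are dropped (flagged); at least three positive scales are
#' required. The Hurst exponent is derived as `H = alpha` for
#' `alpha` in `[0, 1]` and `H = alpha - 1` for `alpha` in `(1, 2]`.
#'
#' @param table Data frame with columns `scale` and `fluctuation`.
#' @param params Optional parameter list/row recorded in the result.
#' @return A list of class `dfa_result` with fields `alpha`, `hurst`,
#'   `r_squared`, `n_scales`, `dropped_scales`, `table`, `params`.
#' @export
estimate_alpha <- function(table, params = NULL) {
  stopifnot(all(c("scale", "fluctuation") %in% names(table)))
  dropped <- table$scale[table$fluctuation <= 0]
  ok <- table$fluctuation > 0
  if (sum(ok) < 3) abort("fewer than 3 scales with positive fluctuation")
  if (length(dropped) > 0) {
    warn(sprintf("dropped %d zero-fluctuation scale(s)", length(dropped)))
  }
  fit <- lm(log(fluctuation) ~ log(scale), data = table[ok, ])
  # suppressed: summary.lm warns on numerically perfect fits, which are
  # legitimate for exact power-law tables
  r2 <- suppressWarnings(summary(fit)$r.squared)
  alpha <- unname(coef(fit)[2])
  hurst <- if (alpha >= 0 && alpha <= 1) {
    alpha
  } else if (alpha > 1 && alpha <= 2) {
    alpha - 1
  } else {
    NA_real_
  }
  out <- list(
    alpha = alpha,
    hurst = hurst,
    r_squared = r2,
    n_scales = sum(ok),
    dropped_scales = as.integer(dropped),
    table = tibble(scale = table$scale[ok], fluctuation = table$fluctuation[ok]),
    params = params
  )
  class(out) <- "dfa_result"
  out
}

#' Detrended fluctuation analysis of a series
#'
#' Integrates the series (mean-centred cumulative sum), computes the RMS
#' detrended fluctuation over a dyadic grid of box sizes, and fits the
#' scaling exponent `alpha` on the log-log plot. `alpha = 0.5` corresponds to
#' uncorrelated noise, values above 0.5 to persistent long-range correlation,
#' below 0.5 to anti-persistence, and `alpha = 1.5` to a Brownian random
#' walk.
#'
#' @param x Numeric series (in the standard pipeline, a full-trial velocity
#'   series).
#' @param detrend `"poly1"` (least-squares line per box) or `"bridge"`
#'   (first-to-last chord per box).
#' @param min_scale,max_scale Dyadic box-size grid limits (see
#'   [dfa_scales()]).
#' @param integrate Set `FALSE` if `x` is already an integrated profile.
#' @return A `dfa_result`; see [estimate_alpha()].
#' @export
#' @examples
#' set.seed(1)
#' res <- dfa(rnorm(3000))
#' res$alpha  # close to 0.5
dfa <- function(x, detrend = c("poly1", "bridge"), min_scale = 30,
                max_scale = 500, integrate = TRUE) {
  detrend <- match.arg(detrend)
  y <- if (integrate) dfa_integrate(x) else x
  scales <- dfa_scales(min_scale, max_scale)
  scales <- scales[scales <= length(y)]
  if (length(scales) < 3) abort("series too short for 3 DFA scales")
  fl <- vapply(scales, function(s) dfa_fluctuation(y, s, detrend), numeric(1))
  estimate_alpha(
    tibble(scale = scales, fluctuation = fl),
    params = list(detrend = detrend, min_scale = min_scale,
                  max_scale = max_scale)
  )
}
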