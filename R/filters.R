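#' Position filter bank labels
#'
#' The eight preprocessing variants applied to raw position traces before
#' dynamical analysis: `N` (none), running medians `M5`, `M9`, `M15`,
#' third-degree Savitzky-Golay `SG7`, `SG15`, and undecimated Daubechies
#' wavelet denoising `W8`, `W20` (filter lengths 8 and 20, 3 decomposition
#' levels, hard thresholding).
#'
#' @return Character vector of filter labels.
#' @export
filter_labels <- function() {
  c("N", "M5", "M9", "M15", "SG7", "SG15", "W8", "W20")
}

#' Apply a filter by its label
#'
#' @param x Numeric position series.
#' @param label One of [filter_labels()].
#' @return Filtered series, same length as `x`.
#' @export
#' @examples
#' apply_filter(sin(1:100 / 5) + rnorm(100, sd = 0.1), "SG7")
apply_filter <- function(x, label) {
  switch(label,
    N = x,
    M5 = running_median(x, 5),
    M9 = running_median(x, 9),
    M15 = running_median(x, 15),
    SG7 = savitzky_golay(x, 7, 3),
    SG15 = savitzky_golay(x, 15, 3),
    W8 = wavelet_denoise(x, 8, 3),
    W20 = wavelet_denoise(x, 20, 3),
    abort(sprintf("unknown filter label '%s'", label))
  )
}

#' Running median filter
#'
#' Replaces each sample by the median of the surrounding window. Endpoints
#' use Tukey-style shrinking windows: at distance `d` from either end the
#' window shrinks to `2d + 1` samples, so the first and last values are kept.
#'
#' @param x Numeric series.
#' @param window Odd window length >= 3, at most `length(x)`.
#' @return Filtered series, same length as `x`. Interior values are always a
#'   member of the input window (medians of odd windows).
#' @export
running_median <- function(x, window) {
  window <- as.integer(window)
  n <- length(x)
  if (window %% 2L == 0L || window < 3L) abort("`window` must be odd and >= 3")
  if (window > n) abort("`window` exceeds the series length")
  out <- as.numeric(stats::runmed(x, window, endrule = "keep"))
  h <- (window - 1L) %/% 2L
  for (d in seq_len(min(h, n))) {       # shrink symmetric window near edges
    w <- d - 1L
    out[d] <- median(x[(d - w):(d + w)])
    out[n - d + 1L] <- median(x[(n - d + 1L - w):(n - d + 1L + w)])
  }
  out
}

#' Savitzky-Golay smoothing filter
#'
#' Least-squares fit of a degree-`degree` polynomial over each moving window;
#' the smoothed value is the fitted polynomial at the window centre. Edges
#' are handled by evaluating off-centre fits of the first/last full window.
#'
#' @param x Numeric series.
#' @param window Odd window length, `degree < window <= length(x)`.
#' @param degree Polynomial degree (default 3).
#' @return Filtered series, same length as `x`.
#' @export
savitzky_golay <- function(x, window, degree = 3) {
  window <- as.integer(window)
  degree <- as.integer(degree)
  if (window %% 2L == 0L) abort("`window` must be odd")
  if (degree >= window) abort("`degree` must be smaller than `window`")
  if (window > length(x)) abort("`window` exceeds the series length")
  as.numeric(signal::sgolayfilt(x, p = degree, n = window))
}

# Daubechies scaling filters (orthonormal, sum = sqrt(2)); published constants
daubechies_filter <- function(filter_length) {
  switch(as.character(filter_length),
    "8" = c(
      0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
      -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
      0.0328830116668852, -0.010597401785069032
    ),
    "20" = c(
      0.026670057900555554, 0.1881768000776915, 0.5272011889317256,
      0.6884590394536035, 0.2811723436605775, -0.24984642432731538,
      -0.19594627437737705, 0.12736934033579325, 0.09305736460357235,
      -0.07139414716639708, -0.029457536821875813, 0.033212674059341,
      0.0036065535669561697, -0.010733175483330575, 0.001395351747052901,
      0.001992405295185056, -0.0006858566949597116, -0.00011646685512928545,
      9.358867032006959e-05, -1.3264202894521244e-05
    ),
    abort("`filter_length` must be 8 or 20")
  )
}

# frequency response of a filter upsampled by `stride`, periodic length n
filter_dft <- function(filt, stride, n) {
  f <- numeric(n)
  idx <- ((seq_along(filt) - 1L) * stride) %% n + 1L
  for (k in seq_along(filt)) f[idx[k]] <- f[idx[k]] + filt[k]
  fft(f)
}

#' Undecimated Daubechies wavelet denoising
#'
#' Translation-invariant (undecimated) Daubechies wavelet transform with
#' periodic boundary handling, computed in the Fourier domain. Detail
#' coefficients at levels 1..`levels` are hard-thresholded and the signal is
#' reconstructed; with `threshold = 0` the transform pair reconstructs the
#' input to machine precision. The default threshold is the universal
#' threshold `sigma * sqrt(2 log n)` with `sigma` estimated as
#' `mad(finest detail) / 0.6745`, applied at every level.
#'
#' @param x Numeric series, length >= `2^levels`.
#' @param filter_length Daubechies filter length, 8 or 20 (4 and 10 vanishing
#'   moments).
#' @param levels Decomposition depth (default 3).
#' @param threshold `NULL` for the universal threshold, or a fixed
#'   nonnegative value.
#' @return Denoised series, same length as `x`.
#' @export
wavelet_denoise <- function(x, filter_length = 8, levels = 3, threshold = NULL) {
  n <- length(x)
  levels <- as.integer(levels)
  if (levels < 1L) abort("`levels` must be >= 1")
  if (n < 2^levels) abort("series shorter than 2^levels")
  h <- daubechies_filter(filter_length)
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1) * rev(h)   # quadrature-mirror wavelet filter

  A <- fft(x)
  Hs <- vector("list", levels)
  Gs <- vector("list", levels)
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    stride <- 2^(j - 1)
    Hs[[j]] <- filter_dft(h, stride, n)
    Gs[[j]] <- filter_dft(g, stride, n)
    details[[j]] <- Re(fft(Gs[[j]] * A, inverse = TRUE)) / n
    A <- Hs[[j]] * A
  }

  if (is.null(threshold)) {
    sigma <- median(abs(details[[1]])) / 0.6745
    threshold <- sigma * sqrt(2 * log(n))
  }
  if (threshold < 0) abort("`threshold` must be nonnegative")
  details <- map(details, function(d) {
    d[abs(d) < threshold] <- 0
    d
  })

  # adjoint reconstruction: |H|^2 + |G|^2 = 2 for orthonormal QMF pairs
  for (j in rev(seq_len(levels))) {
    D <- fft(details[[j]])
    A <- (Conj(Hs[[j]]) * A + Conj(Gs[[j]]) * D) / 2
  }
  Re(fft(A, inverse = TRUE)) / n
}
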