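#' Histogram binning by Scott's rule
#'
#' Bin width `h = 3.5 * sigma * n^(-1/3)` with `sigma` the sample standard
#' deviation, and bin count `ceiling(range / h)` (at least 2). Used to
#' discretise series for the mutual-information estimate.
#'
#' @param x Numeric series, length >= 2, nonzero variance.
#' @return A list of class `bin_spec` with fields `width`, `count`, `sigma`,
#'   `n`, `origin` (left edge of the first bin).
#' @export
#' @examples
#' scott_bins(rnorm(1000))
scott_bins <- function(x) {
  n <- length(x)
  if (n < 2) abort("need at least 2 samples")
  sigma <- sd(x)
  if (!is.finite(sigma) || sigma == 0) {
    abort("degenerate series: zero variance", class = "oculodyn_degenerate")
  }
  h <- 3.5 * sigma * n^(-1 / 3)
  count <- max(2L, as.integer(ceiling(diff(range(x)) / h)))
  structure(list(width = h, count = count, sigma = sigma, n = n,
                 origin = min(x)),
            class = "bin_spec")
}

bin_index <- function(x, bins) {
  pmin(pmax(floor((x - bins$origin) / bins$width) + 1L, 1L), bins$count)
}

#' Time-delayed mutual information profile
#'
#' For each lag `tau`, bins the pairs `(x[i], x[i + tau])` on a joint
#' histogram whose bin width follows Scott's rule over the whole series, and
#' computes the mutual information in bits; empty cells contribute zero.
#' The lag of the first (prominent) local minimum of this profile is the
#' standard choice of embedding delay.
#'
#' With `shifts > 1` the estimate at each lag is averaged over a grid of
#' `shifts^2` bin-origin offsets (an average-shifted-histogram estimator):
#' this keeps the Scott bin width but removes the bin-edge artefacts that
#' make single-histogram profiles of smooth signals spuriously jagged.
#' `shifts = 1` recovers the plain single-histogram estimator, for which
#' `I(0)` equals the binned marginal entropy exactly.
#'
#' Saccadic velocity traces have extremely heavy-tailed amplitude
#' distributions: a bin width from the raw standard deviation collapses the
#' fixational dynamics into one or two bins. The estimator therefore uses the
#' robust normal-reference scale `min(sd, IQR/1.349)` in Scott's formula and
#' restricts the equal-width grid to `median +/- clip_sigmas` robust sigmas,
#' with two overflow bins collecting the (rare, saccadic) samples beyond. For
#' light-tailed signals the clip is inactive and the robust scale coincides
#' with (or is close to) the standard deviation.
#'
#' @param x Numeric series.
#' @param max_lag Largest lag evaluated (default 100); silently reduced when
#'   the series is too short to leave `2 * bins` pairs at the largest lag.
#' @param shifts Number of bin-origin offsets per margin (default 4).
#' @param clip_sigmas Half-width of the binned span in robust sigmas
#'   (default 8).
#' @return A tibble of class `mi_profile` with columns `lag` (0..max_lag) and
#'   `mi` (bits); the `bin_spec` is attached as attribute `bins`.
#' @export
#' @examples
#' mi <- mutual_information(sin(2 * pi * (1:2000) / 100), max_lag = 50)
mutual_information <- function(x, max_lag = 100, shifts = 4, clip_sigmas = 8) {
  n <- length(x)
  s_rob <- min(sd(x), stats::IQR(x) / 1.349)
  if (!is.finite(s_rob) || s_rob == 0) s_rob <- sd(x)
  if (!is.finite(s_rob) || s_rob == 0) {
    abort("degenerate series: zero variance", class = "oculodyn_degenerate")
  }
  h <- 3.5 * s_rob * n^(-1 / 3)
  lo <- max(min(x), median(x) - clip_sigmas * s_rob)
  hi <- min(max(x), median(x) + clip_sigmas * s_rob)
  count <- max(2L, as.integer(ceiling((hi - lo) / h)))
  bins <- structure(list(width = h, count = count, sigma = s_rob, n = n,
                         origin = lo),
                    class = "bin_spec")
  max_lag <- min(as.integer(max_lag), n - 2L * min(count, 50L))
  if (max_lag < 1) abort("series too short for the requested lags")
  shifts <- max(1L, as.integer(shifts))
  jj <- count + 2L  # spare bins absorb origin offsets and clipped tails
  offsets <- h * (seq_len(shifts) - 1L) / shifts
  # precompute bin indices for every origin offset; out-of-span samples land
  # in the first/last (overflow) bin
  ix <- lapply(offsets, function(o) {
    pmin(pmax(floor((x - (lo - o)) / h) + 2L, 1L), jj)
  })
  mi_one <- function(a, b, npair) {
    joint <- tabulate(a + (b - 1L) * jj, nbins = jj * jj) / npair
    pj <- matrix(joint, jj, jj)
    ph <- rowSums(pj)
    pk <- colSums(pj)
    nz <- pj > 0
    sum(pj[nz] * log2(pj[nz] / outer(ph, pk)[nz]))
  }
  mi <- vapply(0:max_lag, function(tau) {
    lead <- seq_len(n - tau)
    acc <- 0
    for (sa in seq_len(shifts)) {
      for (sb in seq_len(shifts)) {
        acc <- acc + mi_one(ix[[sa]][lead], ix[[sb]][lead + tau], n - tau)
      }
    }
    acc / shifts^2
  }, numeric(1))
  out <- tibble(lag = 0:max_lag, mi = mi)
  attr(out, "bins") <- bins
  attr(out, "shifts") <- shifts
  class(out) <- c("mi_profile", class(out))
  out
}

#' Choose the embedding delay from a mutual-information profile
#'
#' Returns the smallest lag that is a local minimum of `I(tau)` with
#' sufficient prominence: after the candidate, and before any lower value
#' occurs, the profile must rise by at least `min_prominence` times the
#' profile's total range. This guards against shallow wiggles of the
#' histogram estimator being mistaken for the decorrelation minimum;
#' `min_prominence = 0` reduces to the plain first-local-minimum rule. When
#' no acceptable minimum exists (e.g. monotonically decaying profiles), the
#' first lag where `I(tau) < I(0)/e` is used and flagged; failing that, the
#' lag of the overall minimum, flagged.
#'
#' @param profile An `mi_profile` from [mutual_information()].
#' @param min_prominence Required rise after a candidate minimum, as a
#'   fraction of the profile range (default 0.05).
#' @return A list with fields `tau`, `flagged`, `method`.
#' @export
select_delay <- function(profile, min_prominence = 0.05) {
  stopifnot(inherits(profile, "mi_profile"))
  v <- profile$mi
  lags <- profile$lag
  L <- length(v)
  thr_rise <- min_prominence * (max(v) - min(v))
  if (L >= 3) {
    for (i in 2:(L - 1)) {
      is_min <- v[i] <= v[i - 1] && v[i] <= v[i + 1] &&
        (v[i] < v[i - 1] || v[i] < v[i + 1])
      if (!is_min) next
      after <- v[(i + 1):L]
      lower <- which(after < v[i])
      upto <- if (length(lower) > 0) lower[1] - 1L else length(after)
      if (upto >= 1 && max(after[seq_len(upto)]) - v[i] >= thr_rise) {
        return(list(tau = as.integer(lags[i]), flagged = FALSE,
                    method = "first_local_minimum"))
      }
    }
  }
  thr <- v[1] / exp(1)
  below <- which(v < thr & lags >= 1)
  if (length(below) > 0) {
    return(list(tau = as.integer(lags[below[1]]), flagged = TRUE,
                method = "first_below_1_over_e"))
  }
  list(tau = as.integer(lags[which.min(v)]), flagged = TRUE,
       method = "global_minimum")
}

#' False-nearest-neighbour profile
#'
#' For each candidate dimension `m`, embeds the series with delay `tau`,
#' finds every point's nearest neighbour (Euclidean metric, ties to the
#' smallest index, pairs within the Theiler window excluded), and counts the
#' fraction of neighbours whose separation in the added `(m+1)`-th coordinate
#' exceeds `R` times their distance in dimension `m`. The fraction drops to
#' near zero once the dynamics unfold without trajectory crossings.
#'
#' @param x Numeric series.
#' @param tau Embedding delay (samples).
#' @param m_max Largest dimension tested.
#' @param R Distance-ratio threshold (default 10).
#' @param theiler Theiler window; defaults to `tau`.
#' @return A tibble of class `fnn_profile` with columns `m`, `fnn_fraction`,
#'   `n_points`; parameters attached as attributes.
#' @export
false_nearest_neighbors <- function(x, tau, m_max = 10, R = 10,
                                    theiler = tau) {
  tau <- as.integer(tau)
  if (tau < 1) abort("`tau` must be >= 1")
  if (length(x) <= (m_max + 1) * tau + 1) {
    abort("series too short for `m_max` at this delay")
  }
  rows <- map(seq_len(m_max), function(m) {
    cnt <- fnn_count_cpp(x, tau, m, R, as.integer(theiler))
    tibble(
      m = m,
      fnn_fraction = if (cnt$n_total > 0) cnt$n_false / cnt$n_total else NA_real_,
      n_points = cnt$n_total
    )
  })
  out <- list_rbind(rows)
  attr(out, "tau") <- tau
  attr(out, "R") <- R
  attr(out, "theiler") <- as.integer(theiler)
  class(out) <- c("fnn_profile", class(out))
  out
}

#' Choose the embedding dimension from an FNN profile
#'
#' Smallest dimension whose false-neighbour fraction is at or below
#' `drop_threshold` (default 1%); if none qualifies, the dimension with the
#' minimum fraction is returned and flagged.
#'
#' @param profile An `fnn_profile`.
#' @param drop_threshold Acceptable false-neighbour fraction.
#' @return A list with fields `m`, `flagged`.
#' @export
select_dimension <- function(profile, drop_threshold = 0.01) {
  stopifnot(inherits(profile, "fnn_profile"))
  ok <- which(!is.na(profile$fnn_fraction) &
                profile$fnn_fraction <= drop_threshold)
  if (length(ok) > 0) {
    return(list(m = as.integer(profile$m[ok[1]]), flagged = FALSE))
  }
  list(m = as.integer(profile$m[which.min(profile$fnn_fraction)]),
       flagged = TRUE)
}

#' Estimate both embedding parameters of a series
#'
#' Convenience wrapper: the delay is the first local minimum of the
#' mutual-information profile, then false-nearest-neighbour fractions are
#' computed for increasing dimension until they fall below `drop_threshold`.
#' Noisy physiological series have a stochastic FNN floor above the 1%
#' criterion; when the criterion is never met, the search stops (flagged) at
#' the knee of the FNN curve -- the first dimension after which the relative
#' improvement falls below `min_improve` -- rather than chasing the noise
#' floor to high dimensions.
#'
#' @inheritParams false_nearest_neighbors
#' @param max_lag Largest delay scanned by [mutual_information()].
#' @param drop_threshold FNN acceptance fraction (default 1%).
#' @param min_improve Relative per-step FNN improvement below which the
#'   curve is considered flat (default 0.3).
#' @return A list with fields `tau`, `m`, `tau_flagged`, `m_flagged`.
#' @export
select_embedding <- function(x, max_lag = 100, m_max = 10, R = 10,
                             theiler = NULL, drop_threshold = 0.01,
                             min_improve = 0.3) {
  del <- select_delay(mutual_information(x, max_lag = max_lag))
  tau <- max(1L, del$tau)
  if (is.null(theiler)) theiler <- tau
  fracs <- rep(NA_real_, m_max)
  chosen <- NA_integer_
  m_flagged <- FALSE
  for (m in seq_len(m_max)) {
    if (length(x) <= (m + 1) * tau + 1) break
    cnt <- fnn_count_cpp(x, tau, m, R, as.integer(theiler))
    if (cnt$n_total == 0) break
    fracs[m] <- cnt$n_false / cnt$n_total
    if (fracs[m] <= drop_threshold) {
      chosen <- m
      break
    }
    if (m > 1 && fracs[m] > fracs[m - 1] * (1 - min_improve)) {
      chosen <- if (fracs[m] < fracs[m - 1]) m else m - 1L  # knee
      m_flagged <- TRUE
      break
    }
  }
  if (is.na(chosen)) {
    usable <- which(!is.na(fracs))
    if (length(usable) == 0) {
      return(list(tau = tau, m = 1L, tau_flagged = TRUE, m_flagged = TRUE))
    }
    chosen <- usable[which.min(fracs[usable])]
    m_flagged <- TRUE
  }
  list(tau = tau, m = as.integer(chosen), tau_flagged = del$flagged,
       m_flagged = m_flagged)
}

#' Delay embedding (Takens vectors)
#'
#' Builds the matrix of delay vectors
#' `y_i = (x_i, x_{i+tau}, ..., x_{i+(m-1)tau})`, one row per reconstructed
#' state, giving `M = N - (m-1) * tau` rows.
#'
#' @param x Numeric series of length `N > (m-1) * tau`.
#' @param tau Delay in samples (>= 1).
#' @param m Embedding dimension (>= 1).
#' @return An `M x m` numeric matrix of class `delay_embedding` with
#'   attributes `tau` and `m`.
#' @export
#' @examples
#' delay_embed(1:5, tau = 1, m = 2)
delay_embed <- function(x, tau, m) {
  tau <- as.integer(tau)
  m <- as.integer(m)
  if (tau < 1 || m < 1) abort("`tau` and `m` must be >= 1")
  N <- length(x)
  M <- N - (m - 1L) * tau
  if (M < 1) abort("series too short for this (tau, m)")
  emb <- vapply(seq_len(m) - 1L, function(k) x[seq_len(M) + k * tau],
                numeric(M))
  emb <- matrix(emb, nrow = M, ncol = m)
  attr(emb, "tau") <- tau
  attr(emb, "m") <- m
  class(emb) <- c("delay_embedding", class(emb))
  emb
}
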