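#' Two-point velocity differentiation
#'
#' Converts a position series (degrees) to velocity (deg/s) by the forward
#' two-point difference `v[i] = (x[i+1] - x[i]) * sampling_rate`. The output
#' is one sample shorter than the input.
#'
#' @param positions Numeric position series, length >= 2.
#' @param sampling_rate Sampling rate in Hz.
#' @return Velocity series of length `length(positions) - 1`.
#' @export
#' @examples
#' differentiate(c(0, 0.001, 0.002), 1000)  # 1 deg/s ramp
differentiate <- function(positions, sampling_rate = 1000) {
  if (length(positions) < 2) abort("need at least two samples to differentiate")
  diff(positions) * sampling_rate
}

#' Analysis segments of a fixation trial
#'
#' The five time windows used to study the evolution of the dynamics over a
#' trial: three nested segments covering the saccadic-latency period (0-50,
#' 0-100, 0-200 ms) and two covering the fixation proper (200-700 and
#' 700-1500 ms).
#'
#' @return A tibble with columns `label`, `start_ms`, `end_ms`.
#' @export
segment_specs <- function() {
  tibble(
    label = c("S0_50", "S0_100", "S0_200", "S200_700", "S700_1500"),
    start_ms = c(0, 0, 0, 200, 700),
    end_ms = c(50, 100, 200, 700, 1500)
  )
}

#' Extract a time segment from a series
#'
#' Half-open sample window: samples with 0-based index in
#' `[start_ms * rate / 1000, end_ms * rate / 1000)`, so adjacent segments
#' share no sample. At 1000 Hz the five standard segments contain exactly
#' 50, 100, 200, 500 and 800 samples.
#'
#' @param x Numeric series (position or velocity).
#' @param start_ms,end_ms Segment boundaries in ms, `start_ms < end_ms`.
#' @param sampling_rate Sampling rate in Hz.
#' @return The segment as a numeric vector.
#' @export
#' @examples
#' length(extract_segment(rnorm(3000), 200, 700, 1000))  # 500
extract_segment <- function(x, start_ms, end_ms, sampling_rate = 1000) {
  if (start_ms >= end_ms) abort("`start_ms` must be < `end_ms`")
  from <- floor(start_ms * sampling_rate / 1000)
  to <- floor(end_ms * sampling_rate / 1000)
  if (to > length(x)) abort("segment extends beyond the series")
  x[(from + 1):to]
}
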