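# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately naive (plain loops, no shared code with the package
# internals beyond exported constructors).

# running median with Tukey-style shrinking windows at the edges
oracle_running_median <- function(x, window) {
  n <- length(x)
  h <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- min(h, i - 1L, n - i)
    out[i] <- median(x[(i - w):(i + w)])
  }
  out
}

# per-window least-squares polynomial fit evaluated at the window centre
oracle_savitzky_golay_interior <- function(x, window, degree) {
  n <- length(x)
  h <- (window - 1L) %/% 2L
  out <- rep(NA_real_, n)
  for (i in (h + 1):(n - h)) {
    idx <- (i - h):(i + h)
    fit <- lm(y ~ poly(t, degree, raw = TRUE),
              data = data.frame(y = x[idx], t = seq_along(idx)))
    out[i] <- unname(predict(fit, newdata = data.frame(t = h + 1)))
  }
  out
}

# all-pairs false-nearest-neighbour fractions, one dimension at a time
oracle_fnn_fraction <- function(x, tau, m, R, theiler) {
  N <- length(x)
  M <- N - m * tau
  n_false <- 0L
  n_total <- 0L
  for (i in seq_len(M)) {
    best <- Inf
    bj <- -1L
    for (j in seq_len(M)) {
      if (abs(i - j) <= theiler) next
      d <- 0
      for (k in 0:(m - 1)) d <- d + (x[i + k * tau] - x[j + k * tau])^2
      if (d < best) {
        best <- d
        bj <- j
      }
    }
    if (bj < 0) next
    dm <- sqrt(best)
    extra <- abs(x[i + m * tau] - x[bj + m * tau])
    n_total <- n_total + 1L
    if (dm == 0) {
      if (extra > 0) n_false <- n_false + 1L
    } else if (extra / dm > R) {
      n_false <- n_false + 1L
    }
  }
  c(n_false = n_false, n_total = n_total)
}

# all-pairs mean log-divergence curve (nearest neighbour, Theiler window)
oracle_divergence <- function(emb, theiler, max_steps) {
  M <- nrow(emb)
  sums <- numeric(max_steps + 1)
  counts <- integer(max_steps + 1)
  for (i in seq_len(M)) {
    best <- Inf
    bj <- -1L
    for (j in seq_len(M)) {
      if (abs(i - j) <= theiler) next
      d <- sum((emb[i, ] - emb[j, ])^2)
      if (d < best) {
        best <- d
        bj <- j
      }
    }
    if (bj < 0 || best == 0) next
    d0 <- sqrt(best)
    for (k in 0:max_steps) {
      if (i + k > M || bj + k > M) break
      d <- sqrt(sum((emb[i + k, ] - emb[bj + k, ])^2))
      if (d > 0) {
        sums[k + 1] <- sums[k + 1] + log(d / d0)
        counts[k + 1] <- counts[k + 1] + 1L
      }
    }
  }
  ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_)
}

# per-box DFA fluctuation by direct lm / chord arithmetic
oracle_dfa_fluctuation <- function(y, n, detrend) {
  nbox <- length(y) %/% n
  res <- c()
  for (b in seq_len(nbox)) {
    seg <- y[((b - 1) * n + 1):(b * n)]
    t <- seq_len(n)
    trend <- if (detrend == "poly1") {
      fitted(lm(seg ~ t))
    } else {
      seg[1] + (seg[n] - seg[1]) * (t - 1) / (n - 1)
    }
    res <- c(res, seg - trend)
  }
  sqrt(mean(res^2))
}

# plain single-histogram mutual information in bits (fixed bins)
oracle_mutual_information <- function(a_idx, b_idx, nbins) {
  npair <- length(a_idx)
  joint <- matrix(0, nbins, nbins)
  for (p in seq_len(npair)) {
    joint[a_idx[p], b_idx[p]] <- joint[a_idx[p], b_idx[p]] + 1
  }
  joint <- joint / npair
  ph <- rowSums(joint)
  pk <- colSums(joint)
  s <- 0
  for (h in seq_len(nbins)) {
    for (k in seq_len(nbins)) {
      if (joint[h, k] > 0) {
        s <- s + joint[h, k] * log2(joint[h, k] / (ph[h] * pk[k]))
      }
    }
  }
  s
}

# noise-free single-saccade config: every stochastic fixational component off
noise_free_config <- function(amp = 10, ...) {
  sim_config(
    n_participants = 1, n_sessions = 1, n_positions = 1,
    saccade_amplitude_deg = c(amp, amp),
    drift_speed_arcmin_s = c(0, 0), tremor_amp_deg = 0,
    microsaccade_rate_hz = 0, chaos_enabled = FALSE,
    noise_amp_deg = 0, quantum_deg = 0, ...
  )
}
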