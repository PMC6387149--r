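#' Configuration for the synthetic eye-movement generator
#'
#' Builds the parameter set used by [generate_trial()] and
#' [generate_dataset()]. Defaults emulate a jumping-point experiment recorded
#' at 1000 Hz: 24 participants observed a point shown at 29 screen positions
#' in each of 2 sessions, giving 29 x 24 x 2 = 1392 trials of 3000 samples.
#' Each trial contains a saccadic-latency hold (~200 ms), one saccade with
#' amplitude 4--20 degrees and duration 30--80 ms (peak velocity capped at
#' 500 deg/s), and a fixation composed of slow drift (6--25 arcmin/s,
#' fractional Gaussian velocity noise with tunable Hurst exponent, low-passed
#' below 40 Hz), tremor (40--100 Hz, ~0.0017 deg), corrective microsaccades
#' (10--40 arcmin, 10--30 ms), and an optional chaotic velocity component.
#'
#' @param n_participants,n_sessions,n_positions Design counts.
#' @param samples_per_trial Samples recorded per stimulus presentation.
#' @param sampling_rate Sampling rate in Hz.
#' @param latency_ms Minimum saccadic latency in ms.
#' @param latency_jitter_ms Latency is drawn uniformly from
#'   `[latency_ms, latency_ms + latency_jitter_ms]`.
#' @param saccade_amplitude_deg Length-2 range of saccade amplitudes (deg).
#' @param saccade_duration_ms Length-2 range of saccade durations (ms). The
#'   lower bound is raised per trial so the raised-cosine peak velocity stays
#'   at or below `max_velocity_deg_s`.
#' @param max_velocity_deg_s Peak saccadic velocity cap (deg/s).
#' @param undershoot_frac Fraction of the saccade amplitude initially
#'   undershot and recovered by a glissadic exponential correction.
#' @param glissade_tau_ms Time constant of the glissadic correction (ms).
#' @param fixation_hurst Hurst exponent of the drift velocity noise, in (0,1).
#' @param drift_speed_arcmin_s Length-2 range of drift RMS speed (arcmin/s).
#' @param drift_cutoff_hz Low-pass cutoff applied to drift velocity (Hz).
#' @param tremor_freq_hz Length-2 range of tremor frequency (Hz).
#' @param tremor_amp_deg Tremor amplitude (deg).
#' @param microsaccade_amp_arcmin Length-2 range of microsaccade amplitude.
#' @param microsaccade_duration_ms Length-2 range of microsaccade duration.
#'   The lower bound is raised per event so the raised-cosine peak velocity
#'   stays at or below `microsaccade_max_velocity_deg_s`.
#' @param microsaccade_rate_hz Mean microsaccade rate during fixation (1/s).
#' @param microsaccade_max_velocity_deg_s Peak microsaccade velocity cap.
#' @param settle_floor,settle_tau_s Post-acquisition settling of fixational
#'   instability: after the eye lands, drift velocity, tremor and corrective
#'   microsaccade amplitudes decay exponentially (time constant
#'   `settle_tau_s` seconds) towards `settle_floor` times their initial
#'   level. `settle_floor = 1` disables settling.
#' @param drift_reversion_tau_s Time constant (s) of the mean-reverting
#'   (closed-loop) drift control that pulls the eye back towards the target;
#'   `Inf` disables reversion and leaves a pure random-walk drift.
#' @param chaos_enabled Add a low-amplitude chaotic (Lorenz-driven) component
#'   to the position signal during the pre-saccadic (open-loop) period; it is
#'   ramped off over the saccade, reflecting the onset of visually guided
#'   stabilisation.
#' @param chaos_amp_deg RMS amplitude of the chaotic component (deg).
#' @param chaos_dt Integration step of the chaotic component per sample.
#' @param noise_amp_deg RMS of additive white measurement noise on the
#'   recorded position (deg); emulates the sensor noise floor present in any
#'   real recording.
#' @param quantum_deg Quantization step of the recorded position (deg); the
#'   sensor's least significant bit. Produces the runs of exactly repeated
#'   samples (zero velocities) characteristic of digitized oculography; set
#'   to 0 for an ideal continuous recording.
#' @param anomalous_participants Data frame (or NULL) with columns
#'   `participant` and `session`: all trials of those participant-session
#'   pairs are flagged anomalous, mirroring exclusion by visual inspection.
#' @param seed Integer seed; every trial derives its own substream from it.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_participants = 1, n_sessions = 1, n_positions = 2)
#' trials <- generate_dataset(cfg)
sim_config <- function(n_participants = 24,
                       n_sessions = 2,
                       n_positions = 29,
                       samples_per_trial = 3000,
                       sampling_rate = 1000,
                       latency_ms = 200,
                       latency_jitter_ms = 40,
                       saccade_amplitude_deg = c(4, 20),
                       saccade_duration_ms = c(30, 80),
                       max_velocity_deg_s = 500,
                       undershoot_frac = 0.1,
                       glissade_tau_ms = 80,
                       fixation_hurst = 0.7,
                       drift_speed_arcmin_s = c(6, 25),
                       drift_cutoff_hz = 10,
                       tremor_freq_hz = c(40, 100),
                       tremor_amp_deg = 0.0017,
                       microsaccade_amp_arcmin = c(10, 40),
                       microsaccade_duration_ms = c(10, 30),
                       microsaccade_rate_hz = 1.5,
                       microsaccade_max_velocity_deg_s = 50,
                       settle_floor = 0.5,
                       settle_tau_s = 0.5,
                       drift_reversion_tau_s = 0.25,
                       chaos_enabled = TRUE,
                       chaos_amp_deg = 0.02,
                       chaos_dt = 0.02,
                       noise_amp_deg = 1e-4,
                       quantum_deg = 0,
                       anomalous_participants = NULL,
                       seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_sessions = as.integer(n_sessions),
    n_positions = as.integer(n_positions),
    samples_per_trial = as.integer(samples_per_trial),
    sampling_rate = sampling_rate,
    latency_ms = latency_ms,
    latency_jitter_ms = latency_jitter_ms,
    saccade_amplitude_deg = saccade_amplitude_deg,
    saccade_duration_ms = saccade_duration_ms,
    max_velocity_deg_s = max_velocity_deg_s,
    undershoot_frac = undershoot_frac,
    glissade_tau_ms = glissade_tau_ms,
    fixation_hurst = fixation_hurst,
    drift_speed_arcmin_s = drift_speed_arcmin_s,
    drift_cutoff_hz = drift_cutoff_hz,
    tremor_freq_hz = tremor_freq_hz,
    tremor_amp_deg = tremor_amp_deg,
    microsaccade_amp_arcmin = microsaccade_amp_arcmin,
    microsaccade_duration_ms = microsaccade_duration_ms,
    microsaccade_rate_hz = microsaccade_rate_hz,
    microsaccade_max_velocity_deg_s = microsaccade_max_velocity_deg_s,
    settle_floor = settle_floor,
    settle_tau_s = settle_tau_s,
    drift_reversion_tau_s = drift_reversion_tau_s,
    chaos_enabled = isTRUE(chaos_enabled),
    chaos_amp_deg = chaos_amp_deg,
    chaos_dt = chaos_dt,
    noise_amp_deg = noise_amp_deg,
    quantum_deg = quantum_deg,
    anomalous_participants = anomalous_participants,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  chk_range <- function(r, name) {
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2]) {
      abort(sprintf("`%s` must be a finite length-2 range with low <= high", name))
    }
  }
  if (cfg$samples_per_trial <= 0) abort("`samples_per_trial` must be positive")
  if (cfg$sampling_rate <= 0) abort("`sampling_rate` must be positive")
  if (cfg$n_participants < 1 || cfg$n_sessions < 1 || cfg$n_positions < 1) {
    abort("design counts must be >= 1")
  }
  if (cfg$fixation_hurst <= 0 || cfg$fixation_hurst >= 1) {
    abort("`fixation_hurst` must lie in (0, 1)")
  }
  chk_range(cfg$saccade_amplitude_deg, "saccade_amplitude_deg")
  chk_range(cfg$saccade_duration_ms, "saccade_duration_ms")
  chk_range(cfg$drift_speed_arcmin_s, "drift_speed_arcmin_s")
  chk_range(cfg$tremor_freq_hz, "tremor_freq_hz")
  chk_range(cfg$microsaccade_amp_arcmin, "microsaccade_amp_arcmin")
  chk_range(cfg$microsaccade_duration_ms, "microsaccade_duration_ms")
  # worst case: longest latency + longest saccade must fit in the trial
  worst_ms <- cfg$latency_ms + cfg$latency_jitter_ms + cfg$saccade_duration_ms[2]
  if (worst_ms * cfg$sampling_rate / 1000 >= cfg$samples_per_trial) {
    abort("latency plus saccade duration exceeds the trial length; reject config")
  }
  if (!is.null(cfg$anomalous_participants)) {
    ap <- cfg$anomalous_participants
    if (!is.data.frame(ap) || !all(c("participant", "session") %in% names(ap))) {
      abort("`anomalous_participants` must be a data frame with columns participant, session")
    }
  }
  invisible(cfg)
}

# Deterministic per-trial substream: the dataset seed and the trial counter
# define the trial's RNG state, so trials are reproducible in any order.
trial_seed <- function(cfg, participant, session, stimulus_index) {
  counter <- ((participant - 1) * cfg$n_sessions + (session - 1)) *
    cfg$n_positions + (stimulus_index - 1)
  as.integer((as.double(cfg$seed) * 48271 + counter * 16807 + 1) %% 2147483647)
}

with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Fractional Gaussian noise by circulant embedding
#'
#' Generates exact, stationary fractional Gaussian noise with unit variance
#' using the circulant-embedding (Davies-Harte) construction, which samples
#' from the true covariance of the process rather than an approximation.
#' Used both as the drift-velocity model inside [generate_trial()] and as a
#' validation signal with known Hurst exponent for DFA.
#'
#' @param hurst Target Hurst exponent in (0, 1).
#' @param n Series length (>= 2).
#' @return Numeric vector of length `n`. Consumes the current RNG stream.
#' @export
#' @examples
#' set.seed(1)
#' x <- generate_fgn(0.8, 1024)
generate_fgn <- function(hurst, n) {
  if (!is.finite(hurst) || hurst <= 0 || hurst >= 1) {
    abort("`hurst` must lie in (0, 1)")
  }
  n <- as.integer(n)
  if (n < 2) abort("`n` must be >= 2")
  h2 <- 2 * hurst
  k <- 0:n
  acov <- 0.5 * (abs(k + 1)^h2 - 2 * abs(k)^h2 + abs(k - 1)^h2)
  row1 <- c(acov, acov[n:2])
  ev <- Re(fft(row1))
  if (min(ev) < -1e-8 * max(ev)) {
    abort("circulant embedding not nonnegative definite for this `hurst`")
  }
  ev[ev < 0] <- 0
  m <- 2L * n
  z0 <- rnorm(1)
  zn <- rnorm(1)
  zre <- rnorm(n - 1)
  zim <- rnorm(n - 1)
  v <- complex(length.out = m)
  v[1] <- sqrt(ev[1]) * z0
  v[n + 1] <- sqrt(ev[n + 1]) * zn
  v[2:n] <- sqrt(ev[2:n] / 2) * complex(real = zre, imaginary = zim)
  v[m:(n + 2)] <- Conj(v[2:n])
  Re(fft(v))[1:n] / sqrt(m)
}

# fixed-step RK4 integration of the Lorenz system (sigma=10, rho=28, beta=8/3)
lorenz_series <- function(n, dt = 0.01, state = c(1, 1, 20), burn = 1000,
                          coord = 1L) {
  sigma <- 10; rho <- 28; beta <- 8 / 3
  f <- function(s) {
    c(sigma * (s[2] - s[1]),
      s[1] * (rho - s[3]) - s[2],
      s[1] * s[2] - beta * s[3])
  }
  out <- numeric(n)
  s <- state
  total <- burn + n
  for (i in seq_len(total)) {
    k1 <- f(s)
    k2 <- f(s + dt / 2 * k1)
    k3 <- f(s + dt / 2 * k2)
    k4 <- f(s + dt * k3)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (i > burn) out[i - burn] <- s[coord]
  }
  out
}

#' Canonical validation signals
#'
#' Reference series with known dynamical or fractal properties, used to
#' validate the embedding, Lyapunov and DFA stages: white Gaussian noise,
#' a Brownian random walk (cumulative sum of unit white noise), the logistic
#' map (transient of 1000 iterates discarded), the x-coordinate of the Lorenz
#' system (sigma = 10, rho = 28, beta = 8/3, fixed-step RK4), and a pure
#' sinusoid.
#'
#' @param kind One of `"white"`, `"brownian"`, `"logistic"`, `"lorenz"`,
#'   `"sine"`.
#' @param n Series length (>= 2).
#' @param r,x0 Logistic-map rate in (0, 4] and initial state in (0, 1);
#'   `x0 = NULL` draws it uniformly.
#' @param transient Logistic-map iterations discarded before recording
#'   (default 1000); the first recorded value is the iterate following the
#'   transient.
#' @param dt Lorenz RK4 step (time units per sample).
#' @param randomize_ic Perturb the Lorenz initial condition randomly.
#' @param period,phase Sinusoid period in samples and phase in radians.
#' @return Numeric vector of length `n`. Stochastic kinds consume the
#'   current RNG stream.
#' @export
#' @examples
#' x <- generate_canonical("logistic", 100, x0 = 0.2)
generate_canonical <- function(kind = c("white", "brownian", "logistic",
                                        "lorenz", "sine"),
                               n, r = 4, x0 = NULL, transient = 1000,
                               dt = 0.01, randomize_ic = FALSE, period = 100,
                               phase = 0) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (n < 2) abort("`n` must be >= 2")
  switch(kind,
    white = rnorm(n),
    brownian = cumsum(rnorm(n)),
    logistic = {
      if (r <= 0 || r > 4) abort("logistic `r` must lie in (0, 4]")
      if (is.null(x0)) x0 <- runif(1, 0.05, 0.95)
      if (x0 <= 0 || x0 >= 1) abort("logistic `x0` must lie in (0, 1)")
      x <- x0
      for (i in seq_len(transient)) x <- r * x * (1 - x)
      out <- numeric(n)
      for (i in seq_len(n)) {
        x <- r * x * (1 - x)
        out[i] <- x
      }
      out
    },
    lorenz = {
      ic <- c(1, 1, 20)
      if (randomize_ic) ic <- ic + rnorm(3, sd = 0.5)
      lorenz_series(n, dt = dt, state = ic)
    },
    sine = sin(2 * pi * (0:(n - 1)) / period + phase)
  )
}

# raised-cosine displacement profile over `len` samples reaching `amp`
raised_cosine_step <- function(amp, len) {
  u <- seq_len(len) / len
  amp * (u - sin(2 * pi * u) / (2 * pi))
}

#' Generate one synthetic eye-movement trial
#'
#' Simulates a single horizontal eye-position trace for one stimulus
#' presentation: the eye holds near its previous position for the saccadic
#' latency, executes one raised-cosine saccade toward the new target
#' (with a small glissadic undershoot correction), then fixates. Drift
#' (fractional Gaussian velocity noise), tremor, corrective microsaccades and
#' an optional chaotic component are superimposed. The trial is deterministic
#' given the config seed and the trial indices.
#'
#' @param config A [sim_config()].
#' @param participant,session,stimulus_index 1-based trial indices.
#' @param anomalous Flag carried through to the output.
#' @return A tibble with columns `sample_index`, `time_ms`, `position_deg`
#'   and attributes `participant`, `session`, `stimulus_index`, `anomalous`.
#' @export
#' @examples
#' tr <- generate_trial(sim_config(), 1, 1, 1)
generate_trial <- function(config, participant = 1L, session = 1L,
                           stimulus_index = 1L, anomalous = FALSE) {
  validate_sim_config(config)
  n <- config$samples_per_trial
  fs <- config$sampling_rate
  pos <- with_seed(
    trial_seed(config, participant, session, stimulus_index),
    trial_positions(config, n, fs)
  )
  out <- tibble(
    sample_index = seq_len(n) - 1L,
    time_ms = (seq_len(n) - 1L) * 1000 / fs,
    position_deg = pos
  )
  attr(out, "participant") <- as.integer(participant)
  attr(out, "session") <- as.integer(session)
  attr(out, "stimulus_index") <- as.integer(stimulus_index)
  attr(out, "anomalous") <- isTRUE(anomalous)
  class(out) <- c("eye_trace", class(out))
  out
}

# core waveform synthesis; assumes the RNG state is already set
trial_positions <- function(cfg, n, fs) {
  ms_per_sample <- 1000 / fs

  # -- saccade kinematics ------------------------------------------------
  amp <- runif(1, cfg$saccade_amplitude_deg[1], cfg$saccade_amplitude_deg[2])
  # raised-cosine peak velocity is 2A/D; raise the minimum duration so the
  # peak respects the physiological velocity cap
  dur_lo <- max(cfg$saccade_duration_ms[1],
                2 * amp / cfg$max_velocity_deg_s * 1000)
  dur_lo <- min(dur_lo, cfg$saccade_duration_ms[2])
  dur_ms <- runif(1, dur_lo, cfg$saccade_duration_ms[2])
  latency_ms <- runif(1, cfg$latency_ms, cfg$latency_ms + cfg$latency_jitter_ms)
  lat_n <- round(latency_ms / ms_per_sample)
  sac_n <- max(2L, round(dur_ms / ms_per_sample))
  if (lat_n + sac_n >= n) abort("saccade does not fit in the trial; reject config")

  base <- numeric(n)
  main_amp <- amp * (1 - cfg$undershoot_frac)
  base[(lat_n + 1):(lat_n + sac_n)] <- raised_cosine_step(main_amp, sac_n)
  if (lat_n + sac_n < n) {
    post <- (lat_n + sac_n + 1):n
    t_post <- (post - (lat_n + sac_n)) * ms_per_sample
    base[post] <- main_amp +
      amp * cfg$undershoot_frac * (1 - exp(-t_post / cfg$glissade_tau_ms))
  }

  # -- post-acquisition settling envelope for fixational instability ------
  land <- lat_n + sac_n
  envelope <- rep(1, n)
  if (cfg$settle_floor < 1 && land < n) {
    t_post <- (seq_len(n - land)) / fs
    envelope[(land + 1):n] <- cfg$settle_floor +
      (1 - cfg$settle_floor) * exp(-t_post / cfg$settle_tau_s)
  }

  # -- drift: fGn velocity, low-passed, integrated to position with weak
  # mean reversion (closed-loop fixation control) -------------------------
  drift_speed <- runif(1, cfg$drift_speed_arcmin_s[1],
                       cfg$drift_speed_arcmin_s[2]) / 60  # deg/s
  if (drift_speed > 0) {
    v <- generate_fgn(cfg$fixation_hurst, n)
    if (is.finite(cfg$drift_cutoff_hz) && cfg$drift_cutoff_hz < fs / 2) {
      bf <- signal::butter(2, cfg$drift_cutoff_hz / (fs / 2))
      v <- signal::filtfilt(bf, v)
    }
    v <- v / sqrt(mean(v^2)) * drift_speed * envelope
    kappa <- if (is.finite(cfg$drift_reversion_tau_s)) {
      1 / (cfg$drift_reversion_tau_s * fs)
    } else {
      0
    }
    drift <- numeric(n)
    for (i in 2:n) {
      drift[i] <- drift[i - 1] * (1 - kappa) + v[i - 1] / fs
    }
  } else {
    drift <- numeric(n)
  }

  # -- tremor ------------------------------------------------------------
  tremor <- if (cfg$tremor_amp_deg > 0) {
    f <- runif(1, cfg$tremor_freq_hz[1], cfg$tremor_freq_hz[2])
    ph <- runif(1, 0, 2 * pi)
    cfg$tremor_amp_deg * envelope *
      sin(2 * pi * f * (seq_len(n) - 1) / fs + ph)
  } else {
    numeric(n)
  }

  # -- chaotic component: open-loop oculomotor drive before the saccade,
  # ramped off across the saccade as visual stabilisation takes over ------
  chaos <- if (cfg$chaos_enabled && cfg$chaos_amp_deg > 0) {
    z <- lorenz_series(n, dt = cfg$chaos_dt,
                       state = c(1, 1, 20) + rnorm(3, sd = 0.5))
    z <- (z - mean(z)) / sd(z) * cfg$chaos_amp_deg
    gate <- c(rep(1, lat_n),
              0.5 * (1 + cos(pi * seq_len(sac_n) / sac_n)),
              rep(0, n - lat_n - sac_n))
    z * gate
  } else {
    numeric(n)
  }

  # -- microsaccades: Poisson-placed corrective miniature saccades during
  # fixation, with a refractory gap and the same overshoot-plus-glissade
  # kinematics as the main saccade ----------------------------------------
  micro <- numeric(n)
  fix_start <- lat_n + sac_n + 1L
  if (cfg$microsaccade_rate_hz > 0 && fix_start < n) {
    fix_dur_s <- (n - fix_start + 1) / fs
    k <- rpois(1, cfg$microsaccade_rate_hz * fix_dur_s)
    if (k > 0) {
      onsets <- sort(sample.int(n - fix_start, k, replace = TRUE) + fix_start)
      refractory <- round(150 / ms_per_sample)  # min inter-event interval
      keep <- !logical(length(onsets))
      last <- -Inf
      for (q in seq_along(onsets)) {
        if (onsets[q] - last < refractory) keep[q] <- FALSE else last <- onsets[q]
      }
      onsets <- onsets[keep]
      for (on in onsets) {
        a <- runif(1, cfg$microsaccade_amp_arcmin[1],
                   cfg$microsaccade_amp_arcmin[2]) / 60 * envelope[on]
        # couple duration to amplitude so the peak velocity (2a/d) respects
        # the physiological microsaccade velocity range
        d_lo <- max(cfg$microsaccade_duration_ms[1],
                    2 * a / cfg$microsaccade_max_velocity_deg_s * 1000)
        d_lo <- min(d_lo, cfg$microsaccade_duration_ms[2])
        d_ms <- runif(1, d_lo, cfg$microsaccade_duration_ms[2])
        d_n <- max(2L, round(d_ms / ms_per_sample))
        # corrective: oppose the accumulated fixational offset at onset
        off <- drift[on] + micro[on] + chaos[on]
        sgn <- if (abs(off) > 1e-12) -sign(off) else sample(c(-1, 1), 1)
        stop_at <- min(n, on + d_n - 1L)
        # dynamic overshoot: the movement overshoots its landing point and
        # glides back exponentially (miniature-saccade glissade)
        over <- 1 + cfg$undershoot_frac
        prof <- raised_cosine_step(sgn * a * over, d_n)[seq_len(stop_at - on + 1L)]
        micro[on:stop_at] <- micro[on:stop_at] + prof
        if (stop_at < n) {
          tail_idx <- (stop_at + 1):n
          t_tail <- (tail_idx - stop_at) * ms_per_sample
          back <- sgn * a * (over - cfg$undershoot_frac *
                               (1 - exp(-t_tail / cfg$glissade_tau_ms)))
          micro[tail_idx] <- micro[tail_idx] + back
        }
      }
    }
  }

  noise <- if (cfg$noise_amp_deg > 0) rnorm(n, sd = cfg$noise_amp_deg) else numeric(n)

  pos <- base + drift + tremor + chaos + micro + noise
  if (cfg$quantum_deg > 0) pos <- round(pos / cfg$quantum_deg) * cfg$quantum_deg
  stopifnot(all(is.finite(pos)), length(pos) == n)
  pos
}

#' Generate a full synthetic dataset
#'
#' Produces the full factorial participant x session x stimulus-position set
#' of trials. Trials of participant-session pairs listed in the config's
#' `anomalous_participants` are flagged `anomalous = TRUE` (and can later be
#' removed with [exclude_anomalous()]).
#'
#' @param config A [sim_config()].
#' @return A tibble of class `trial_set` with one row per trial: `trial_id`,
#'   `participant`, `session`, `stimulus`, `anomalous`, and a list-column
#'   `trace` holding the position vector (degrees). The config is attached as
#'   attribute `config`.
#' @export
#' @examples
#' cfg <- sim_config(n_participants = 2, n_sessions = 1, n_positions = 3)
#' generate_dataset(cfg)
generate_dataset <- function(config) {
  validate_sim_config(config)
  design <- tidyr::expand_grid(
    participant = seq_len(config$n_participants),
    session = seq_len(config$n_sessions),
    stimulus = seq_len(config$n_positions)
  )
  ap <- config$anomalous_participants
  flagged <- if (is.null(ap)) {
    rep(FALSE, nrow(design))
  } else {
    paste(design$participant, design$session) %in% paste(ap$participant, ap$session)
  }
  traces <- pmap(design, function(participant, session, stimulus) {
    with_seed(
      trial_seed(config, participant, session, stimulus),
      trial_positions(config, config$samples_per_trial, config$sampling_rate)
    )
  })
  out <- design %>%
    mutate(
      trial_id = sprintf("P%02d_S%d_T%02d", .data$participant, .data$session,
                         .data$stimulus),
      anomalous = flagged,
      trace = traces
    ) %>%
    select(all_of(c("trial_id", "participant", "session", "stimulus",
                    "anomalous", "trace")))
  attr(out, "config") <- config
  class(out) <- c("trial_set", class(out))
  out
}

#' Drop trials flagged as anomalous
#'
#' Mirrors the exclusion-by-inspection bookkeeping of the study design: all
#' trials whose participant-session pair showed abnormal behaviour are
#' removed before analysis, and the counts are reported.
#'
#' @param trials A `trial_set` tibble from [generate_dataset()].
#' @return The filtered trial set.
#' @export
exclude_anomalous <- function(trials) {
  stopifnot(is.data.frame(trials), "anomalous" %in% names(trials))
  n_flagged <- sum(trials$anomalous)
  out <- dplyr::filter(trials, !.data$anomalous)
  inform(sprintf("excluded %d of %d trials; %d retained",
                 n_flagged, nrow(trials), nrow(out)))
  if (nrow(out) == 0) warn("all trials were flagged anomalous")
  attr(out, "config") <- attr(trials, "config")
  class(out) <- unique(c("trial_set", class(out)))
  out
}

#' Write / read a trial set as plain CSV files
#'
#' `write_eye_dataset()` writes one CSV per trial (columns `sample_index`,
#' `position_deg`), a `manifest.csv` with columns
#' `participant,session,stimulus,file,anomalous`, and the generator config as
#' `config.yaml`. `read_eye_dataset()` reads the directory back into a
#' `trial_set` tibble.
#'
#' @param trials A `trial_set` tibble.
#' @param dir Output directory (created if missing).
#' @return `write_eye_dataset()` returns `dir` invisibly;
#'   `read_eye_dataset()` returns a `trial_set` tibble.
#' @export
write_eye_dataset <- function(trials, dir) {
  stopifnot(is.data.frame(trials))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- sprintf("%s.csv", trials$trial_id)
  for (i in seq_len(nrow(trials))) {
    utils::write.csv(
      data.frame(sample_index = seq_along(trials$trace[[i]]) - 1L,
                 position_deg = trials$trace[[i]]),
      file.path(dir, files[i]), row.names = FALSE
    )
  }
  manifest <- data.frame(
    participant = trials$participant, session = trials$session,
    stimulus = trials$stimulus, file = files, anomalous = trials$anomalous
  )
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  cfg <- attr(trials, "config")
  if (!is.null(cfg)) write_sim_config(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_eye_dataset
#' @export
read_eye_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  traces <- map(manifest$file, function(f) {
    utils::read.csv(file.path(dir, f))$position_deg
  })
  out <- tibble(
    trial_id = sub("\\.csv$", "", manifest$file),
    participant = manifest$participant,
    session = manifest$session,
    stimulus = manifest$stimulus,
    anomalous = as.logical(manifest$anomalous),
    trace = traces
  )
  cfg_path <- file.path(dir, "config.yaml")
  if (file.exists(cfg_path)) attr(out, "config") <- read_sim_config(cfg_path)
  class(out) <- c("trial_set", class(out))
  out
}

#' Write / read a simulation config as YAML
#' @param config A [sim_config()].
#' @param path File path.
#' @return `write_sim_config()` returns `path` invisibly;
#'   `read_sim_config()` returns a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  validate_sim_config(config)
  x <- unclass(config)
  if (!is.null(x$anomalous_participants)) {
    x$anomalous_participants <- as.list(as.data.frame(x$anomalous_participants))
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$anomalous_participants)) {
    x$anomalous_participants <- as.data.frame(x$anomalous_participants)
  }
  do.call(sim_config, x)
}
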