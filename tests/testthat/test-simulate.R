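test_that("noise-free saccade reaches its amplitude and is monotone", {
  cfg <- noise_free_config(amp = 10)
  tr <- generate_trial(cfg, 1, 1, 1)
  pos <- tr$position_deg
  expect_length(pos, cfg$samples_per_trial)
  expect_true(all(is.finite(pos)))
  # landing on the target: glissade correction has fully decayed by trial end
  expect_equal(mean(tail(pos, 100)) - pos[1], 10, tolerance = 1e-6)
  # monotone throughout (latency flat, saccade rising, glissade rising)
  expect_true(all(diff(pos) >= -1e-12))
  # peak two-point velocity respects the physiological cap
  v <- differentiate(pos, cfg$sampling_rate)
  expect_lte(max(abs(v)), 500)
})

test_that("default-config trials respect the velocity cap and trial length", {
  cfg <- sim_config()
  for (k in 1:3) {
    tr <- generate_trial(cfg, 1, 1, k)
    expect_length(tr$position_deg, 3000)
    v <- differentiate(tr$position_deg, 1000)
    expect_lte(max(abs(v)), 500)
  }
})

test_that("trial generation is deterministic and order-independent", {
  cfg <- sim_config(n_participants = 2, n_sessions = 2, n_positions = 3,
                    seed = 99)
  a <- generate_trial(cfg, 2, 1, 3)
  b <- generate_trial(cfg, 2, 1, 3)
  expect_identical(a$position_deg, b$position_deg)
  trials <- generate_dataset(cfg)
  row <- trials[trials$participant == 2 & trials$session == 1 &
                  trials$stimulus == 3, ]
  expect_identical(row$trace[[1]], a$position_deg)
})

test_that("dataset cardinality equals the factorial design", {
  cfg <- sim_config(n_participants = 2, n_sessions = 1, n_positions = 3,
                    samples_per_trial = 500)
  trials <- generate_dataset(cfg)
  expect_equal(nrow(trials), 2 * 1 * 3)
  cfg1 <- sim_config(n_participants = 1, n_sessions = 1, n_positions = 1,
                     samples_per_trial = 500)
  expect_equal(nrow(generate_dataset(cfg1)), 1)
})

test_that("anomalous participant-session pairs are flagged and excludable", {
  cfg <- sim_config(
    n_participants = 4, n_sessions = 2, n_positions = 5,
    samples_per_trial = 500,
    anomalous_participants = data.frame(participant = c(1, 2), session = 2)
  )
  trials <- generate_dataset(cfg)
  expect_equal(sum(trials$anomalous), 2 * 5)
  kept <- suppressMessages(exclude_anomalous(trials))
  expect_equal(nrow(kept), nrow(trials) - 10)
  none <- generate_dataset(sim_config(n_participants = 2, n_sessions = 1,
                                      n_positions = 2,
                                      samples_per_trial = 500))
  expect_equal(nrow(suppressMessages(exclude_anomalous(none))), 4)
  all_flagged <- none
  all_flagged$anomalous <- TRUE
  expect_warning(suppressMessages(exclude_anomalous(all_flagged)),
                 "all trials")
})

test_that("invalid configs are rejected", {
  expect_error(sim_config(fixation_hurst = 1.2), "fixation_hurst")
  expect_error(sim_config(saccade_amplitude_deg = c(20, 4)), "range")
  expect_error(sim_config(samples_per_trial = 200), "exceeds the trial length")
})

test_that("fractional Gaussian noise has the exact target autocovariance", {
  set.seed(1)
  x <- generate_fgn(0.5, 4096)
  r1 <- cor(x[-1], x[-length(x)])
  expect_lt(abs(r1), 3 / sqrt(4096))
  set.seed(2)
  y <- generate_fgn(0.8, 4096)
  r1y <- cor(y[-1], y[-length(y)])
  expect_equal(r1y, 2^(2 * 0.8 - 1) - 1, tolerance = 0.05)
  set.seed(7)
  a <- generate_fgn(0.7, 256)
  set.seed(7)
  b <- generate_fgn(0.7, 256)
  expect_identical(a, b)
  expect_error(generate_fgn(1.2, 100), "hurst")
})

test_that("fGn at H = 0.5 is indistinguishable from white noise (Ljung-Box)", {
  set.seed(9)
  pv <- replicate(100, stats::Box.test(generate_fgn(0.5, 512), lag = 10,
                                       type = "Ljung-Box")$p.value)
  # rejection count at the 5% level should be binomially plausible
  expect_lte(sum(pv < 0.05), 12)
})

test_that("canonical validation signals match their closed forms", {
  expect_equal(generate_canonical("logistic", 3, x0 = 0.2, transient = 0),
               c(0.64, 0.9216, 0.28901376))
  s <- generate_canonical("sine", 200, period = 100)
  expect_equal(s[1:100], s[101:200], tolerance = 1e-12)
  set.seed(3)
  b <- generate_canonical("brownian", 1000)
  expect_equal(var(diff(b)), 1, tolerance = 0.15)
  expect_error(generate_canonical("logistic", 10, r = 5), "r")
})

test_that("Lorenz integration matches an independent fixed-step RK4 oracle", {
  n <- 200
  x <- generate_canonical("lorenz", n, dt = 0.01)
  lorenz_rhs <- function(t, y, p) {
    list(c(10 * (y[2] - y[1]), y[1] * (28 - y[3]) - y[2],
           y[1] * y[2] - 8 / 3 * y[3]))
  }
  out <- deSolve::ode(c(1, 1, 20), seq(0, (1000 + n) * 0.01, by = 0.01),
                      lorenz_rhs, NULL, method = "rk4")
  expect_equal(x, unname(out[1002:(1001 + n), 2]), tolerance = 1e-8)
})

test_that("datasets round-trip through CSV and YAML", {
  cfg <- sim_config(n_participants = 1, n_sessions = 2, n_positions = 2,
                    samples_per_trial = 400, seed = 3,
                    anomalous_participants = data.frame(participant = 1,
                                                        session = 2))
  trials <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_eye_dataset(trials, dir)
  back <- read_eye_dataset(dir)
  expect_equal(nrow(back), nrow(trials))
  expect_equal(back$trace[[3]], trials$trace[[3]], tolerance = 1e-12)
  expect_equal(back$anomalous, trials$anomalous)
  cfg2 <- attr(back, "config")
  expect_equal(cfg2$seed, cfg$seed)
  expect_equal(cfg2$saccade_amplitude_deg, cfg$saccade_amplitude_deg)
  expect_equal(cfg2$anomalous_participants$session, 2)
})
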