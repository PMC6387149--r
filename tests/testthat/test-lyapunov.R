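test_that("divergence curves match the all-pairs oracle", {
  set.seed(1)
  x <- rnorm(120)
  emb <- delay_embed(x, 2, 3)
  cv <- divergence_curve(emb, theiler = 4, max_steps = 10)
  ref <- oracle_divergence(unclass(emb), 4, 10)
  expect_equal(cv$mean_log_div, ref[cv$step + 1], tolerance = 1e-12)
  expect_equal(cv$mean_log_div[1], 0)  # step 0 is zero by construction
})

test_that("degenerate embeddings are reported infeasible with a reason", {
  emb <- delay_embed(rep(1, 50), 1, 2)           # all states identical
  cv <- divergence_curve(emb, theiler = 2)
  expect_false(attr(cv, "feasible"))
  expect_equal(attr(cv, "reason"), "zero_distance_pairs")
  res <- estimate_lle(cv)
  expect_false(res$feasible)
  expect_true(is.na(res$lambda))
  expect_equal(classify_dynamics(res), "infeasible")
  short <- delay_embed(rnorm(6), 1, 2)
  expect_false(attr(divergence_curve(short, theiler = 10), "feasible"))
})

test_that("the logistic map exponent matches the derivative-sum oracle", {
  for (s in 1:3) {
    set.seed(s)
    x <- generate_canonical("logistic", 3000)
    oracle <- mean(log(abs(4 * (1 - 2 * x))))   # analytic: ln 2
    cv <- divergence_curve(delay_embed(x, 1, 2), theiler = 2, max_steps = 10)
    lam <- estimate_lle(cv, 1:4)$lambda
    expect_equal(lam, oracle, tolerance = 0.1)
  }
  # curve is initially linear with positive slope
  set.seed(1)
  x <- generate_canonical("logistic", 3000)
  cv <- divergence_curve(delay_embed(x, 1, 2), theiler = 2, max_steps = 10)
  expect_true(all(diff(cv$mean_log_div[1:5]) > 0))
})

test_that("a contracting linear map yields exactly ln(1/2) per step", {
  x <- 2 * 0.5^(0:29)
  cv <- divergence_curve(delay_embed(x, 1, 1), theiler = 0, max_steps = 8)
  res <- estimate_lle(cv, 1:8)
  expect_equal(res$lambda, log(0.5), tolerance = 1e-9)
})

test_that("an exact line in the curve recovers slope / dt", {
  curve <- tibble::tibble(step = 0:10, time = (0:10) * 2,
                          mean_log_div = 0.3 * (0:10), n_pairs = 50L)
  attr(curve, "dt") <- 2
  attr(curve, "n_pairs") <- 50L
  attr(curve, "zero_frac") <- 0
  attr(curve, "feasible") <- TRUE
  attr(curve, "reason") <- "none"
  class(curve) <- c("divergence_curve", class(curve))
  expect_equal(estimate_lle(curve, 1:10)$lambda, 0.15)  # 0.3 per step, dt = 2
})

test_that("stochastic and stable signals show no sustained divergence", {
  set.seed(4)
  w <- rnorm(2000)
  cv <- divergence_curve(delay_embed(w, 1, 3), theiler = 3, max_steps = 30)
  res <- estimate_lle(cv, 5:20)      # beyond the initial jump
  expect_lt(abs(res$lambda), 0.05)
  expect_lt(res$r_squared, 0.9)      # flagged poor fit quality
  t <- 0:999
  damped <- exp(-t / 300) * sin(2 * pi * t / 40)
  rd <- estimate_lle(divergence_curve(delay_embed(damped, 10, 3),
                                      theiler = 30, max_steps = 40))
  expect_lt(rd$lambda, 0)
  periodic <- sin(2 * pi * t / 40)
  rp <- estimate_lle(divergence_curve(delay_embed(periodic, 10, 3),
                                      theiler = 30, max_steps = 40))
  expect_lt(abs(rp$lambda), 0.1)
  expect_lt(rp$r_squared, 0.5)
})

test_that("dynamics classification follows the sign with tolerance", {
  mk <- function(lambda) {
    structure(list(lambda = lambda, r_squared = 0.9, fit_range = c(1, 20),
                   dt = 1, n_pairs = 10L, feasible = TRUE, reason = "none"),
              class = "lle_result")
  }
  expect_equal(classify_dynamics(mk(0.0083), tol = 1e-4), "chaotic")
  expect_equal(classify_dynamics(mk(-0.00082), tol = 1e-4), "convergent")
  expect_equal(classify_dynamics(mk(0)), "neutral")
})

test_that("median filtering raises the infeasible fraction relative to SG", {
  cfg <- sim_config(n_participants = 2, n_sessions = 1, n_positions = 5,
                    seed = 21)
  trials <- generate_dataset(cfg)
  rec <- analyze_lle(trials, filters = c("M5", "SG7"))
  frac <- tapply(!rec$feasible, rec$filter, mean)
  expect_gt(frac[["M5"]], frac[["SG7"]])
})
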