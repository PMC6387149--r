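test_that("Scott's rule bin width and count follow the closed form", {
  set.seed(1)
  x <- rnorm(1000)
  x <- (x - mean(x)) / sd(x)  # sd exactly 1
  b <- scott_bins(x)
  expect_equal(b$width, 0.35)   # 3.5 * 1 * 1000^(-1/3)
  b2 <- scott_bins(2 * x)
  expect_equal(b2$width, 0.70)
  u <- runif(1000)
  bu <- scott_bins(u)
  expect_equal(bu$count, max(2L, ceiling(diff(range(u)) / bu$width)))
  expect_error(scott_bins(rep(1, 100)), class = "oculodyn_degenerate")
})

test_that("mutual information vanishes for independent samples and is nonnegative", {
  set.seed(2)
  u <- runif(5000)
  mi <- mutual_information(u, max_lag = 20)
  expect_true(all(mi$mi >= 0))
  expect_true(all(mi$mi[-1] < 0.1))          # small-sample bias bound
  expect_true(all(mi$mi[1] >= mi$mi[-1]))    # I(0) dominates
})

test_that("plain-histogram I(0) equals the binned marginal entropy", {
  set.seed(3)
  x <- rnorm(2000)
  mi <- mutual_information(x, max_lag = 5, shifts = 1)
  b <- attr(mi, "bins")
  idx <- pmin(pmax(floor((x - (b$origin)) / b$width) + 2L, 1L), b$count + 2L)
  p <- tabulate(idx, nbins = b$count + 2L) / length(x)
  entropy <- -sum(p[p > 0] * log2(p[p > 0]))
  expect_equal(mi$mi[1], entropy, tolerance = 1e-12)
})

test_that("plain-histogram MI matches a naive double-loop oracle exactly", {
  set.seed(4)
  x <- rnorm(300)
  mi <- mutual_information(x, max_lag = 4, shifts = 1)
  b <- attr(mi, "bins")
  idx <- pmin(pmax(floor((x - b$origin) / b$width) + 2L, 1L), b$count + 2L)
  for (tau in 1:4) {
    lead <- seq_len(300 - tau)
    expect_equal(mi$mi[tau + 1],
                 oracle_mutual_information(idx[lead], idx[lead + tau],
                                           b$count + 2L),
                 tolerance = 1e-12)
  }
})

test_that("the delay is the first prominent mutual-information minimum", {
  fake <- tibble::tibble(lag = 0:4, mi = c(3, 2, 1, 1.5, 1.2))
  class(fake) <- c("mi_profile", class(fake))
  sel <- select_delay(fake)
  expect_equal(sel$tau, 2L)
  expect_false(sel$flagged)
  # monotone decay: falls back to the 1/e rule, flagged
  dec <- tibble::tibble(lag = 0:10, mi = 3 * exp(-(0:10) / 2))
  class(dec) <- c("mi_profile", class(dec))
  fb <- select_delay(dec)
  expect_true(fb$flagged)
  expect_equal(fb$tau, 3L)  # first lag with 3 exp(-tau/2) < 3/e
  # sine of period 100 decorrelates near the quarter period
  mi <- mutual_information(generate_canonical("sine", 2000, period = 100),
                           max_lag = 60)
  tau <- select_delay(mi)$tau
  expect_gte(tau, 22)
  expect_lte(tau, 28)
})

test_that("FNN fractions match the all-pairs brute-force oracle exactly", {
  set.seed(5)
  w <- rnorm(300)
  lo <- generate_canonical("lorenz", 400)
  for (sig in list(w, lo)) {
    prof <- false_nearest_neighbors(sig, tau = 3, m_max = 4, R = 10,
                                    theiler = 3)
    for (m in 1:4) {
      ref <- oracle_fnn_fraction(sig, 3, m, 10, 3)
      expect_identical(prof$n_points[m], as.integer(ref["n_total"]))
      expect_equal(prof$fnn_fraction[m],
                   ref["n_false"] / ref["n_total"],
                   ignore_attr = TRUE, tolerance = 1e-15)
    }
  }
})

test_that("FNN separates noise from low-dimensional dynamics", {
  set.seed(6)
  w <- rnorm(2000)
  fw <- false_nearest_neighbors(w, 1, m_max = 2, theiler = 1)
  expect_gt(fw$fnn_fraction[1], 0.9)   # noise: no unfolding at low dimension
  expect_gt(fw$fnn_fraction[2], 0.5)
  lo <- generate_canonical("lorenz", 5000)
  fl <- false_nearest_neighbors(lo, 16, m_max = 4, theiler = 16)
  expect_lt(fl$fnn_fraction[3], 0.01)  # Lorenz unfolds by dimension 3
  # infinite threshold: the ratio test can never trigger on distinct values
  f0 <- false_nearest_neighbors(w[1:200], 2, m_max = 3, R = 1e12, theiler = 2)
  expect_equal(f0$fnn_fraction, rep(0, 3))
})

test_that("dimension selection applies the drop threshold, else flags the argmin", {
  prof <- tibble::tibble(m = 1:4, fnn_fraction = c(0.9, 0.3, 0.005, 0.004),
                         n_points = rep(100L, 4))
  class(prof) <- c("fnn_profile", class(prof))
  sel <- select_dimension(prof, 0.01)
  expect_equal(sel$m, 3L)
  expect_false(sel$flagged)
  prof$fnn_fraction <- c(0.9, 0.3, 0.15, 0.12)
  sel2 <- select_dimension(prof, 0.01)
  expect_equal(sel2$m, 4L)
  expect_true(sel2$flagged)
})

test_that("select_embedding recovers Lorenz parameters", {
  lo <- generate_canonical("lorenz", 5000)
  sel <- select_embedding(lo)
  expect_gte(sel$tau, 10)
  expect_lte(sel$tau, 25)
  expect_lte(sel$m, 4)
  expect_false(sel$m_flagged)
})

test_that("delay embedding obeys the row formula M = N - (m-1) tau", {
  e <- delay_embed(1:5, 1, 2)
  expect_equal(unclass(e)[, ], cbind(1:4, 2:5), ignore_attr = TRUE)
  expect_equal(as.numeric(delay_embed(sin(1:20), 3, 1)), sin(1:20))
  expect_equal(nrow(delay_embed(1:10, 3, 3)), 4)
  for (n in c(20, 57)) {
    x <- rnorm(n)
    for (tau in c(1, 3)) {
      for (m in c(1, 2, 4)) {
        e <- delay_embed(x, tau, m)
        expect_equal(nrow(e), n - (m - 1) * tau)
        expect_equal(e[1, ], x[1 + (0:(m - 1)) * tau], ignore_attr = TRUE)
      }
    }
  }
  expect_error(delay_embed(1:5, 3, 3), "too short")
})
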