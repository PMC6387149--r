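make_lle_records <- function() {
  tibble::tibble(
    trial_id = rep(sprintf("T%02d", 1:20), each = 2),
    filter = rep(c("N", "SG7"), 20),
    segment = "S200_700",
    lambda = c(rnorm(20, -2, 0.3), rnorm(20, -1, 0.3))[order(rep(1:20, 2))],
    feasible = TRUE,
    reason = "none",
    r2 = 0.9
  )
}

test_that("group summaries report mean, sd and exclusion counts", {
  rec <- tibble::tibble(
    filter = c("N", "N", "SG7", "SG7", "SG7"),
    lambda = c(1, 3, 2, 2, NA),
    feasible = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  gs <- group_summary(rec, "lambda")
  expect_equal(gs$mean[gs$filter == "N"], 2)
  expect_equal(gs$sd[gs$filter == "SG7"], 0)
  expect_equal(gs$n_excluded[gs$filter == "SG7"], 1)
  one <- group_summary(tibble::tibble(filter = "N", alpha = 0.7), "alpha")
  expect_equal(one$sd, 0)   # single record: sd reported as 0
})

test_that("summary means are invariant to record order", {
  set.seed(1)
  rec <- tibble::tibble(filter = sample(c("A", "B"), 50, TRUE),
                        alpha = rnorm(50))
  a <- group_summary(rec, "alpha")
  b <- group_summary(rec[sample(50), ], "alpha")
  expect_equal(a, b)
})

test_that("indistinguishable groups are not declared different", {
  set.seed(2)
  rec <- tibble::tibble(filter = rep(c("A", "B"), each = 100),
                        alpha = rnorm(200))
  st <- run_tests(rec, "alpha")
  expect_false(any(st$significant))
  expect_true(all(st$p_value > 0.05))
})

test_that("well-separated groups are detected with high power", {
  set.seed(3)
  rec <- tibble::tibble(filter = rep(c("A", "B"), each = 100),
                        alpha = c(rnorm(100, 0), rnorm(100, 5)))
  st <- run_tests(rec, "alpha")
  expect_true(all(st$significant))
})

test_that("the normality gate selects the rank-based branch for skewed data", {
  set.seed(4)
  rec <- tibble::tibble(filter = rep(c("A", "B", "C"), each = 80),
                        alpha = rexp(240) + rep(c(0, 0, 1), each = 80))
  st <- run_tests(rec, "alpha")
  expect_equal(attr(st, "test"), "kruskal")
  expect_equal(nrow(st), 3)   # all pairs
  expect_true(st$significant[st$group1 == "C" | st$group2 == "C"][1])
})

test_that("small groups are skipped with a warning", {
  rec <- tibble::tibble(filter = c(rep("A", 10), "B"),
                        alpha = rnorm(11))
  expect_warning(expect_error(run_tests(rec, "alpha"), "two groups"),
                 "fewer than 3")
})

test_that("sign tests use the segment-specific directional hypotheses", {
  set.seed(5)
  rec <- tibble::tibble(
    trial_id = sprintf("T%02d", 1:60),
    filter = "N",
    segment = rep(c("S0_50", "S200_700", "S700_1500"), each = 20),
    lambda = c(abs(rnorm(20, 2)), -abs(rnorm(20, 2)), rnorm(20, 0, 3)),
    feasible = TRUE, reason = "none", r2 = 0.9
  )
  st <- lle_sign_tests(rec)
  expect_equal(st$alternative[st$segment == "S0_50"], "greater")
  expect_equal(st$alternative[st$segment == "S200_700"], "less")
  expect_equal(st$alternative[st$segment == "S700_1500"], "less")
  expect_true(st$significant[st$segment == "S0_50"])
  expect_true(st$significant[st$segment == "S200_700"])
  # all-positive sample rejects lambda = 0 upward at 95%
  expect_lt(st$p_value[st$segment == "S0_50"], 0.05)
})

test_that("the analysis pipeline emits one row per trial, filter and cell", {
  cfg <- sim_config(n_participants = 1, n_sessions = 1, n_positions = 2,
                    seed = 13)
  trials <- generate_dataset(cfg)
  lle <- analyze_lle(trials, filters = c("N", "SG7"))
  expect_equal(nrow(lle), 2 * 2 * 5)
  expect_true(all(c("trial_id", "filter", "segment", "tau", "m", "lambda",
                    "feasible", "reason", "r2") %in% names(lle)))
  dfa_res <- analyze_dfa(trials, filters = c("N", "W8"))
  expect_equal(nrow(dfa_res), 2 * 2 * 4)
  expect_true(all(is.finite(dfa_res$alpha)))
  expect_true(all(dfa_res$dfa_label %in% dfa_param_grid()$label))
})

test_that("analysis results are reproducible across runs", {
  cfg <- sim_config(n_participants = 1, n_sessions = 1, n_positions = 2,
                    seed = 13)
  a <- analyze_dfa(generate_dataset(cfg), filters = "N")
  b <- analyze_dfa(generate_dataset(cfg), filters = "N")
  expect_identical(a, b)
})
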