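trial_sampling_rate <- function(trials, sampling_rate = NULL) {
  if (!is.null(sampling_rate)) return(sampling_rate)
  cfg <- attr(trials, "config")
  if (!is.null(cfg)) cfg$sampling_rate else 1000
}

#' Per-trial embedding parameters and segment-wise Lyapunov exponents
#'
#' Runs the dynamical branch of the pipeline over a trial set: each position
#' trace is filtered, differentiated to velocity, embedding parameters
#' (delay from the mutual-information minimum, dimension from false nearest
#' neighbours) are estimated on the full velocity series, and the largest
#' Lyapunov exponent is estimated per analysis segment via the
#' nearest-neighbour divergence curve. Exponents are reported per
#' millisecond. Segments whose reconstruction is impossible (too short for
#' the trial's embedding, no admissible neighbours, or dominated by
#' zero-distance pairs) are kept as infeasible rows with a reason code.
#'
#' @param trials A `trial_set` tibble.
#' @param filters Character vector of [filter_labels()] to apply.
#' @param segments Segment table as from [segment_specs()].
#' @param sampling_rate Hz; defaults to the generator config attached to
#'   `trials`.
#' @param max_lag,m_max,R,drop_threshold Embedding-estimation settings passed
#'   to [select_embedding()].
#' @param max_steps Divergence-curve length in steps.
#' @param fit_range Steps used in the slope fit (default as in
#'   [estimate_lle()]).
#' @return A tibble with one row per trial x filter x segment:
#'   `trial_id`, `filter`, `segment`, `tau`, `m`, `tau_flagged`, `m_flagged`,
#'   `lambda`, `feasible`, `reason`, `r2`, `dynamics`.
#' @export
analyze_lle <- function(trials, filters = "N", segments = segment_specs(),
                        sampling_rate = NULL, max_lag = 100, m_max = 10,
                        R = 10, drop_threshold = 0.01, max_steps = 80,
                        fit_range = NULL) {
  fs <- trial_sampling_rate(trials, sampling_rate)
  dt_ms <- 1000 / fs
  rows <- vector("list", nrow(trials) * length(filters) * nrow(segments))
  idx <- 0L
  for (i in seq_len(nrow(trials))) {
    pos <- trials$trace[[i]]
    for (fl in filters) {
      vel <- differentiate(apply_filter(pos, fl), fs)
      emb_par <- tryCatch(
        select_embedding(vel, max_lag = max_lag, m_max = m_max, R = R,
                         drop_threshold = drop_threshold),
        error = function(e) NULL
      )
      for (s in seq_len(nrow(segments))) {
        idx <- idx + 1L
        base <- tibble(
          trial_id = trials$trial_id[i],
          filter = fl,
          segment = segments$label[s],
          tau = if (is.null(emb_par)) NA_integer_ else emb_par$tau,
          m = if (is.null(emb_par)) NA_integer_ else emb_par$m,
          tau_flagged = if (is.null(emb_par)) NA else emb_par$tau_flagged,
          m_flagged = if (is.null(emb_par)) NA else emb_par$m_flagged
        )
        if (is.null(emb_par)) {
          rows[[idx]] <- mutate(base, lambda = NA_real_, feasible = FALSE,
                                reason = "too_short", r2 = NA_real_,
                                dynamics = "infeasible")
          next
        }
        seg <- extract_segment(vel, segments$start_ms[s], segments$end_ms[s],
                               fs)
        res <- segment_lle(seg, emb_par$tau, emb_par$m, dt_ms, max_steps,
                           fit_range)
        rows[[idx]] <- mutate(base,
          lambda = res$lambda, feasible = res$feasible, reason = res$reason,
          r2 = res$r_squared, dynamics = classify_dynamics(res)
        )
      }
    }
  }
  list_rbind(rows[seq_len(idx)])
}

segment_lle <- function(seg, tau, m, dt_ms, max_steps, fit_range) {
  M <- length(seg) - (m - 1L) * tau
  if (M < 10L) {
    out <- list(lambda = NA_real_, r_squared = NA_real_, dt = dt_ms,
                n_pairs = 0L, feasible = FALSE, reason = "too_short")
    class(out) <- "lle_result"
    return(out)
  }
  emb <- delay_embed(seg, tau, m)
  # the full tau*m window would swallow short latency segments whole;
  # shrink it so at least ~half of the candidate neighbours stay admissible
  theiler <- max(1L, min(tau * m, (M - 2L) %/% 4L))
  curve <- divergence_curve(emb, theiler = theiler, max_steps = max_steps,
                            dt = dt_ms)
  estimate_lle(curve, fit_range = fit_range)
}

#' Per-trial detrended fluctuation analysis
#'
#' Runs the fractal branch of the pipeline: each position trace is filtered,
#' differentiated to velocity over the full trial, and analysed with every
#' DFA parameter combination in `params`.
#'
#' @param trials A `trial_set` tibble.
#' @param filters Character vector of [filter_labels()].
#' @param params DFA parameter grid as from [dfa_param_grid()].
#' @param sampling_rate Hz; defaults to the config attached to `trials`.
#' @param on `"velocity"` (default) or `"position"`.
#' @return A tibble with one row per trial x filter x parameter set:
#'   `trial_id`, `filter`, `dfa_label`, `alpha`, `hurst`, `r2`.
#' @export
analyze_dfa <- function(trials, filters = filter_labels(),
                        params = dfa_param_grid(), sampling_rate = NULL,
                        on = c("velocity", "position")) {
  on <- match.arg(on)
  fs <- trial_sampling_rate(trials, sampling_rate)
  rows <- vector("list", nrow(trials) * length(filters) * nrow(params))
  idx <- 0L
  for (i in seq_len(nrow(trials))) {
    pos <- trials$trace[[i]]
    for (fl in filters) {
      x <- apply_filter(pos, fl)
      if (on == "velocity") x <- differentiate(x, fs)
      for (p in seq_len(nrow(params))) {
        idx <- idx + 1L
        res <- dfa(x, detrend = params$detrend[p],
                   min_scale = params$min_scale[p],
                   max_scale = params$max_scale[p])
        rows[[idx]] <- tibble(
          trial_id = trials$trial_id[i], filter = fl,
          dfa_label = params$label[p], alpha = res$alpha, hurst = res$hurst,
          r2 = res$r_squared
        )
      }
    }
  }
  list_rbind(rows[seq_len(idx)])
}

#' Full analysis of a trial set
#'
#' Convenience wrapper running both pipeline branches; anomalous trials are
#' excluded first.
#'
#' @param trials A `trial_set` tibble.
#' @param lle_filters,dfa_filters Filter labels for each branch.
#' @param ... Passed on to [analyze_lle()].
#' @return A list with elements `lle` and `dfa` (tibbles) of class
#'   `ocd_analysis`.
#' @export
analyze_dataset <- function(trials, lle_filters = "N",
                            dfa_filters = filter_labels(), ...) {
  trials <- exclude_anomalous(trials)
  out <- list(
    lle = analyze_lle(trials, filters = lle_filters, ...),
    dfa = analyze_dfa(trials, filters = dfa_filters)
  )
  class(out) <- "ocd_analysis"
  out
}

#' Group means and standard deviations of a metric
#'
#' Per-group mean and SD of a per-trial metric (e.g. `lambda`, `alpha`,
#' `tau`, `m`). For Lyapunov metrics, infeasible rows are excluded and their
#' count reported, mirroring the per-filter infeasibility accounting of the
#' original analysis.
#'
#' @param records A results tibble from [analyze_lle()] or [analyze_dfa()].
#' @param metric Column name of the metric (string).
#' @param group Grouping column(s), default `"filter"`.
#' @return A tibble with `mean`, `sd`, `n`, and `n_excluded` per group.
#' @export
group_summary <- function(records, metric, group = "filter") {
  stopifnot(metric %in% names(records))
  if ("feasible" %in% names(records)) {
    excl <- records %>%
      group_by(across(all_of(group))) %>%
      summarise(n_excluded = sum(!.data$feasible), .groups = "drop")
    records <- dplyr::filter(records, .data$feasible)
  } else {
    excl <- NULL
  }
  out <- records %>%
    dplyr::filter(!is.na(.data[[metric]])) %>%
    group_by(across(all_of(group))) %>%
    summarise(
      mean = mean(.data[[metric]]),
      sd = if (dplyr::n() > 1) sd(.data[[metric]]) else 0,
      n = dplyr::n(),
      .groups = "drop"
    )
  if (!is.null(excl)) out <- left_join(out, excl, by = group)
  if (nrow(out) == 0) warn("no non-empty groups")
  out
}

#' Between-group significance tests of a metric
#'
#' Follows the branching of the original analysis: a Shapiro-Wilk test on the
#' group-centred residuals decides between parametric and rank-based
#' comparisons. Normal residuals: one-way ANOVA followed by Tukey's HSD,
#' returning adjusted p-values per filter pair. Non-normal: Kruskal-Wallis
#' overall test plus pairwise two-group rank tests (unadjusted, as in the
#' source analysis, which applied no correction beyond Tukey HSD).
#'
#' @param records Results tibble.
#' @param metric Metric column name (string).
#' @param group Grouping column (string, default `"filter"`).
#' @param alpha Significance level for the `significant` flag.
#' @return A tibble of class `significance_table` with columns `pair`,
#'   `group1`, `group2`, `p_value`, `significant`; attributes `test`
#'   (`"tukey_hsd"` or `"kruskal"`), `shapiro_p`, `overall_p`.
#' @export
run_tests <- function(records, metric, group = "filter", alpha = 0.05) {
  stopifnot(metric %in% names(records), group %in% names(records))
  if ("feasible" %in% names(records)) {
    records <- dplyr::filter(records, .data$feasible)
  }
  records <- records[!is.na(records[[metric]]), , drop = FALSE]
  sizes <- table(records[[group]])
  small <- names(sizes)[sizes < 3]
  if (length(small) > 0) {
    warn(sprintf("skipping groups with fewer than 3 records: %s",
                 paste(small, collapse = ", ")))
    records <- records[!records[[group]] %in% small, , drop = FALSE]
  }
  if (length(unique(records[[group]])) < 2) {
    abort("need at least two groups of size >= 3")
  }
  df <- data.frame(value = records[[metric]],
                   grp = factor(records[[group]]))
  resid <- df$value - stats::ave(df$value, df$grp)
  sw_sample <- if (length(resid) > 5000) sample(resid, 5000) else resid
  shapiro_p <- tryCatch(shapiro.test(sw_sample)$p.value,
                        error = function(e) NA_real_)

  if (!is.na(shapiro_p) && shapiro_p > alpha) {
    fit <- aov(value ~ grp, data = df)
    overall_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- TukeyHSD(fit)$grp
    pairs <- rownames(tk)
    parts <- strsplit(pairs, "-", fixed = TRUE)
    out <- tibble(
      pair = pairs,
      group1 = vapply(parts, `[`, "", 1),
      group2 = vapply(parts, `[`, "", 2),
      p_value = unname(tk[, "p adj"]),
      significant = unname(tk[, "p adj"]) < alpha
    )
    test <- "tukey_hsd"
  } else {
    overall_p <- kruskal.test(value ~ grp, data = df)$p.value
    lv <- levels(df$grp)
    combos <- utils::combn(lv, 2)
    out <- map(seq_len(ncol(combos)), function(k) {
      g1 <- combos[1, k]; g2 <- combos[2, k]
      sub <- df[df$grp %in% c(g1, g2), ]
      p <- kruskal.test(value ~ droplevels(grp), data = sub)$p.value
      tibble(pair = paste0(g2, "-", g1), group1 = g2, group2 = g1,
             p_value = p, significant = p < alpha)
    }) %>% list_rbind()
    test <- "kruskal"
  }
  attr(out, "test") <- test
  attr(out, "shapiro_p") <- shapiro_p
  attr(out, "overall_p") <- overall_p
  class(out) <- c("significance_table", class(out))
  out
}

#' One-sided t-tests of the Lyapunov exponent's sign per segment
#'
#' For the saccadic-latency segments (0-50, 0-100, 0-200 ms) the alternative
#' hypothesis is that the true mean exponent is greater than zero (chaos);
#' for the fixation segments (200-700 and 700-1500 ms) that it is less than
#' zero (convergence). Infeasible records are excluded.
#'
#' @param records Tibble from [analyze_lle()].
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with one row per segment: `segment`, `alternative`,
#'   `mean_lambda`, `p_value`, `conf_low`, `conf_high`, `n`, `significant`.
#' @export
lle_sign_tests <- function(records, conf_level = 0.95) {
  recs <- dplyr::filter(records, .data$feasible, !is.na(.data$lambda))
  segs <- unique(recs$segment)
  out <- map(segs, function(s) {
    x <- recs$lambda[recs$segment == s]
    alt <- if (grepl("^S0_", s)) "greater" else "less"
    if (length(x) < 3) {
      return(tibble(segment = s, alternative = alt, mean_lambda = mean(x),
                    p_value = NA_real_, conf_low = NA_real_,
                    conf_high = NA_real_, n = length(x), significant = NA))
    }
    tt <- t.test(x, mu = 0, alternative = alt, conf.level = conf_level)
    tibble(
      segment = s, alternative = alt, mean_lambda = unname(tt$estimate),
      p_value = tt$p.value, conf_low = tt$conf.int[1],
      conf_high = tt$conf.int[2], n = length(x),
      significant = tt$p.value < 1 - conf_level
    )
  }) %>% list_rbind()
  out
}
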