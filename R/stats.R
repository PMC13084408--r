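#' Spearman correlation between a trial feature and reaction time
#'
#' Per-neuron, per-condition Spearman correlation between a trial-wise
#' neuronal feature (onset latency, burst strength or pre-stimulus count) and
#' saccadic reaction time. Pairs with an undefined feature value (e.g. trials
#' without a detectable latency) are dropped. Ties receive average ranks. The
#' two-sided p-value is exact for n <= 9 with untied data and uses the
#' t-approximation otherwise.
#'
#' A neuron with no pre-stimulus activity at all (every count zero) cannot be
#' ranked; by convention such a neuron is designated as having zero
#' correlation (`rho = 0`, `zero_assigned = TRUE`). This convention applies
#' only when `feature = "prestim"`.
#'
#' @param x Trial feature values.
#' @param rt Reaction times (ms), same length.
#' @param feature One of `"latency"`, `"strength"`, `"prestim"` (controls the
#'   all-zero convention).
#' @return List with `rho`, `p`, `n`, `zero_assigned`. `rho` is `NA` when
#'   fewer than 3 pairs remain or a variable is constant (and the convention
#'   does not apply).
#' @export
spearman_feature_rt <- function(x, rt, feature = c("latency", "strength",
                                                   "prestim")) {
  feature <- match.arg(feature)
  keep <- !is.na(x) & !is.na(rt)
  x <- x[keep]
  rt <- rt[keep]
  n <- length(x)
  if (feature == "prestim" && n > 0 && all(x == 0)) {
    return(list(rho = 0, p = NA_real_, n = n, zero_assigned = TRUE))
  }
  if (n < 3 || stats::sd(x) == 0 || stats::sd(rt) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, zero_assigned = FALSE))
  }
  rho <- stats::cor(rank(x), rank(rt))
  has_ties <- anyDuplicated(x) > 0 || anyDuplicated(rt) > 0
  if (n <= 9 && !has_ties) {
    p <- suppressWarnings(
      stats::cor.test(x, rt, method = "spearman", exact = TRUE)$p.value
    )
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n, zero_assigned = FALSE)
}

#' Wilcoxon signed-rank test against zero (normal approximation)
#'
#' Reduced-sample procedure: values equal to `mu` are discarded (so the
#' reported `n` counts only informative samples), the absolute deviations are
#' ranked with average ties, and the sum of positive ranks `W` is compared to
#' its null mean with a tie-corrected normal approximation (no continuity
#' correction).
#'
#' @param x Sample values.
#' @param mu Null location (default 0).
#' @return List with `W`, `z`, `p` (two-sided), `n` (non-zero samples).
#' @export
signed_rank_test <- function(x, mu = 0) {
  d <- x[!is.na(x)] - mu
  d <- d[d != 0]
  n <- length(d)
  if (n < 1) return(list(W = NA_real_, z = NA_real_, p = NA_real_, n = 0L))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu_w <- n * (n + 1) / 4
  ties <- table(abs(d))
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sig2 <= 0) return(list(W = W, z = NA_real_, p = NA_real_, n = n))
  z <- (W - mu_w) / sqrt(sig2)
  list(W = W, z = z, p = 2 * stats::pnorm(-abs(z)), n = n)
}

#' Mann-Whitney U test (normal approximation, tie-corrected)
#'
#' Rank-sum comparison of two independent samples. `U` is reported for the
#' first sample; `z` uses the tie-corrected normal approximation without
#' continuity correction.
#'
#' @param x,y The two samples.
#' @return List with `U`, `z`, `p` (two-sided), `n1`, `n2`.
#' @export
rank_sum_test <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1 || n2 < 1) {
    return(list(U = NA_real_, z = NA_real_, p = NA_real_, n1 = n1, n2 = n2))
  }
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  ties <- table(c(x, y))
  sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sig2 <= 0) return(list(U = U, z = NA_real_, p = NA_real_,
                             n1 = n1, n2 = n2))
  z <- (U - n1 * n2 / 2) / sqrt(sig2)
  list(U = U, z = z, p = 2 * stats::pnorm(-abs(z)), n1 = n1, n2 = n2)
}

#' Population test battery over per-neuron correlation records
#'
#' Two classes of population statistics over per-neuron Spearman
#' coefficients: (i) a pooled test across all levels of `by`, and (ii) one
#' test per level with Bonferroni correction over the number of levels.
#' Without `group`, values are tested against zero with the signed-rank test
#' (zero-valued samples discarded by the reduced-sample procedure; the
#' effective n is reported). With a two-level `group` column, levels are
#' compared with the Mann-Whitney U test.
#'
#' @param records Data frame with a `rho` column (NA rows dropped).
#' @param by Name of the column defining correction levels (default
#'   `"contrast"`).
#' @param group Optional name of a two-level grouping column (e.g. `"area"`);
#'   switches from one-sample to between-group testing.
#' @param alpha Family-wise significance level (default 0.05).
#' @return List with `pooled` (test on all records) and `per_level` (data
#'   frame with the level, descriptive stats, test statistic, `z`, raw `p`,
#'   Bonferroni-adjusted `p_adj = min(1, p * n_levels)` and `significant`).
#' @export
population_tests <- function(records, by = "contrast", group = NULL,
                             alpha = 0.05) {
  records <- records[!is.na(records$rho), , drop = FALSE]
  if (nrow(records) == 0) {
    warning("no records with defined rho")
    return(list(pooled = NULL, per_level = NULL))
  }
  levels_by <- sort(unique(records[[by]]))
  n_lev <- length(levels_by)
  run_test <- function(df) {
    if (is.null(group)) {
      tt <- signed_rank_test(df$rho)
      data.frame(stat = tt$W, z = tt$z, p = tt$p, n = tt$n,
                 n1 = NA, n2 = NA,
                 mean_rho = mean(df$rho), median_rho = stats::median(df$rho),
                 sem_rho = stats::sd(df$rho) / sqrt(nrow(df)))
    } else {
      g <- df[[group]]
      lv <- sort(unique(records[[group]]))
      if (length(lv) != 2) stop("'group' must have exactly 2 levels")
      x <- df$rho[g == lv[1]]
      y <- df$rho[g == lv[2]]
      tt <- rank_sum_test(x, y)
      data.frame(stat = tt$U, z = tt$z, p = tt$p, n = tt$n1 + tt$n2,
                 n1 = tt$n1, n2 = tt$n2,
                 mean_rho = mean(df$rho), median_rho = stats::median(df$rho),
                 sem_rho = stats::sd(df$rho) / sqrt(nrow(df)))
    }
  }
  pooled <- run_test(records)
  per_level <- do.call(rbind, lapply(levels_by, function(lv) {
    df <- records[records[[by]] == lv, , drop = FALSE]
    if (nrow(df) < 2) {
      warning("level ", lv, " has fewer than 2 records; omitted")
      return(NULL)
    }
    out <- run_test(df)
    out[[by]] <- lv
    out
  }))
  if (!is.null(per_level)) {
    per_level$p_adj <- pmin(1, per_level$p * n_lev)
    per_level$significant <- !is.na(per_level$p_adj) & per_level$p_adj < alpha
  }
  list(pooled = pooled, per_level = per_level)
}

#' Across-trial reliability of a neuronal parameter
#'
#' For each neuron (within each level of `by`), the across-trial sample SD of
#' a trial-wise parameter; then, across neurons, the mean and SEM of those
#' SDs. Applying the same summary to reaction time yields the behavioral
#' variability estimate.
#'
#' @param df Data frame with columns `neuron_id`, the value column, and any
#'   grouping columns.
#' @param value Name of the trial-wise value column (NA trials dropped).
#' @param by Character vector of grouping columns (default
#'   `c("contrast", "polarity")`).
#' @return List with `per_neuron` (neuron x group SDs, neurons with >= 2
#'   defined trials) and `population` (per group: `mean_sd`, `sem_sd`, `n`).
#' @export
reliability_summary <- function(df, value = "latency",
                                by = c("contrast", "polarity")) {
  df <- df[!is.na(df[[value]]), , drop = FALSE]
  key <- interaction(df[c("neuron_id", by)], drop = TRUE)
  per <- do.call(rbind, lapply(split(df, key), function(d) {
    if (nrow(d) < 2) return(NULL)
    out <- d[1, c("neuron_id", by), drop = FALSE]
    out$sd <- stats::sd(d[[value]])
    out
  }))
  rownames(per) <- NULL
  gkey <- interaction(per[by], drop = TRUE)
  pop <- do.call(rbind, lapply(split(per, gkey), function(d) {
    out <- d[1, by, drop = FALSE]
    out$mean_sd <- mean(d$sd)
    out$sem_sd <- stats::sd(d$sd) / sqrt(nrow(d))
    out$n <- nrow(d)
    out
  }))
  rownames(pop) <- NULL
  list(per_neuron = per, population = pop)
}

#' Normalized population firing rate on the fastest and slowest trial thirds
#'
#' For one condition (contrast x polarity), each neuron's trial-wise rate
#' traces are normalized to the peak of the neuron's *average* visual
#' response (peak taken inside the area-specific strength window), trials are
#' sorted by reaction time, and the fastest and slowest `floor(n/3)` trials
#' are averaged separately. Across neurons, the mean and SEM of the
#' normalized traces summarize how activity differs before fast versus slow
#' saccades.
#'
#' @param session A `"bl_session"`.
#' @param contrast,polarity Condition selector.
#' @param area `"SC"` or `"V1"` (defaults to the session area tag).
#' @param grid Time grid (ms) for the traces.
#' @param kernel Smoothing kernel.
#' @param min_trials Minimum trials per neuron (default 6).
#' @return List with `time`, matrices are collapsed to `fast_mean`,
#'   `fast_sem`, `slow_mean`, `slow_sem` (per time point), and `n_neurons`.
#'   Neurons with a non-positive average-response peak are dropped.
#' @export
fastslow_summary <- function(session, contrast, polarity, area = NULL,
                             grid = -100:300, kernel = build_kernel(),
                             min_trials = 6) {
  if (is.null(area)) area <- session$neurons$area[1]
  trials <- session$trials
  trials <- trials[trials$contrast == contrast &
                     trials$polarity == polarity, , drop = FALSE]
  sp_by_trial <- split(session$spikes$spike_time, session$spikes$trial_id)
  grp <- contrast_group_of(contrast, sort(unique(session$trials$contrast)))
  ep <- epoch_config(area, grp)
  win_idx <- grid >= ep$strength_window[1] & grid < ep$strength_window[2]
  fast_l <- slow_l <- list()
  for (nid in unique(trials$neuron_id)) {
    ct <- trials[trials$neuron_id == nid, , drop = FALSE]
    n <- nrow(ct)
    if (n < min_trials) next
    traces <- t(vapply(as.character(ct$trial_id), function(tid) {
      s <- sp_by_trial[[tid]]
      if (is.null(s)) s <- numeric(0)
      estimate_rate(s, kernel, grid)$rate
    }, numeric(length(grid))))
    avg <- colMeans(traces)
    peak <- max(avg[win_idx])
    if (peak <= 0) next
    k <- floor(n / 3)
    ord <- order(ct$reaction_time)  # stable: ties broken by trial order
    fast_l[[length(fast_l) + 1L]] <- colMeans(traces[ord[seq_len(k)], ,
                                                     drop = FALSE]) / peak
    slow_l[[length(slow_l) + 1L]] <- colMeans(traces[ord[seq(n - k + 1, n)], ,
                                                     drop = FALSE]) / peak
  }
  if (length(fast_l) == 0) stop("no neuron had enough trials")
  fast <- do.call(rbind, fast_l)
  slow <- do.call(rbind, slow_l)
  nn <- nrow(fast)
  list(
    time = grid,
    fast_mean = colMeans(fast),
    fast_sem = apply(fast, 2, stats::sd) / sqrt(nn),
    slow_mean = colMeans(slow),
    slow_sem = apply(slow, 2, stats::sd) / sqrt(nn),
    fast_traces = fast,
    slow_traces = slow,
    n_neurons = nn
  )
}

#' Per-neuron Spearman correlation records for a feature table
#'
#' Convenience driver: applies [spearman_feature_rt()] to every neuron x
#' condition cell of a [session_features()] table, honoring the latency
#' inclusion rule for the latency feature.
#'
#' @param features Output of [session_features()].
#' @param feature `"latency"`, `"strength"` or `"prestim"`.
#' @return Data frame of correlation records: `neuron_id`, `contrast`,
#'   `polarity`, `feature`, `rho`, `p`, `n_trials`, `zero_assigned`.
#' @export
correlation_records <- function(features,
                                feature = c("latency", "strength",
                                            "prestim")) {
  feature <- match.arg(feature)
  col <- switch(feature, latency = "latency", strength = "strength",
                prestim = "prestim_count")
  key <- interaction(features[c("neuron_id", "contrast", "polarity")],
                     drop = TRUE)
  out <- lapply(split(features, key), function(d) {
    if (feature == "latency" && !d$latency_included[1]) return(NULL)
    r <- spearman_feature_rt(d[[col]], d$reaction_time, feature)
    data.frame(
      neuron_id = d$neuron_id[1], contrast = d$contrast[1],
      polarity = d$polarity[1], feature = feature,
      rho = r$rho, p = r$p, n_trials = r$n, zero_assigned = r$zero_assigned
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
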