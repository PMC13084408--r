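#' Inter-spike-interval quality control
#'
#' Single-unit gate: a unit passes only if fewer than 1.5% of its within-trial
#' inter-spike intervals violate a minimal ISI of 0.8 ms.
#'
#' @param spikes_by_trial List of per-trial spike-time vectors (ms), or a
#'   single numeric vector for one continuous train.
#' @param min_isi Minimal allowed ISI (ms, default 0.8).
#' @param max_violation Maximum tolerated violation fraction (default 0.015);
#'   the unit fails when `fraction >= max_violation`.
#' @return List with `qc_pass`, `violation_fraction`, `n_isi`.
#' @export
isi_qc <- function(spikes_by_trial, min_isi = 0.8, max_violation = 0.015) {
  if (is.numeric(spikes_by_trial)) spikes_by_trial <- list(spikes_by_trial)
  isis <- unlist(lapply(spikes_by_trial, function(s) diff(sort(s))),
                 use.names = FALSE)
  if (length(isis) == 0L) {
    return(list(qc_pass = TRUE, violation_fraction = 0, n_isi = 0L))
  }
  frac <- mean(isis < min_isi)
  list(qc_pass = frac < max_violation, violation_fraction = frac,
       n_isi = length(isis))
}

# Dunn's post-hoc z tests on the pooled ranks of a Kruskal-Wallis setup,
# Bonferroni-corrected over all pairwise comparisons.
dunn_pairwise <- function(values, groups) {
  groups <- as.factor(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(groups)
  combs <- utils::combn(lv, 2)
  m <- ncol(combs)
  z <- p <- numeric(m)
  for (k in seq_len(m)) {
    a <- combs[1, k]; b <- combs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[a]] + 1 / n[[b]]))
    z[k] <- (rbar[[a]] - rbar[[b]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(
    group1 = combs[1, ], group2 = combs[2, ], z = z, p = p,
    p_adj = pmin(1, p * m)
  )
}

#' Functional classification of a neuron as visual / visual-motor
#'
#' Applies the four-window rate comparison: a visual window (40-95 ms after
#' stimulus onset), a pre-motor window (-25-0 ms relative to saccade onset),
#' a post-motor window (0-65 ms relative to saccade onset), and a baseline
#' window (final 50 ms before stimulus onset). Per-trial mean rates in the
#' four windows enter a Kruskal-Wallis omnibus test at `alpha`, followed by
#' Dunn's rank-based pairwise comparisons with Bonferroni family-wise
#' correction.
#'
#' The `"visual"` label requires visual-window activity significantly above
#' baseline. The `"motor"` label requires (i) post-motor vs baseline
#' significant, (ii) pre-motor vs post-motor significant, (iii) mean
#' pre-motor < mean post-motor, and (iv) mean pre-motor > mean baseline.
#' Neurons with both labels are `"visual-motor"`, with only the first
#' `"visual"`, with only the second `"motor-only"`, otherwise
#' `"unclassified"`.
#'
#' @param window_rates Data frame (or matrix) with per-trial mean firing
#'   rates (spikes/s) in columns `visual`, `premotor`, `postmotor`,
#'   `baseline`; one row per trial. See [neuron_window_rates()].
#' @param alpha Significance level (default 0.05).
#' @return List with `label`, the omnibus Kruskal-Wallis p-value
#'   (`kw_p`), and the Dunn post-hoc table (`posthoc`).
#' @export
classify_functional <- function(window_rates, alpha = 0.05) {
  wr <- as.data.frame(window_rates)
  need <- c("visual", "premotor", "postmotor", "baseline")
  if (!all(need %in% names(wr))) {
    stop("window_rates needs columns ", paste(need, collapse = ", "))
  }
  if (nrow(wr) < 5) {
    warning("fewer than 5 trials; neuron left unclassified")
    return(list(label = "unclassified", kw_p = NA_real_, posthoc = NULL))
  }
  values <- c(wr$visual, wr$premotor, wr$postmotor, wr$baseline)
  groups <- rep(need, each = nrow(wr))
  kw <- stats::kruskal.test(values, factor(groups))
  ph <- dunn_pairwise(values, groups)
  sig <- function(a, b) {
    row <- ph[(ph$group1 == a & ph$group2 == b) |
                (ph$group1 == b & ph$group2 == a), ]
    nrow(row) == 1 && row$p_adj < alpha
  }
  omnibus <- is.finite(kw$p.value) && kw$p.value < alpha
  mu <- colMeans(wr[need])
  visual_label <- omnibus && sig("visual", "baseline") &&
    mu[["visual"]] > mu[["baseline"]]
  motor_label <- omnibus && sig("postmotor", "baseline") &&
    sig("premotor", "postmotor") &&
    mu[["premotor"]] < mu[["postmotor"]] &&
    mu[["premotor"]] > mu[["baseline"]]
  label <- if (visual_label && motor_label) "visual-motor"
  else if (visual_label) "visual"
  else if (motor_label) "motor-only"
  else "unclassified"
  list(label = label, kw_p = kw$p.value, posthoc = ph)
}

#' Per-trial mean rates in the four classification windows
#'
#' Computes, for one neuron of a session, the per-trial mean firing rate
#' (spike count / window duration) in the visual, pre-motor, post-motor and
#' baseline windows. Saccade-aligned windows are evaluated relative to each
#' trial's `saccade_onset`.
#'
#' @param session A `"bl_session"`.
#' @param neuron_id Neuron to extract.
#' @return Data frame with columns `visual`, `premotor`, `postmotor`,
#'   `baseline` (spikes/s), one row per trial of the neuron.
#' @export
neuron_window_rates <- function(session, neuron_id) {
  ep <- epoch_config("SC", "high")
  trials <- session$trials[session$trials$neuron_id == neuron_id, ,
                           drop = FALSE]
  sp <- session$spikes[session$spikes$neuron_id == neuron_id, , drop = FALSE]
  sp_by_trial <- split(sp$spike_time, sp$trial_id)
  rate_in <- function(s, win) {
    sum(s >= win[1] & s < win[2]) / (win[2] - win[1]) * 1000
  }
  res <- t(vapply(seq_len(nrow(trials)), function(j) {
    s <- sp_by_trial[[as.character(trials$trial_id[j])]]
    if (is.null(s)) s <- numeric(0)
    sacc <- trials$saccade_onset[j]
    c(
      visual = rate_in(s, ep$visual_window),
      premotor = rate_in(s - sacc, ep$premotor_window),
      postmotor = rate_in(s - sacc, ep$postmotor_window),
      baseline = rate_in(s, ep$baseline_window)
    )
  }, numeric(4)))
  as.data.frame(res)
}

#' Visuomotor index (VMI)
#'
#' `VMI = (V - M) / (V + M)` where `V` and `M` are the baseline-subtracted
#' visual and motor burst measures of a neuron (from the delayed saccade
#' task). The index runs from +1 (no motor response above baseline, some
#' visual response) to -1 (no visual response, some motor response). A neuron
#' significantly suppressed in the motor epoch is assigned VMI = +1. The
#' returned value is clipped to `[-1, 1]` (raw baseline-subtracted measures
#' can be slightly negative without reaching suppression significance).
#'
#' @param visual_measure Baseline-subtracted visual burst measure (spikes/s).
#' @param motor_measure Baseline-subtracted motor burst measure (spikes/s).
#' @param motor_suppressed Was motor-epoch activity significantly suppressed
#'   below baseline?
#' @return VMI in `[-1, 1]`, or `NA` when `V + M == 0`.
#' @examples
#' compute_vmi(50, 0)   # +1
#' compute_vmi(0, 80)   # -1
#' compute_vmi(30, 30)  # 0
#' @export
compute_vmi <- function(visual_measure, motor_measure,
                        motor_suppressed = FALSE) {
  if (isTRUE(motor_suppressed)) return(1)
  s <- visual_measure + motor_measure
  if (s == 0) return(NA_real_)
  max(-1, min(1, (visual_measure - motor_measure) / s))
}

#' Visual and motor burst measures for the VMI
#'
#' From a delayed-task session, measures for one neuron: the visual burst as
#' the mean firing rate 50-100 ms after stimulus onset minus the pre-stimulus
#' baseline rate (-100 to -1 ms); the motor burst as the peak of the
#' trial-averaged saccade-aligned firing rate within +/-25 ms of saccade
#' onset minus the pre-go baseline rate (final 100 ms before the go signal).
#' Motor suppression is a one-sided paired Wilcoxon test (motor-epoch trial
#' rates below pre-go baseline rates) at `alpha`.
#'
#' @param session A delayed-task `"bl_session"` (needs `go_time`).
#' @param neuron_id Neuron to measure.
#' @param kernel Smoothing kernel for the motor peak rate.
#' @param alpha Significance level for the suppression test.
#' @return List with `visual_measure`, `motor_measure`, `motor_suppressed`,
#'   and `vmi`.
#' @export
vmi_measures <- function(session, neuron_id, kernel = build_kernel(),
                         alpha = 0.05) {
  trials <- session$trials[session$trials$neuron_id == neuron_id, ,
                           drop = FALSE]
  if (all(is.na(trials$go_time))) {
    stop("VMI requires a delayed-task session (go_time present)")
  }
  sp <- session$spikes[session$spikes$neuron_id == neuron_id, , drop = FALSE]
  sp_by_trial <- split(sp$spike_time, sp$trial_id)
  n <- nrow(trials)
  rate_in <- function(s, a, b) sum(s >= a & s < b) / (b - a) * 1000
  vis <- base_stim <- motor <- base_go <- numeric(n)
  motor_grid <- -25:25
  motor_traces <- matrix(0, n, length(motor_grid))
  for (j in seq_len(n)) {
    s <- sp_by_trial[[as.character(trials$trial_id[j])]]
    if (is.null(s)) s <- numeric(0)
    go <- trials$go_time[j]
    sacc <- trials$saccade_onset[j]
    vis[j] <- rate_in(s, 50, 100)
    base_stim[j] <- rate_in(s, -100, -1)
    motor[j] <- rate_in(s - sacc, -25, 25)
    base_go[j] <- rate_in(s - go, -100, -1)
    motor_traces[j, ] <- estimate_rate(s - sacc, kernel, motor_grid)$rate
  }
  visual_measure <- mean(vis) - mean(base_stim)
  motor_measure <- max(colMeans(motor_traces)) - mean(base_go)
  suppressed <- FALSE
  if (any(motor != base_go)) {
    wt <- suppressWarnings(
      stats::wilcox.test(motor, base_go, paired = TRUE,
                         alternative = "less")
    )
    suppressed <- is.finite(wt$p.value) && wt$p.value < alpha
  }
  list(
    visual_measure = visual_measure,
    motor_measure = motor_measure,
    motor_suppressed = suppressed,
    vmi = compute_vmi(visual_measure, motor_measure, suppressed)
  )
}

#' Sliding-bin VMI summary of per-neuron correlation values
#'
#' Bins neurons by VMI into overlapping bins of half-width 0.1 centered at
#' -1.0, -0.95, ..., +1.0 (step 0.05) and reports the mean, SEM and count of
#' the neurons' correlation coefficients in each bin. Empty bins are reported
#' with count 0.
#'
#' @param vmi Per-neuron VMI values in `[-1, 1]` (NA dropped with its rho).
#' @param rho Per-neuron correlation coefficients, same length.
#' @param half_width Bin half-width (default 0.1).
#' @param step Bin-center step (default 0.05).
#' @return Data frame with `bin_center`, `mean_rho`, `sem_rho`, `n`.
#' @export
vmi_binned_summary <- function(vmi, rho, half_width = 0.1, step = 0.05) {
  stopifnot(length(vmi) == length(rho))
  keep <- !is.na(vmi) & !is.na(rho)
  vmi <- vmi[keep]
  rho <- rho[keep]
  centers <- seq(-1, 1, by = step)
  res <- lapply(centers, function(cc) {
    inbin <- abs(vmi - cc) <= half_width + 1e-12
    n <- sum(inbin)
    data.frame(
      bin_center = cc,
      mean_rho = if (n > 0) mean(rho[inbin]) else NA_real_,
      sem_rho = if (n > 1) stats::sd(rho[inbin]) / sqrt(n) else
        if (n == 1) 0 else NA_real_,
      n = n
    )
  })
  do.call(rbind, res)
}
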