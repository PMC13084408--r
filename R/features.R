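#' Area- and contrast-specific analysis epochs
#'
#' Returns the epoch windows used for single-trial feature extraction. The
#' latency search and visual-response strength windows depend on the brain
#' area (SC bursts are transient, V1 bursts longer-lasting, hence an 85 ms
#' counting window in V1 versus 60 ms in SC) and on the contrast group (the
#' two lowest contrasts give later responses than the two highest):
#'
#' | area | group | latency search | strength window |
#' |------|-------|----------------|-----------------|
#' | SC   | low   | 40-110 ms      | 50-110 ms       |
#' | SC   | high  | 40-100 ms      | 40-100 ms       |
#' | V1   | low   | 30-105 ms      | 35-120 ms       |
#' | V1   | high  | 30-95 ms       | 30-115 ms       |
#'
#' The baseline epoch is always the final 50 ms before stimulus onset.
#' Strength windows are half-open `[start, end)` so adjacent epochs never
#' double-count a spike.
#'
#' @param area `"SC"` or `"V1"`.
#' @param contrast_group `"low"` (two lowest contrasts) or `"high"` (two
#'   highest).
#' @return List with `latency_window`, `strength_window`, `baseline_window`
#'   (each a length-2 ms vector) and the classification windows used
#'   downstream (`visual_window`, `premotor_window`, `postmotor_window`).
#' @export
epoch_config <- function(area = c("SC", "V1"),
                         contrast_group = c("low", "high")) {
  area <- match.arg(area)
  contrast_group <- match.arg(contrast_group)
  key <- paste(area, contrast_group)
  latency_window <- switch(key,
    "SC low" = c(40, 110), "SC high" = c(40, 100),
    "V1 low" = c(30, 105), "V1 high" = c(30, 95)
  )
  strength_window <- switch(key,
    "SC low" = c(50, 110), "SC high" = c(40, 100),
    "V1 low" = c(35, 120), "V1 high" = c(30, 115)
  )
  list(
    area = area,
    contrast_group = contrast_group,
    latency_window = latency_window,
    strength_window = strength_window,
    baseline_window = c(-50, 0),
    visual_window = c(40, 95),     # post stimulus
    premotor_window = c(-25, 0),   # relative to saccade onset
    postmotor_window = c(0, 65)    # relative to saccade onset
  )
}

# Contrast group of each contrast relative to the set present in a session:
# the two lowest contrasts are "low", everything else "high".
contrast_group_of <- function(contrast, all_contrasts) {
  lows <- sort(unique(all_contrasts))[1:min(2, length(unique(all_contrasts)))]
  ifelse(contrast %in% lows, "low", "high")
}

#' Burst-onset detection threshold from pre-stimulus activity
#'
#' The single-trial latency detector uses a threshold set 2 standard
#' deviations above the mean pre-stimulus activity across trials: given the
#' per-trial mean pre-stimulus firing rates of one neuron in one condition,
#' `theta = mean + 2 * SD` (sample SD, n-1 denominator).
#'
#' @param prestim_trial_means Per-trial mean pre-stimulus rates (spikes/s),
#'   length >= 2.
#' @param n_sd Number of SDs above the mean (default 2).
#' @return Threshold in spikes/s.
#' @examples
#' detection_threshold(c(8, 10, 12))  # 10 + 2*2 = 14
#' @export
detection_threshold <- function(prestim_trial_means, n_sd = 2) {
  if (length(prestim_trial_means) < 2) {
    stop("need at least 2 trials to set a detection threshold")
  }
  mean(prestim_trial_means) + n_sd * stats::sd(prestim_trial_means)
}

#' Detect single-trial visual response onset latency
#'
#' Peak-and-backward-walk detector on a single-trial firing-rate trace:
#' \enumerate{
#'   \item Find the peak firing rate within the search window (first time of
#'     the maximum if tied). If the peak is below the threshold, the trial has
#'     no detectable response.
#'   \item Walk backward in time from the peak until the rate has been below
#'     the threshold for at least 5 ms, i.e. find the latest time `t_c` before
#'     the peak such that the rate is subthreshold at every grid time in
#'     `[t_c - 5, t_c]`. Shorter subthreshold dips are walked through (they
#'     are noise, not the pre-burst silence). If no such run exists down to
#'     the window start, the trial is undefined.
#'   \item The latency is the time of the earliest spike strictly after `t_c`
#'     and at or before the peak time -- the "last spike before the threshold
#'     crossing" seen from the peak walking backward.
#' }
#'
#' @param trace A `"bl_rate_trace"` (or list with `time`, `rate` on a 1 ms
#'   grid) covering `window[1] - 5` through `window[2]`.
#' @param spikes Spike times of the trial (ms).
#' @param theta Detection threshold (spikes/s), from [detection_threshold()].
#' @param window Latency search window (ms pair), e.g. from [epoch_config()].
#' @param run_ms Minimum subthreshold run (ms, default 5).
#' @return Latency in ms, or `NA_real_` when undefined.
#' @export
detect_latency <- function(trace, spikes, theta, window, run_ms = 5) {
  time <- trace$time
  rate <- trace$rate
  if (length(window) != 2 || window[2] <= window[1]) stop("empty window")
  if (time[1] > window[1] - run_ms || time[length(time)] < window[2]) {
    stop("trace must cover the window and ", run_ms, " ms before it")
  }
  in_win <- which(time >= window[1] & time <= window[2])
  peak_i <- in_win[which.max(rate[in_win])]
  if (rate[peak_i] < theta) return(NA_real_)
  win_start_i <- in_win[1]
  if (peak_i - 1 < win_start_i) return(NA_real_)
  sub <- rate < theta
  tc_i <- NA_integer_
  for (j in seq(peak_i - 1, win_start_i)) {
    if (all(sub[(j - run_ms):j])) {
      tc_i <- j
      break
    }
  }
  if (is.na(tc_i)) return(NA_real_)
  t_c <- time[tc_i]
  cand <- spikes[spikes > t_c & spikes <= time[peak_i]]
  if (length(cand) == 0L) return(NA_real_)
  min(cand)
}

#' Baseline-subtracted visual response strength
#'
#' Counts the spikes of one trial in the stimulus-aligned visual response
#' epoch (half-open `[start, end)`) and subtracts the mean baseline spike
#' count of the same neuron and condition across trials.
#'
#' @param spikes Spike times of the trial (ms).
#' @param strength_window Length-2 ms window.
#' @param baseline_mean_count Across-trial mean spike count in the baseline
#'   epoch (same duration scale: raw counts).
#' @return Baseline-subtracted spike count (may be negative).
#' @export
burst_strength <- function(spikes, strength_window, baseline_mean_count) {
  if (length(strength_window) != 2 || strength_window[2] <= strength_window[1]) {
    stop("malformed strength window")
  }
  sum(spikes >= strength_window[1] & spikes < strength_window[2]) -
    baseline_mean_count
}

#' Pre-stimulus state of a trial
#'
#' Spike count in the final 50 ms before stimulus onset, `[-50, 0)` ms.
#'
#' @param spikes Spike times of the trial (ms, stimulus-aligned).
#' @param window Baseline window (default `c(-50, 0)`), half-open.
#' @return Integer spike count.
#' @export
prestim_state <- function(spikes, window = c(-50, 0)) {
  sum(spikes >= window[1] & spikes < window[2])
}

#' Neuron inclusion rule for latency analyses
#'
#' A neuron enters a latency analysis for a given condition only if its
#' trial-wise onset latency could be estimated on at least 60% of the
#' condition's trials.
#'
#' @param detected Logical vector (one per trial): latency defined?
#' @param min_fraction Minimum detected fraction (default 0.60).
#' @return `TRUE` if the neuron is included.
#' @export
latency_inclusion <- function(detected, min_fraction = 0.60) {
  if (length(detected) < 1) stop("need at least 1 trial")
  mean(detected) >= min_fraction
}

#' Extract per-trial burst features for every neuron of a session
#'
#' Runs the full single-trial feature extraction: causal-kernel rate
#' estimation, per-condition detection threshold (2 SD above the mean
#' pre-stimulus rate), peak-and-backward-walk latency detection,
#' baseline-subtracted strength counts, and pre-stimulus counts.
#'
#' The pre-stimulus rate entering the threshold is the per-trial mean of the
#' kernel-smoothed rate over the 50 ms baseline window, so threshold and
#' trace are on the same scale.
#'
#' @param session A `"bl_session"` from [generate_session()] or
#'   [read_session()].
#' @param area `"SC"` or `"V1"`; defaults to the session's area tag.
#' @param kernel Smoothing kernel (default [build_kernel()]).
#' @param min_fraction Latency-inclusion fraction (default 0.60).
#' @return Data frame with one row per neuron x trial: `neuron_id`,
#'   `trial_id`, `contrast`, `polarity`, `contrast_group`, `reaction_time`,
#'   `latency` (ms or NA), `detected`, `strength`, `prestim_count`, `theta`
#'   (the condition's detection threshold) and `latency_included` (the
#'   per-condition inclusion flag, replicated over the condition's trials).
#' @export
session_features <- function(session, area = NULL, kernel = build_kernel(),
                             min_fraction = 0.60) {
  stopifnot(inherits(session, "bl_session") || is.list(session))
  if (is.null(area)) area <- session$neurons$area[1]
  trials <- session$trials
  spikes <- session$spikes
  all_contrasts <- sort(unique(trials$contrast))
  sp_by_trial <- split(spikes$spike_time, spikes$trial_id)
  # Threshold baseline: the full recorded pre-stimulus period. A longer
  # window than the 50 ms baseline epoch stabilizes the across-trial SD that
  # sets the detection threshold.
  base_grid <- (session$window[1] + 50):-1
  out <- vector("list", 64)
  k_out <- 0L
  for (nid in unique(trials$neuron_id)) {
    ntr <- trials[trials$neuron_id == nid, , drop = FALSE]
    for (pol in unique(ntr$polarity)) {
      for (con in unique(ntr$contrast)) {
        ct <- ntr[ntr$polarity == pol & ntr$contrast == con, , drop = FALSE]
        if (nrow(ct) < 2) next
        grp <- contrast_group_of(con, all_contrasts)
        ep <- epoch_config(area, grp)
        lat_grid <- (ep$latency_window[1] - 5):ep$latency_window[2]
        tid <- as.character(ct$trial_id)
        sp <- sp_by_trial[tid]
        sp[vapply(sp, is.null, logical(1))] <- list(numeric(0))
        names(sp) <- tid  # trials absent from the spike table keep their id
        # per-trial mean pre-stimulus rate (kernel-smoothed)
        prestim_rate <- vapply(sp, function(s) {
          mean(estimate_rate(s[s < 0], kernel, base_grid)$rate)
        }, numeric(1))
        theta <- detection_threshold(prestim_rate)
        base_counts <- vapply(sp, prestim_state, numeric(1),
                              window = ep$baseline_window)
        base_mean <- mean(base_counts)
        latency <- vapply(seq_along(sp), function(j) {
          s <- sp[[j]]
          tr <- estimate_rate(s[s <= ep$latency_window[2] + 1], kernel,
                              lat_grid)
          detect_latency(tr, s, theta, ep$latency_window)
        }, numeric(1))
        strength <- vapply(sp, burst_strength, numeric(1),
                           strength_window = ep$strength_window,
                           baseline_mean_count = base_mean)
        detected <- !is.na(latency)
        k_out <- k_out + 1L
        out[[k_out]] <- data.frame(
          neuron_id = nid,
          trial_id = ct$trial_id,
          contrast = con,
          polarity = pol,
          contrast_group = grp,
          reaction_time = ct$reaction_time,
          latency = latency,
          detected = detected,
          strength = strength,
          prestim_count = base_counts,
          theta = theta,
          latency_included = latency_inclusion(detected, min_fraction),
          row.names = NULL
        )
      }
    }
  }
  res <- do.call(rbind, out[seq_len(k_out)])
  rownames(res) <- NULL
  res
}
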