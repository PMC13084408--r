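# Independent brute-force oracles and small fixture builders used across the
# test files. These deliberately re-derive results by exhaustive enumeration
# or direct formulas, independent of the package's code paths.

# Brute-force latency detector: enumerate every candidate crossing time t_c
# (any grid time before the peak whose trailing run_ms+1 grid points are all
# subthreshold), take the latest, then the earliest spike in (t_c, t_peak].
oracle_latency <- function(time, rate, spikes, theta, window, run_ms = 5) {
  in_win <- which(time >= window[1] & time <= window[2])
  peak_i <- in_win[which.max(rate[in_win])]
  if (rate[peak_i] < theta) return(NA_real_)
  cand <- integer(0)
  for (j in seq_along(time)) {
    if (time[j] < window[1] || time[j] >= time[peak_i]) next
    idx <- which(time >= time[j] - run_ms & time <= time[j])
    if (length(idx) == run_ms + 1 && all(rate[idx] < theta)) {
      cand <- c(cand, j)
    }
  }
  if (length(cand) == 0) return(NA_real_)
  t_c <- time[max(cand)]
  sp <- sort(spikes[spikes > t_c & spikes <= time[peak_i]])
  if (length(sp) == 0) NA_real_ else sp[1]
}

# Hand-built session bundle with fully deterministic spikes (no simulator
# involvement), for exercising downstream code on known inputs.
make_fixed_session <- function(n_neurons = 2, n_trials = 6,
                               spike_template = c(-40, -10, 55, 58, 61, 64,
                                                  70, 120),
                               rt = NULL) {
  if (is.null(rt)) rt <- seq(150, by = 10, length.out = n_trials)
  trials <- do.call(rbind, lapply(seq_len(n_neurons), function(i) {
    data.frame(
      trial_id = (i - 1) * n_trials + seq_len(n_trials),
      neuron_id = i, contrast = 100, polarity = "dark",
      reaction_time = rt, go_time = NA_real_, saccade_onset = rt
    )
  }))
  spikes <- do.call(rbind, lapply(seq_len(nrow(trials)), function(j) {
    data.frame(neuron_id = trials$neuron_id[j],
               trial_id = trials$trial_id[j],
               spike_time = spike_template)
  }))
  structure(
    list(
      trials = trials, spikes = spikes,
      neurons = data.frame(neuron_id = seq_len(n_neurons), area = "SC"),
      latents = NULL, window = c(-200, 600), config = NULL
    ),
    class = "bl_session"
  )
}

# One-neuron, one-condition simulator wrapper used by classification tests.
quick_session <- function(profile, n_trials = 40, seed = 1, ...) {
  cfg <- sim_config(profile, n_neurons = 1,
                    n_trials_per_condition = n_trials,
                    contrasts = 100, polarities = "dark", seed = seed, ...)
  generate_session(cfg)
}

skewness <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
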