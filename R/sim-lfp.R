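#' Generate a laminar LFP array with a known current sink
#'
#' Forward model for testing current-source-density (CSD) analysis. A
#' depth profile of current sources and sinks is constructed with a focal
#' sink (negative CSD) at `sink_channel`, flanked by two balancing sources.
#' The profile is integrated twice over depth -- the inverse of the second
#' spatial difference that CSD analysis applies -- to produce a potential
#' profile, which is then modulated by a stimulus-locked temporal envelope
#' covering 0-100 ms after stimulus onset, and corrupted by white Gaussian
#' noise.
#'
#' @param sink_channel Index (1-based) of the sink channel; must be an
#'   interior channel (the second spatial difference is undefined at the
#'   edges).
#' @param n_channels Number of channels (>= 5).
#' @param spacing Inter-channel spacing (micrometers).
#' @param noise_sd Gaussian noise SD in the same arbitrary voltage units as
#'   the signal.
#' @param n_trials Number of trials.
#' @param time Time grid (ms relative to stimulus onset).
#' @param seed Integer seed.
#' @return A list of class `"bl_lfp"`: `lfp` (array channel x time x trial),
#'   `time`, `spacing`, and the ground truth `sink_channel` and `csd_profile`
#'   (per-channel CSD amplitude, interior channels).
#' @export
generate_laminar_lfp <- function(sink_channel, n_channels = 16, spacing = 50,
                                 noise_sd = 0, n_trials = 10,
                                 time = -50:200, seed = 1L) {
  if (n_channels < 5) stop("need at least 5 channels")
  if (sink_channel <= 1 || sink_channel >= n_channels) {
    stop("sink_channel must be an interior channel")
  }
  set.seed(as.integer(seed))
  # CSD depth profile: unit sink flanked by two +0.5 sources (current
  # conservation over the column).
  csd <- numeric(n_channels)
  csd[sink_channel] <- -1
  csd[sink_channel - 1] <- csd[sink_channel - 1] + 0.5
  csd[sink_channel + 1] <- csd[sink_channel + 1] + 0.5
  # Double integration over depth: second difference of phi equals
  # -csd * spacing^2 (so the analysis stage recovers csd with sinks
  # negative). phi built with zero value and slope at channel 1.
  phi <- numeric(n_channels)
  for (i in 2:(n_channels - 1)) {
    phi[i + 1] <- 2 * phi[i] - phi[i - 1] - csd[i] * spacing^2
  }
  phi <- phi / max(abs(phi))  # arbitrary voltage units
  envelope <- ifelse(time >= 0 & time <= 100,
                     sin(pi * time / 100)^2, 0)
  signal <- outer(phi, envelope)  # channel x time
  lfp <- array(rep(signal, n_trials),
               dim = c(n_channels, length(time), n_trials))
  if (noise_sd > 0) {
    lfp <- lfp + stats::rnorm(length(lfp), 0, noise_sd)
  }
  structure(
    list(
      lfp = lfp, time = time, spacing = spacing,
      sink_channel = sink_channel,
      csd_profile = csd[2:(n_channels - 1)]
    ),
    class = "bl_lfp"
  )
}

#' Generate a biphasic spike waveform template
#'
#' Produces a mean extracellular action-potential waveform with a negative
#' trough followed by a positive peak, separated by a requested trough-to-peak
#' interval. The two phases are Gaussian bumps whose widths scale with the
#' requested interval, so the measured trough-to-peak width equals the request
#' to within half a sample.
#'
#' @param trough_to_peak Requested trough-to-peak interval (microseconds).
#' @param sampling_period Sampling period (microseconds), e.g. 25.
#' @param peak_ratio Amplitude of the positive peak relative to the trough
#'   depth (0 < ratio <= 1).
#' @param noise_sd Gaussian amplitude noise added to the template (relative
#'   to a trough depth of 1).
#' @param seed Integer seed (only used when `noise_sd > 0`).
#' @return A list of class `"bl_waveform"`: `amplitude` (arbitrary units),
#'   `time` (microseconds), `sampling_period`.
#' @export
generate_waveform <- function(trough_to_peak, sampling_period = 25,
                              peak_ratio = 0.5, noise_sd = 0, seed = 1L) {
  if (!is.finite(trough_to_peak) || trough_to_peak <= 0) {
    stop("trough_to_peak must be > 0")
  }
  if (sampling_period <= 0) stop("sampling_period must be > 0")
  if (trough_to_peak < 2 * sampling_period) {
    stop("trough_to_peak smaller than 2 samples cannot be represented")
  }
  total <- max(1500, trough_to_peak * 3 + 600)
  time <- seq(0, total, by = sampling_period)
  t_trough <- total / 3
  t_peak <- t_trough + trough_to_peak
  # sigma = width/4 keeps the two phases nearly non-interacting, so the
  # extrema stay at the programmed positions.
  sig <- trough_to_peak / 4
  amp <- -exp(-((time - t_trough) / sig)^2) +
    peak_ratio * exp(-((time - t_peak) / sig)^2)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    amp <- amp + stats::rnorm(length(amp), 0, noise_sd)
  }
  structure(
    list(amplitude = amp, time = time, sampling_period = sampling_period,
         true_width = trough_to_peak),
    class = "bl_waveform"
  )
}
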