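#' Current-source-density profile and input-layer identification
#'
#' Averages the stimulus-aligned LFP across trials, takes the second spatial
#' difference across depth,
#'
#'   csd_i(t) = -(phi_{i-1}(t) - 2 phi_i(t) + phi_{i+1}(t)) / spacing^2 ,
#'
#' signed so that current sinks are negative, and identifies the input layer
#' as the channel with the strongest sink (most negative CSD) averaged over
#' 0-100 ms after stimulus onset. Channels are then split into superficial
#' and deep relative to the input channel: at 50 micrometer spacing (or
#' finer) the input channel plus one adjacent channel on each side act as
#' the separator; at coarser spacings only the input channel itself does.
#'
#' @param lfp Channel x time matrix, or channel x time x trial array (trials
#'   are averaged first). Channel 1 is the most superficial.
#' @param spacing Inter-channel spacing (micrometers), uniform.
#' @param time Time grid (ms relative to stimulus onset), length matching
#'   `ncol`.
#' @param sink_window Window over which the sink is averaged (ms, default
#'   0-100).
#' @return List of class `"bl_csd"`: `csd` (interior-channel x time matrix),
#'   `channels` (interior channel indices), `input_channel`, `layer_map`
#'   (per-channel `"superficial"` / `"input"` / `"deep"`), `spacing`, `time`.
#' @export
csd_from_lfp <- function(lfp, spacing, time, sink_window = c(0, 100)) {
  if (length(dim(lfp)) == 3) lfp <- apply(lfp, c(1, 2), mean)
  if (!is.matrix(lfp)) stop("lfp must be a channel x time matrix or array")
  nch <- nrow(lfp)
  if (nch < 3) stop("need at least 3 channels")
  if (length(spacing) > 1) {
    if (length(unique(round(diff(spacing), 9))) > 1) {
      stop("non-uniform channel spacing")
    }
    spacing <- diff(spacing)[1]
  }
  if (length(time) != ncol(lfp)) stop("time grid does not match lfp")
  interior <- 2:(nch - 1)
  csd <- -(lfp[interior - 1, , drop = FALSE] -
             2 * lfp[interior, , drop = FALSE] +
             lfp[interior + 1, , drop = FALSE]) / spacing^2
  tsel <- time >= sink_window[1] & time <= sink_window[2]
  sink_mean <- rowMeans(csd[, tsel, drop = FALSE])
  input_channel <- interior[which.min(sink_mean)]
  adjacency <- if (spacing <= 50) 1L else 0L
  sep <- max(1, input_channel - adjacency):min(nch, input_channel + adjacency)
  layer_map <- rep("deep", nch)
  layer_map[seq_len(nch) < min(sep)] <- "superficial"
  layer_map[sep] <- "input"
  structure(
    list(csd = csd, channels = interior, input_channel = input_channel,
         layer_map = layer_map, spacing = spacing, time = time),
    class = "bl_csd"
  )
}

#' Zero-phase LFP filtering
#'
#' Band-pass (Butterworth, forward-backward via `signal::filtfilt`) followed
#' by an optional low-pass, both zero-phase so that filtering introduces no
#' group delay -- a filtered impulse peaks at the impulse time.
#'
#' @param x Numeric vector, or channel x time matrix (filtered along time).
#' @param fs Sampling rate (Hz).
#' @param band Band-pass corners (Hz); use `c(0, hi)` for pure low-pass.
#' @param lowpass Optional additional low-pass corner (Hz), `NA` to skip.
#' @param order Butterworth order per pass (default 2).
#' @return Filtered data, same shape as `x`.
#' @export
lfp_preprocess <- function(x, fs, band = c(0.7, 300), lowpass = 100,
                           order = 2) {
  ny <- fs / 2
  if (any(band >= ny) || (!is.na(lowpass) && lowpass >= ny)) {
    stop("filter corners must be below the Nyquist frequency ", ny, " Hz")
  }
  filt1 <- function(v) {
    if (band[1] > 0) {
      bf <- signal::butter(order, band / ny, type = "pass")
    } else {
      bf <- signal::butter(order, band[2] / ny, type = "low")
    }
    v <- signal::filtfilt(bf, v)
    if (!is.na(lowpass)) {
      lf <- signal::butter(order, lowpass / ny, type = "low")
      v <- signal::filtfilt(lf, v)
    }
    v
  }
  if (is.matrix(x)) t(apply(x, 1, filt1)) else filt1(x)
}

#' Area under the ROC curve between two score samples
#'
#' Rank-based AUROC: the probability that a draw from `pos` exceeds a draw
#' from `neg`, with ties counted half. Identical samples give 0.5.
#'
#' @param neg,pos Numeric score samples.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(neg, pos) {
  n1 <- length(pos)
  n2 <- length(neg)
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty")
  r <- rank(c(pos, neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Waveform quality from pre-spike versus spike amplitude separation
#'
#' For a set of spike-waveform snippets of one unit, quantifies how well the
#' spike stands out of the noise: the per-snippet amplitude (signal minimum)
#' is collected in a pre-spike interval (the first `pre_frac` of the snippet)
#' and in a spike interval (within `spike_half_us` of the trough of the mean
#' waveform), and the AUROC between the two amplitude distributions is
#' computed (spike amplitudes are more negative, so separation drives the
#' AUROC toward 1). Units pass the quality gate at AUROC >= 0.95.
#'
#' @param snippets Snippet x sample matrix of waveform amplitudes.
#' @param sampling_period Sampling period (microseconds, default 25).
#' @param pre_frac Fraction of the snippet treated as pre-spike (default
#'   0.2).
#' @param spike_half_us Half-width of the spike interval around the trough
#'   (microseconds, default 200).
#' @param threshold Quality gate (default 0.95).
#' @return List with `auroc_quality` and `pass`.
#' @export
waveform_quality <- function(snippets, sampling_period = 25, pre_frac = 0.2,
                             spike_half_us = 200, threshold = 0.95) {
  snippets <- as.matrix(snippets)
  m <- ncol(snippets)
  if (nrow(snippets) < 2 || m < 5) stop("need a snippet x sample matrix")
  pre_cols <- seq_len(max(1, floor(pre_frac * m)))
  trough_col <- which.min(colMeans(snippets))
  half <- max(1, round(spike_half_us / sampling_period))
  spike_cols <- max(1, trough_col - half):min(m, trough_col + half)
  pre_amp <- apply(snippets[, pre_cols, drop = FALSE], 1, min)
  spike_amp <- apply(snippets[, spike_cols, drop = FALSE], 1, min)
  # spike amplitudes are more negative than noise; AUROC of pre over spike
  a <- auroc(neg = spike_amp, pos = pre_amp)
  list(auroc_quality = a, pass = a >= threshold)
}

#' Trough-to-peak width and narrow/broad classification of a mean waveform
#'
#' Upsamples the mean waveform to a 5 microsecond grid by cubic
#' interpolation, normalizes the amplitude, and measures the interval from
#' the global trough to the first positive peak after it. Waveforms narrower
#' than 350 microseconds are classed `"narrow"` (putative interneurons),
#' others `"broad"` (putative pyramidal neurons). Units failing the AUROC
#' quality gate, or without a positive post-trough peak, are `"rejected"`.
#'
#' @param mean_waveform Numeric amplitude vector, or a `"bl_waveform"`.
#' @param sampling_period Sampling period of the input (microseconds,
#'   default 25).
#' @param auroc_quality Optional quality value from [waveform_quality()];
#'   below `quality_threshold` forces rejection.
#' @param width_threshold Narrow/broad boundary (microseconds, default 350):
#'   `narrow` iff width < threshold.
#' @param quality_threshold AUROC gate (default 0.95).
#' @param target_period Upsampled grid (microseconds, default 5).
#' @return List of class `"bl_waveform_metrics"`: `trough_to_peak`
#'   (microseconds or NA), `cls` (`"narrow"`, `"broad"` or `"rejected"`),
#'   `auroc_quality`.
#' @export
waveform_width_class <- function(mean_waveform, sampling_period = 25,
                                 auroc_quality = NA_real_,
                                 width_threshold = 350,
                                 quality_threshold = 0.95,
                                 target_period = 5) {
  if (inherits(mean_waveform, "bl_waveform")) {
    sampling_period <- mean_waveform$sampling_period
    mean_waveform <- mean_waveform$amplitude
  }
  w <- as.numeric(mean_waveform)
  n <- length(w)
  reject <- function() list(trough_to_peak = NA_real_, cls = "rejected",
                            auroc_quality = auroc_quality)
  if (n < 4 || max(abs(w)) == 0) return(reject())
  t_in <- (seq_len(n) - 1) * sampling_period
  if (sampling_period > target_period) {
    t_out <- seq(0, t_in[n], by = target_period)
    w <- stats::spline(t_in, w, xout = t_out, method = "fmm")$y
  } else {
    t_out <- t_in
  }
  w <- w / max(abs(w))
  trough_i <- which.min(w)
  if (w[trough_i] >= 0 || trough_i >= length(w)) return(reject())
  post <- w[(trough_i + 1):length(w)]
  if (max(post) <= 0) return(reject())  # no positive post-trough peak
  peak_i <- trough_i + which.max(post)
  width <- t_out[peak_i] - t_out[trough_i]
  if (!is.na(auroc_quality) && auroc_quality < quality_threshold) {
    return(reject())
  }
  list(
    trough_to_peak = width,
    cls = if (width < width_threshold) "narrow" else "broad",
    auroc_quality = auroc_quality
  )
}

#' Largest-mode filtering of a multimodal amplitude distribution
#'
#' Spike-interval amplitude distributions contaminated by overlapping units
#' are multimodal; only snippets from the largest mode should enter the mean
#' waveform. Multimodality is detected by 1-D Gaussian-mixture model
#' selection (BIC over 1-3 components, `mclust`); when more than one
#' component is selected, snippets assigned to the component with the most
#' members are kept (ties broken toward the component with the larger mean
#' amplitude). Unimodal distributions keep every snippet.
#'
#' @param amplitudes Per-snippet spike-interval amplitude values (length >=
#'   some tens; the quality pipeline uses 2000).
#' @param max_modes Maximum number of mixture components tried (default 3).
#' @return List with `keep` (logical per snippet), `n_modes`, `mode_means`.
#' @importFrom mclust Mclust mclustBIC
#' @export
mode_filter <- function(amplitudes, max_modes = 3) {
  x <- as.numeric(amplitudes)
  if (length(x) < 10) stop("need at least 10 amplitude samples")
  fit <- mclust::Mclust(x, G = 1:max_modes, modelNames = c("E", "V"),
                        verbose = FALSE)
  if (is.null(fit) || fit$G == 1) {
    return(list(keep = rep(TRUE, length(x)), n_modes = 1L,
                mode_means = mean(x)))
  }
  cl <- fit$classification
  counts <- tabulate(cl, fit$G)
  best <- which(counts == max(counts))
  if (length(best) > 1) {
    means <- vapply(best, function(g) mean(x[cl == g]), numeric(1))
    best <- best[which.max(means)]
  }
  list(keep = cl == best, n_modes = fit$G,
       mode_means = as.numeric(fit$parameters$mean))
}
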