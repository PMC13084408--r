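test_that("identical config and seed give identical sessions; seeds differ", {
  cfg1 <- sim_config("SC-like", n_neurons = 2, n_trials_per_condition = 5,
                     seed = 1)
  s1 <- generate_session(cfg1)
  s2 <- generate_session(cfg1)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$trials, s2$trials)
  cfg2 <- sim_config("SC-like", n_neurons = 2, n_trials_per_condition = 5,
                     seed = 2)
  s3 <- generate_session(cfg2)
  expect_false(identical(s1$spikes, s3$spikes))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_trials_per_condition = 1), "n_trials")
  expect_error(sim_config(baseline_rate = -1), "rates")
  expect_error(sim_config(rt_noise_sd = -5), "deviations")
  expect_error(sim_config(baseline_rate = NaN), "non-finite")
})

test_that("zero couplings decouple every latent feature from reaction time", {
  cfg <- sim_config("SC-like", n_neurons = 1, n_trials_per_condition = 5000,
                    contrasts = 100, polarities = "dark",
                    coupling_latency = 0, coupling_strength = 0,
                    coupling_baseline = 0, seed = 4)
  s <- generate_session(cfg)
  d <- merge(s$latents, s$trials[c("trial_id", "reaction_time")])
  for (feat in c("latency", "amplitude", "baseline")) {
    rho <- cor(rank(d[[feat]]), rank(d$reaction_time))
    expect_lt(abs(rho), 0.1)
  }
})

test_that("burst-free neurons emit pure Poisson baseline spiking", {
  cfg <- sim_config("SC-like", n_neurons = 1, n_trials_per_condition = 2000,
                    contrasts = 100, polarities = "dark",
                    burst_amp_mean = 0, burst_amp_sd = 0, motor_amp = 0,
                    baseline_rate = 20, baseline_sd = 0, seed = 5)
  s <- generate_session(cfg)
  counts_in <- function(a, b) {
    tabulate(
      factor(s$spikes$trial_id[s$spikes$spike_time >= a &
                                 s$spikes$spike_time < b],
             levels = s$trials$trial_id),
      nbins = nrow(s$trials)
    )
  }
  for (win in list(c(0, 50), c(-100, -50), c(300, 350))) {
    counts <- counts_in(win[1], win[2])
    expected <- 20 * 0.05
    se <- sqrt(expected / length(counts))
    expect_lt(abs(mean(counts) - expected), 4 * se)
  }
  # Poisson dispersion of pre-stimulus counts (chi-square index, alpha=0.01)
  counts <- counts_in(-50, 0)
  disp <- (length(counts) - 1) * var(counts) / mean(counts)
  lims <- qchisq(c(0.005, 0.995), df = length(counts) - 1)
  expect_gt(disp, lims[1])
  expect_lt(disp, lims[2])
})

test_that("reaction-time marginal is strictly positive and right-skewed", {
  cfg <- sim_config("SC-like", n_neurons = 2, n_trials_per_condition = 500,
                    contrasts = c(10, 100), polarities = "dark", seed = 6)
  s <- generate_session(cfg)
  expect_true(all(s$trials$reaction_time > 0))
  expect_gt(skewness(s$trials$reaction_time), 0.2)
  # saccade never precedes the visual burst by construction
  d <- merge(s$latents, s$trials[c("trial_id", "reaction_time")])
  expect_true(all(d$reaction_time >= d$latency + 20))
})

test_that("programmed coupling signs appear in 1000-trial latent correlations", {
  settings <- list(
    c(bl = 0.5, ba = 0, bb = 0), c(bl = 0, ba = 0.3, bb = 0),
    c(bl = 0, ba = 0, bb = 1.5), c(bl = 0.5, ba = 0.3, bb = 1.5)
  )
  for (st in settings) {
    cfg <- sim_config("SC-like", n_neurons = 1,
                      n_trials_per_condition = 1000, contrasts = 100,
                      polarities = "dark", coupling_latency = st[["bl"]],
                      coupling_strength = st[["ba"]],
                      coupling_baseline = st[["bb"]], seed = 7)
    s <- generate_session(cfg)
    d <- merge(s$latents, s$trials[c("trial_id", "reaction_time")])
    sp <- function(x) cor(rank(x), rank(d$reaction_time))
    if (st[["bl"]] > 0) expect_gt(sp(d$latency), 0)
    if (st[["ba"]] > 0) expect_lt(sp(d$amplitude), 0)
    if (st[["bb"]] > 0) expect_lt(sp(d$baseline), 0)
  }
})

test_that("laminar LFP forward model inverts exactly without noise", {
  g <- generate_laminar_lfp(sink_channel = 8, n_channels = 16, spacing = 50,
                            noise_sd = 0)
  prof <- csd_from_lfp(g$lfp, g$spacing, g$time)
  expect_equal(prof$input_channel, 8)
  expect_error(generate_laminar_lfp(1, 16), "interior")
  expect_error(generate_laminar_lfp(16, 16), "interior")
  expect_error(generate_laminar_lfp(3, 4), "5 channels")
})

test_that("quadratic-in-depth potentials have constant second spatial difference", {
  depth <- 1:12
  phi <- outer(3 * depth^2 - 5 * depth + 1, sin(seq(0, 2, length.out = 40)))
  prof <- csd_from_lfp(phi, spacing = 50, time = seq_len(40))
  for (tt in c(5, 20)) {
    expect_equal(diff(range(prof$csd[, tt])), 0, tolerance = 1e-12)
  }
})

test_that("synthetic waveforms carry the requested trough-to-peak width", {
  wf <- generate_waveform(200, sampling_period = 25)
  m <- waveform_width_class(wf)
  expect_lt(abs(m$trough_to_peak - 200), 5)
  expect_identical(m$cls, "narrow")
  m2 <- waveform_width_class(generate_waveform(500, sampling_period = 25))
  expect_identical(m2$cls, "broad")
  expect_error(generate_waveform(30, sampling_period = 25), "2 samples")
  # degenerate flat waveform has no measurable width
  flat <- waveform_width_class(rep(0, 60), sampling_period = 25)
  expect_identical(flat$cls, "rejected")
  expect_true(is.na(flat$trough_to_peak))
})
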