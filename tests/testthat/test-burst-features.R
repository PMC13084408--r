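test_that("detection threshold sits 2 SDs above the mean pre-stimulus rate", {
  expect_equal(detection_threshold(c(10, 10, 10)), 10)
  expect_equal(detection_threshold(c(8, 10, 12)), 14)
  expect_error(detection_threshold(5), "2 trials")
  # recover the programmed SD multiple from random baselines
  set.seed(1)
  for (rep in 1:20) {
    m <- rpois(40, 20)
    theta <- detection_threshold(m)
    expect_equal((theta - mean(m)) / sd(m), 2, tolerance = 1e-12)
  }
})

test_that("latency detector handles flat, bursty and dipped traces", {
  k <- build_kernel()
  window <- c(40, 110)
  grid <- 35:110
  # flat subthreshold trace: no detectable response
  flat <- list(time = grid, rate = rep(5, length(grid)))
  expect_true(is.na(detect_latency(flat, c(50, 60), theta = 20, window)))
  # silence then dense burst from 60 ms: latency = first burst spike
  burst_spikes <- seq(60, 100, by = 2) + 0.25
  tr <- estimate_rate(burst_spikes, k, grid)
  theta <- 20
  expect_equal(detect_latency(tr, burst_spikes, theta, window), 60.25)
  expect_equal(detect_latency(tr, burst_spikes, theta, window),
               oracle_latency(grid, tr$rate, burst_spikes, theta, window))
  # a 3 ms subthreshold dip between onset and peak is walked through
  rate <- rep(100, length(grid))
  rate[grid %in% 71:73] <- 5    # 3 ms dip, run < 5 ms
  rate[grid < 58] <- 0          # true pre-burst silence
  rate[grid == 100] <- 150      # peak
  spikes <- grid + 0.5
  lat <- detect_latency(list(time = grid, rate = rate), spikes, 20, window)
  oracle <- oracle_latency(grid, rate, spikes, 20, window)
  expect_equal(lat, oracle)
  expect_equal(lat, 57.5)       # earliest spike after the pre-burst silence
  expect_error(detect_latency(tr, spikes, 20, c(50, 50)), "empty window")
})

test_that("latency detector matches the brute-force oracle on random trials", {
  k <- build_kernel()
  cfg <- sim_config("SC-like", n_neurons = 2, n_trials_per_condition = 25,
                    contrasts = c(10, 100), polarities = "dark", seed = 11)
  s <- generate_session(cfg)
  f <- session_features(s)
  sp_by_trial <- split(s$spikes$spike_time, s$spikes$trial_id)
  checked <- 0L
  for (j in seq_len(nrow(f))) {
    grp <- f$contrast_group[j]
    ep <- epoch_config("SC", grp)
    grid <- (ep$latency_window[1] - 5):ep$latency_window[2]
    sp <- sp_by_trial[[as.character(f$trial_id[j])]]
    if (is.null(sp)) sp <- numeric(0)
    tr <- estimate_rate(sp[sp <= ep$latency_window[2] + 1], k, grid)
    expect_equal(
      detect_latency(tr, sp, f$theta[j], ep$latency_window),
      oracle_latency(grid, tr$rate, sp, f$theta[j], ep$latency_window)
    )
    checked <- checked + 1L
  }
  expect_gte(checked, 100L)
})

test_that("shifting all spikes shifts the detected latency exactly", {
  k <- build_kernel()
  set.seed(3)
  spikes <- sort(c(runif(5, -50, 30), 60 + cumsum(rexp(15, 1 / 2))))
  window <- c(40, 110)
  grid <- 35:110
  lat0 <- detect_latency(estimate_rate(spikes, k, grid), spikes, 30, window)
  for (delta in c(7, 20)) {
    lat <- detect_latency(
      estimate_rate(spikes + delta, k, grid + delta),
      spikes + delta, 30, window + delta
    )
    expect_equal(lat, lat0 + delta)
  }
})

test_that("mean detected latency tracks the programmed onset within 3 ms", {
  # Sharp, strong bursts isolate detector bias from the Poisson first-spike
  # delay of slow ramps (an inhomogeneous-Poisson burst ramping up over
  # several ms emits its first spike a few ms after the intensity onset, a
  # floor no detector can beat).
  cfg <- sim_config("SC-like", n_neurons = 3, n_trials_per_condition = 200,
                    contrasts = c(50, 100), polarities = "dark",
                    baseline_sd = 0, burst_amp_mean = 1200,
                    burst_tau_rise = 1, seed = 13)
  f <- session_features(generate_session(cfg))
  for (con in c(50, 100)) {
    mu <- cfg$burst_latency_mean[match(con, sort(cfg$contrasts))]
    got <- mean(f$latency[f$contrast == con], na.rm = TRUE)
    expect_lt(abs(got - mu), 3)
  }
  # Under the default (slower-ramp) conditions, *differences* between
  # condition means still track the programmed latency differences.
  cfg2 <- sim_config("SC-like", n_neurons = 3, n_trials_per_condition = 200,
                     contrasts = c(50, 100), polarities = "dark",
                     baseline_sd = 0, seed = 13)
  f2 <- session_features(generate_session(cfg2))
  dmean <- mean(f2$latency[f2$contrast == 50], na.rm = TRUE) -
    mean(f2$latency[f2$contrast == 100], na.rm = TRUE)
  dmu <- diff(rev(cfg2$burst_latency_mean))
  expect_lt(abs(dmean - dmu), 3)
})

test_that("burst strength is the baseline-subtracted epoch count", {
  expect_equal(burst_strength(numeric(0), c(50, 110), 1.5), -1.5)
  expect_equal(burst_strength(c(55, 60, 65, 70, 75, 80, 85), c(50, 110), 2), 5)
  # half-open window: spike exactly at the end is excluded, at the start kept
  expect_equal(burst_strength(c(50, 110), c(50, 110), 0), 1)
  expect_error(burst_strength(1:3, c(100, 50), 0), "malformed")
  # strength grows monotonically with programmed amplitude
  means <- vapply(c(100, 200, 400), function(a) {
    cfg <- sim_config("SC-like", n_neurons = 1,
                      n_trials_per_condition = 1000, contrasts = 100,
                      polarities = "dark", burst_amp_mean = a, seed = 17)
    mean(session_features(generate_session(cfg))$strength)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("pre-stimulus state counts spikes in the final 50 ms", {
  expect_equal(prestim_state(c(-60, -10, -3, 5)), 2)
  expect_equal(prestim_state(numeric(0)), 0)
  expect_equal(prestim_state(c(-50, 0)), 1)  # half-open [-50, 0)
  set.seed(19)
  counts <- vapply(1:10000, function(i) {
    prestim_state(runif(rpois(1, 20 * 0.8), -600, 200))
  }, numeric(1))
  expect_equal(mean(counts), 1.0, tolerance = 0.05)
})

test_that("latency inclusion requires 60% detected trials", {
  expect_true(latency_inclusion(rep(c(TRUE, FALSE), c(24, 16))))
  expect_false(latency_inclusion(rep(c(TRUE, FALSE), c(23, 17))))
  expect_false(latency_inclusion(rep(FALSE, 10)))
  expect_error(latency_inclusion(logical(0)), "1 trial")
})
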