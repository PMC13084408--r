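test_that("Spearman correlation endpoints, conventions and p-values", {
  r <- spearman_feature_rt(1:10, (1:10)^2 + 100)
  expect_equal(r$rho, 1)
  r2 <- spearman_feature_rt(1:10, rev(1:10))
  expect_equal(r2$rho, -1)
  # all-zero pre-stimulus counts: designated zero correlation
  r3 <- spearman_feature_rt(rep(0, 20), rnorm(20), feature = "prestim")
  expect_equal(r3$rho, 0)
  expect_true(r3$zero_assigned)
  # but a constant non-prestim feature is undefined
  r4 <- spearman_feature_rt(rep(2, 20), rnorm(20), feature = "strength")
  expect_true(is.na(r4$rho))
  expect_true(is.na(spearman_feature_rt(1:2, 2:1)$rho))
  # undefined latencies are dropped pairwise
  r5 <- spearman_feature_rt(c(1, NA, 3, 4, NA, 6), c(10, 0, 30, 40, 0, 60))
  expect_equal(r5$n, 4)
  expect_equal(r5$rho, 1)
  # agreement with the reference implementation, with and without ties
  set.seed(7)
  for (i in 1:10) {
    n <- sample(8:40, 1)
    x <- sample(1:12, n, replace = TRUE)
    y <- rnorm(n) + 0.3 * x
    ours <- spearman_feature_rt(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
    expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-6)
  }
})

test_that("signed-rank and rank-sum statistics match the reference tests", {
  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(30, mean = 0.2)
    ours <- signed_rank_test(x)
    ref <- wilcox.test(x, correct = FALSE, exact = FALSE)
    expect_equal(ours$W, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    y <- rnorm(25, mean = 0.4)
    ours2 <- rank_sum_test(x, y)
    ref2 <- wilcox.test(x, y, correct = FALSE, exact = FALSE)
    expect_equal(ours2$U, unname(ref2$statistic))
    expect_equal(ours2$p, ref2$p.value, tolerance = 1e-10)
  }
  # zero-value exclusion: the reduced-sample n is reported
  sr <- signed_rank_test(c(0, 0, 1, -2, 3))
  expect_equal(sr$n, 3)
})

test_that("population battery: calibration, power and Bonferroni arithmetic", {
  # null records symmetric about zero: pooled signed-rank rarely significant
  set.seed(13)
  fp <- vapply(1:100, function(i) {
    recs <- data.frame(rho = rnorm(40, 0, 0.15),
                       contrast = rep(c(10, 20, 50, 100), 10))
    population_tests(recs)$pooled$p < 0.05
  }, logical(1))
  expect_gte(sum(!fp), 93)
  # strong shared effect: decisively significant
  recs <- data.frame(rho = 0.3 + rnorm(40, 0, 0.02),
                     contrast = rep(c(10, 20, 50, 100), 10))
  expect_lt(population_tests(recs)$pooled$p, 1e-3)
  # Bonferroni across the four contrast levels
  pt <- population_tests(recs)
  expect_equal(pt$per_level$p_adj, pmin(1, pt$per_level$p * 4))
  # two-group mode uses the rank-sum test
  recs$area <- rep(c("SC", "V1"), each = 20)
  recs$rho[recs$area == "V1"] <- rnorm(20, 0, 0.02)
  pt2 <- population_tests(recs, group = "area")
  expect_lt(pt2$pooled$p, 0.01)
  expect_equal(pt2$pooled$n1, 20)
})

test_that("reliability summary recovers programmed across-trial variability", {
  expect_equal(reliability_summary(
    data.frame(neuron_id = 1, contrast = 10, polarity = "dark",
               latency = c(50, 60)))$per_neuron$sd,
    sd(c(50, 60)))
  df <- data.frame(neuron_id = 1, contrast = 10, polarity = "dark",
                   latency = rep(55, 8))
  expect_equal(reliability_summary(df)$per_neuron$sd, 0)
  # larger programmed latency jitter yields larger recovered SDs
  get_mean_sd <- function(sigma, seed) {
    cfg <- sim_config("SC-like", n_neurons = 5, n_trials_per_condition = 40,
                      contrasts = 100, polarities = "dark",
                      burst_latency_sd = sigma, seed = seed)
    f <- session_features(generate_session(cfg))
    reliability_summary(f, "latency")$population$mean_sd
  }
  expect_gt(get_mean_sd(12, 41), get_mean_sd(6, 41))
})

test_that("fast/slow split on identical trials returns identical unit traces", {
  ses <- make_fixed_session(n_neurons = 2, n_trials = 9)
  fs <- fastslow_summary(ses, contrast = 100, polarity = "dark", area = "SC")
  expect_equal(fs$fast_mean, fs$slow_mean)
  # every neuron's average trace is normalized to peak 1 in the visual epoch
  win <- fs$time >= 40 & fs$time < 100
  expect_equal(max(fs$fast_mean[win]), 1, tolerance = 1e-9)
  expect_equal(fs$n_neurons, 2)
})

test_that("correlation records honor the latency inclusion rule", {
  cfg <- sim_config("SC-like", n_neurons = 4, n_trials_per_condition = 30,
                    contrasts = c(10, 100), polarities = "dark", seed = 23)
  f <- session_features(generate_session(cfg))
  rl <- correlation_records(f, "latency")
  # only included neuron x condition cells produce latency records
  agg <- unique(f[f$latency_included,
                  c("neuron_id", "contrast", "polarity")])
  expect_equal(nrow(rl), nrow(agg))
  rs <- correlation_records(f, "strength")
  expect_true(all(rs$rho >= -1 & rs$rho <= 1, na.rm = TRUE))
  expect_true(all(rs$n_trials[!is.na(rs$rho)] >= 3))
})
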