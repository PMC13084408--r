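# burstlink

Trial-by-trial analysis of how single-neuron visual responses relate to
saccadic reaction-time (SRT) variability, for electrophysiologists comparing
sensory areas — here the superior colliculus (SC) and primary visual cortex
(V1) — on simulated or tabular spike/trial data.

On every trial, three features of a neuron's response are measured and
correlated with the latency of the orienting eye movement:

- **visual response onset latency**: detected on the single-trial firing
  rate estimated with a strictly causal rise–decay kernel
  (k(τ) ∝ (1 − e^(−τ/τ_rise)) e^(−τ/τ_decay), τ ≥ 0); the peak rate is found
  in an area/contrast-specific window, a backward walk finds where the rate
  was below a threshold (2 SDs above mean pre-stimulus activity) for at
  least 5 ms, and the first spike after that crossing is the onset;
- **visual response strength**: baseline-subtracted spike count in a short
  stimulus-aligned epoch (60 ms in SC, 85 ms in V1);
- **pre-stimulus state**: spike count in the final 50 ms before stimulus
  onset.

Per-neuron Spearman coefficients ρ are aggregated with Wilcoxon signed-rank
and Mann–Whitney U tests (Bonferroni over contrasts), and latency and
strength compete directly in a Gamma log-link mixed model

    SRT ~ latency × contrast + strength × contrast + (1 | neuron)

fitted by a Laplace-approximation ML engine implemented in the package, with
Wald tests, single-term deletions (df = 2 for latency/strength, 3 for
contrast) and AIC. Support modules cover unit quality control (ISI
violations), visual vs visual-motor classification, the visuomotor index
VMI = (V − M)/(V + M) with its sliding-bin summary, CSD input-layer
identification on laminar LFPs, and spike-waveform narrow/broad typing at
350 µs. A seeded inhomogeneous-Poisson session generator with known
latent-feature→RT couplings makes every stage testable by parameter
recovery.

## Worked example

```r
library(burstlink)

cfg <- sim_config("SC-like", n_neurons = 20, n_trials_per_condition = 40,
                  polarities = "dark", seed = 42)
session  <- generate_session(cfg)
features <- session_features(session)
recs     <- correlation_records(features, "strength")
pt       <- population_tests(recs)
round(unlist(pt$pooled), 4)
#>       stat          z          p          n         n1         n2   mean_rho median_rho    sem_rho
#>   177.0000    -6.9210     0.0000    80.0000         NA         NA    -0.1695    -0.1611     0.0168
```

A 20-neuron SC-like run recovers the programmed coupling: the mean
strength–RT Spearman coefficient is −0.17 (stronger visual bursts on faster
trials), and the signed-rank test against zero is decisive (z = −6.92,
n = 80 neuron × contrast records). A `"V1-like"` configuration (no
coupling) yields mean ρ near 0 and a non-significant test.

The mixed model on the same features:

```r
d <- features[features$detected & features$latency_included, ]
fit <- fit_gamma_glmm(data.frame(rt = d$reaction_time, latency = d$latency,
                                 strength = d$strength, contrast = d$contrast,
                                 neuron = d$neuron_id))
fit$coefficients[2:4, ]
#>       term     estimate          se         z            p
#> 2  latency  0.006061644 0.005637876  1.075164 2.823011e-01
#> 3 strength -0.033942242 0.004156066 -8.166917 3.163716e-16
#> 4 contrast  0.022434001 0.005416577  4.141731 3.446950e-05
```

The burst-strength effect is decisive on the per-SD log-RT scale (−0.034:
a one-SD stronger burst predicts ~3.4% faster saccades). The trial-wise
latency effect is attenuated at this sample size — single-trial onset
detection adds jitter, and the contrast term absorbs the across-condition
latency trend (mean latency falls as contrast rises), which is also why its
coefficient is positive here.

The numbered scripts under `analysis/` run the full workflow (simulate →
features → typing/VMI → correlations → GLMM → laminar/waveforms) and write
their tables under `results/run/`:

```sh
Rscript analysis/01_simulate.R && Rscript analysis/02_features.R
Rscript analysis/03_typing.R   && Rscript analysis/04_correlations.R
Rscript analysis/05_glmm.R     && Rscript analysis/06_laminar_waveforms.R
```

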