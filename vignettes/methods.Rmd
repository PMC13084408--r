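---
title: "Linking single-trial visual bursts to saccadic reaction time: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking single-trial visual bursts to saccadic reaction time: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstlink)
```

## The scientific problem

When a visual stimulus appears and an observer orients to it with a saccade,
the time from stimulus onset to eye-movement onset (the saccadic reaction
time, SRT) varies substantially from trial to trial even under identical
stimulation. `burstlink` implements a trial-by-trial analysis chain that asks
how much of that behavioral variability is visible in the visual responses of
single neurons — in the superior colliculus (SC), where visual bursts sit two
synapses from the saccade-generating circuitry, versus primary visual cortex
(V1), the main cortical source of visual input to the SC.

Three trial-wise neuronal features carry the analysis:

* **visual response onset latency** — the time of the first stimulus-evoked
  spike of the trial's visual burst;
* **visual response strength** — the baseline-subtracted spike count in a
  short stimulus-aligned epoch;
* **pre-stimulus state** — the spike count in the final 50 ms before
  stimulus onset, an index of motor readiness.

Each feature is correlated (Spearman) with SRT per neuron and condition, the
per-neuron coefficients are aggregated with non-parametric population tests,
and a Gamma log-link mixed model puts latency and strength into a single
regression on reaction time. Because no public recordings accompany the
original study, every stage is validated against a synthetic session
generator with known ground truth; the package's tests are
parameter-recovery experiments, not comparisons to archived data.

## Single-trial rate estimation

Spike trains are converted to firing-rate traces by convolution with a
causal rise–decay kernel,

$$k(\tau) \propto \left(1 - e^{-\tau/\tau_{rise}}\right)e^{-\tau/\tau_{decay}},
\qquad \tau \ge 0,$$

truncated where less than 0.1% of its mass remains and normalized to unit
area on a 1 ms grid (`build_kernel()`). Strict causality — zero weight at
all negative lags — is the load-bearing property: a symmetric smoother would
blur burst onsets earlier in time and bias every latency estimate. The exact
time constants behind the original analysis are not published; we default to
$\tau_{rise} = 1$ ms, $\tau_{decay} = 20$ ms, a postsynaptic-potential-like
kernel standard in single-trial latency work, and both constants are
arguments. The kernel is evaluated at continuous lags, so causality holds
exactly for non-integer spike times; tests assert linearity, shift
equivariance, and exact causality on random trains.

## Latency detection

`detect_latency()` implements the peak-and-backward-walk rule on the 1 ms
grid: find the peak rate in an area- and contrast-specific search window
(SC 40–110 / 40–100 ms, V1 30–105 / 30–95 ms for the two lowest / two
highest contrasts); reject the trial if the peak is below threshold; walk
backward until the rate has been below threshold for at least 5 ms; report
the earliest spike after that subthreshold run. The threshold is 2 sample
standard deviations above the mean pre-stimulus rate across the condition's
trials. Geometry choices we had to fix ourselves: the 5 ms requirement is a
*contiguous* subthreshold run immediately preceding the crossing (shorter
dips are noise and are walked through); peak ties break to the earliest
time; the reported spike must lie strictly after the crossing and at or
before the peak. A brute-force enumerator over all candidate crossing times
reproduces the detector exactly on hundreds of random synthetic trials.

Two further choices deserve a note. The per-trial pre-stimulus rate entering
the threshold is the mean of the kernel-smoothed trace over the *full*
recorded pre-stimulus period (−150 to 0 ms), not just the 50 ms baseline
epoch: with tens of trials and low baseline rates, the across-trial SD of a
50 ms estimate is dominated by Poisson noise and inflates the threshold.
And on simulated data the detected latency sits a few ms after the latent
burst-onset parameter — an inhomogeneous Poisson burst that ramps up over
several ms emits its first spike a few ms after its intensity onset, a floor
no detector can beat; recovery tests therefore use sharp strong bursts when
they assert absolute (rather than differential) onset tracking.

## Strength, pre-stimulus state, inclusion

Strength is the spike count in a half-open, area/contrast-specific window
(SC 50–110 / 40–100 ms; V1 35–120 / 30–115 ms — 60 ms in SC, 85 ms in V1
because V1 bursts last longer) minus the across-trial mean count in the
50 ms baseline epoch. Pre-stimulus state is the count in [−50, 0) ms. A
neuron enters latency analyses of a condition only when at least 60% of that
condition's trials yielded a defined latency; the rule is evaluated per
condition (contrast × polarity), which is why neuron counts differ across
contrasts. Contrast groups ("two lowest" vs "two highest") are defined
relative to the contrasts present in the session.

## Classification, VMI, and statistics

Visual vs visual-motor classification compares per-trial mean rates in four
windows (visual 40–95 ms post stimulus; pre-motor −25–0 ms and post-motor
0–65 ms around saccade onset; 50 ms baseline) with a Kruskal–Wallis omnibus
test at $\alpha = 0.05$ followed by Dunn's rank-based pairwise comparisons,
Bonferroni-corrected over the six pairs. The phrase "multiple comparison
Kruskal-Wallis test" does not pin down a post-hoc procedure; Dunn's test on
the pooled ranks is the standard reading (it is what MATLAB's
`multcompare` does after `kruskalwallis`) and the choice is configurable in
spirit: the post-hoc table is returned for inspection.

The visuomotor index, computed from the delayed saccade task, is
$\mathrm{VMI} = (V - M)/(V + M)$ with $V$ the baseline-subtracted mean rate
50–100 ms after stimulus onset and $M$ the baseline-subtracted peak rate
within ±25 ms of saccade onset (pre-go baseline). Neurons significantly
suppressed in the motor epoch (one-sided paired Wilcoxon at 0.05 — the
source does not define the suppression test) are assigned +1. Values are
clipped to [−1, 1] because mildly negative baseline-subtracted measures can
otherwise push the ratio outside its nominal range. The sliding-bin summary
uses centers −1 … +1 in steps of 0.05 with half-width 0.1, so each neuron
contributes to 3–5 overlapping bins.

Population statistics are the non-parametric battery: Wilcoxon signed-rank
versus zero with the reduced-sample convention (zero-valued coefficients —
notably the designated-zero neurons with no pre-stimulus activity — are
discarded and the effective n reported), Mann–Whitney U between groups, both
as tie-corrected normal approximations without continuity correction (the z
statistics are the reported quantities), and Bonferroni correction across
contrast levels. Two-sided alternatives are used throughout.

## The reaction-time mixed model

`fit_gamma_glmm()` fits

$$\mathrm{SRT} \sim \mathrm{latency} \times \mathrm{contrast} +
\mathrm{strength} \times \mathrm{contrast} + (1\,|\,\mathrm{neuron})$$

with a Gamma response and log link; the three predictors are continuous and
z-scored over the fitted data, contrast entering as numeric percent. Fits
are separate per luminance polarity. The estimation engine is written in
this package rather than delegated: the marginal likelihood is maximized
with a Laplace approximation over the neuron intercepts (the integrand is
strictly log-concave in each intercept, so the inner Newton solve is
globally convergent and is vectorized across neurons), and the outer
optimization runs over the fixed effects, $\log \sigma_u$ and the log Gamma
shape — the shape is estimated jointly, not profiled. Owning the engine
gives exact control of parameter accounting: single-term deletion removes a
predictor with all its interactions (2 parameters for latency or strength,
3 for contrast), and AIC counts fixed effects + variance + shape. Wald
standard errors come from a central-difference Hessian of the Laplace
log-likelihood. Convergence demands a relative log-likelihood change below
1e-8 with an evaluation cap of 2×10^5. The collapsed limit
($\sigma_u = 0$) reproduces an independent IRLS Gamma GLM to 1e-4, and fixed
effects agree with `lme4::glmer` to ~1e-3 on shared simulations.

## Laminar and waveform analyses

CSD analysis averages stimulus-aligned LFPs across trials and takes the
second spatial difference across depth, signed so sinks are negative; the
input layer is the channel with the most negative CSD averaged 0–100 ms
post stimulus. At 50 µm contact spacing the input channel and one neighbor
on each side separate superficial from deep; at coarser spacing the
identified channel alone does. LFP preprocessing is zero-phase Butterworth
filtering (default 0.7–300 Hz band-pass then 100 Hz low-pass; the original
report prints an ambiguous "0.7-6KHz" band, so the corners are arguments and
our defaults follow LFP convention).

Waveform typing gates units at an AUROC of 0.95 between pre-spike and spike
amplitude distributions (pre-spike = first 20% of the snippet, spike =
±0.2 ms around the trough; the source does not define these intervals),
filters multimodal spike-amplitude distributions to their largest mode
(BIC-selected 1-D Gaussian mixtures; ties break to the larger-mean mode),
upsamples mean waveforms from 25 to 5 µs by cubic interpolation, and splits
trough-to-peak widths at 350 µs into narrow (putative interneurons) versus
broad (putative pyramidal).

## The synthetic session generator

No generative model is stated in the source; ours is the simplest one whose
parameters map one-to-one onto the analysis chain. Each neuron × trial draws
a latent burst latency $L_t$, amplitude $A_t$ and baseline $B_t$ (normal,
the rates truncated at 0), and spikes come from an inhomogeneous Poisson
process

$$\lambda(\tau) = B_t + A_t\,s(\tau - L_t) + M\,s(\tau - (S_t - 3)),$$

where $s$ is a unit-peak rise–decay transient (defaults 5/15 ms), $M$ the
motor burst amplitude and $S_t$ the saccade time; the motor burst leads the
saccade by 3 ms, since SC motor bursts build up before the eye moves (and a
purely post-saccadic burst could never satisfy the pre-motor classification
criterion). Reaction time is a linear function of the centered latents,

$$\mathrm{RT}_t = \mu_{RT} + \beta_L (L_t - \mu_L) - \beta_A (A_t - \mu_A)
- \beta_B (B_t - b) + \varepsilon_t,$$

truncated below at $L_t + 20$ ms so the saccade never precedes the visual
burst. The noise $\varepsilon$ is a mean-zero scaled Gamma deviate (shape 4)
rather than Gaussian, so the RT marginal is strictly positive and
right-skewed — the distributional shape the Gamma GLMM assumes. Trials are
recorded over [−200, +600] ms; each simulated neuron is paired with its own
behavioral trial block (one-neuron sessions pooled), which matches how
per-neuron correlations are computed but does not emulate shared-trial
covariance between simultaneously recorded neurons.

Defaults are the study conditions: 40 trials per condition (the experiments
collected 35–45), Weber contrasts {10, 20, 50, 100}%, both luminance
polarities, contrast-dependent amplitudes (200–440 spikes/s peak) and
latencies (85–55 ms, interpolated for other contrast values), bright stimuli
2 ms later than dark, SC baseline 20 spikes/s versus V1 8, and larger
latency jitter in the V1-like profile (9 vs 6 ms), reflecting the higher
across-trial variability reported for V1 — whether that jitter couples to
behavior is left to the caller, and the V1-like default leaves it uncoupled.
The SC-like couplings $\beta_L = 0.42$, $\beta_A = 0.15$, $\beta_B = 0.8$
were fixed once by the prescribed oracle calibration: a 100,000-trial run of
the full pipeline under these defaults yields population Spearman
correlations of about +0.09 (latency–RT) and −0.21 (strength–RT), the
target regime of roughly +0.10 / −0.20. The V1-like profile zeroes all
couplings and the motor burst.

What passing tests do and do not show: the generator produces Poisson spike
trains with smooth burst templates, independent trials, and stationary
baselines. Real recordings add bursty non-Poisson firing, drift, shared
trial-to-trial population covariance, and saccade-detection noise — recovery
under the generator demonstrates correctness of the analysis chain, not
robustness to those real-data features.

## Problem sizes and numerical choices

Test simulations use 100 neurons × 40 trials per condition for coupling
recovery (with the 100,000-trial oracle defining the recovery target), 100
seeded runs for coverage and type-I calibration, 200 seeds for the
likelihood-ratio uniformity check at 30 neurons × 20 trials, and 100 noisy
seeds for CSD recovery; these sizes give the population statistics enough
resolution for the ±0.05 correlation and 2-SE coverage bands while keeping
the full suite comfortably re-runnable on one CPU. Fast/slow thirds take
`floor(n/3)` trials per tail with ties broken by trial order; peak
normalization uses the area-specific strength window; bins, windows and
epochs are half-open where double counting is possible; degenerate inputs
(all-zero pre-stimulus activity, zero-peak neurons, flat waveforms,
V + M = 0) are assigned the documented conventions rather than propagating
NaN.

## Known limitations

* The kernel time constants and the original CSD variant are educated
  defaults, not published values; sensitivity to the kernel constants is
  exercised in tests but conclusions about real data would need the
  authors' settings.
* The generator's linear latent-to-RT map is a measurement model, not a
  mechanistic claim; it exists to make Spearman correlations and GLMM
  coefficients recoverable quantities.
* Shared-trial covariance between simultaneously recorded neurons, eye
  position, and microsaccades are out of scope.
* The Laplace approximation can understate variance-component uncertainty
  at very small neuron counts; fixed-effect inference at the tested sizes
  agrees with an independent implementation.
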