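#!/usr/bin/env Rscript
# Simulate the study's two recording conditions: an SC-like population whose
# trial-wise burst features are coupled to saccadic reaction time, and a
# V1-like population with identical visual drive but no behavioral coupling.
# Writes the session bundles (trials/spikes/neurons/latents TSV) under
# results/run/.

library(burstlink)

out_root <- "results/run"
seed <- 20260928L

# half the SC units visual-only (no motor burst), half visual-motor
sc_cfg <- sim_config("SC-like", n_neurons = 40, n_trials_per_condition = 40,
                     motor_amp = rep(c(0, 200), each = 20), seed = seed)
v1_cfg <- sim_config("V1-like", n_neurons = 40, n_trials_per_condition = 40,
                     seed = seed + 1L)

for (cfg in list(sc_cfg, v1_cfg)) {
  tag <- if (cfg$area_profile == "SC-like") "sc" else "v1"
  dir <- file.path(out_root, tag)
  s <- generate_session(cfg)
  write_session(s, dir)
  v <- validate_tables(dir)
  stopifnot(all(v$pass))
  cat(sprintf(
    "%s: %d neurons, %d trials, %d spikes; mean RT %.1f ms (SD %.1f)\n",
    cfg$area_profile, nrow(s$neurons), nrow(s$trials), nrow(s$spikes),
    mean(s$trials$reaction_time), sd(s$trials$reaction_time)
  ))
}

# companion delayed-task SC session for the visuomotor index (half the
# neurons visual-only, half visual-motor)
vmi_cfg <- sim_config("SC-like", n_neurons = 20, n_trials_per_condition = 40,
                      contrasts = c(50, 100), polarities = "dark",
                      motor_amp = rep(c(0, 450), each = 10),
                      task = "delayed", seed = seed + 2L)
write_session(generate_session(vmi_cfg), file.path(out_root, "sc_delayed"))
cat("delayed-task SC session written for VMI analysis\n")
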