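#!/usr/bin/env Rscript
# Unit quality control, visual vs visual-motor classification, and the
# visuomotor index from the delayed-task session. Writes
# results/run/neuron_profiles.tsv.

library(burstlink)

sc <- read_session("results/run/sc")
delayed <- read_session("results/run/sc_delayed")

profiles <- do.call(rbind, lapply(unique(sc$neurons$neuron_id), function(nid) {
  sp <- sc$spikes[sc$spikes$neuron_id == nid, ]
  qc <- isi_qc(split(sp$spike_time, sp$trial_id))
  cls <- classify_functional(neuron_window_rates(sc, nid))
  data.frame(neuron_id = nid, qc_pass = qc$qc_pass,
             isi_violation_pct = 100 * qc$violation_fraction,
             label = cls$label)
}))

vmi_tab <- do.call(rbind, lapply(unique(delayed$neurons$neuron_id),
                                 function(nid) {
  m <- vmi_measures(delayed, nid)
  data.frame(neuron_id = nid,
             motor_amp_true = delayed$neurons$motor_amp[
               delayed$neurons$neuron_id == nid],
             visual_measure = m$visual_measure,
             motor_measure = m$motor_measure,
             motor_suppressed = m$motor_suppressed, vmi = m$vmi)
}))

write.table(profiles, "results/run/neuron_profiles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(vmi_tab, "results/run/vmi.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("functional labels:\n")
print(table(profiles$label))
cat(sprintf("QC pass: %d/%d units\n", sum(profiles$qc_pass), nrow(profiles)))
cat(sprintf("VMI (delayed task): visual-only median %.2f, visual-motor median %.2f\n",
            median(vmi_tab$vmi[vmi_tab$motor_amp_true == 0]),
            median(vmi_tab$vmi[vmi_tab$motor_amp_true > 0])))
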