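#!/usr/bin/env Rscript
# Gamma log-link mixed models of saccadic reaction time (separate fits per
# luminance polarity), with Wald tests, single-term deletions and AIC.
# Trials enter if the latency was detected and the neuron passed the
# per-condition inclusion rule.

library(burstlink)

f <- read.table("results/run/sc/features.tsv", header = TRUE, sep = "\t")

for (pol in c("dark", "bright")) {
  d <- f[f$polarity == pol & f$detected & f$latency_included, ]
  md <- data.frame(rt = d$reaction_time, latency = d$latency,
                   strength = d$strength, contrast = d$contrast,
                   neuron = d$neuron_id)
  fit <- fit_gamma_glmm(md)
  cat(sprintf("\n== %s contrasts: %d trials, %d neurons ==\n", pol,
              nrow(md), length(unique(md$neuron))))
  print(fit)
  write.table(fit$coefficients,
              sprintf("results/run/glmm_fit_%s.tsv", pol), sep = "\t",
              quote = FALSE, row.names = FALSE)
  dels <- do.call(rbind, lapply(c("latency", "strength", "contrast"),
                                function(term) {
    del <- single_term_deletion(fit, term)
    data.frame(term = term, chisq = del$chisq, df = del$df, p = del$p,
               AIC_full = del$AIC_full, AIC_reduced = del$AIC_reduced)
  }))
  print(dels, digits = 4)
  write.table(dels, sprintf("results/run/glmm_deletions_%s.tsv", pol),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
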