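#!/usr/bin/env Rscript
# The correlation battery: per-neuron Spearman correlations between each
# trial-wise feature (onset latency, burst strength, pre-stimulus count) and
# saccadic reaction time; population signed-rank and SC-vs-V1 rank-sum tests
# with Bonferroni correction; across-trial reliability; and the normalized
# fast/slow-third population traces.

library(burstlink)

feats <- lapply(c(sc = "sc", v1 = "v1"), function(tag) {
  read.table(file.path("results/run", tag, "features.tsv"), header = TRUE,
             sep = "\t")
})

records <- do.call(rbind, lapply(names(feats), function(tag) {
  do.call(rbind, lapply(c("latency", "strength", "prestim"), function(ft) {
    r <- correlation_records(feats[[tag]], ft)
    r$area <- toupper(tag)
    r
  }))
}))
write.table(records, "results/run/correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

for (ft in c("latency", "strength", "prestim")) {
  d <- records[records$feature == ft & records$polarity == "dark", ]
  cat(sprintf("\n== %s vs reaction time (dark contrasts) ==\n", ft))
  for (ar in c("SC", "V1")) {
    da <- d[d$area == ar, ]
    pt <- population_tests(da)
    cat(sprintf(
      "  %s: mean rho %+.4f (median %+.4f, n=%d); signed-rank z=%.2f p=%.2g\n",
      ar, pt$pooled$mean_rho, pt$pooled$median_rho,
      sum(!is.na(da$rho)), pt$pooled$z, pt$pooled$p))
  }
  between <- population_tests(d, group = "area")
  cat(sprintf("  SC vs V1 rank-sum: U=%.0f z=%.2f p=%.2g\n",
              between$pooled$stat, between$pooled$z, between$pooled$p))
}

cat("\n== across-trial reliability (latency SD, dark 100%) ==\n")
for (tag in names(feats)) {
  rel <- reliability_summary(
    feats[[tag]][feats[[tag]]$polarity == "dark", ], "latency"
  )
  pop <- rel$population[rel$population$contrast == 100, ]
  cat(sprintf("  %s: mean SD %.2f ms (SEM %.2f, n=%d)\n", toupper(tag),
              pop$mean_sd, pop$sem_sd, pop$n))
}

cat("\n== fast/slow thirds (50% dark contrast, peak-normalized) ==\n")
for (tag in c("sc", "v1")) {
  s <- read_session(file.path("results/run", tag))
  fs <- fastslow_summary(s, 50, "dark")
  win <- fs$time >= 30 & fs$time < 120
  cat(sprintf("  %s: fast-third peak %.3f vs slow-third peak %.3f (n=%d neurons)\n",
              toupper(tag), max(fs$fast_mean[win]), max(fs$slow_mean[win]),
              fs$n_neurons))
}

# VMI sliding-bin summary over SC strength correlations
vmi_tab <- read.table("results/run/vmi.tsv", header = TRUE, sep = "\t")
sc_str <- records[records$area == "SC" & records$feature == "strength", ]
rho_by_neuron <- tapply(sc_str$rho, sc_str$neuron_id, mean, na.rm = TRUE)
common <- intersect(vmi_tab$neuron_id, as.integer(names(rho_by_neuron)))
bins <- vmi_binned_summary(vmi_tab$vmi[match(common, vmi_tab$neuron_id)],
                           rho_by_neuron[as.character(common)])
write.table(bins, "results/run/vmi_binned.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nVMI-binned strength correlations written to results/run/vmi_binned.tsv\n")
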