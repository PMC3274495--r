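#!/usr/bin/env Rscript

# Step 2: probe normalization.
#
# Per-probe, per-replicate log2(IP/control) ratios are quantile-normalized
# across the two replicates and averaged into a single signal track:
#   1/2 [ log2(IP_i1/C_i1) + log2(IP_i2/C_i2) ]
# The track is written as bedGraph for the profiling steps.

suppressMessages(library(chdipmeta))

probes <- read_probe_table("scratch/sim/probes.tsv")
lr <- probe_log_ratios(probes)
qn <- quantile_normalize(lr)
track <- average_replicates(qn, probes)
write_signal_bedgraph(track, "scratch/signal.bedgraph")

summary <- data.frame(
  quantity = c("probes", "replicates",
               "rep1_raw_median", "rep2_raw_median",
               "rep1_normalized_median", "rep2_normalized_median",
               "track_mean", "track_sd"),
  value = round(c(nrow(probes), ncol(lr),
                  median(lr[, 1]), median(lr[, 2]),
                  median(qn[, 1]), median(qn[, 2]),
                  mean(track$value), sd(track$value)), 4)
)
write.table(summary, "results/02_normalization_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("normalized", nrow(probes), "probes;",
    "replicate medians", round(median(qn[, 1]), 4), "/",
    round(median(qn[, 2]), 4), "after quantile normalization;",
    "track mean", round(mean(track$value), 4), "\n")
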