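#!/usr/bin/env Rscript
# Stage 3 — MARS differential expression over the six pairwise comparisons.
#
# Each root part is compared A vs B, A vs C and B vs C (first pool as
# numerator). Genes with |normalized log2 fold change| >= 1 and p < 0.001
# are flagged as DEGs; no multiple-testing correction, as the selection
# logic downstream operates on raw p-values.

library(macetrait)

seed <- 1L
cfg <- pipeline_config(seed = seed)
hdr <- output_header(cfg)
counts <- read_counts("results/counts.tsv")

summary_rows <- list()
for (part in cfg$parts) {
  for (pr in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    l1 <- paste0(pr[1], "_", part); l2 <- paste0(pr[2], "_", part)
    deg <- call_degs(mars_compare(counts, l1, l2),
                     cfg$l2fc_min, cfg$p_max)
    key <- paste0(pr[1], "v", pr[2], "_", part)
    write_table(deg, paste0("results/degs_", key, ".tsv"), comments = hdr)
    summary_rows[[key]] <- data.frame(
      comparison = key, genes_tested = nrow(deg), degs = sum(deg$deg),
      deg_up = sum(deg$deg & deg$l2fc_norm > 0),
      deg_down = sum(deg$deg & deg$l2fc_norm < 0))
  }
}
smry <- do.call(rbind, summary_rows)
write_table(smry, "results/deg_summary.tsv", comments = hdr)
cat("DEG counts per comparison:\n")
print(smry, row.names = FALSE)
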