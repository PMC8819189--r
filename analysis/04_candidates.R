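#!/usr/bin/env Rscript
# Stage 4 — Venn partition and trait candidate selection.
#
# Root-volume candidates: DEG in A vs B and A vs C with a quiet B vs C fold
# change. Root-length candidates: DEG in A vs B and B vs C with a quiet
# A vs C fold change. Selection is checked against the planted truth, and
# direction patterns are tallied (the length signature is counter-regulated
# by construction; the volume signature never is).

library(macetrait)

seed <- 1L
cfg <- pipeline_config(seed = seed)
hdr <- output_header(cfg)
roles_df <- read_table("results/truth_roles.tsv")
roles <- setNames(roles_df$role, roles_df$gene_id)

for (part in cfg$parts) {
  ab <- read_table(paste0("results/degs_AvB_", part, ".tsv"))
  ac <- read_table(paste0("results/degs_AvC_", part, ".tsv"))
  bc <- read_table(paste0("results/degs_BvC_", part, ".tsv"))
  common <- Reduce(intersect, list(ab$gene_id, ac$gene_id, bc$gene_id))
  restrict <- function(d) d[d$gene_id %in% common, ]
  v <- venn_partition(restrict(ab), restrict(ac), restrict(bc))
  cat("\n==", part, "root:", v$n_deg, "DEGs\n")
  print(v)
  for (trait in c("RV", "RL")) {
    cand <- if (trait == "RV") select_rv(ab, ac, bc, cfg$l2fc_min)
            else select_rl(ab, bc, ac, cfg$l2fc_min)
    s <- summarize_candidates(cand)
    planted <- names(roles)[startsWith(roles, trait)]
    cat(sprintf(
      "%s %s: %d candidates, sensitivity %.2f, %d cross-trait, %d null, %s%% up in trait-positive pools\n",
      trait, part, s$n, mean(planted %in% cand$gene_id),
      sum(startsWith(roles[cand$gene_id],
                     setdiff(c("RV", "RL"), trait))),
      sum(roles[cand$gene_id] == "null"), format(s$fraction_up_pct)))
    print(s$pattern_counts)
    write_table(cand, paste0("results/candidates_", trait, "_", part,
                             ".tsv"), comments = hdr)
    hm <- data.frame(gene_id = rownames(s$heatmap), s$heatmap,
                     check.names = FALSE)
    write_table(hm, paste0("results/heatmap_", trait, "_", part, ".tsv"),
                comments = hdr)
  }
}
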