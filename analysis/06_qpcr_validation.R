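#!/usr/bin/env Rscript
# Stage 6 — single-plant qPCR validation of recovered candidates.
#
# One recovered root-volume gene and one recovered root-length gene are
# measured by simulated qPCR in individual plants (positive relation to
# their phenotype), normalized against two reference genes with the
# efficiency-corrected ratio, and correlated with the phenotype after
# normality checks and Grubbs outlier removal — plus a no-relation control
# that should show no correlation.

library(macetrait)

seed <- 1L
cfg <- pipeline_config(seed = seed)
hdr <- output_header(cfg)

phen <- read_table("results/phenotypes.csv")
roles_df <- read_table("results/truth_roles.tsv")
roles <- setNames(roles_df$role, roles_df$gene_id)
rv <- read_table("results/candidates_RV_upper.tsv")$gene_id
rl <- read_table("results/candidates_RL_upper.tsv")$gene_id
rv <- rv[roles[rv] != "null"][1]
rl <- rl[roles[rl] != "null"][1]

targets <- data.frame(
  gene = c(rv, rl, "control"),
  relation = c("positive", "positive", "none"),
  against = c("volume_cm3", "length_cm", "volume_cm3"))
qp <- simulate_qpcr(phen, targets, reference_genes = cfg$reference_genes,
                    seed = stage_seed(seed, "qpcr"))
write_table(qp$cq, "results/qpcr_cq.csv", comments = hdr)
write_table(qp$efficiencies, "results/qpcr_efficiencies.csv",
            comments = hdr)

rows <- list()
for (i in seq_len(nrow(targets))) {
  g <- targets$gene[i]
  ne <- qpcr_normalize(qp$cq, qp$efficiencies, g, cfg$reference_genes)
  v <- phen[[targets$against[i]]][match(ne$plant_id, phen$plant_id)]
  rep <- correlate(v, ne$normalized_expression)
  cat("\n==", g, "(", targets$relation[i], "vs", targets$against[i], ")\n")
  print(rep)
  rows[[g]] <- data.frame(gene = g, relation = targets$relation[i],
                          against = targets$against[i],
                          n = rep$n_after, r = rep$r,
                          r_squared = rep$r_squared, slope = rep$slope)
}
write_table(do.call(rbind, rows), "results/validation_summary.tsv",
            comments = hdr)
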