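#!/usr/bin/env Rscript
# Stage 1 — generate the study-like synthetic dataset.
#
# Produces the three plant pools (A: thick/medium-length, B: short/thin,
# C: long/thin roots) with single-plant phenotypes, checks that the pools
# separate the way the design intends, and draws the six pooled tag-count
# libraries (pool x root part) with 50 planted root-volume and 50 planted
# root-length genes at effect size 4.

library(macetrait)

seed <- 1L
cfg <- pipeline_config(seed = seed)
dir.create("results", showWarnings = FALSE)
hdr <- output_header(cfg)

phen <- simulate_phenotypes(seed = stage_seed(seed, "phenotypes"))
write_table(phen, "results/phenotypes.csv", comments = hdr)
st <- pool_stats(phen)
write_table(st$tests, "results/pool_tests.tsv", comments = hdr)
cat("Plants per pool:\n")
print(table(phen$pool))
cat("\nPool contrasts (two-tailed t-tests):\n")
print(st$tests)

truth <- simulate_truth(n_genes = 1e4, n_rv = 50, n_rl = 50, effect = 4,
                        library_totals = 1e6, planted_min_prop = 5e-5,
                        seed = stage_seed(seed, "truth"))
sim <- simulate_counts(truth, seed = stage_seed(seed, "counts"))
write_counts(sim$counts, "results/counts.tsv", comments = hdr)
write_table(data.frame(gene_id = truth$gene_id, role = truth$roles),
            "results/truth_roles.tsv", comments = hdr)
cat("\nSimulated", nrow(sim$counts), "genes x", ncol(sim$counts),
    "libraries; totals:\n")
print(colSums(sim$counts))
cat("Planted:", sum(truth$roles != "null"), "genes (",
    sum(startsWith(truth$roles, "RV")), "RV,",
    sum(startsWith(truth$roles, "RL")), "RL )\n")
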