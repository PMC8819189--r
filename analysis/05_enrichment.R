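#!/usr/bin/env Rscript
# Stage 5 — GO term enrichment of the candidate sets.
#
# Background = all transcripts expressed in the corresponding root part.
# Annotations are simulated over a small demonstration hierarchy and closed
# under the true-path rule; each term is tested with chi-square or, when
# expected cells fall below 5, the exact hypergeometric test, two-sided,
# with the direction (enriched / underrepresented) reported separately.

library(macetrait)

seed <- 1L
cfg <- pipeline_config(seed = seed)
hdr <- output_header(cfg)
counts <- read_counts("results/counts.tsv")

edges <- toy_go_graph()
ann <- simulate_annotations(rownames(counts), edges,
                            seed = stage_seed(seed, "annotations"))
closed <- propagate_annotations(ann, edges)
cat("Annotations:", nrow(ann), "direct,", nrow(closed),
    "after true-path closure over", length(unique(c(edges$child,
                                                    edges$parent))),
    "terms\n")

for (part in cfg$parts) {
  libs <- paste0(cfg$pools, "_", part)
  background <- rownames(counts)[rowSums(counts[, libs]) > 0]
  for (trait in c("RV", "RL")) {
    cand_file <- paste0("results/candidates_", trait, "_", part, ".tsv")
    cand <- intersect(read_table(cand_file)$gene_id, background)
    if (!length(cand)) next
    res <- enrich_terms(cand, background, closed, edges,
                        alpha = cfg$enrich_alpha,
                        min_expected = cfg$enrich_min_expected)
    write_table(res, paste0("results/enrichment_", trait, "_", part,
                            ".tsv"), comments = hdr)
    sig <- res[res$significant, ]
    cat(sprintf("\n%s %s: %d terms tested, %d significant at %.2f\n",
                trait, part, nrow(res), nrow(sig), cfg$enrich_alpha))
    if (nrow(sig))
      print(sig[, c("term_id", "namespace", "level", "k", "K", "p",
                    "direction")], row.names = FALSE)
  }
}
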