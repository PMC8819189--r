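test_that("phenotype pools respect sizes, ranges and degenerate SDs", {
  phen <- simulate_phenotypes(seed = 2)
  sizes <- table(phen$pool)
  expect_true(all(sizes >= 21 & sizes <= 36))
  expect_true(all(phen$length_cm > 0 & phen$d1_mm > 0 & phen$d2_mm > 0))
  expect_equal(phen$volume_cm3, frustum_volume(phen$d1_mm, phen$d2_mm))

  pp <- default_pool_params()
  pp[, grep("_sd$", names(pp))] <- 0
  det <- simulate_phenotypes(n_per_pool = 5, pool_params = pp, seed = 1)
  expect_equal(sd(det$volume_cm3[det$pool == "A"]), 0)

  pp$length_sd[1] <- -1
  expect_error(simulate_phenotypes(pool_params = pp), "non-negative")
})

test_that("phenotype generation is reproducible under a fixed seed", {
  a <- simulate_phenotypes(seed = 33)
  b <- simulate_phenotypes(seed = 33)
  expect_identical(a, b)
})

test_that("library counts are exact multinomial draws of their totals", {
  truth <- simulate_truth(n_genes = 500, n_rv = 10, n_rl = 10,
                          library_totals = 5e4, seed = 1)
  sim <- simulate_counts(truth, seed = 2)
  expect_equal(unname(colSums(sim$counts)),
               unname(truth$library_totals[colnames(sim$counts)]))
  expect_true(all(sim$counts == round(sim$counts)))
  expect_identical(dim(sim$counts), c(500L, 6L))
})

test_that("a zero-proportion gene never produces counts", {
  truth <- simulate_truth(n_genes = 200, n_rv = 0, n_rl = 0,
                          library_totals = 1e4, seed = 3)
  truth$base_prop[1] <- 0
  truth$base_prop <- truth$base_prop / sum(truth$base_prop)
  cm <- simulate_counts(truth, seed = 4)$counts
  expect_true(all(cm[1, ] == 0))
})

test_that("a planted four-fold volume gene shows l2fc near 2 in A vs B", {
  truth <- simulate_truth(n_genes = 200, n_rv = 2, n_rl = 0, effect = 4,
                          library_totals = 1e5, planted_min_prop = 5e-3,
                          seed = 5)
  cm <- simulate_counts(truth, seed = 6)$counts
  res <- suppressMessages(mars_compare(cm, "A_upper", "B_upper"))
  up <- truth$gene_id[truth$roles == "RV_up"]
  expect_equal(res$l2fc_norm[res$gene_id == up], 2, tolerance = 0.3)
  dn <- truth$gene_id[truth$roles == "RV_down"]
  expect_equal(res$l2fc_norm[res$gene_id == dn], -2, tolerance = 0.3)
  # volume effects act in pool A only: B vs C stays quiet
  res_bc <- suppressMessages(mars_compare(cm, "B_upper", "C_upper"))
  expect_lt(abs(res_bc$l2fc_norm[res_bc$gene_id == up]), 0.5)
})

test_that("invalid effect sizes are rejected", {
  expect_error(simulate_truth(effect = 1), "effect")
  truth <- simulate_truth(n_genes = 200, library_totals = 1e4, seed = 1)
  truth$effect <- Inf
  expect_error(simulate_counts(truth), "non-normalizable")
})

test_that("simulated reads respect tag geometry and length bounds", {
  truth <- simulate_truth(n_genes = 150, n_rv = 4, n_rl = 4,
                          library_totals = 1e4, seed = 7)
  cm <- pmin(simulate_counts(truth, seed = 8)$counts[1:25, ], 30)
  rd <- simulate_reads(cm, polya_frac = 0.5, lowq_frac = 0.5, seed = 9)
  all_reads <- do.call(rbind, rd$reads)
  lens <- nchar(all_reads$seq)
  expect_gte(min(lens), 16)
  expect_lte(max(lens), 145)
  # noise off and transcripts without genomic poly(A): every read is an
  # exact transcript substring and survives preprocessing untouched
  set.seed(99)
  tx0 <- setNames(vapply(rep(900, nrow(cm)), function(L)
    paste(sample(c("C", "G", "T"), L, replace = TRUE), collapse = ""), ""),
    rownames(cm))
  rd0 <- simulate_reads(cm, transcripts = tx0, polya_frac = 0,
                        lowq_frac = 0, seed = 10)
  lib <- rd0$reads[[1]]
  tr <- rd0$truth_alignments[[1]]
  hit <- vapply(seq_len(nrow(lib)), function(i) {
    tx <- rd0$transcripts[[tr$transcript_id[i]]]
    substr(tx, tr$pos[i], tr$pos[i] + nchar(lib$seq[i]) - 1) == lib$seq[i]
  }, TRUE)
  expect_true(all(hit))
  pp <- preprocess_library(lib, pipeline_config())
  expect_identical(pp$reads, lib)
})

test_that("appended poly(A) tails are removed by preprocessing", {
  truth <- simulate_truth(n_genes = 120, n_rv = 0, n_rl = 0,
                          library_totals = 1e4, seed = 11)
  cm <- pmin(simulate_counts(truth, seed = 12)$counts[1:20, ], 25)
  rd <- simulate_reads(cm, polya_frac = 1, polya_len = c(20, 20),
                       lowq_frac = 0, seed = 13)
  cfg <- pipeline_config()
  for (lib in rd$reads[1:2]) {
    out <- preprocess_library(lib, cfg)$reads
    tails <- substring(out$seq, nchar(out$seq) - cfg$polya_min_run + 1)
    expect_false(any(tails == strrep("A", cfg$polya_min_run)))
  }
})

test_that("transcripts too short for the tag window are skipped", {
  cm <- matrix(5L, 2, 1, dimnames = list(c("gA", "gB"), "A_upper"))
  tx <- c(gA = strrep("ACGT", 200), gB = strrep("ACGT", 5))
  expect_warning(rd <- simulate_reads(cm, transcripts = tx, seed = 1),
                 "skipping 1")
  expect_true(all(rd$truth_alignments$A_upper$transcript_id == "gA"))
})

test_that("qPCR reference genes stay independent of the phenotype", {
  phen <- simulate_phenotypes(n_per_pool = 12, seed = 20)  # n = 36
  targets <- data.frame(gene = "cand1", relation = "none",
                        against = "volume_cm3")
  rs <- vapply(1:30, function(s) {
    qp <- simulate_qpcr(phen, targets, seed = s)
    ref_cq <- qp$cq$Cq[qp$cq$assay == "TkEF1a"]
    cor(phen$volume_cm3, ref_cq)
  }, 1)
  # independence: correlations centred on zero at the null sampling scale
  expect_lt(mean(abs(rs)), 0.2)
  expect_lt(abs(mean(rs)), 0.1)
  qp <- simulate_qpcr(phen, targets, seed = 1)
  expect_true(all(qp$efficiencies$amplification_base > 1.5 &
                    qp$efficiencies$amplification_base < 2.5))
  expect_error(simulate_qpcr(phen, targets, noise_sd = -1), "non-negative")
})

test_that("a no-relation target yields weak correlations and a null slope", {
  phen <- simulate_phenotypes(n_per_pool = 12, seed = 21)
  targets <- data.frame(gene = "cand1", relation = "none",
                        against = "length_cm")
  cover <- 0
  for (s in 1:20) {
    qp <- simulate_qpcr(phen, targets, seed = 100 + s)
    ne <- qpcr_normalize(qp$cq, qp$efficiencies, "cand1")
    v <- phen$length_cm[match(ne$plant_id, phen$plant_id)]
    fit <- lm(ne$normalized_expression ~ v)
    ci <- confint(fit)["v", ]
    if (ci[1] <= 0 && ci[2] >= 0) cover <- cover + 1
  }
  expect_gte(cover / 20, 0.8)
})
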