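test_that("direction classification follows the sign pair", {
  expect_identical(classify_direction(c(1.5, -1.1, 1.4), c(1.2, -2, -1.3)),
                   c("up_up", "down_down", "counter"))
  expect_error(classify_direction(0, 1), "exactly 0")
})

test_that("Venn partition handles empty and single-set membership", {
  g <- c("g1", "g2", "g3")
  none <- deg_fixture(g, c(0.1, 0.2, -0.1), rep(0.5, 3))
  v <- venn_partition(none, none, none)
  expect_equal(v$n_deg, 0)
  expect_true(all(vapply(v$regions, function(r) length(r$genes) == 0, TRUE)))

  only_ab <- deg_fixture(g, c(1.5, 0.1, 0.1), c(1e-5, 0.5, 0.5))
  v <- venn_partition(only_ab, none, none)
  expect_identical(v$regions$AvB_only$genes, "g1")
  expect_equal(unname(v$regions$AvB_only$tally["up"]), 1L)
  expect_equal(sum(vapply(v$regions, function(r) length(r$genes), 1L)), 1L)

  mismatched <- deg_fixture(c("g1", "g2"), c(0.1, 0.2), c(0.5, 0.5))
  expect_error(venn_partition(none, none, mismatched), "gene universe")
})

test_that("Venn region sizes match brute-force set arithmetic on random data", {
  set.seed(14)
  g <- sprintf("g%02d", 1:50)
  rand_deg <- function() {
    deg <- runif(50) < 0.3
    deg_fixture(g, ifelse(deg, sample(c(-1, 1), 50, TRUE) * runif(50, 1, 3),
                          runif(50, -0.9, 0.9)),
                ifelse(deg, 1e-6, 0.5))
  }
  for (rep in 1:10) {
    ab <- rand_deg(); ac <- rand_deg(); bc <- rand_deg()
    v <- venn_partition(ab, ac, bc)
    A <- g[ab$deg]; B <- g[ac$deg]; C <- g[bc$deg]
    expect_setequal(v$regions$AvB_only$genes, setdiff(A, union(B, C)))
    expect_setequal(v$regions$AvB_AvC$genes,
                    setdiff(intersect(A, B), C))
    expect_setequal(v$regions$all_three$genes,
                    intersect(A, intersect(B, C)))
    expect_equal(v$n_deg, length(union(A, union(B, C))))
    sizes <- vapply(v$regions, function(r) length(r$genes), 1L)
    expect_equal(sum(sizes), v$n_deg)  # disjoint cover
    tallies <- vapply(v$regions, function(r) sum(r$tally), 1L)
    expect_equal(unname(tallies), unname(sizes))
  }
})

test_that("RV selection applies the intersection and exclusion rule", {
  ab <- deg_fixture(c("g1", "g2", "g3"), c(1.5, 1.5, 1.2), rep(1e-5, 3))
  ac <- deg_fixture(c("g1", "g2", "g3"), c(1.2, 1.2, 1.4), rep(1e-4, 3))
  # g1: quiet in BvC -> candidate. g2: large but non-significant BvC fold
  # change -> still excluded (the robustness refinement). g3: quiet BvC.
  bc <- data.frame(gene_id = c("g1", "g2", "g3"),
                   l2fc_norm = c(0.3, 1.1, -0.2), p = c(0.4, 0.02, 0.6))
  rv <- select_rv(ab, ac, bc)
  expect_identical(rv$gene_id, c("g1", "g3"))
  expect_identical(rv$pattern, c("up_up", "up_up"))
  expect_equal(rv$l2fc_excl, c(0.3, -0.2))

  expect_error(select_rv(ab, ac, bc[1:2, ]), "missing")
})

test_that("RL selection keeps counter-regulated genes quiet in A vs C", {
  ab <- deg_fixture(c("g1", "g2"), c(1.4, 1.4), c(1e-5, 1e-5))
  bc <- deg_fixture(c("g1", "g2"), c(-1.3, 1.3), c(1e-4, 1e-4))
  ac <- data.frame(gene_id = c("g1", "g2"),
                   l2fc_norm = c(0.1, 2.7), p = c(0.7, 1e-8))
  rl <- select_rl(ab, bc, ac)
  # g2 is co-regulated: additivity pushes its AvC fold change past the
  # threshold, so only the counter-regulated g1 survives
  expect_identical(rl$gene_id, "g1")
  expect_identical(rl$pattern, "counter")
})

test_that("planted genes are recovered with clean trait separation", {
  truth <- simulate_truth(n_genes = 3000, n_rv = 30, n_rl = 30, effect = 4,
                          library_totals = 3e5, planted_min_prop = 2e-4,
                          seed = 5)
  cm <- simulate_counts(truth, seed = 6)$counts
  ab <- call_degs(suppressMessages(mars_compare(cm, "A_upper", "B_upper")))
  ac <- call_degs(suppressMessages(mars_compare(cm, "A_upper", "C_upper")))
  bc <- call_degs(suppressMessages(mars_compare(cm, "B_upper", "C_upper")))
  rv <- select_rv(ab, ac, bc)
  rl <- select_rl(ab, bc, ac)
  roles <- setNames(truth$roles, truth$gene_id)
  expect_gte(mean(truth$gene_id[startsWith(roles, "RV")] %in% rv$gene_id), 0.9)
  expect_gte(mean(truth$gene_id[startsWith(roles, "RL")] %in% rl$gene_id), 0.9)
  # disjoint outputs and deterministic gene-id ordering
  expect_length(intersect(rv$gene_id, rl$gene_id), 0)
  expect_identical(rv$gene_id, sort(rv$gene_id))
  # direction regularity: RL candidates counter-regulated, RV never
  expect_true(all(rl$pattern == "counter"))
  expect_true(all(rv$pattern != "counter"))
})

test_that("candidate summaries report trait-positive fractions and heatmaps", {
  ab <- deg_fixture(sprintf("g%02d", 1:10),
                    c(rep(1.5, 3), rep(-1.5, 7)), rep(1e-6, 10))
  ac <- deg_fixture(sprintf("g%02d", 1:10),
                    c(rep(1.2, 3), rep(-1.2, 7)), rep(1e-6, 10))
  bc <- data.frame(gene_id = sprintf("g%02d", 1:10),
                   l2fc_norm = rep(0.1, 10), p = rep(0.9, 10))
  rv <- select_rv(ab, ac, bc)
  s <- summarize_candidates(rv)
  expect_equal(s$n, 10)
  expect_equal(s$fraction_up_pct, 30)  # 3 of 10 up in pool A
  expect_equal(nrow(s$heatmap), 10)
  expect_identical(colnames(s$heatmap), c("A_vs_B", "A_vs_C", "B_vs_C"))

  empty <- rv[0, ]
  attributes(empty) <- attributes(rv)[c("names", "trait", "defining",
                                        "excluded", "class")]
  attr(empty, "row.names") <- integer()
  expect_message(s0 <- summarize_candidates(empty), "empty")
  expect_equal(s0$n, 0)
})
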