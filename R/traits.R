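#' Direction-pattern classification
#'
#' Classifies a candidate gene by the signs of its fold changes in the two
#' comparisons that define it: `"up_up"` (positive in both), `"down_down"`
#' (negative in both) or `"counter"` (opposite signs, the counter-regulated
#' pattern). A defining fold change of exactly zero is an error: such a gene
#' cannot have passed the DEG threshold.
#'
#' @param l2fc1,l2fc2 Fold changes in the two defining comparisons
#'   (vectors of equal length).
#' @return Character vector of patterns.
#' @export
classify_direction <- function(l2fc1, l2fc2) {
  stopifnot(length(l2fc1) == length(l2fc2))
  if (any(l2fc1 == 0) || any(l2fc2 == 0))
    stop("a defining log2 fold change of exactly 0 cannot be classified")
  ifelse(l2fc1 > 0 & l2fc2 > 0, "up_up",
         ifelse(l2fc1 < 0 & l2fc2 < 0, "down_down", "counter"))
}

.deg_genes <- function(deg) deg$gene_id[deg$deg]

.sign_pattern_tally <- function(signs_mat) {
  # signs_mat: genes x defining-comparison sign matrix (+1/-1)
  if (nrow(signs_mat) == 0 || ncol(signs_mat) == 0)
    return(c(up = 0L, down = 0L, up_up = 0L, down_down = 0L, counter = 0L)[0])
  if (ncol(signs_mat) == 1) {
    tab <- table(factor(ifelse(signs_mat[, 1] > 0, "up", "down"),
                        levels = c("up", "down")))
  } else {
    lab <- apply(signs_mat, 1, function(s)
      if (all(s > 0)) "up_up" else if (all(s < 0)) "down_down" else "counter")
    tab <- table(factor(lab, levels = c("up_up", "down_down", "counter")))
  }
  v <- as.integer(tab)
  names(v) <- names(tab)
  v
}

#' Three-set Venn partition of pairwise DEG calls
#'
#' Partitions the DEGs of one root part into the seven regions of the three
#' pairwise comparison sets (A vs B, A vs C, B vs C) and tallies direction
#' patterns (from the signs of `l2fc_norm`) over each region's defining
#' comparisons.
#'
#' @param deg_avb,deg_avc,deg_bvc `deg_table`s over the same gene universe.
#' @return A list of class `venn_partition`: per region, the gene ids and a
#'   direction tally; regions are disjoint and union to all DEGs.
#' @export
venn_partition <- function(deg_avb, deg_avc, deg_bvc) {
  u <- sort(deg_avb$gene_id)
  if (!identical(u, sort(deg_avc$gene_id)) ||
      !identical(u, sort(deg_bvc$gene_id)))
    stop("the three DEG tables must share one gene universe")
  sets <- list(AvB = .deg_genes(deg_avb), AvC = .deg_genes(deg_avc),
               BvC = .deg_genes(deg_bvc))
  l2fc <- list(
    AvB = setNames(deg_avb$l2fc_norm, deg_avb$gene_id),
    AvC = setNames(deg_avc$l2fc_norm, deg_avc$gene_id),
    BvC = setNames(deg_bvc$l2fc_norm, deg_bvc$gene_id))
  all_deg <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) all_deg %in% s,
                   logical(length(all_deg)))
  if (length(all_deg) <= 1)
    member <- matrix(member, nrow = length(all_deg), ncol = length(sets),
                     dimnames = list(all_deg, names(sets)))
  region_key <- c("100" = "AvB_only", "010" = "AvC_only", "001" = "BvC_only",
                  "110" = "AvB_AvC", "101" = "AvB_BvC", "011" = "AvC_BvC",
                  "111" = "all_three")
  key <- apply(member, 1, function(m) paste(as.integer(m), collapse = ""))
  regions <- lapply(names(region_key), function(k) {
    genes <- all_deg[key == k]
    comps <- names(sets)[as.logical(as.integer(strsplit(k, "")[[1]]))]
    signs <- matrix(NA_real_, length(genes), length(comps),
                    dimnames = list(genes, comps))
    for (cc in comps) signs[, cc] <- sign(l2fc[[cc]][genes])
    list(genes = genes, comparisons = comps,
         tally = .sign_pattern_tally(signs))
  })
  names(regions) <- region_key
  structure(list(regions = regions, n_deg = length(all_deg)),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Venn partition of", x$n_deg, "DEGs\n")
  for (r in names(x$regions)) {
    reg <- x$regions[[r]]
    tal <- paste(names(reg$tally), reg$tally, sep = ":", collapse = " ")
    cat(sprintf("  %-9s %5d  %s\n", r, length(reg$genes), tal))
  }
  invisible(x)
}

.select_candidates <- function(deg1, deg2, res_excl, l2fc_min, trait,
                               defining, excluded_label) {
  cand <- intersect(.deg_genes(deg1), .deg_genes(deg2))
  miss <- setdiff(cand, res_excl$gene_id)
  if (length(miss))
    stop("candidate gene(s) missing from the ", excluded_label,
         " results: ", paste(utils::head(miss, 3), collapse = ", "))
  cand <- sort(cand)
  i1 <- match(cand, deg1$gene_id)
  i2 <- match(cand, deg2$gene_id)
  ie <- match(cand, res_excl$gene_id)
  keep <- abs(res_excl$l2fc_norm[ie]) < l2fc_min
  cand <- cand[keep]; i1 <- i1[keep]; i2 <- i2[keep]; ie <- ie[keep]
  out <- data.frame(
    gene_id = cand,
    l2fc_def1 = deg1$l2fc_norm[i1], p_def1 = deg1$p[i1],
    l2fc_def2 = deg2$l2fc_norm[i2], p_def2 = deg2$p[i2],
    l2fc_excl = res_excl$l2fc_norm[ie], p_excl = res_excl$p[ie],
    stringsAsFactors = FALSE)
  out$pattern <- if (nrow(out)) classify_direction(out$l2fc_def1,
                                                   out$l2fc_def2) else character()
  attr(out, "trait") <- trait
  attr(out, "defining") <- defining
  attr(out, "excluded") <- excluded_label
  class(out) <- c("candidate_set", "data.frame")
  out
}

#' Root-volume candidate selection
#'
#' A gene is a root-volume (RV) candidate when it is a DEG in A vs B and in
#' A vs C while its fold change in the excluded comparison B vs C stays
#' below the DEG threshold: `|l2fc_norm(BvC)| < l2fc_min`, irrespective of
#' the B-vs-C p-value. This single rule subsumes both the Venn "not in the
#' third set" condition and the robustness refinement that drops genes whose
#' B-vs-C fold change is large but statistically unsupported.
#'
#' @param deg_avb,deg_avc `deg_table`s of the defining comparisons.
#' @param res_bvc Full (unthresholded) B-vs-C results; every candidate gene
#'   must be present.
#' @param l2fc_min DEG fold-change threshold (default 1).
#' @return A `candidate_set` data.frame, sorted by gene id, with the
#'   defining and excluded fold changes, p-values, and direction `pattern`.
#' @export
select_rv <- function(deg_avb, deg_avc, res_bvc, l2fc_min = 1) {
  .select_candidates(deg_avb, deg_avc, res_bvc, l2fc_min, trait = "RV",
                     defining = c("A_vs_B", "A_vs_C"),
                     excluded_label = "B_vs_C")
}

#' Root-length candidate selection
#'
#' A gene is a root-length (RL) candidate when it is a DEG in A vs B and in
#' B vs C while `|l2fc_norm(AvC)| < l2fc_min` in the excluded comparison
#' A vs C (pools A and C share long roots, so a length gene must not differ
#' between them).
#'
#' @param deg_avb,deg_bvc `deg_table`s of the defining comparisons.
#' @param res_avc Full (unthresholded) A-vs-C results.
#' @param l2fc_min DEG fold-change threshold (default 1).
#' @return A `candidate_set` data.frame (see [select_rv()]).
#' @export
select_rl <- function(deg_avb, deg_bvc, res_avc, l2fc_min = 1) {
  .select_candidates(deg_avb, deg_bvc, res_avc, l2fc_min, trait = "RL",
                     defining = c("A_vs_B", "B_vs_C"),
                     excluded_label = "A_vs_C")
}

#' Summarize a candidate set
#'
#' Reports the fraction of candidates expressed more strongly in the
#' trait-positive pools (RV: up in pool A, i.e. positive in both defining
#' comparisons; RL: up in pools A and C, i.e. positive in A vs B and
#' negative in B vs C) and assembles the fold-change matrix (genes x three
#' comparisons, ordered A vs B, A vs C, B vs C) used for heat-map rendering.
#'
#' @param cand A `candidate_set`.
#' @return List with `trait`, `n`, `fraction_up_pct`, `pattern_counts`, and
#'   `heatmap` (the l2fc matrix). Empty sets yield empty outputs with a
#'   message.
#' @export
summarize_candidates <- function(cand) {
  trait <- attr(cand, "trait")
  defining <- attr(cand, "defining")
  if (nrow(cand) == 0) {
    message("empty candidate set (", trait, ")")
    return(list(trait = trait, n = 0L, fraction_up_pct = NA_real_,
                pattern_counts = table(character()),
                heatmap = matrix(numeric(), 0, 3,
                                 dimnames = list(NULL, c("A_vs_B", "A_vs_C",
                                                         "B_vs_C")))))
  }
  up <- if (trait == "RV") cand$l2fc_def1 > 0 & cand$l2fc_def2 > 0
        else cand$l2fc_def1 > 0 & cand$l2fc_def2 < 0
  cols <- c(defining, attr(cand, "excluded"))
  hm <- cbind(cand$l2fc_def1, cand$l2fc_def2, cand$l2fc_excl)
  dimnames(hm) <- list(cand$gene_id, cols)
  hm <- hm[, c("A_vs_B", "A_vs_C", "B_vs_C"), drop = FALSE]
  list(trait = trait, n = nrow(cand),
       fraction_up_pct = round_half_up(100 * mean(up)),
       pattern_counts = table(cand$pattern),
       heatmap = hm)
}
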