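.go_graph <- function(edges) {
  stopifnot(all(c("child", "parent", "namespace") %in% names(edges)))
  g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                     directed = TRUE)
  if (!igraph::is_dag(g)) stop("GO hierarchy contains a cycle")
  g
}

.go_namespaces <- function(edges) {
  ns <- c(setNames(edges$namespace, edges$child),
          setNames(edges$namespace, edges$parent))
  ns[!duplicated(names(ns))]
}

#' Assign DAG levels to GO terms
#'
#' Level is one plus the shortest-path distance from the namespace root
#' (the unique term with no parent): the root sits at level 1, its direct
#' children at level 2, and a multi-parent term carries the minimum over its
#' parents. Each namespace must have exactly one root; cycles and orphans
#' (terms not reachable from their root) are errors.
#'
#' @param edges Child-to-parent edge list (`child`, `parent`, `namespace`).
#' @return Data.frame with `term_id`, `namespace`, `level`.
#' @export
assign_levels <- function(edges) {
  g <- .go_graph(edges)
  ns <- .go_namespaces(edges)
  terms <- names(ns)
  roots <- setdiff(unique(edges$parent), unique(edges$child))
  out <- lapply(unique(edges$namespace), function(space) {
    t_ns <- terms[ns == space]
    r <- intersect(roots, t_ns)
    if (length(r) != 1)
      stop("namespace '", space, "' must have exactly one root, found ",
           length(r))
    # edges point child -> parent; distance term -> root counts upward steps
    d <- igraph::distances(g, v = t_ns, to = r, mode = "out")[, 1]
    if (any(!is.finite(d)))
      stop("term(s) not connected to the root of '", space, "': ",
           paste(utils::head(t_ns[!is.finite(d)], 3), collapse = ", "))
    data.frame(term_id = t_ns, namespace = space, level = as.integer(d + 1),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$namespace, res$level, res$term_id), ]
}

#' True-path closure of gene annotations
#'
#' Annotates each gene to every ancestor of each of its terms (the true-path
#' rule), so that a gene counted at a specific term is also counted at all
#' more general terms. Idempotent; an ancestor reachable along several paths
#' of a diamond is counted once.
#'
#' @param annotations Data.frame with `gene_id`, `term_id`.
#' @param edges GO hierarchy edge list.
#' @return Closed annotation data.frame (`gene_id`, `term_id`), deduplicated
#'   and sorted.
#' @export
propagate_annotations <- function(annotations, edges) {
  g <- .go_graph(edges)
  known <- union(edges$child, edges$parent)
  orphans <- setdiff(unique(annotations$term_id), known)
  if (length(orphans))
    stop("annotated term(s) absent from the hierarchy: ",
         paste(orphans, collapse = ", "))
  terms <- unique(annotations$term_id)
  anc <- lapply(terms, function(t)
    names(igraph::subcomponent(g, t, mode = "out")))  # includes the term
  names(anc) <- terms
  out <- data.frame(
    gene_id = rep(annotations$gene_id,
                  lengths(anc[annotations$term_id])),
    term_id = unlist(anc[annotations$term_id], use.names = FALSE),
    stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$gene_id, out$term_id), ]
  rownames(out) <- NULL
  out
}

# Two-sided exact hypergeometric p: total probability of all tables whose
# point probability does not exceed the observed one (with the conventional
# (1 + 1e-7) tie slack, as in stats::fisher.test).
.hyper_two_sided <- function(k, K, N, n) {
  lo <- max(0, n - (N - K))
  hi <- min(n, K)
  d <- dhyper(lo:hi, K, N - K, n)
  d_obs <- dhyper(k, K, N - K, n)
  min(1, sum(d[d <= d_obs * (1 + 1e-7)]))
}

#' GO term enrichment of a candidate set
#'
#' Tests, for every GO term annotated in the background, whether the
#' candidate genes hit it more or less often than the background (all
#' transcripts of the corresponding root part). Each term's 2x2 table
#' (candidate vs non-candidate, annotated vs not) is tested with the Pearson
#' chi-square test, replaced by the two-sided exact hypergeometric (Fisher)
#' test whenever any expected cell falls below `min_expected`. Direction is
#' `"enriched"` when the candidate hit rate exceeds the background rate,
#' `"underrepresented"` otherwise. No multiple-testing correction is
#' applied; `significant` flags `p < alpha`.
#'
#' @param candidates Character vector of candidate gene ids (must be a
#'   subset of `background`).
#' @param background Character vector of background gene ids.
#' @param annotations Closed gene-to-term annotations (run
#'   [propagate_annotations()] first).
#' @param edges GO hierarchy edge list (for level assignment).
#' @param alpha Significance level (default 0.05).
#' @param min_expected Expected-cell threshold for the exact-test fallback
#'   (default 5).
#' @return Data.frame with term, namespace, level, counts (`k`, `n`, `K`,
#'   `N`), `p`, `test`, `direction`, `significant`, ordered by `p`.
#' @export
enrich_terms <- function(candidates, background, annotations, edges,
                         alpha = 0.05, min_expected = 5) {
  bad <- setdiff(candidates, background)
  if (length(bad))
    stop("candidate gene(s) not in the background: ",
         paste(utils::head(bad, 3), collapse = ", "))
  ann <- annotations[annotations$gene_id %in% background, , drop = FALSE]
  levels_df <- assign_levels(edges)
  N <- length(unique(background))
  n <- length(unique(candidates))
  by_term <- split(ann$gene_id, ann$term_id)
  rows <- lapply(names(by_term), function(term) {
    genes <- unique(by_term[[term]])
    K <- length(genes)
    k <- sum(genes %in% candidates)
    expd <- c(n * K, n * (N - K), (N - n) * K, (N - n) * (N - K)) / N
    if (any(expd < min_expected)) {
      p <- .hyper_two_sided(k, K, N, n)
      test <- "hypergeometric"
    } else {
      tab <- matrix(c(k, n - k, K - k, N - K - n + k), 2, 2)
      p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
      if (is.nan(p)) p <- 1  # degenerate margin
      test <- "chi-square"
    }
    data.frame(term_id = term, k = k, n = n, K = K, N = N, p = p,
               test = test,
               direction = if (k / n > K / N) "enriched" else "underrepresented",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- merge(res, levels_df, by = "term_id", all.x = TRUE)
  res$significant <- res$p < alpha
  res <- res[order(res$p, res$term_id), ]
  rownames(res) <- NULL
  res
}
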