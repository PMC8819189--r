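#' A small three-namespace GO-style hierarchy for demonstrations
#'
#' Hand-built DAG with one root per namespace, terms down to level 4 and a
#' diamond (multi-parent term), used by the demo pipeline and tests in place
#' of a full ontology snapshot.
#'
#' @return Edge-list data.frame (`child`, `parent`, `namespace`).
#' @export
toy_go_graph <- function() {
  bp <- rbind(
    c("metabolic_process", "biological_process"),
    c("response_to_stimulus", "biological_process"),
    c("cellular_metabolic_process", "metabolic_process"),
    c("small_molecule_metabolic_process", "metabolic_process"),
    c("macromolecule_metabolic_process", "metabolic_process"),
    c("response_to_chemical", "response_to_stimulus"),
    c("response_to_hormone", "response_to_chemical"),
    c("cellular_macromolecule_metabolic_process", "cellular_metabolic_process"),
    c("cellular_macromolecule_metabolic_process", "macromolecule_metabolic_process"))
  mf <- rbind(
    c("catalytic_activity", "molecular_function"),
    c("binding", "molecular_function"),
    c("hydrolase_activity", "catalytic_activity"),
    c("transferase_activity", "catalytic_activity"))
  cc <- rbind(
    c("cell_part", "cellular_component"),
    c("membrane", "cellular_component"),
    c("organelle", "cell_part"),
    c("membrane_part", "membrane"),
    c("intrinsic_component_of_membrane", "membrane_part"))
  edges <- rbind(
    data.frame(child = bp[, 1], parent = bp[, 2],
               namespace = "biological process", stringsAsFactors = FALSE),
    data.frame(child = mf[, 1], parent = mf[, 2],
               namespace = "molecular function", stringsAsFactors = FALSE),
    data.frame(child = cc[, 1], parent = cc[, 2],
               namespace = "cellular component", stringsAsFactors = FALSE))
  edges
}

#' Random gene-to-term annotations over a hierarchy
#'
#' Draws, per gene, a Poisson number of leaf terms (genes may stay
#' unannotated), yielding an unclosed annotation table for
#' [propagate_annotations()].
#'
#' @param gene_ids Genes to annotate.
#' @param edges Hierarchy edge list.
#' @param mean_terms Mean annotations per gene.
#' @param seed RNG seed.
#' @return Data.frame (`gene_id`, `term_id`).
#' @export
simulate_annotations <- function(gene_ids, edges, mean_terms = 2, seed = 1L) {
  set.seed(seed)
  leaves <- setdiff(edges$child, edges$parent)
  k <- rpois(length(gene_ids), mean_terms)
  data.frame(
    gene_id = rep(gene_ids, k),
    term_id = sample(leaves, sum(k), replace = TRUE),
    stringsAsFactors = FALSE)
}

.pairs_of <- function(pools) {
  list(c(pools[1], pools[2]), c(pools[1], pools[3]), c(pools[2], pools[3]))
}

#' Run the whole workflow on synthetic data
#'
#' Executes, under one configuration and one master seed (with independent
#' named substreams per stage): phenotype simulation and pool statistics;
#' tag-count simulation with planted trait genes; optionally a read-level
#' demonstration (read simulation, preprocessing, fractional counting) on a
#' small library subset; the six pairwise MARS comparisons (three pool
#' pairs x two root parts); Venn partition and the four candidate sets (RV
#' and RL x both parts) with recovery metrics against the planted truth; GO
#' enrichment of each candidate set against its root part's expressed
#' transcripts; and qPCR validation of one recovered gene per trait. When
#' `outdir` is given, every table is written in the TSV dialect with a
#' config-hash/seed header, plus a JSON run manifest; rerunning with the
#' same config and seed reproduces the outputs.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory (created if missing).
#' @param n_genes,n_rv,n_rl,effect,library_totals Generator scale (defaults
#'   are a desk-scale run; see [simulate_truth()] for the full-scale
#'   defaults the acceptance analyses use).
#' @param read_level Also run the read-level demonstration stage.
#' @return The run manifest (list), invisibly containing all stage outputs
#'   under `$data`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         n_genes = 2000, n_rv = 20, n_rl = 20, effect = 4,
                         library_totals = 2e5, read_level = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  ss <- function(stage) stage_seed(config$seed, stage)
  hdr <- output_header(config)
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   stages = list())
  emit <- function(name, df, file) {
    if (!is.null(outdir)) {
      path <- file.path(outdir, file)
      write_table(df, path, comments = hdr)
      path
    } else NA_character_
  }
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)

  # -- phenotypes ---------------------------------------------------------
  phen <- simulate_phenotypes(seed = ss("phenotypes"))
  pstats <- pool_stats(phen)
  manifest$stages$phenotypes <- list(
    n_plants = nrow(phen),
    file = emit("phenotypes", phen, "phenotypes.tsv"))

  # -- counts -------------------------------------------------------------
  truth <- simulate_truth(n_genes = n_genes, n_rv = n_rv, n_rl = n_rl,
                          effect = effect, library_totals = library_totals,
                          pools = config$pools, parts = config$parts,
                          seed = ss("truth"))
  sim <- simulate_counts(truth, seed = ss("counts"))
  counts <- sim$counts
  if (!is.null(outdir))
    write_counts(counts, file.path(outdir, "counts.tsv"), comments = hdr)
  manifest$stages$counts <- list(
    n_genes = nrow(counts), libraries = colnames(counts),
    totals = as.list(colSums(counts)))

  # -- optional read-level demonstration ---------------------------------
  if (read_level) {
    sub_genes <- utils::head(rownames(counts), 40)
    sub <- pmin(counts[sub_genes, , drop = FALSE], 50)
    rd <- simulate_reads(sub, seed = ss("reads"))
    pp <- lapply(rd$reads, preprocess_library, config = config)
    kept <- lapply(names(pp), function(lib) {
      tr <- rd$truth_alignments[[lib]]
      tr[tr$read_id %in% pp[[lib]]$reads$id, , drop = FALSE]
    })
    names(kept) <- names(pp)
    demo_counts <- build_count_matrix(kept, gene_ids = sub_genes)
    manifest$stages$reads <- list(
      input_reads = sum(vapply(pp, function(x) x$stats$input, 1)),
      clean_reads = sum(vapply(pp, function(x) x$stats$output, 1)),
      counted_reads = sum(demo_counts))
  }

  # -- differential expression -------------------------------------------
  pairs <- .pairs_of(config$pools)
  de <- list()
  for (part in config$parts) {
    for (pr in pairs) {
      l1 <- paste0(pr[1], "_", part)
      l2 <- paste0(pr[2], "_", part)
      res <- suppressMessages(mars_compare(counts, l1, l2))
      deg <- call_degs(res, config$l2fc_min, config$p_max)
      key <- paste0(pr[1], "v", pr[2], "_", part)
      de[[key]] <- deg
      emit(key, deg, paste0("degs_", key, ".tsv"))
    }
  }
  manifest$stages$de <- list(
    comparisons = names(de),
    n_deg = lapply(de, function(d) sum(d$deg)))

  # -- candidates ---------------------------------------------------------
  p <- config$pools
  cands <- list(); venns <- list()
  for (part in config$parts) {
    ab <- de[[paste0(p[1], "v", p[2], "_", part)]]
    ac <- de[[paste0(p[1], "v", p[3], "_", part)]]
    bc <- de[[paste0(p[2], "v", p[3], "_", part)]]
    common <- Reduce(intersect, list(ab$gene_id, ac$gene_id, bc$gene_id))
    restrict <- function(d) d[d$gene_id %in% common, , drop = FALSE]
    venns[[part]] <- venn_partition(restrict(ab), restrict(ac), restrict(bc))
    cands[[paste0("RV_", part)]] <- select_rv(ab, ac, bc, config$l2fc_min)
    cands[[paste0("RL_", part)]] <- select_rl(ab, bc, ac, config$l2fc_min)
  }
  for (key in names(cands)) emit(key, cands[[key]],
                                 paste0("candidates_", key, ".tsv"))
  roles <- setNames(truth$roles, truth$gene_id)
  recovery <- lapply(names(cands), function(key) {
    trait <- sub("_.*$", "", key)
    got <- cands[[key]]$gene_id
    planted <- truth$gene_id[startsWith(truth$roles, trait)]
    other <- truth$gene_id[startsWith(truth$roles,
                                      setdiff(c("RV", "RL"), trait))]
    list(n = length(got),
         sensitivity = if (length(planted)) mean(planted %in% got) else NA,
         cross_trait = sum(got %in% other),
         false_null = sum(roles[got] == "null"))
  })
  names(recovery) <- names(cands)
  manifest$stages$candidates <- list(
    sizes = lapply(cands, nrow), recovery = recovery)

  # -- enrichment ---------------------------------------------------------
  edges <- toy_go_graph()
  ann <- simulate_annotations(rownames(counts), edges,
                              seed = ss("annotations"))
  closed <- propagate_annotations(ann, edges)
  enr <- list()
  for (part in config$parts) {
    libs <- paste0(config$pools, "_", part)
    background <- rownames(counts)[rowSums(counts[, libs]) > 0]
    for (trait in c("RV", "RL")) {
      key <- paste0(trait, "_", part)
      cand <- intersect(cands[[key]]$gene_id, background)
      if (length(cand) == 0) next
      enr[[key]] <- enrich_terms(cand, background, closed, edges,
                                 alpha = config$enrich_alpha,
                                 min_expected = config$enrich_min_expected)
      emit(key, enr[[key]], paste0("enrichment_", key, ".tsv"))
    }
  }
  manifest$stages$enrichment <- list(
    tested_sets = names(enr),
    significant = lapply(enr, function(e) sum(e$significant)))

  # -- qPCR validation ----------------------------------------------------
  pick <- function(key, rel, against) {
    g <- cands[[key]]$gene_id
    g <- g[roles[g] != "null"]
    if (!length(g)) return(NULL)
    data.frame(gene = g[1], relation = rel, against = against,
               stringsAsFactors = FALSE)
  }
  targets <- rbind(pick(paste0("RV_", config$parts[1]), "positive",
                        "volume_cm3"),
                   pick(paste0("RL_", config$parts[1]), "positive",
                        "length_cm"))
  validation <- NULL
  if (!is.null(targets) && nrow(targets)) {
    qp <- simulate_qpcr(phen, targets,
                        reference_genes = config$reference_genes,
                        seed = ss("qpcr"))
    validation <- lapply(seq_len(nrow(targets)), function(i) {
      ne <- qpcr_normalize(qp$cq, qp$efficiencies, targets$gene[i],
                           config$reference_genes)
      v <- phen[[targets$against[i]]][match(ne$plant_id, phen$plant_id)]
      rep <- correlate(v, ne$normalized_expression)
      list(gene = targets$gene[i], against = targets$against[i],
           r = rep$r, r_squared = rep$r_squared, n = rep$n_after)
    })
    names(validation) <- targets$gene
  }
  manifest$stages$validation <- validation

  manifest$data <- list(phenotypes = phen, pool_stats = pstats,
                        counts = counts, truth = truth, de = de,
                        venn = venns, candidates = cands,
                        enrichment = enr)
  if (!is.null(outdir)) {
    out <- manifest
    out$data <- NULL
    jsonlite::write_json(out, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(manifest)
}
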