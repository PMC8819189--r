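#' Default phenotype distributions of the three plant pools
#'
#' Means and standard deviations of primary root length and the two upper
#' diameters per pool, chosen to emulate the study design: pool A (thick,
#' medium-to-long roots) clearly exceeds B and C in diameter, pools A and C
#' clearly exceed B in length, and B and C are alike in diameter while A and
#' C are alike in length. The study reports only boxplots for these
#' quantities, so the numbers are free generator parameters, not published
#' values.
#'
#' @return Data.frame with one row per pool.
#' @export
default_pool_params <- function() {
  data.frame(
    pool = c("A", "B", "C"),
    length_mean = c(17, 9, 19), length_sd = c(3, 2, 3.5),
    d1_mean = c(11, 5, 5), d1_sd = c(1.5, 0.8, 0.8),
    d2_mean = c(8, 3.5, 3.5), d2_sd = c(1.2, 0.6, 0.6),
    stringsAsFactors = FALSE)
}

.rnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  while (any(x <= 0)) x[x <= 0] <- rnorm(sum(x <= 0), mean, sd)
  x
}

#' Simulate single-plant phenotypes for the three pools
#'
#' Draws, per pool, a sample size in the requested range and truncated-normal
#' lengths and diameters from the pool parameters, then computes the upper
#' 5 cm frustum volume.
#'
#' @param n_per_pool Either a single size or a `c(min, max)` range (default
#'   21-36 plants, the pooling design of the study).
#' @param pool_params As [default_pool_params()]; SD 0 gives identical
#'   plants, negative SD is an error.
#' @param seed RNG seed.
#' @return Data.frame: `plant_id`, `pool`, `length_cm`, `d1_mm`, `d2_mm`,
#'   `volume_cm3`.
#' @export
simulate_phenotypes <- function(n_per_pool = c(21, 36),
                                pool_params = default_pool_params(),
                                seed = 1L) {
  sds <- unlist(pool_params[c("length_sd", "d1_sd", "d2_sd")])
  if (any(sds < 0)) stop("pool parameter SDs must be non-negative")
  if (any(unlist(pool_params[c("length_mean", "d1_mean", "d2_mean")]) <= 0))
    stop("pool parameter means must be positive")
  set.seed(seed)
  out <- lapply(seq_len(nrow(pool_params)), function(i) {
    pr <- pool_params[i, ]
    n <- if (length(n_per_pool) == 1) n_per_pool
         else sample(seq(n_per_pool[1], n_per_pool[2]), 1)
    data.frame(
      plant_id = sprintf("%s%02d", pr$pool, seq_len(n)),
      pool = pr$pool,
      length_cm = .rnorm_pos(n, pr$length_mean, pr$length_sd),
      d1_mm = .rnorm_pos(n, pr$d1_mean, pr$d1_sd),
      d2_mm = .rnorm_pos(n, pr$d2_mean, pr$d2_sd),
      stringsAsFactors = FALSE)
  })
  phen <- do.call(rbind, out)
  phen$volume_cm3 <- frustum_volume(phen$d1_mm, phen$d2_mm)
  phen
}

#' Ground truth for a pooled tag-count simulation
#'
#' Assigns each gene a role (`RV_up`, `RV_down`, `RL_up`, `RL_down`,
#' `null`), a base expression proportion (log-normal across genes,
#' normalized to sum to one), an effect size, and per-library totals. Effect
#' placement mirrors the phenotype contrasts: root-volume effects act in
#' pool A only, root-length effects in pools A and C, in both root parts.
#' Planted genes have their base proportion floored at `planted_min_prop`
#' so recovery is a property of the method, not of vanishing counts.
#'
#' @param n_genes Number of genes (>= 100).
#' @param n_rv,n_rl Planted root-volume / root-length genes (split evenly
#'   into up- and down-regulated).
#' @param effect Fold change applied in the affected pools (> 1).
#' @param library_totals Single total or named vector over the six
#'   libraries (>= 1e4).
#' @param base_sdlog Log-normal spread of base expression.
#' @param planted_min_prop Floor on planted genes' base proportion.
#' @param pools,parts Labels (defaults A/B/C, upper/tip).
#' @param seed RNG seed.
#' @return List of class `sim_truth`.
#' @export
simulate_truth <- function(n_genes = 10000, n_rv = 50, n_rl = 50,
                           effect = 4, library_totals = 1e6,
                           base_sdlog = 1, planted_min_prop = 5e-5,
                           pools = c("A", "B", "C"),
                           parts = c("upper", "tip"), seed = 1L) {
  stopifnot(n_genes >= 100, n_rv + n_rl <= n_genes)
  if (effect <= 1) stop("effect size must exceed 1")
  libs <- as.vector(t(outer(pools, parts, paste, sep = "_")))
  if (length(library_totals) == 1)
    library_totals <- setNames(rep(library_totals, length(libs)), libs)
  stopifnot(identical(sort(names(library_totals)), sort(libs)),
            all(library_totals >= 1e4))
  set.seed(seed)
  gene_id <- sprintf("g%05d", seq_len(n_genes))
  roles <- rep("null", n_genes)
  planted <- sample(n_genes, n_rv + n_rl)
  rv <- planted[seq_len(n_rv)]
  rl <- setdiff(planted, rv)
  roles[rv] <- rep(c("RV_up", "RV_down"), length.out = n_rv)
  roles[rl] <- rep(c("RL_up", "RL_down"), length.out = n_rl)
  base <- rlnorm(n_genes, meanlog = 0, sdlog = base_sdlog)
  base <- base / sum(base)
  base[planted] <- pmax(base[planted], planted_min_prop)
  base <- base / sum(base)
  structure(list(gene_id = gene_id, roles = roles, base_prop = base,
                 effect = effect, library_totals = library_totals[libs],
                 pools = pools, parts = parts),
            class = "sim_truth")
}

.library_props <- function(truth) {
  pools <- truth$pools
  libs <- names(truth$library_totals)
  e <- truth$effect
  vapply(libs, function(lib) {
    pool <- sub("_.*$", "", lib)
    p <- truth$base_prop
    if (pool == pools[1]) {                      # pool A: RV and RL effects
      p[truth$roles == "RV_up"] <- p[truth$roles == "RV_up"] * e
      p[truth$roles == "RV_down"] <- p[truth$roles == "RV_down"] / e
      p[truth$roles == "RL_up"] <- p[truth$roles == "RL_up"] * e
      p[truth$roles == "RL_down"] <- p[truth$roles == "RL_down"] / e
    } else if (pool == pools[3]) {               # pool C: RL effects only
      p[truth$roles == "RL_up"] <- p[truth$roles == "RL_up"] * e
      p[truth$roles == "RL_down"] <- p[truth$roles == "RL_down"] / e
    }
    s <- sum(p)
    if (!is.finite(s) || s <= 0)
      stop("effect size makes the proportion vector non-normalizable")
    p / s
  }, numeric(length(truth$base_prop)))
}

#' Simulate pooled tag-count libraries
#'
#' Each of the six libraries (pool x root part) is one multinomial draw of
#' its configured total from its proportion vector — exactly the random
#' sampling null the MARS test assumes, so test calibration is itself
#' testable. Counts per library sum exactly to the configured total.
#'
#' @param truth A [simulate_truth()] object.
#' @param seed RNG seed.
#' @return List with `counts` (integer matrix, genes x libraries) and
#'   `truth`.
#' @export
simulate_counts <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  props <- .library_props(truth)
  set.seed(seed)
  counts <- vapply(seq_len(ncol(props)), function(j)
    rmultinom(1, size = truth$library_totals[j], prob = props[, j])[, 1],
    numeric(nrow(props)))
  dimnames(counts) <- list(truth$gene_id, names(truth$library_totals))
  list(counts = counts, truth = truth)
}

#' Simulate MACE-like raw reads for a count matrix
#'
#' Emulates 3'-anchored tag sequencing: each transcript ends in a genomic
#' poly(A) stretch, read start positions fall 50-800 bp upstream of the 3'
#' end, and a configurable fraction of reads carries an appended poly(A)
#' suffix and/or low-quality (Q < 20) 3' bases. Read lengths stay within
#' 16-145 bp. Ground-truth alignments (`n_hits = 1`) are emitted alongside
#' for counting tests. Transcripts shorter than `min_offset` are skipped
#' with a warning.
#'
#' @param counts Integer count matrix (small/demo scale).
#' @param transcripts Optional named transcript sequences; generated when
#'   `NULL`.
#' @param polya_frac Fraction of reads with an appended poly(A) tail.
#' @param polya_len Tail length range.
#' @param lowq_frac Fraction of reads with a low-quality 3' stretch.
#' @param lowq_len Low-quality stretch length range.
#' @param read_len Nominal read length range (clipped to 16-145).
#' @param offset_range Distance of the read start upstream of the 3' end.
#' @param seed RNG seed.
#' @return List with `reads` (named list of FASTQ data.frames per library)
#'   and `truth_alignments` (named list of alignment tables).
#' @export
simulate_reads <- function(counts, transcripts = NULL,
                           polya_frac = 0.3, polya_len = c(8, 25),
                           lowq_frac = 0.2, lowq_len = c(3, 10),
                           read_len = c(30, 100),
                           offset_range = c(50, 800), seed = 1L) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (any(counts != round(counts))) stop("read simulation needs integer counts")
  set.seed(seed)
  genes <- rownames(counts)
  if (is.null(transcripts)) {
    lens <- sample(500:1500, length(genes), replace = TRUE)
    transcripts <- setNames(vapply(lens, function(L)
      paste0(paste(sample(c("A", "C", "G", "T"), L - 30, replace = TRUE),
                   collapse = ""),
             strrep("A", 30)), ""), genes)
  }
  tlen <- nchar(transcripts)
  short <- genes[tlen[genes] < offset_range[1]]
  if (length(short)) {
    warning("skipping ", length(short), " transcript(s) shorter than ",
            offset_range[1], " bp")
    genes <- setdiff(genes, short)
  }
  reads <- list(); truths <- list()
  for (lib in colnames(counts)) {
    gene_rep <- rep(genes, counts[genes, lib])
    n <- length(gene_rep)
    if (n == 0) {
      reads[[lib]] <- data.frame(id = character(), seq = character(),
                                 qual = character(), stringsAsFactors = FALSE)
      truths[[lib]] <- data.frame(read_id = character(),
                                  transcript_id = character(),
                                  pos = integer(), n_hits = integer(),
                                  is_split = logical(),
                                  stringsAsFactors = FALSE)
      next
    }
    L <- tlen[gene_rep]
    offset <- pmin(sample(offset_range[1]:offset_range[2], n, replace = TRUE),
                   L)
    start <- L - offset + 1
    rl <- pmin(sample(read_len[1]:read_len[2], n, replace = TRUE), offset)
    seqs <- substring(transcripts[gene_rep], start, start + rl - 1)
    quals <- vapply(rl, function(k)
      phred_string(sample(33:40, k, replace = TRUE)), "")
    tail_on <- runif(n) < polya_frac
    if (any(tail_on)) {
      tl <- sample(polya_len[1]:polya_len[2], sum(tail_on), replace = TRUE)
      tl <- pmin(tl, 145 - nchar(seqs[tail_on]))
      seqs[tail_on] <- paste0(seqs[tail_on], strrep("A", tl))
      quals[tail_on] <- paste0(quals[tail_on],
                               vapply(tl, function(k)
                                 phred_string(sample(33:40, k, replace = TRUE)),
                                 ""))
    }
    low_on <- runif(n) < lowq_frac
    if (any(low_on)) {
      for (i in which(low_on)) {
        k <- min(sample(lowq_len[1]:lowq_len[2], 1), nchar(quals[i]) - 1)
        good <- substr(quals[i], 1, nchar(quals[i]) - k)
        quals[i] <- paste0(good, phred_string(sample(2:15, k, replace = TRUE)))
      }
    }
    ids <- sprintf("%s_r%06d", lib, seq_len(n))
    reads[[lib]] <- data.frame(id = ids, seq = seqs, qual = quals,
                               stringsAsFactors = FALSE)
    truths[[lib]] <- data.frame(read_id = ids, transcript_id = gene_rep,
                                pos = unname(start), n_hits = 1L,
                                is_split = FALSE, stringsAsFactors = FALSE)
  }
  list(reads = reads, truth_alignments = truths, transcripts = transcripts)
}

#' Simulate single-plant qPCR measurements
#'
#' For each target gene, the true relative expression is linear in the
#' chosen phenotype variable (increasing, decreasing, or flat), so a
#' noiseless run recovers Pearson R of exactly +/-1. Quantification cycles
#' follow `Cq = Cq0 - log2(x) / log2(b)` with a per-assay amplification base
#' `b` near 2, plus Gaussian noise. Two reference genes are measured with
#' phenotype-independent expression.
#'
#' @param phenotypes A [simulate_phenotypes()] data.frame.
#' @param targets Data.frame (`gene`, `relation` in
#'   `c("positive", "negative", "none")`, `against` naming a phenotype
#'   column).
#' @param reference_genes Reference assay ids.
#' @param noise_sd Gaussian Cq noise (>= 0).
#' @param seed RNG seed.
#' @return List with `cq` (long table `plant_id`, `assay`, `Cq`),
#'   `efficiencies` (`assay`, `amplification_base`, `percent_efficiency`),
#'   and `targets`.
#' @export
simulate_qpcr <- function(phenotypes, targets,
                          reference_genes = c("TkEF1a", "TkRP"),
                          noise_sd = 0.25, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  stopifnot(all(c("gene", "relation", "against") %in% names(targets)),
            all(targets$relation %in% c("positive", "negative", "none")),
            all(targets$against %in% names(phenotypes)))
  set.seed(seed)
  assays <- c(targets$gene, reference_genes)
  b <- setNames(runif(length(assays), 1.9, 2.05), assays)
  rows <- list()
  for (i in seq_len(nrow(targets))) {
    g <- targets$gene[i]
    v <- phenotypes[[targets$against[i]]]
    x <- switch(targets$relation[i],
                positive = v / mean(v),
                # linear decrease that stays positive over the observed range
                negative = (max(v) + min(v) - v) / mean(v),
                none = rep(1, length(v)))
    cq <- 28 - log2(x) / log2(b[g]) + rnorm(length(v), 0, noise_sd)
    rows[[g]] <- data.frame(plant_id = phenotypes$plant_id, assay = g,
                            Cq = cq, stringsAsFactors = FALSE)
  }
  for (r in reference_genes) {
    cq <- 20 + rnorm(nrow(phenotypes), 0, noise_sd)
    rows[[r]] <- data.frame(plant_id = phenotypes$plant_id, assay = r,
                            Cq = cq, stringsAsFactors = FALSE)
  }
  list(cq = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       efficiencies = data.frame(assay = assays,
                                 amplification_base = unname(b),
                                 percent_efficiency = unname(b - 1) * 100,
                                 stringsAsFactors = FALSE),
       targets = targets)
}
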