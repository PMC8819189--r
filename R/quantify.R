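#' Round half away from zero
#'
#' Percentage reporting uses commercial rounding (half-up) rather than R's
#' banker's rounding, matching how alignment summary tables are printed.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Fractional read counting
#'
#' A read placed at `k` transcripts contributes `1/k` to each of them
#' ("partially counted multiple hits"); unmapped reads contribute nothing.
#' The column therefore sums exactly to the number of mapped reads.
#'
#' @param aln Alignment data.frame (see [read_alignments()]).
#' @param gene_ids Optional gene universe; missing genes get zero counts.
#'   A transcript-to-gene collapse map can be supplied as a named character
#'   vector via `collapse` (defaults to identity).
#' @param collapse Optional named character vector mapping transcript ids to
#'   gene ids.
#' @return Named numeric vector of fractional counts.
#' @export
count_reads <- function(aln, gene_ids = NULL, collapse = NULL) {
  validate_alignments(aln)
  mapped <- aln[aln$transcript_id != UNMAPPED & !is.na(aln$transcript_id), ,
                drop = FALSE]
  target <- mapped$transcript_id
  if (!is.null(collapse)) {
    hit <- target %in% names(collapse)
    target[hit] <- collapse[target[hit]]
  }
  if (nrow(mapped)) {
    agg <- rowsum(1 / mapped$n_hits, group = target)
    counts <- setNames(agg[, 1], rownames(agg))
  } else counts <- setNames(numeric(), character())
  if (!is.null(gene_ids)) {
    full <- setNames(numeric(length(gene_ids)), gene_ids)
    extra <- setdiff(names(counts), gene_ids)
    if (length(extra))
      stop("alignments reference genes outside the given universe: ",
           paste(utils::head(extra, 3), collapse = ", "))
    full[names(counts)] <- counts
    counts <- full
  }
  counts
}

#' Assemble a count matrix from per-library alignments
#'
#' @param aln_list Named list of alignment data.frames (names = library ids).
#' @param gene_ids Optional gene universe (default: union of targets, sorted).
#' @param collapse Optional transcript-to-gene map (see [count_reads()]).
#' @return Numeric matrix, genes x libraries.
#' @export
build_count_matrix <- function(aln_list, gene_ids = NULL, collapse = NULL) {
  stopifnot(length(aln_list) > 0, !is.null(names(aln_list)))
  cols <- lapply(aln_list, count_reads, gene_ids = gene_ids,
                 collapse = collapse)
  if (is.null(gene_ids))
    gene_ids <- sort(unique(unlist(lapply(cols, names))))
  m <- matrix(0, nrow = length(gene_ids), ncol = length(aln_list),
              dimnames = list(gene_ids, names(aln_list)))
  for (j in seq_along(cols)) m[names(cols[[j]]), j] <- cols[[j]]
  m
}

#' Mapping summary from category counts
#'
#' Computes the percentage layout of a per-library alignment summary table:
#' mapped and unmapped reads as a share of total clean reads, and unique,
#' multi-position and split reads — a disjoint partition of the mapped
#' reads — as shares of mapped reads. Percentages are rounded half-up to 2
#' decimals and recomputable from the stored counts.
#'
#' @param total_clean Total clean (preprocessed) reads.
#' @param mapped Mapped reads.
#' @param unique_matches Non-split reads with a single placement.
#' @param multi_position Non-split reads with more than one placement.
#' @param split_reads Reads mapped via a split alignment.
#' @return A list of class `mapping_summary` with counts and percentages.
#' @export
mapping_summary <- function(total_clean, mapped, unique_matches,
                            multi_position, split_reads) {
  if (total_clean <= 0) stop("total_clean must be positive")
  if (mapped > total_clean) stop("mapped cannot exceed total_clean")
  if (unique_matches + multi_position + split_reads != mapped)
    stop("unique_matches + multi_position + split_reads must equal mapped")
  unmapped <- total_clean - mapped
  structure(list(
    total_clean = total_clean,
    mapped = mapped, mapped_pct = round_half_up(100 * mapped / total_clean),
    unique_matches = unique_matches,
    unique_pct = round_half_up(100 * unique_matches / mapped),
    multi_position = multi_position,
    multi_pct = round_half_up(100 * multi_position / mapped),
    split_reads = split_reads,
    split_pct = round_half_up(100 * split_reads / mapped),
    unmapped = unmapped,
    unmapped_pct = round_half_up(100 * unmapped / total_clean)
  ), class = "mapping_summary")
}

#' Summarize mapping of one library
#'
#' Counts reads (not records) per category from alignment records and
#' delegates the percentage arithmetic to [mapping_summary()]. A read with
#' any split placement counts as a split read; the remaining mapped reads
#' divide into unique and multi-position by their number of hits.
#'
#' @param aln Alignment data.frame.
#' @param total_clean Total clean reads entering the aligner; must be at
#'   least the number of distinct mapped reads. Unmapped reads are
#'   `total_clean - mapped`.
#' @return A `mapping_summary`.
#' @export
summarize_mapping <- function(aln, total_clean) {
  if (total_clean == 0) stop("total_clean must be positive")
  validate_alignments(aln)
  mapped <- aln[aln$transcript_id != UNMAPPED & !is.na(aln$transcript_id), ,
                drop = FALSE]
  per_read_hits <- tapply(mapped$n_hits, mapped$read_id, `[`, 1)
  per_read_split <- tapply(mapped$is_split, mapped$read_id, any)
  n_mapped <- length(per_read_hits)
  if (total_clean < n_mapped)
    stop("total_clean is smaller than the number of mapped reads")
  split <- if (n_mapped) per_read_split else logical()
  mapping_summary(total_clean = total_clean,
                  mapped = n_mapped,
                  unique_matches = sum(per_read_hits == 1 & !split),
                  multi_position = sum(per_read_hits > 1 & !split),
                  split_reads = sum(split))
}

#' @export
print.mapping_summary <- function(x, ...) {
  cat("Mapping summary\n")
  cat(sprintf("  Total clean reads  %12.0f\n", x$total_clean))
  cat(sprintf("  Mapped reads       %12.0f (%.2f%%)\n", x$mapped, x$mapped_pct))
  cat(sprintf("  Unique matches     %12.0f (%.2f%% of mapped)\n",
              x$unique_matches, x$unique_pct))
  cat(sprintf("  Multi-position     %12.0f (%.2f%% of mapped)\n",
              x$multi_position, x$multi_pct))
  cat(sprintf("  Split reads        %12.0f (%.2f%% of mapped)\n",
              x$split_reads, x$split_pct))
  cat(sprintf("  Unmapped reads     %12.0f (%.2f%%)\n", x$unmapped,
              x$unmapped_pct))
  invisible(x)
}

#' @export
as.data.frame.mapping_summary <- function(x, ...) {
  data.frame(category = c("total_clean", "mapped", "unique_matches",
                          "multi_position", "split_reads", "unmapped"),
             count = c(x$total_clean, x$mapped, x$unique_matches,
                       x$multi_position, x$split_reads, x$unmapped),
             percent = c(NA, x$mapped_pct, x$unique_pct, x$multi_pct,
                         x$split_pct, x$unmapped_pct),
             stringsAsFactors = FALSE)
}
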