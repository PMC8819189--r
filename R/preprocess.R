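#' 3' quality trimming by the partial-sum rule
#'
#' Removes the 3' suffix that maximizes the accumulated score
#' `sum(q_min - Q_i)` over all candidate cut points (the empty suffix scores
#' zero, so reads with no sub-threshold run are untouched). This is the
#' trimming algorithm of BWA and cutadapt: isolated high-quality bases inside
#' a low-quality tail are removed together with it. Never lengthens a read;
#' idempotent. Ties are resolved toward the longer trim.
#'
#' @param reads Data.frame with columns `seq` and `qual` (Phred+33).
#' @param q_min Quality threshold (default 20).
#' @return The data.frame with trimmed `seq`/`qual`.
#' @export
trim_quality_3prime <- function(reads, q_min = 20L) {
  stopifnot(q_min >= 0)
  keep_len <- vapply(seq_len(nrow(reads)), function(i) {
    qual <- reads$qual[i]
    n <- nchar(qual)
    if (n == 0) return(0L)
    sc <- utf8ToInt(qual) - 33L
    gain <- rev(cumsum(rev(q_min - sc)))  # gain[k]: remove suffix k..n
    if (max(gain) <= 0) n else which.max(gain) - 1L
  }, 1L)
  reads$seq <- substring(reads$seq, 1, keep_len)
  reads$qual <- substring(reads$qual, 1, keep_len)
  reads
}

#' Poly(A) tail removal
#'
#' Removes the longest suffix of length at least `min_run` that starts and
#' ends in A and whose A-fraction is at least `1 - max_mismatch_frac` —
#' mismatches are tolerated inside the tail, never at its edges, so the
#' mismatch budget cannot eat into the transcript body. Only a suffix is
#' ever removed; internal bases are never touched; `N` never counts as A.
#' Idempotent: a remaining qualifying suffix would have qualified jointly
#' with the removed one and therefore cannot exist.
#'
#' @param reads Data.frame with columns `seq` and `qual`.
#' @param min_run Minimum removable tail length (>= 3).
#' @param max_mismatch_frac Maximum tolerated non-A fraction (in \[0, 0.5)).
#' @return The data.frame with trimmed `seq`/`qual`.
#' @export
trim_polyA <- function(reads, min_run = 5L, max_mismatch_frac = 0.1) {
  stopifnot(min_run >= 3, max_mismatch_frac >= 0, max_mismatch_frac < 0.5)
  cut_len <- vapply(reads$seq, function(s) {
    n <- nchar(s)
    if (n < min_run) return(0L)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    if (ch[n] != "A") return(0L)
    isA <- rev(ch) == "A"
    a_from_end <- cumsum(isA)
    len <- seq_len(n)
    ok <- len >= min_run & isA &              # suffix must start with A
      a_from_end >= (1 - max_mismatch_frac) * len
    if (!any(ok)) 0L else max(len[ok])
  }, 1L, USE.NAMES = FALSE)
  keep <- nchar(reads$seq) - cut_len
  reads$seq <- substring(reads$seq, 1, keep)
  reads$qual <- substring(reads$qual, 1, keep)
  reads
}

#' Minimum-length filter
#'
#' @param reads Data.frame with a `seq` column.
#' @param min_len Reads shorter than this are discarded (default 25 bp).
#' @return Logical vector: `TRUE` = keep.
#' @export
filter_length <- function(reads, min_len = 25L) {
  stopifnot(min_len >= 1)
  nchar(reads$seq) >= min_len
}

#' Preprocess one tag library
#'
#' Applies, per read and in this order: 3' quality trimming, poly(A) tail
#' removal, minimum-length filtering. Deterministic; read count is conserved
#' (`input = output + discarded`).
#'
#' @param reads A FASTQ data.frame (see [read_fastq()]) or a path to a FASTQ
#'   file.
#' @param config A [pipeline_config()] carrying the thresholds.
#' @return List with `reads` (the surviving, trimmed reads) and `stats`, a
#'   list of counters: `input`, `quality_trimmed`, `polya_trimmed`,
#'   `discarded`, `output`, `bp_in`, `bp_out`.
#' @export
preprocess_library <- function(reads, config = pipeline_config()) {
  if (is.character(reads)) reads <- read_fastq(reads)
  bp_in <- sum(nchar(reads$seq))
  n_in <- nrow(reads)
  len0 <- nchar(reads$seq)
  reads <- trim_quality_3prime(reads, config$phred_min)
  n_qtrim <- sum(nchar(reads$seq) < len0)
  len1 <- nchar(reads$seq)
  reads <- trim_polyA(reads, config$polya_min_run, config$polya_max_mismatch)
  n_ptrim <- sum(nchar(reads$seq) < len1)
  keep <- filter_length(reads, config$read_min_len)
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(reads = out,
       stats = list(input = n_in,
                    quality_trimmed = n_qtrim,
                    polya_trimmed = n_ptrim,
                    discarded = sum(!keep),
                    output = sum(keep),
                    bp_in = bp_in,
                    bp_out = sum(nchar(out$seq))))
}
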