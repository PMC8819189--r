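#' Read a FASTQ file of single-end tags
#'
#' Minimal strict reader for Phred+33 FASTQ. Every malformed four-line block
#' is reported with its record index; sequence and quality strings must have
#' equal length and bases must be A/C/G/T/N.
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return A data.frame with columns `id`, `seq`, `qual` (one row per read).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0)
    stop("FASTQ file does not consist of 4-line records: ", path)
  n <- length(lines) / 4
  if (n == 0)
    return(data.frame(id = character(), seq = character(), qual = character(),
                      stringsAsFactors = FALSE))
  ids <- lines[seq(1, by = 4, length.out = n)]
  seqs <- lines[seq(2, by = 4, length.out = n)]
  plus <- lines[seq(3, by = 4, length.out = n)]
  quals <- lines[seq(4, by = 4, length.out = n)]
  bad <- which(!startsWith(ids, "@") | !startsWith(plus, "+"))
  if (length(bad))
    stop("malformed FASTQ record at index ", bad[1])
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop("quality length differs from sequence length at record ", bad[1])
  bad <- which(!grepl("^[ACGTN]*$", seqs))
  if (length(bad))
    stop("invalid bases (expected A/C/G/T/N) at record ", bad[1])
  data.frame(id = substring(ids, 2), seq = seqs, qual = quals,
             stringsAsFactors = FALSE)
}

#' Write reads as FASTQ
#'
#' @param reads Data.frame with columns `id`, `seq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (nrow(reads) && any(nchar(reads$seq) != nchar(reads$qual)))
    stop("sequence/quality length mismatch")
  out <- character(4 * nrow(reads))
  if (nrow(reads)) {
    out[seq(1, by = 4, length.out = nrow(reads))] <- paste0("@", reads$id)
    out[seq(2, by = 4, length.out = nrow(reads))] <- reads$seq
    out[seq(3, by = 4, length.out = nrow(reads))] <- "+"
    out[seq(4, by = 4, length.out = nrow(reads))] <- reads$qual
  }
  writeLines(out, path)
  invisible(path)
}

#' Decode Phred+33 quality strings
#'
#' @param qual Character vector of quality strings.
#' @return A list of integer vectors of per-base Phred scores.
#' @export
phred_scores <- function(qual) {
  lapply(qual, function(q) if (nchar(q)) utf8ToInt(q) - 33L else integer())
}

#' Encode Phred scores as a Phred+33 string
#'
#' @param scores Integer vector of Phred scores.
#' @return A single quality string.
#' @export
phred_string <- function(scores) {
  if (!length(scores)) return("")
  intToUtf8(as.integer(scores) + 33L)
}

UNMAPPED <- "*"

#' Read alignment records
#'
#' Accepts either a SAM subset (header lines ignored; QNAME, FLAG, RNAME, POS
#' and the NH tag are used; FLAG bit 0x4 marks unmapped reads, bit 0x800
#' split/supplementary placements) or the simplified 5-column TSV dialect
#' (`read_id`, `transcript_id`, `pos`, `n_hits`, `is_split`) that the
#' simulator emits, so the pipeline can bypass an aligner entirely.
#'
#' All records of one read must agree on `n_hits`, and a mapped read must
#' have exactly `n_hits` placement lines; violations are errors.
#'
#' @param path Input path.
#' @param format `"auto"` (by extension), `"sam"`, or `"tsv"`.
#' @return A data.frame with columns `read_id`, `transcript_id` (`"*"` for
#'   unmapped), `pos`, `n_hits` (NA for unmapped), `is_split`.
#' @export
read_alignments <- function(path, format = c("auto", "sam", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "tsv"
  aln <- if (format == "sam") .read_sam_subset(path) else .read_aln_tsv(path)
  validate_alignments(aln)
  aln
}

.read_sam_subset <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(data.frame(read_id = character(), transcript_id = character(),
                      pos = integer(), n_hits = integer(), is_split = logical(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 4)
  if (length(short)) stop("SAM line ", short[1], " has fewer than 4 fields")
  qname <- vapply(fields, `[`, "", 1)
  flag <- as.integer(vapply(fields, `[`, "", 2))
  rname <- vapply(fields, `[`, "", 3)
  pos <- as.integer(vapply(fields, `[`, "", 4))
  nh <- vapply(fields, function(f) {
    tag <- grep("^NH:i:", f, value = TRUE)
    if (length(tag)) as.integer(sub("^NH:i:", "", tag[1])) else NA_integer_
  }, 1L)
  unmapped <- bitwAnd(flag, 4L) > 0
  is_split <- bitwAnd(flag, 2048L) > 0
  rname[unmapped] <- UNMAPPED
  nh[unmapped] <- NA_integer_
  pos[unmapped] <- 0L
  # infer n_hits from multiplicity when the NH tag is absent
  if (any(is.na(nh) & !unmapped)) {
    mult <- table(qname[!unmapped])
    miss <- is.na(nh) & !unmapped
    nh[miss] <- as.integer(mult[qname[miss]])
  }
  data.frame(read_id = qname, transcript_id = rname, pos = pos,
             n_hits = nh, is_split = is_split, stringsAsFactors = FALSE)
}

.read_aln_tsv <- function(path) {
  df <- read_table(path, required_cols = c("read_id", "transcript_id", "pos",
                                           "n_hits", "is_split"))
  df$read_id <- as.character(df$read_id)
  df$transcript_id <- as.character(df$transcript_id)
  df$pos <- as.integer(df$pos)
  df$n_hits <- suppressWarnings(as.integer(df$n_hits))
  df$is_split <- as.logical(df$is_split)
  df$n_hits[df$transcript_id == UNMAPPED] <- NA_integer_
  df
}

#' Validate alignment-record invariants
#'
#' @param aln Alignment data.frame as returned by [read_alignments()].
#' @return `aln`, invisibly; errors on violated invariants.
#' @export
validate_alignments <- function(aln) {
  need <- c("read_id", "transcript_id", "pos", "n_hits", "is_split")
  miss <- setdiff(need, names(aln))
  if (length(miss)) stop("alignment table lacks columns: ",
                         paste(miss, collapse = ", "))
  mapped <- aln$transcript_id != UNMAPPED & !is.na(aln$transcript_id)
  if (any(is.na(aln$n_hits[mapped])) || any(aln$n_hits[mapped] < 1))
    stop("mapped records must have n_hits >= 1")
  if (any(mapped)) {
    grp <- split(aln$n_hits[mapped], aln$read_id[mapped])
    k <- vapply(grp, function(v) length(unique(v)), 1L)
    if (any(k > 1))
      stop("records of read '", names(grp)[which(k > 1)[1]],
           "' disagree on n_hits")
    nhit <- vapply(grp, `[`, 1L, 1)
    npl <- lengths(grp)
    bad <- which(npl != nhit)
    if (length(bad))
      stop("read '", names(grp)[bad[1]], "' claims n_hits=", nhit[bad[1]],
           " but has ", npl[bad[1]], " placement record(s)")
  }
  invisible(aln)
}

#' Write alignment records in the TSV dialect
#'
#' @param aln Alignment data.frame.
#' @param path Output path.
#' @param comments Optional header comment lines (without `#`).
#' @return `path`, invisibly.
#' @export
write_alignments <- function(aln, path, comments = character()) {
  write_table(aln, path, comments = comments)
}

#' Write a TSV table with comment header
#'
#' Canonical on-disk table dialect: UTF-8, tab-separated, one header line,
#' `#`-prefixed comment lines on top. Doubles are serialized with full
#' precision (15 significant digits) so write/read round-trips are identity
#' for finite values.
#'
#' @param x A data.frame.
#' @param path Output path.
#' @param comments Character vector of comment lines (without the `#`).
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, comments = character()) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  num <- vapply(x, is.double, TRUE)
  x[num] <- lapply(x[num], function(v) format(v, digits = 15, trim = TRUE,
                                              scientific = NA))
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a TSV table written by [write_table()]
#'
#' @param path Input path.
#' @param required_cols Column names that must be present; missing names are
#'   listed in the error.
#' @return A data.frame.
#' @export
read_table <- function(path, required_cols = NULL) {
  df <- read.delim(path, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(required_cols)) {
    miss <- setdiff(required_cols, names(df))
    if (length(miss))
      stop("table ", path, " lacks required column(s): ",
           paste(miss, collapse = ", "))
  }
  df
}

#' Write a count matrix
#'
#' @param counts Numeric matrix, genes x libraries, with dimnames.
#' @param path Output path.
#' @param comments Optional header comment lines.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, comments = character()) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table(df, path, comments = comments)
}

#' Read a count matrix
#'
#' @param path Path to a TSV written by [write_counts()].
#' @return Numeric matrix, genes x libraries.
#' @export
read_counts <- function(path) {
  df <- read_table(path, required_cols = "gene_id")
  if (anyDuplicated(df$gene_id))
    stop("duplicated gene id in ", path, ": ",
         df$gene_id[duplicated(df$gene_id)][1])
  m <- as.matrix(df[setdiff(names(df), "gene_id")])
  if (!is.numeric(m)) stop("non-numeric count column in ", path)
  rownames(m) <- df$gene_id
  m
}

#' Read a gene-to-GO annotation table
#'
#' @param path 2-column TSV (`gene_id`, `term_id`), one pair per line.
#' @return A data.frame.
#' @export
read_annotations <- function(path) {
  df <- read_table(path, required_cols = c("gene_id", "term_id"))
  df$gene_id <- as.character(df$gene_id)
  df$term_id <- as.character(df$term_id)
  df
}

#' Read a GO hierarchy edge list
#'
#' @param path 3-column TSV (`child`, `parent`, `namespace`).
#' @return A data.frame of child-to-parent edges.
#' @export
read_go_edges <- function(path) {
  df <- read_table(path, required_cols = c("child", "parent", "namespace"))
  df$child <- as.character(df$child)
  df$parent <- as.character(df$parent)
  df$namespace <- as.character(df$namespace)
  df
}
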