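#' Pipeline configuration
#'
#' Bundles every tunable threshold of the workflow in one validated object.
#' Defaults mirror the filtering rules of the study design this package
#' implements: 3' bases below Phred 20 are trimmed, reads shorter than 25 bp
#' are discarded, and a gene is differentially expressed when its normalized
#' |log2 fold change| is at least 1 with p below 0.001.
#'
#' @param phred_min Quality threshold for 3' trimming (Phred scale, >= 0).
#' @param read_min_len Minimum read length kept after trimming (bp).
#' @param l2fc_min Minimum |normalized log2 fold change| for a DEG call (> 0).
#' @param p_max Strict upper bound on the MARS p-value for a DEG call (0, 1).
#' @param polya_min_run Minimum length of a removable poly(A) suffix (>= 3).
#' @param polya_max_mismatch Maximum non-A fraction tolerated in a poly(A)
#'   suffix (in \[0, 0.5)).
#' @param pools Ordered pool labels; comparisons are always
#'   first-pool-as-numerator over this order.
#' @param parts Ordered root-part labels.
#' @param enrich_alpha Significance level for GO enrichment calls.
#' @param enrich_min_expected Expected-cell threshold below which the
#'   chi-square test is replaced by the exact hypergeometric test.
#' @param reference_genes qPCR reference-gene assay ids (two expected).
#' @param seed Master RNG seed; all stage seeds derive from it.
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(phred_min = 20L,
                            read_min_len = 25L,
                            l2fc_min = 1,
                            p_max = 0.001,
                            polya_min_run = 5L,
                            polya_max_mismatch = 0.1,
                            pools = c("A", "B", "C"),
                            parts = c("upper", "tip"),
                            enrich_alpha = 0.05,
                            enrich_min_expected = 5,
                            reference_genes = c("TkEF1a", "TkRP"),
                            seed = 1L) {
  if (phred_min < 0) stop("phred_min must be >= 0")
  if (read_min_len < 1) stop("read_min_len must be >= 1")
  if (l2fc_min <= 0) stop("l2fc_min must be > 0")
  if (p_max <= 0 || p_max >= 1) stop("p_max must lie strictly in (0, 1)")
  if (polya_min_run < 3) stop("polya_min_run must be >= 3")
  if (polya_max_mismatch < 0 || polya_max_mismatch >= 0.5)
    stop("polya_max_mismatch must lie in [0, 0.5)")
  if (anyDuplicated(pools) || length(pools) != 3)
    stop("pools must be three distinct labels")
  if (anyDuplicated(parts) || length(parts) != 2)
    stop("parts must be two distinct labels")
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single number")
  structure(list(
    phred_min = as.integer(phred_min),
    read_min_len = as.integer(read_min_len),
    l2fc_min = as.numeric(l2fc_min),
    p_max = as.numeric(p_max),
    polya_min_run = as.integer(polya_min_run),
    polya_max_mismatch = as.numeric(polya_max_mismatch),
    pools = as.character(pools),
    parts = as.character(parts),
    enrich_alpha = as.numeric(enrich_alpha),
    enrich_min_expected = as.numeric(enrich_min_expected),
    reference_genes = as.character(reference_genes),
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

# 31-polynomial string hash mod 2^31 - 1, used for config fingerprints and
# stage seed derivation; stability across sessions matters, cryptography not.
.str_hash <- function(x) {
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 31 + b) %% 2147483647
  h
}

#' Fingerprint of a configuration
#'
#' Deterministic hex hash over all configuration fields, written into every
#' output table header so results can be traced to the settings that made them.
#'
#' @param config A `pipeline_config`.
#' @return An 8-character hex string.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  flat <- paste(names(config), vapply(config, function(v)
    paste(format(v, digits = 15), collapse = ","), ""), sep = "=", collapse = ";")
  sprintf("%08x", .str_hash(flat))
}

#' Derive a stage-specific seed
#'
#' Every stochastic stage draws from its own named substream so that adding or
#' re-running one stage never perturbs another. The derived seed is a
#' deterministic function of the master seed and the stage name, kept below
#' 2^31.
#'
#' @param seed Master seed (integer-valued).
#' @param stage Stage name, e.g. `"counts"`.
#' @return A single integer seed.
#' @export
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) %% 2147483647 * 10007 + .str_hash(stage)) %%
               2147483647)
}

#' Standard output-file header lines
#'
#' @param config A `pipeline_config`.
#' @return Character vector of comment lines (config hash and seed).
#' @export
output_header <- function(config) {
  c(paste0("config_hash=", config_hash(config)),
    paste0("seed=", config$seed))
}

#' Read a configuration file
#'
#' Parses the sectioned `key = value` text format written by
#' [write_config()]. Section headers (`[name]`) group keys cosmetically and
#' are ignored; `#` starts a comment; vector values are comma-separated.
#' Unknown keys are an error. Missing keys keep their defaults.
#'
#' @param path Path to a config file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  if (!all(grepl("=", lines, fixed = TRUE)))
    stop("config lines must be 'key = value' pairs")
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  known <- names(formals(pipeline_config))
  bad <- setdiff(keys, known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  args <- lapply(vals, function(v) {
    parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else parts
  })
  names(args) <- keys
  do.call(pipeline_config, args)
}

#' Write a configuration file
#'
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  sections <- list(
    thresholds = c("phred_min", "read_min_len", "l2fc_min", "p_max"),
    polya = c("polya_min_run", "polya_max_mismatch"),
    design = c("pools", "parts"),
    enrichment = c("enrich_alpha", "enrich_min_expected"),
    qpcr = "reference_genes",
    run = "seed")
  out <- c(paste0("# config_hash=", config_hash(config)))
  for (s in names(sections)) {
    out <- c(out, paste0("[", s, "]"))
    for (k in sections[[s]])
      out <- c(out, paste0(k, " = ",
                           paste(format(config[[k]], digits = 15), collapse = ",")))
  }
  writeLines(out, path)
  invisible(path)
}
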