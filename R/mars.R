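#' Pseudo-count adjustment for one-sided zeros
#'
#' A gene observed in only one of the two libraries has an undefined log
#' ratio; 0.5 is added to both counts so the fold change stays finite, and
#' the gene is flagged. Genes absent from both libraries carry no
#' information for the comparison and are an error here (callers exclude
#' them upstream).
#'
#' @param c1,c2 Non-negative count vectors (fractional counts allowed).
#' @return List with adjusted `c1`, `c2` and logical `adjusted`.
#' @export
handle_zeros <- function(c1, c2) {
  if (any(c1 < 0) || any(c2 < 0)) stop("counts must be non-negative")
  both0 <- c1 == 0 & c2 == 0
  if (any(both0))
    stop("gene(s) with zero counts in both libraries must be excluded ",
         "before testing (", sum(both0), " found)")
  adjusted <- (c1 == 0) != (c2 == 0)
  list(c1 = c1 + 0.5 * adjusted, c2 = c2 + 0.5 * adjusted,
       adjusted = adjusted)
}

#' MARS test for two un-replicated tag libraries
#'
#' MA-plot-based test with a random-sampling null: both libraries are
#' modelled as binomial draws (`C_i ~ Bin(n_i, p)`) from a common expression
#' proportion `p`. With `M = log2(c1) - log2(c2)` and
#' `A = (log2(c1) + log2(c2))/2`, the common proportion is estimated as
#' `p_hat = 2^A / sqrt(n1 * n2)` (clipped into
#' `[1/(n1+n2), 1 - 1/(n1+n2)]`), and the null moments are
#' `E(M|A) = log2(n1/n2)` and
#' `Var(M|A) = (1/ln(2)^2) (1 - p_hat) (1/(n1 p_hat) + 1/(n2 p_hat))`.
#' The z-score `(M - E(M|A)) / sqrt(Var(M|A))` is referred to the standard
#' normal, two-sided. The library-size-corrected fold change
#' `l2fc_norm = M - log2(n1/n2)` is what DEG thresholds are applied to; raw
#' `M` is kept alongside for transparency.
#'
#' One-sided zero counts are adjusted by [handle_zeros()]; genes zero in
#' both libraries must be excluded upstream (see [mars_compare()]).
#'
#' @param c1,c2 Counts in library 1 and 2 (vectors; fractional allowed).
#' @param n1,n2 Library totals (positive scalars).
#' @param gene_id Optional gene ids carried into the result.
#' @return Data.frame with columns `gene_id` (if given), `c1`, `c2`, `M`,
#'   `A`, `l2fc_norm`, `z`, `p`, `zero_adjusted`.
#' @export
mars_test <- function(c1, c2, n1, n2, gene_id = NULL) {
  if (length(n1) != 1 || length(n2) != 1 || n1 <= 0 || n2 <= 0)
    stop("n1 and n2 must be positive scalars")
  n1 <- as.numeric(n1); n2 <- as.numeric(n2)
  adj <- handle_zeros(as.numeric(c1), as.numeric(c2))
  M <- log2(adj$c1) - log2(adj$c2)
  A <- (log2(adj$c1) + log2(adj$c2)) / 2
  p_hat <- 2^A / sqrt(n1 * n2)
  p_hat <- pmin(pmax(p_hat, 1 / (n1 + n2)), 1 - 1 / (n1 + n2))
  e_m <- log2(n1 / n2)
  var_m <- (1 / log(2)^2) * (1 - p_hat) * (1 / (n1 * p_hat) + 1 / (n2 * p_hat))
  z <- (M - e_m) / sqrt(var_m)
  p <- 2 * pnorm(-abs(z))
  out <- data.frame(c1 = c1, c2 = c2, M = M, A = A,
                    l2fc_norm = M - e_m, z = z, p = p,
                    zero_adjusted = adj$adjusted)
  if (!is.null(gene_id)) out <- cbind(gene_id = gene_id, out)
  out
}

#' Run the MARS test on two columns of a count matrix
#'
#' Extracts the two libraries, excludes genes with zero counts in both (they
#' are reported via a message and recorded in the `excluded` attribute), and
#' tests every remaining gene. Library totals are the column sums.
#'
#' @param counts Numeric count matrix (genes x libraries, dimnames set).
#' @param lib1,lib2 Column names; `lib1` is the numerator library.
#' @return A `mars_result` data.frame with attributes `comparison`
#'   (`"lib1_vs_lib2"`), `n1`, `n2`, `excluded` (gene ids zero in both).
#' @export
mars_compare <- function(counts, lib1, lib2) {
  stopifnot(is.matrix(counts), all(c(lib1, lib2) %in% colnames(counts)))
  c1 <- counts[, lib1]
  c2 <- counts[, lib2]
  n1 <- sum(c1)
  n2 <- sum(c2)
  both0 <- c1 == 0 & c2 == 0
  if (any(both0))
    message(sum(both0), " gene(s) with zero counts in both libraries ",
            "excluded from ", lib1, " vs ", lib2)
  res <- mars_test(c1[!both0], c2[!both0], n1, n2,
                   gene_id = rownames(counts)[!both0])
  attr(res, "comparison") <- paste0(lib1, "_vs_", lib2)
  attr(res, "n1") <- n1
  attr(res, "n2") <- n2
  attr(res, "excluded") <- rownames(counts)[both0]
  class(res) <- c("mars_result", "data.frame")
  res
}

#' Call differentially expressed genes
#'
#' A gene is a DEG when `|l2fc_norm| >= l2fc_min` (boundary included) and
#' `p < p_max` (boundary excluded). No multiple-testing correction is
#' applied; the selection rule operates on raw p-values.
#'
#' @param res A `mars_result` (or any data.frame with `l2fc_norm` and `p`).
#' @param l2fc_min Minimum absolute normalized log2 fold change (default 1).
#' @param p_max Strict p-value ceiling (default 0.001).
#' @return The input with a logical `deg` column, classed `deg_table`;
#'   attributes of `res` are preserved.
#' @export
call_degs <- function(res, l2fc_min = 1, p_max = 0.001) {
  stopifnot(l2fc_min > 0, p_max > 0)
  res$deg <- abs(res$l2fc_norm) >= l2fc_min & res$p < p_max
  class(res) <- unique(c("deg_table", class(res)))
  attr(res, "l2fc_min") <- l2fc_min
  attr(res, "p_max") <- p_max
  res
}
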