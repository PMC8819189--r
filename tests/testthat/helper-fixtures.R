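# Programmatic fixtures shared across test files.

random_reads <- function(n, len = c(20, 80), seed = 1,
                         polya_frac = 0.3, lowq_frac = 0.3) {
  set.seed(seed)
  lens <- sample(len[1]:len[2], n, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T", "N"), L, replace = TRUE,
                 prob = c(0.3, 0.23, 0.23, 0.23, 0.01)), collapse = ""), "")
  quals <- vapply(lens, function(L)
    phred_string(sample(25:40, L, replace = TRUE)), "")
  tail_on <- runif(n) < polya_frac
  tl <- sample(5:20, n, replace = TRUE)
  seqs[tail_on] <- paste0(seqs[tail_on], strrep("A", tl[tail_on]))
  quals[tail_on] <- paste0(quals[tail_on],
                           vapply(tl[tail_on], function(k)
                             phred_string(sample(30:40, k, replace = TRUE)), ""))
  low_on <- runif(n) < lowq_frac
  for (i in which(low_on)) {
    k <- min(sample(3:12, 1), nchar(quals[i]))
    quals[i] <- paste0(substr(quals[i], 1, nchar(quals[i]) - k),
                       phred_string(sample(2:15, k, replace = TRUE)))
  }
  data.frame(id = sprintf("r%04d", seq_len(n)), seq = seqs, qual = quals,
             stringsAsFactors = FALSE)
}

# an alignment table: two unique reads, one double-mapper, one unmapped
toy_alignments <- function() {
  data.frame(
    read_id = c("r1", "r2", "r3", "r3", "r4"),
    transcript_id = c("g1", "g2", "g1", "g3", "*"),
    pos = c(10L, 5L, 7L, 99L, 0L),
    n_hits = c(1L, 1L, 2L, 2L, NA),
    is_split = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

# minimal DEG table for the traits module
deg_fixture <- function(gene_id, l2fc, p, l2fc_min = 1, p_max = 0.001) {
  call_degs(data.frame(gene_id = gene_id, l2fc_norm = l2fc, p = p,
                       stringsAsFactors = FALSE), l2fc_min, p_max)
}

# independent two-sided hypergeometric oracle via direct binomial
# coefficients (the implementation uses dhyper)
hyper_oracle <- function(k, K, N, n) {
  x <- max(0, n - (N - K)):min(n, K)
  lp <- lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
  p <- exp(lp)
  pk <- exp(lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n))
  min(1, sum(p[p <= pk * (1 + 1e-7)]))
}

# independent delta-method z oracle with numerical differentiation
mars_z_oracle <- function(c1, c2, n1, n2) {
  M <- log2(c1) - log2(c2)
  A <- (log2(c1) + log2(c2)) / 2
  ph <- min(max(2^A / sqrt(n1 * n2), 1 / (n1 + n2)), 1 - 1 / (n1 + n2))
  mu1 <- n1 * ph; mu2 <- n2 * ph
  h1 <- mu1 * 1e-5; h2 <- mu2 * 1e-5
  d1 <- (log2(mu1 + h1) - log2(mu1 - h1)) / (2 * h1)
  d2 <- (log2(mu2 + h2) - log2(mu2 - h2)) / (2 * h2)
  v <- d1^2 * n1 * ph * (1 - ph) + d2^2 * n2 * ph * (1 - ph)
  (M - log2(n1 / n2)) / sqrt(v)
}
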