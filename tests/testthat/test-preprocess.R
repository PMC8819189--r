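one_read <- function(seq, scores) {
  data.frame(id = "r", seq = seq, qual = phred_string(scores),
             stringsAsFactors = FALSE)
}

# brute-force oracle: remove the suffix maximizing sum(q_min - Q); keep the
# whole read unless some suffix scores strictly positive, ties toward the
# longer trim
qtrim_oracle_len <- function(scores, q_min) {
  n <- length(scores)
  gains <- vapply(seq_len(n), function(k) sum(q_min - scores[k:n]), 1)
  if (max(gains) <= 0) n else which.max(gains) - 1L
}

test_that("3' quality trimming follows the partial-sum rule", {
  rd <- one_read("ACGTACG", rep(30, 7))
  expect_identical(trim_quality_3prime(rd)$seq, "ACGTACG")

  rd <- one_read("ACGTACG", rep(2, 7))
  expect_identical(trim_quality_3prime(rd)$seq, "")

  # a high-quality base inside the low tail is removed with it: the optimal
  # cut (oracle below) keeps the first 3 bases, not the first 5
  sc <- c(30, 30, 30, 10, 25, 5, 5)
  expect_identical(qtrim_oracle_len(sc, 20), 3L)
  rd <- one_read("ACGTACG", sc)
  out <- trim_quality_3prime(rd, 20)
  expect_identical(out$seq, "ACG")
  expect_identical(nchar(out$qual), 3L)
})

test_that("quality trimming matches the brute-force oracle on random reads", {
  set.seed(5)
  for (i in 1:200) {
    n <- sample(1:60, 1)
    sc <- sample(2:40, n, replace = TRUE)
    rd <- one_read(strrep("A", n), sc)
    expect_identical(nchar(trim_quality_3prime(rd, 20)$seq),
                     qtrim_oracle_len(sc, 20))
  }
})

test_that("poly(A) trimming removes only qualifying suffixes", {
  rd <- function(s) data.frame(id = "r", seq = s,
                               qual = strrep("I", nchar(s)),
                               stringsAsFactors = FALSE)
  expect_identical(trim_polyA(rd(paste0("ACGT", strrep("A", 10))),
                              5, 0.1)$seq, "ACGT")
  # internal A run is not a suffix
  expect_identical(trim_polyA(rd("AAAACGTC"), 5, 0.1)$seq, "AAAACGTC")
  # one mismatch inside a 10-base tail is within a 0.1 mismatch budget
  expect_identical(trim_polyA(rd("ACGTAAAAGAAAAA"), 5, 0.1)$seq, "ACGT")
  # the same tail at 0 tolerance only loses its trailing pure-A run
  expect_identical(trim_polyA(rd("ACGTAAAAGAAAAA"), 5, 0)$seq, "ACGTAAAAG")
  # N never counts as A
  expect_identical(trim_polyA(rd(paste0("ACGT", "AANAA")), 5, 0.1)$seq,
                   paste0("ACGT", "AANAA"))
  # must end in A
  expect_identical(trim_polyA(rd("ACGTAAAAAG"), 5, 0.1)$seq, "ACGTAAAAAG")
})

test_that("poly(A) trimming finds the longest qualifying suffix (oracle)", {
  patrim_oracle <- function(s, min_run, mm) {
    ch <- strsplit(s, "")[[1]]; n <- length(ch)
    best <- 0
    for (L in seq_len(n)) {
      suf <- ch[(n - L + 1):n]
      if (L >= min_run && suf[1] == "A" && suf[L] == "A" &&
          mean(suf == "A") >= 1 - mm)
        best <- L
    }
    substr(s, 1, n - best)
  }
  set.seed(9)
  for (i in 1:200) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(5:40, 1), replace = TRUE,
                      prob = c(0.5, 0.17, 0.17, 0.16)), collapse = "")
    rd <- data.frame(id = "r", seq = s, qual = strrep("I", nchar(s)),
                     stringsAsFactors = FALSE)
    expect_identical(trim_polyA(rd, 5, 0.1)$seq, patrim_oracle(s, 5, 0.1))
  }
})

test_that("length filter boundary is keep-at-25, discard-below", {
  rd <- data.frame(seq = c(strrep("A", 24), strrep("A", 25), ""),
                   stringsAsFactors = FALSE)
  expect_identical(filter_length(rd, 25), c(FALSE, TRUE, FALSE))
})

test_that("library preprocessing conserves reads and is idempotent", {
  reads <- random_reads(300, seed = 11)
  cfg <- pipeline_config()
  out1 <- preprocess_library(reads, cfg)
  st <- out1$stats
  expect_equal(st$input, 300)
  expect_equal(st$output + st$discarded, st$input)
  expect_true(st$bp_out <= st$bp_in)
  out2 <- preprocess_library(out1$reads, cfg)
  expect_identical(out2$reads, out1$reads)
  expect_equal(out2$stats$discarded, 0)
  # trimming only ever removes a suffix
  kept <- match(out1$reads$id, reads$id)
  expect_true(all(startsWith(reads$seq[kept], out1$reads$seq)))
})

test_that("clean libraries pass through and short libraries empty out", {
  clean <- data.frame(id = c("a", "b"),
                      seq = c(strrep("ACGT", 10), strrep("GATC", 10)),
                      qual = c(strrep("I", 40), strrep("I", 40)),
                      stringsAsFactors = FALSE)
  out <- preprocess_library(clean, pipeline_config())
  expect_identical(out$reads, clean)
  expect_equal(out$stats$discarded, 0)

  short <- data.frame(id = sprintf("s%d", 1:5),
                      seq = rep(strrep("C", 20), 5),
                      qual = rep(strrep("I", 20), 5),
                      stringsAsFactors = FALSE)
  out <- preprocess_library(short, pipeline_config())
  expect_equal(out$stats$output, 0)
  expect_equal(out$stats$discarded, 5)
})
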