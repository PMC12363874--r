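# In-code fixtures shared across test files.

# A tiny hand-built alignment: 10 query columns, varied coverage/identity.
tiny_alignment <- function() {
  alignment(c(
    q  = "ACDEFGHIKL",
    h1 = "ACDEFGHIKL",   # identical to query
    h2 = "ACDEFGHIML",   # 9/10 identity
    h3 = "GCDAAGHIKV",   # lower identity, full coverage
    h4 = "ACDEFG----",   # 6/10 coverage
    h5 = "ACDEFGH---"    # 7/10 coverage
  ), "q")
}

# Two blocks of identical sequences differing at half the columns.
two_block_alignment <- function(block_size = 6) {
  s1 <- "AAAACCCC"
  s2 <- "AAAAGGGG"
  seqs <- c(rep(s1, block_size), rep(s2, block_size))
  names(seqs) <- c("q", paste0("a", seq_len(block_size - 1)),
                   paste0("b", seq_len(block_size)))
  alignment(seqs, "q")
}

# Random gapped alignment for property-style tests.
random_alignment <- function(n = 40, l = 25, gap_rate = 0.1, seed = 1,
                             alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  set.seed(seed)
  mat <- matrix(sample(alphabet, n * l, replace = TRUE), n, l)
  mat[-1, ][matrix(runif((n - 1) * l) < gap_rate, n - 1, l)] <- "-"
  seqs <- apply(mat, 1, paste, collapse = "")
  names(seqs) <- c("q", paste0("s", seq_len(n - 1)))
  alignment(seqs, "q")
}

# Random partition of n rows into k non-empty groups.
random_partition <- function(n, k) {
  labels <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))
  sample(labels)
}

expect_same_partition <- function(labels_a, labels_b) {
  expect_equal(adjusted_rand_index(labels_a, labels_b), 1)
}
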