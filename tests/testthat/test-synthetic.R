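test_that("generator output is bit-for-bit reproducible from params + seed", {
  g1 <- generate_planted_msa(seed = 13)
  g2 <- generate_planted_msa(seed = 13)
  expect_identical(g1$alignment$mat, g2$alignment$mat)
  expect_identical(g1$truth, g2$truth)

  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  t1 <- withr::local_tempfile(fileext = ".tsv")
  t2 <- withr::local_tempfile(fileext = ".tsv")
  write_planted_msa(g1, f1, t1)
  write_planted_msa(g2, f2, t2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(t1), readLines(t2))

  g3 <- generate_planted_msa(seed = 14)
  expect_false(identical(g1$alignment$mat, g3$alignment$mat))
})

test_that("planted truth honors its invariants", {
  gen <- generate_planted_msa(n_subfamilies = 4, rows_per_subfamily = 8,
                              n_columns = 40, seed = 2)
  truth <- gen$truth
  expect_equal(length(truth$true_labels), n_sequences(gen$alignment))
  expect_equal(sort(unique(truth$true_labels)), 1:4)
  # specificity columns: distinct residues across subfamily ancestors
  anc <- do.call(rbind, strsplit(truth$ancestors, ""))
  for (j in truth$true_specificity_columns) {
    expect_equal(length(unique(anc[, j])), 4L)
  }
  # conserved columns: one shared residue
  for (j in setdiff(seq_len(40), truth$true_specificity_columns)) {
    expect_equal(length(unique(anc[, j])), 1L)
  }
  # default fraction: 30% of columns
  expect_equal(length(truth$true_specificity_columns), round(0.3 * 40))
})

test_that("noise-free subfamilies are internally identical; query is pristine", {
  gen <- generate_planted_msa(n_subfamilies = 2, rows_per_subfamily = 5,
                              substitution_rate = 0, gap_rate = 0, seed = 6)
  mat <- gen$alignment$mat
  for (k in 1:2) {
    block <- mat[gen$truth$true_labels == k, , drop = FALSE]
    expect_true(all(block == rep(block[1, ], each = nrow(block))))
  }
  noisy <- generate_planted_msa(n_subfamilies = 2, rows_per_subfamily = 40,
                                substitution_rate = 0.2, gap_rate = 0.1,
                                seed = 6)
  qrow <- noisy$alignment$mat[noisy$alignment$query_index, ]
  anc1 <- strsplit(noisy$truth$ancestors[1], "")[[1]]
  expect_identical(unname(qrow), anc1)
})

test_that("empirical substitution rate matches the configured rate", {
  rate <- 0.05
  gen <- generate_planted_msa(n_subfamilies = 3, rows_per_subfamily = 60,
                              n_columns = 80, substitution_rate = rate,
                              gap_rate = 0, seed = 9)
  anc <- do.call(rbind, strsplit(gen$truth$ancestors, ""))
  mat <- gen$alignment$mat
  mism <- mean(mat[-1, ] != anc[gen$truth$true_labels, ][-1, ])
  n_sites <- (nrow(mat) - 1) * ncol(mat)
  se <- sqrt(rate * (1 - rate) / n_sites)
  expect_lt(abs(mism - rate), 3 * se)
})

test_that("a single-subfamily alignment carries no exploitable structure", {
  # no-noise limit: identical rows, objective exactly zero
  clean <- generate_planted_msa(n_subfamilies = 1, rows_per_subfamily = 20,
                                n_columns = 40, substitution_rate = 0,
                                gap_rate = 0, seed = 12)
  expect_equal(ceo_cluster(clean$alignment, a = 0.7, seed = 12)$objective, 0)

  # with substitution noise the optimized objective picks up some Monte-Carlo
  # and noise co-occurrence signal, but stays far below an equally sized
  # alignment with planted structure
  gen <- generate_planted_msa(n_subfamilies = 1, rows_per_subfamily = 30,
                              n_columns = 40, seed = 12)
  part <- ceo_cluster(gen$alignment, a = 0.7, seed = 12)
  structured <- generate_planted_msa(n_subfamilies = 2, rows_per_subfamily = 15,
                                     n_columns = 40, seed = 12)
  ref <- ceo_cluster(structured$alignment, a = 0.7, seed = 12)
  expect_lt(part$objective, 0.5 * ref$objective)

  expect_error(generate_planted_msa(substitution_rate = 1.5), "rates")
  expect_error(generate_planted_msa(rows_per_subfamily = 0), "counts")
})

test_that("the variant panel expresses its planted score signatures", {
  gen <- generate_planted_msa(n_subfamilies = 3, rows_per_subfamily = 150,
                              substitution_rate = 0.01, seed = 5)
  aln <- gen$alignment
  part <- as_subfamily_partition(gen$truth$true_labels, aln)
  panel <- generate_variant_panel(gen$truth)
  expect_setequal(panel$case, c("conserved_to_absent", "switch_of_function",
                                "toward_plurality"))
  scores <- do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
    score_variant(aln, part,
                  mutation(panel$position[i], panel$wt_aa[i], panel$mut_aa[i]))
  }))
  cons_case <- scores[panel$case == "conserved_to_absent", ]
  fam_total <- column_counts(aln, cons_case$position)$total
  expect_equal(cons_case$conservation, log(fam_total), tolerance = 0.05)

  sw <- scores[panel$case == "switch_of_function", ]
  expect_true(sw$switch_of_function)
  expect_gte(sw$specificity, 4.5)
  expect_gte(sw$conjugate_specificity, 4.5)
  expect_lt(sw$conservation, 5.25)

  # mutating toward the plurality residue of a larger subfamily scores negative
  un <- generate_planted_msa(n_subfamilies = 2,
                             rows_per_subfamily = c(20, 60), seed = 9)
  upart <- as_subfamily_partition(un$truth$true_labels, un$alignment)
  up <- generate_variant_panel(un$truth)
  row <- up[up$case == "toward_plurality", ]
  us <- score_variant(un$alignment, upart,
                      mutation(row$position, row$wt_aa, row$mut_aa))
  expect_lt(us$conservation, 0)
})
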