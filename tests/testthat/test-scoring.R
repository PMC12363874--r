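test_that("conservation score is the count log-ratio with +1 mutant smoothing", {
  expect_equal(conservation_score(c(G = 90, D = 9), "G", "D"), log(9))
  expect_equal(conservation_score(c(G = 5, D = 4), "G", "D"), 0)
  expect_equal(conservation_score(c(G = 1, D = 100), "G", "D"), log(1 / 101))
  expect_identical(conservation_score(c(G = 0, D = 3), "G", "D"), -Inf)
  expect_error(conservation_score(c(G = 1), "G", "G"), "differ")

  # strictly increasing in n(wt), strictly decreasing in n(mut)
  by_wt <- vapply(1:30, function(n) conservation_score(c(A = n, V = 5), "A", "V"),
                  numeric(1))
  by_mut <- vapply(1:30, function(n) conservation_score(c(A = 5, V = n), "A", "V"),
                   numeric(1))
  expect_true(all(diff(by_wt) > 0))
  expect_true(all(diff(by_mut) < 0))
})

test_that("specificity score is the same kernel on subfamily counts", {
  expect_equal(specificity_score(c(R = 50), "R", "H"), log(50))
  expect_equal(specificity_score(c(R = 3, H = 2), "R", "H"), 0)
  cnt <- c(A = 7, V = 2, L = 1)
  expect_equal(specificity_score(cnt, "A", "L"),
               conservation_score(cnt, "A", "L"))
})

test_that("FIS is the symmetric mean of its components", {
  expect_equal(fis(5.05, 1.98), 3.515)
  expect_equal(fis(1.98, 5.05), fis(5.05, 1.98))
  expect_equal(fis(4.2, 4.2), 4.2)
})

test_that("conjugate specificity picks subfamilies where the mutant is conserved", {
  # subfamily 1: mut unanimous (40), wt absent -> ln 40
  cnts <- matrix(0, 20, 2, dimnames = list(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], NULL))
  cnts["V", 1] <- 40
  cnts["G", 2] <- 35
  expect_equal(conjugate_specificity_score(cnts, "G", "V"), log(40))

  # mutant absent everywhere -> -Inf
  expect_identical(conjugate_specificity_score(cnts, "G", "W"), -Inf)

  # plurality beats larger non-plurality counts: definitional symmetry with
  # the specificity score of the reverse substitution in that subfamily
  cnts2 <- cnts
  cnts2["V", 2] <- 10   # subfamily 2: G plurality, V present
  expect_equal(conjugate_specificity_score(cnts2, "G", "V"),
               specificity_score(c(V = 40, G = 0), "V", "G"))

  # fallback: mutant nowhere plurality but present
  cnts3 <- matrix(0, 20, 2)
  rownames(cnts3) <- rownames(cnts)
  cnts3["G", ] <- c(30, 20)
  cnts3["V", ] <- c(2, 5)
  expect_equal(conjugate_specificity_score(cnts3, "G", "V"),
               log(5 / 21))
})

test_that("impact categories follow the documented boundary convention", {
  expect_equal(classify_impact(2.04), "neutral")
  expect_equal(classify_impact(3.52), "low")
  expect_equal(classify_impact(c(2.6, 5.25, 7.0)),
               c("low", "medium", "high"))
  expect_equal(classify_impact(c(-Inf, 2.5999, 5.2499, 6.99, 100)),
               c("neutral", "neutral", "low", "medium", "high"))
  # monotone step function
  xs <- sort(runif(50, -3, 10))
  cats <- factor(classify_impact(xs),
                 levels = c("neutral", "low", "medium", "high"), ordered = TRUE)
  expect_true(all(diff(as.integer(cats)) >= 0))
  expect_error(impact_cutoffs(5, 4, 7), "increasing")
})

test_that("switch-of-function rule separates specificity swaps from active-site losses", {
  ref <- sof_reference_scores()
  got <- flag_switch_of_function(ref$conservation, ref$specificity,
                                 ref$conjugate_specificity)
  expect_equal(got, ref$expected_switch)
  # -Inf conjugate never flags
  expect_false(flag_switch_of_function(0, 10, -Inf))
})

test_that("score_variant assembles family and subfamily counts correctly", {
  # 8 rows, wildtype unanimous at column 1, mutant absent
  seqs <- c(q = "RAC", a = "RAC", b = "RAC", c = "RAC",
            d = "RGC", e = "RGC", f = "RGC", g = "RGC")
  aln <- alignment(seqs, "q")
  part <- as_subfamily_partition(rep(1:2, each = 4), aln)
  sc <- score_variant(aln, part, mutation(1, "R", "K"))
  expect_equal(sc$conservation, log(8))   # ln(n/1), n = 8 residues
  expect_equal(sc$specificity, log(4))
  expect_identical(sc$conjugate_specificity, -Inf)
  expect_equal(sc$fis, (log(8) + log(4)) / 2)
  expect_false(sc$switch_of_function)
  expect_false(sc$wt_mismatch)
  expect_equal(sc$category, classify_impact(sc$fis))

  # specificity column 2: A in query subfamily, G in the other
  sw <- score_variant(aln, part, mutation(2, "A", "G"))
  expect_equal(sw$conservation, log(4 / 5))
  expect_equal(sw$specificity, log(4))
  expect_equal(sw$conjugate_specificity, log(4))

  # claimed wildtype disagreeing with the query is flagged, not silently scored
  mm <- score_variant(aln, part, mutation(1, "K", "M"))
  expect_true(mm$wt_mismatch)
  expect_equal(mm$category, "not_scorable")
  expect_identical(mm$conservation, -Inf)

  expect_error(score_variant(aln, part, mutation(99, "R", "K")), "exceeds")
  expect_error(score_variant(aln, part, mutation(1, "R", "K", protein_id = "other")),
               "does not match")
  expect_error(mutation(1, "R", "R"), "differ")
  expect_error(mutation(1, "R", "Z"), "unknown mutant")
})

test_that("low-occupancy columns are retained but marked not_scorable", {
  seqs <- c(q = "RA", a = "R-", b = "R-", c = "R-")
  aln <- alignment(seqs, "q")
  part <- as_subfamily_partition(rep(1, 4), aln)
  sc <- score_variant(aln, part, mutation(2, "A", "G"), min_occupancy = 0.70)
  expect_equal(sc$category, "not_scorable")
  expect_false(sc$switch_of_function)
  expect_equal(sc$conservation, log(1 / 1))  # still computed
})

test_that("the full substitution table is complete and self-consistent", {
  gen <- generate_planted_msa(n_subfamilies = 2, rows_per_subfamily = 10,
                              n_columns = 12, gap_rate = 0, seed = 3)
  aln <- gen$alignment
  part <- as_subfamily_partition(gen$truth$true_labels, aln)
  tab <- score_all_substitutions(aln, part)
  expect_equal(nrow(tab), 19L * 12L)
  expect_equal(sort(unique(tab$position)), 1:12)
  expect_true(all(table(tab$position) == 19L))

  # spot-check agreement with individual scoring
  set.seed(2)
  for (i in sample(nrow(tab), 8)) {
    one <- score_variant(aln, part,
                         mutation(tab$position[i], tab$wt[i], tab$mut[i]))
    expect_equal(one, tab[i, ], ignore_attr = TRUE)
  }

  # an invariant column scores ln(N/1) for every substitution
  inv <- alignment(setNames(rep("W", 9), c("q", paste0("s", 1:8))), "q")
  ipart <- as_subfamily_partition(rep(1, 9), inv)
  itab <- score_all_substitutions(inv, ipart)
  expect_true(all(itab$conservation == log(9)))
})

test_that("score tables serialize -Inf as -inf", {
  seqs <- c(q = "RA", a = "RA", b = "RA", c = "RA")
  aln <- alignment(seqs, "q")
  part <- as_subfamily_partition(rep(1, 4), aln)
  sc <- score_variant(aln, part, mutation(1, "R", "K"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scores_tsv(sc, path)
  raw <- strsplit(readLines(path)[2], "\t")[[1]]
  expect_true("-inf" %in% raw)
  back <- read.delim(path, stringsAsFactors = FALSE)
  expect_identical(back$conjugate_specificity, -Inf)
  expect_equal(back$conservation, log(4), tolerance = 1e-5)
})

test_that("variant tokens and TSV lists parse with validation", {
  m <- parse_mutation("G12D")
  expect_equal(m$position, 12L)
  expect_equal(m$wt_aa, "G")
  expect_equal(m$mut_aa, "D")
  expect_error(parse_mutation("12D"), "malformed")
  expect_error(parse_mutation("G12B"), "unknown mutant")

  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tposition\twt_aa\tmut_aa",
               "q\t3\tD\tE", "q\t1\tA\tA"), path)
  expect_error(read_variants(path), "line 2")
  writeLines(c("protein_id\tposition\twt_aa\tmut_aa", "q\t3\tD\tE"), path)
  muts <- read_variants(path)
  expect_length(muts, 1)
  expect_equal(muts[[1]]$position, 3L)
})
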