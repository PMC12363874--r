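# Combinatorial entropy of alignment columns.
#
# The entropy of a set of residues at one column is the log of the number of
# distinguishable permutations of those residues, ln(total! / prod_a n_a!).
# Splitting the rows into subfamilies can only reduce the summed
# within-block entropy, and the size of that reduction -- relative to what a
# random split of the same block sizes would give -- measures how strongly a
# column's residue usage segregates by subfamily.

# Integer residue codes: 1..20 for the standard amino acids, 0 for gaps and
# ambiguity codes (which contribute nothing to count vectors).
aln_codes <- function(aln) {
  cd <- match(aln$mat, AA_LETTERS)
  cd[is.na(cd)] <- 0L
  matrix(cd, nrow = nrow(aln$mat))
}

#' Amino-acid counts at one alignment column
#'
#' Counts of the 20 standard residues at a column, over all rows or a row
#' subset. Gaps and ambiguity codes (B, J, Z, X, U, O) are not counted.
#'
#' @param aln a [alignment()] object
#' @param column alignment column index
#' @param rows optional integer vector of row indices (default: all rows)
#' @return object of class `column_counts`: list with `counts` (named
#'   integer vector over the 20 amino acids) and `total` (their sum)
#' @export
column_counts <- function(aln, column, rows = NULL) {
  if (length(column) != 1 || column < 1 || column > n_columns(aln)) {
    stop("column index out of range")
  }
  v <- aln$mat[, column]
  if (!is.null(rows)) {
    stopifnot(all(rows >= 1), all(rows <= n_sequences(aln)))
    v <- v[rows]
  }
  cd <- match(v, AA_LETTERS)
  counts <- tabulate(cd[!is.na(cd)], nbins = 20L)
  names(counts) <- AA_LETTERS
  structure(list(counts = counts, total = sum(counts)),
            class = "column_counts")
}

#' @export
print.column_counts <- function(x, ...) {
  nz <- x$counts[x$counts > 0]
  cat("column_counts (total ", x$total, "): ",
      paste(sprintf("%s:%d", names(nz), nz), collapse = " "), "\n", sep = "")
  invisible(x)
}

as_count_vector <- function(x) {
  if (inherits(x, "column_counts")) x$counts else x
}

#' Combinatorial entropy of a residue multiset
#'
#' `ln(total! / prod_a counts(a)!)` -- the log number of permutations of the
#' residues -- computed with log-gamma for stability. Zero when at most one
#' residue type is present.
#'
#' @param counts a [column_counts()] object or a non-negative integer vector
#' @return entropy in nats
#' @export
#' @examples
#' log_multinomial(c(A = 2, G = 1)) # ln 3
log_multinomial <- function(counts) {
  counts <- as_count_vector(counts)
  stopifnot(all(counts >= 0))
  lgamma(sum(counts) + 1) - sum(lgamma(counts + 1))
}

partition_labels <- function(partition, n) {
  labels <- if (inherits(partition, "subfamily_partition")) {
    partition$labels
  } else {
    partition
  }
  labels <- as.integer(labels)
  if (length(labels) != n || anyNA(labels)) {
    stop("partition must assign exactly one label to every row")
  }
  labels
}

#' Entropy difference between a column and its subfamily decomposition
#'
#' `S_family - sum_k S_subfamily_k` at one column, each `S` the
#' combinatorial entropy of the residues in the block. Always non-negative:
#' arrangements that respect the block structure are a subset of all
#' arrangements of the column.
#'
#' @param aln a [alignment()] object
#' @param column alignment column index
#' @param partition a `subfamily_partition` or an integer label vector with
#'   one entry per row
#' @return entropy difference in nats (>= 0)
#' @export
partition_entropy_difference <- function(aln, column, partition) {
  labels <- partition_labels(partition, n_sequences(aln))
  cd <- match(aln$mat[, column], AA_LETTERS)
  keep <- !is.na(cd)
  s_fam <- log_multinomial(tabulate(cd[keep], 20L))
  s_sub <- vapply(split(cd[keep], labels[keep]),
                  function(g) log_multinomial(tabulate(g, 20L)), numeric(1))
  s_fam - sum(s_sub)
}

#' Expected entropy difference under random subfamily assignment
#'
#' Monte-Carlo estimate of the mean of [partition_entropy_difference()] when
#' the column's symbols (residues and gaps alike) are randomly permuted
#' across rows while the subfamily sizes are held fixed. This is the null
#' against which an observed entropy difference is judged: any partition
#' earns some entropy difference just by splitting a variable column, and
#' only the excess above the permutation mean indicates real segregation.
#'
#' @param counts a [column_counts()] object for the column
#' @param subfamily_sizes integer vector of block sizes; must sum to at
#'   least `counts$total` (the difference is taken up by gap rows)
#' @param n_perm number of permutations (default 100)
#' @param seed integer seed
#' @return expected entropy difference in nats
#' @export
null_entropy_difference <- function(counts, subfamily_sizes,
                                    n_perm = 100L, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  cv <- as_count_vector(counts)
  n <- sum(subfamily_sizes)
  n_gap <- n - sum(cv)
  if (n_gap < 0) stop("subfamily sizes sum to fewer rows than residue count")
  symbols <- c(rep.int(seq_along(cv), cv), rep.int(0L, n_gap))
  s_fam <- log_multinomial(cv)
  if (s_fam == 0 || length(subfamily_sizes) == 1L) return(0)
  block <- rep.int(seq_along(subfamily_sizes), subfamily_sizes)
  local_seed(seed, {
    deltas <- vapply(seq_len(n_perm), function(p) {
      perm <- sample(symbols)
      s_sub <- vapply(split(perm, block), function(g) {
        log_multinomial(tabulate(g[g > 0L], 20L))
      }, numeric(1))
      s_fam - sum(s_sub)
    }, numeric(1))
    mean(deltas)
  })
}

# Null-expectation table via shared permutations.
#
# For each column j (processed in ascending order under one seeded RNG
# stream), draws n_perm random permutations of the column's N symbols and
# accumulates the running combinatorial entropy of every prefix. Because a
# prefix of a random permutation is a uniform random subset, the mean over
# permutations estimates E_j(m) = E[S(random m-subset)] for all m at once,
# and by linearity the null expectation of the partition entropy difference
# for blocks of sizes m_k is S_family(j) - sum_k E_j(m_k).
#
# Returns list(columns, E = |columns| x (N+1) matrix with E[j, m+1],
# s_fam = per-column family entropy).
make_null_table <- function(codes, columns, n_perm, seed) {
  columns <- sort(columns)
  n <- nrow(codes)
  E <- matrix(0, nrow = length(columns), ncol = n + 1L)
  s_fam <- numeric(length(columns))
  local_seed(seed, {
    for (ji in seq_along(columns)) {
      v <- codes[, columns[ji]]
      cnt <- tabulate(v[v > 0L], 20L)
      nl <- sum(cnt)
      s_fam[ji] <- lgamma(nl + 1) - sum(lgamma(cnt + 1))
      if (s_fam[ji] == 0) next  # <= 1 residue type: every subset has S = 0
      v <- sort(v)  # estimates depend on the symbol multiset, not row order
      logt <- log(seq_len(nl))
      cnt_nz <- cnt[cnt > 0L]
      acc <- numeric(n)
      for (p in seq_len(n_perm)) {
        w <- v[sample.int(n)]
        nzp <- which(w > 0L)
        lw <- w[nzp]
        ord <- order(lw, method = "radix")
        occ <- integer(nl)
        occ[ord] <- sequence(cnt_nz)
        contrib <- numeric(n)
        contrib[nzp] <- logt - log(occ)
        acc <- acc + cumsum(contrib)
      }
      E[ji, 2:(n + 1L)] <- acc / n_perm
    }
  })
  list(columns = columns, E = E, s_fam = s_fam)
}

# Per-column actual within-block entropy sum for a labeling.
block_entropy_sums <- function(codes, columns, labels) {
  vapply(columns, function(col) {
    v <- codes[, col]
    keep <- v > 0L
    sum(vapply(split(v[keep], labels[keep]),
               function(g) log_multinomial(tabulate(g, 20L)), numeric(1)))
  }, numeric(1))
}

#' Rank columns by subfamily-specific conservation
#'
#' For each column, computes the raw entropy difference of the partition,
#' its permutation-null expectation (shared-permutation estimator, see
#' [null_entropy_difference()]), and the excess. Columns whose residue
#' usage segregates cleanly by subfamily -- specificity columns -- have
#' large positive excess; invariant or well-mixed columns sit near zero.
#'
#' @param aln a [alignment()] object
#' @param partition a `subfamily_partition` or integer label vector
#' @param columns columns to rank (default: [select_scoring_columns()])
#' @param n_perm permutations for the null (default 100)
#' @param seed integer seed
#' @return data.frame with columns `column`, `delta_s`, `null_expectation`,
#'   `excess`, sorted by excess descending (ties by ascending column index)
#' @export
rank_specificity_columns <- function(aln, partition,
                                     columns = select_scoring_columns(aln),
                                     n_perm = 100L, seed = 1L) {
  labels <- partition_labels(partition, n_sequences(aln))
  codes <- aln_codes(aln)
  nt <- make_null_table(codes, columns, n_perm, seed)
  sizes <- tabulate(labels)
  sizes <- sizes[sizes > 0L]
  e_null_blocks <- rowSums(nt$E[, sizes + 1L, drop = FALSE])
  delta_s <- nt$s_fam - block_entropy_sums(codes, nt$columns, labels)
  null_exp <- nt$s_fam - e_null_blocks
  out <- data.frame(
    column = nt$columns,
    delta_s = delta_s,
    null_expectation = null_exp,
    excess = delta_s - null_exp
  )
  out <- out[order(-out$excess, out$column), ]
  rownames(out) <- NULL
  out
}
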