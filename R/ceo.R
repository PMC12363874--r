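# Combinatorial entropy optimization (CEO).
#
# Joint selection of (i) a partition of the aligned sequences into
# subfamilies and (ii) a set of specificity columns, by agglomerative
# clustering. The objective of a partition is the sum, over the selected
# columns, of the column's entropy difference in excess of its
# permutation-null expectation:
#
#   objective(P) = sum_{j in top ceil(a*C) by excess} sum_k [E_j(m_k) - S_k(j)]
#
# where S_k(j) is the combinatorial entropy of subfamily k's residues at
# column j and E_j(m) the expected entropy of a uniform random m-subset of
# the column (estimated once per column from seeded shared permutations, see
# make_null_table). The excess is exactly zero at both trivial partitions
# (all singletons: every block has S = E = 0; one cluster: E_j(N) equals the
# family entropy), so the maximum along the merge path is an interior
# optimum whenever the alignment has real subfamily structure. The
# granularity parameter `a` is the fraction of candidate columns admitted to
# the specificity set.

#' Construct a subfamily partition
#'
#' Wraps a per-row labeling of an alignment as the partition object consumed
#' by the scoring functions. Labels are canonicalized to 1..K in order of
#' first appearance. Usually produced by [ceo_cluster()] or [scan_a()], but
#' any externally obtained clustering can be wrapped for scoring.
#'
#' @param labels integer-like vector, one subfamily label per alignment row
#' @param aln the [alignment()] the labels refer to
#' @param specificity_columns selected specificity column indices (optional)
#' @param a_value granularity parameter used (optional)
#' @param objective CEO objective value (optional)
#' @param n_perm,seed null-model parameters used (optional)
#' @return object of class `subfamily_partition` with elements `labels`
#'   (named 1..K integer vector), `n_subfamilies`, `query_label` (the
#'   subfamily containing the query), `specificity_columns`, `a_value`,
#'   `objective`, `n_perm`, `seed`
#' @export
as_subfamily_partition <- function(labels, aln, specificity_columns = integer(),
                                   a_value = NA_real_, objective = NA_real_,
                                   n_perm = NA_integer_, seed = NA_integer_) {
  if (length(labels) != n_sequences(aln) || anyNA(labels)) {
    stop("labels must assign exactly one subfamily to every row")
  }
  lab <- match(labels, unique(labels))
  names(lab) <- aln$ids
  structure(
    list(labels = lab,
         n_subfamilies = length(unique(lab)),
         query_label = lab[[aln$query_index]],
         specificity_columns = as.integer(specificity_columns),
         a_value = a_value,
         objective = objective,
         n_perm = n_perm,
         seed = seed),
    class = "subfamily_partition"
  )
}

#' @export
print.subfamily_partition <- function(x, ...) {
  cat(sprintf(
    "subfamily_partition: %d sequences in %d subfamilies (query in #%d)\n",
    length(x$labels), x$n_subfamilies, x$query_label))
  if (!is.na(x$a_value)) {
    cat(sprintf("  a = %.3f, objective = %.4f nats, %d specificity columns\n",
                x$a_value, x$objective, length(x$specificity_columns)))
  }
  invisible(x)
}

# Precomputations shared by every granularity value: residue codes, the
# per-column null table, log-factorial lookup, and the singleton-level
# merged-pair excess rows.
ceo_context <- function(aln, columns, n_perm, seed) {
  if (length(columns) < 1) stop("no scoring columns supplied")
  n <- n_sequences(aln)
  if (n < 2) stop("clustering needs at least 2 sequences")
  codes <- aln_codes(aln)
  nt <- make_null_table(codes, columns, n_perm, seed)
  cc <- length(nt$columns)
  mx <- codes[, nt$columns, drop = FALSE]
  lg <- lgamma(seq_len(n + 1L))  # lg[k+1] = ln k!

  # Per-singleton one-hot count matrices (20 x C), merged pairwise below.
  singles <- lapply(seq_len(n), function(i) {
    m <- matrix(0L, 20L, cc)
    idx <- which(mx[i, ] > 0L)
    m[cbind(mx[i, idx], idx)] <- 1L
    m
  })

  # Singleton pair rows: q_{uv}(j) = E_j(2) - S_pair(j), with S_pair = ln 2
  # exactly when both rows carry distinct residues at j.
  pu0 <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  pv0 <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n), use.names = FALSE)
  pm0 <- matrix(0, length(pu0), cc)
  e2 <- nt$E[, 3L]
  for (j in seq_len(cc)) {
    cj <- mx[, j]
    s_pair <- log(2) * (cj[pu0] != cj[pv0] & cj[pu0] > 0L & cj[pv0] > 0L)
    pm0[, j] <- e2[j] - s_pair
  }

  list(n = n, columns = nt$columns, cc = cc, mx = mx, E = nt$E,
       s_fam = nt$s_fam, lg = lg, singles = singles,
       pu0 = pu0, pv0 = pv0, pm0 = pm0,
       n_perm = n_perm, seed = seed, ids = aln$ids,
       query_index = aln$query_index)
}

# Entropy vector (length C) of a 20 x C count matrix via the lookup table.
count_entropy <- function(cnt, lg) {
  tot <- colSums(cnt)
  lg[tot + 1L] - colSums(matrix(lg[cnt + 1L], nrow = 20L))
}

# One agglomerative run at a fixed granularity value. Greedy: at each level
# the specificity set is the current top-t columns by summed excess; the
# candidate merge maximizing the objective restricted to that set is
# applied; the recorded level objective re-selects columns for the merged
# partition. The full path to a single cluster is walked and the level with
# maximal objective returned (ties resolve to the later level, so an
# alignment of identical rows yields one subfamily, not singletons).
ceo_cluster_run <- function(ctx, a) {
  n <- ctx$n
  cc <- ctx$cc
  t_sel <- max(1L, ceiling(a * cc))
  max_id <- 2L * n - 1L

  size <- integer(max_id)
  size[seq_len(n)] <- 1L
  qmat <- matrix(0, max_id, cc)           # singleton q rows are exactly 0
  counts <- vector("list", max_id)
  counts[seq_len(n)] <- ctx$singles

  pm <- matrix(0, n * n, cc)
  np0 <- length(ctx$pu0)
  pm[seq_len(np0), ] <- ctx$pm0
  pu <- ctx$pu0; pv <- ctx$pv0; prow <- seq_len(np0)
  next_row <- np0 + 1L

  active <- seq_len(n)
  q_total <- numeric(cc)
  ones <- rep(1, t_sel)

  obj_path <- numeric(n)                  # level L = partition after L-1 merges
  sel_path <- vector("list", n)
  merges <- matrix(0L, max(n - 1L, 1L), 2L)
  sel0 <- order(-q_total)[seq_len(t_sel)]
  obj_path[1L] <- sum(q_total[sel0])
  sel_path[[1L]] <- sort(sel0)

  for (lvl in seq_len(n - 1L)) {
    sel <- order(-q_total)[seq_len(t_sel)]
    csel <- as.vector(qmat[, sel, drop = FALSE] %*% ones)
    psum <- as.vector(pm[prow, sel, drop = FALSE] %*% ones)
    score <- psum - csel[pu] - csel[pv]
    cand <- which(score == max(score))
    if (length(cand) > 1L) cand <- cand[order(pu[cand], pv[cand])[1L]]
    u <- pu[cand]; v <- pv[cand]

    w <- n + lvl
    merges[lvl, ] <- c(u, v)
    size[w] <- size[u] + size[v]
    counts[[w]] <- counts[[u]] + counts[[v]]
    counts[u] <- list(NULL); counts[v] <- list(NULL)
    qmat[w, ] <- ctx$E[, size[w] + 1L] - count_entropy(counts[[w]], ctx$lg)
    q_total <- q_total - qmat[u, ] - qmat[v, ] + qmat[w, ]
    active <- c(active[active != u & active != v], w)

    sel2 <- order(-q_total)[seq_len(t_sel)]
    obj_path[lvl + 1L] <- sum(q_total[sel2])
    sel_path[[lvl + 1L]] <- sort(sel2)

    keep <- pu != u & pu != v & pv != u & pv != v
    pu <- pu[keep]; pv <- pv[keep]; prow <- prow[keep]
    others <- active[active != w]
    if (length(others)) {
      new_rows <- next_row - 1L + seq_along(others)
      for (k in seq_along(others)) {
        x <- others[k]
        cnt2 <- counts[[x]] + counts[[w]]
        pm[new_rows[k], ] <- ctx$E[, size[x] + size[w] + 1L] -
          count_entropy(cnt2, ctx$lg)
      }
      pu <- c(pu, others); pv <- c(pv, rep.int(w, length(others)))
      prow <- c(prow, new_rows)
      next_row <- next_row + length(others)
    }
  }

  best <- max(which(obj_path == max(obj_path)))
  assign <- seq_len(n)
  if (best > 1L) {
    for (lvl in seq_len(best - 1L)) {
      u <- merges[lvl, 1L]; v <- merges[lvl, 2L]
      assign[assign == u | assign == v] <- n + lvl
    }
  }
  list(labels = match(assign, unique(assign)),
       objective = obj_path[best],
       specificity_columns = ctx$columns[sel_path[[best]]],
       a = a)
}

#' Cluster aligned sequences into subfamilies by CEO at fixed granularity
#'
#' Agglomerative combinatorial entropy optimization: starting from
#' singletons, repeatedly merges the pair of clusters that maximizes the CEO
#' objective -- the summed excess (over the permutation null) of the
#' partition's entropy differences across the selected specificity columns.
#' At every level the specificity set is re-selected as the top
#' `ceiling(a * length(columns))` columns by excess. The partition along the
#' merge path with maximal objective is returned. Deterministic for a fixed
#' seed.
#'
#' @param aln a [alignment()] object with at least 2 rows
#' @param columns candidate (scoring) column indices, usually
#'   [select_scoring_columns()]
#' @param a granularity parameter in (0, 1]: fraction of candidate columns
#'   admitted to the specificity set
#' @param n_perm permutations per column for the null table (default 100)
#' @param seed integer seed for the permutation null
#' @return a [as_subfamily_partition()] object
#' @seealso [scan_a()] for the granularity scan, [ceo_objective()] to
#'   recompute a partition's objective from scratch
#' @export
ceo_cluster <- function(aln, columns = select_scoring_columns(aln),
                        a = 0.7, n_perm = 100L, seed = 1L) {
  stopifnot(length(a) == 1, a > 0, a <= 1)
  ctx <- ceo_context(aln, columns, n_perm, seed)
  res <- ceo_cluster_run(ctx, a)
  as_subfamily_partition(res$labels, aln,
                         specificity_columns = res$specificity_columns,
                         a_value = a, objective = res$objective,
                         n_perm = n_perm, seed = seed)
}

#' Scan the CEO granularity parameter and keep the best partition
#'
#' Runs [ceo_cluster()] at each grid value (default 0.5 to 0.975 in steps of
#' 0.025) and returns the partition with the maximal entropy-difference
#' objective; ties resolve to the smallest granularity value.
#'
#' @inheritParams ceo_cluster
#' @param grid granularity values in (0, 1]
#' @return a [as_subfamily_partition()] object
#' @export
scan_a <- function(aln, columns = select_scoring_columns(aln),
                   grid = seq(0.5, 0.975, by = 0.025),
                   n_perm = 100L, seed = 1L) {
  stopifnot(length(grid) >= 1, all(grid > 0), all(grid <= 1))
  ctx <- ceo_context(aln, columns, n_perm, seed)
  best <- NULL
  for (a in sort(grid)) {
    res <- ceo_cluster_run(ctx, a)
    if (is.null(best) || res$objective > best$objective) best <- res
  }
  as_subfamily_partition(best$labels, aln,
                         specificity_columns = best$specificity_columns,
                         a_value = best$a, objective = best$objective,
                         n_perm = n_perm, seed = seed)
}

#' Recompute a partition's CEO objective from scratch
#'
#' Independent recomputation of the objective reported by [ceo_cluster()] /
#' [scan_a()]: builds the per-column excess of the partition's entropy
#' difference over the permutation-null expectation (same seeded
#' shared-permutation estimator), selects the top `ceiling(a * C)` columns,
#' and sums. Matches the stored `objective` of a returned partition up to
#' floating-point accumulation order.
#'
#' @inheritParams ceo_cluster
#' @param partition a `subfamily_partition` or integer label vector
#' @param a granularity; defaults to the partition's own `a_value`
#' @return list with `objective`, `specificity_columns`, and the per-column
#'   `excess` vector (named by column index)
#' @export
ceo_objective <- function(aln, partition,
                          columns = select_scoring_columns(aln),
                          a = NULL, n_perm = NULL, seed = NULL) {
  if (inherits(partition, "subfamily_partition")) {
    if (is.null(a)) a <- partition$a_value
    if (is.null(n_perm)) n_perm <- partition$n_perm
    if (is.null(seed)) seed <- partition$seed
  }
  stopifnot(!is.null(a), !is.na(a), !is.null(n_perm), !is.null(seed))
  labels <- partition_labels(partition, n_sequences(aln))
  codes <- aln_codes(aln)
  nt <- make_null_table(codes, columns, n_perm, seed)
  sizes <- tabulate(labels)
  sizes <- sizes[sizes > 0L]
  e_blocks <- rowSums(nt$E[, sizes + 1L, drop = FALSE])
  excess <- e_blocks - block_entropy_sums(codes, nt$columns, labels)
  t_sel <- max(1L, ceiling(a * length(nt$columns)))
  sel <- order(-excess)[seq_len(t_sel)]
  list(objective = sum(excess[sel]),
       specificity_columns = sort(nt$columns[sel]),
       excess = stats::setNames(excess, nt$columns))
}
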