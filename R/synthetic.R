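# Seeded synthetic alignments with planted subfamily structure.
#
# Each subfamily descends from its own ancestor sequence. At specificity
# columns the ancestors carry distinct residues (one diagnostic residue per
# subfamily); at all other columns every ancestor shares one residue. Rows
# are ancestor copies with i.i.d. substitutions and i.i.d. gaps, so the true
# labels and the true specificity columns are known exactly and every stage
# of the pipeline can be tested without any external alignment.

#' Generate a synthetic alignment with planted subfamilies
#'
#' @param n_subfamilies number of planted subfamilies K (1..20; specificity
#'   columns need K distinct residues)
#' @param rows_per_subfamily sequences per subfamily: a scalar or a length-K
#'   vector for unequal subfamily sizes
#' @param n_columns alignment length L
#' @param fraction_specificity_columns fraction of columns planted as
#'   subfamily-diagnostic (rounded to a count)
#' @param substitution_rate per-site probability that a row differs from its
#'   ancestor (substituted residues are uniform over the other 19)
#' @param gap_rate per-site gap probability
#' @param seed integer seed; output is bit-for-bit reproducible from the
#'   parameters and seed
#' @param query_id identifier given to the query row
#' @return list with `alignment` (a [alignment()]; the query is the first
#'   row of subfamily 1 and carries no substitutions or gaps) and `truth`,
#'   a `planted_msa_truth` object: `true_labels` (named integer vector),
#'   `true_specificity_columns`, `ancestors` (per-subfamily consensus
#'   strings) and `params`
#' @export
#' @examples
#' gen <- generate_planted_msa(n_subfamilies = 2, rows_per_subfamily = 5,
#'                             n_columns = 20, seed = 1)
#' table(gen$truth$true_labels)
generate_planted_msa <- function(n_subfamilies = 3,
                                 rows_per_subfamily = 30,
                                 n_columns = 60,
                                 fraction_specificity_columns = 0.30,
                                 substitution_rate = 0.03,
                                 gap_rate = 0.02,
                                 seed = 1L,
                                 query_id = "query") {
  k <- as.integer(n_subfamilies)
  stopifnot(k >= 1, k <= 20, n_columns >= 1)
  rps <- as.integer(rows_per_subfamily)
  if (length(rps) == 1L) rps <- rep.int(rps, k)
  if (length(rps) != k || any(rps < 1)) {
    stop("rows_per_subfamily must be a scalar or length-K vector of counts >= 1")
  }
  for (r in c(fraction_specificity_columns, substitution_rate, gap_rate)) {
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  }
  ll <- as.integer(n_columns)
  n <- sum(rps)

  local_seed(seed, {
    n_spec <- round(fraction_specificity_columns * ll)
    spec_cols <- sort(sample.int(ll, n_spec))
    anc <- matrix("", nrow = k, ncol = ll)
    for (j in seq_len(ll)) {
      anc[, j] <- if (j %in% spec_cols && k > 1) {
        sample(AA_LETTERS, k)            # distinct diagnostic residues
      } else {
        rep(sample(AA_LETTERS, 1), k)
      }
    }
    labels <- rep.int(seq_len(k), rps)
    mat <- anc[labels, , drop = FALSE]
    noise_ok <- rep(TRUE, n)
    noise_ok[1L] <- FALSE                # query row kept pristine
    sub_mask <- matrix(stats::runif(n * ll) < substitution_rate, n, ll) &
      noise_ok
    if (any(sub_mask)) {
      cur <- mat[sub_mask]
      repl <- AA_LETTERS[
        (match(cur, AA_LETTERS) - 1L + sample.int(19L, length(cur),
                                                  replace = TRUE)) %% 20L + 1L]
      mat[sub_mask] <- repl
    }
    gap_mask <- matrix(stats::runif(n * ll) < gap_rate, n, ll) & noise_ok
    mat[gap_mask] <- GAP_CHAR

    ids <- sprintf("sf%d_seq%03d", labels, stats::ave(labels, labels,
                                                      FUN = seq_along))
    ids[1L] <- query_id
    seqs <- apply(mat, 1, paste, collapse = "")
    names(seqs) <- ids
    aln <- alignment(seqs, query_id)
    truth <- structure(
      list(true_labels = stats::setNames(labels, ids),
           true_specificity_columns = spec_cols,
           ancestors = apply(anc, 1, paste, collapse = ""),
           params = list(n_subfamilies = k, rows_per_subfamily = rps,
                         n_columns = ll,
                         fraction_specificity_columns =
                           fraction_specificity_columns,
                         substitution_rate = substitution_rate,
                         gap_rate = gap_rate, seed = seed,
                         query_id = query_id)),
      class = "planted_msa_truth"
    )
    list(alignment = aln, truth = truth)
  })
}

#' Variant panel with known qualitative outcomes
#'
#' Builds a small set of substitutions on the query of a planted alignment
#' whose score signatures are known from the construction:
#' \describe{
#'   \item{`conserved_to_absent`}{a mutation at a conserved column to a
#'     residue no ancestor carries: conservation close to the log of the
#'     family residue count, high impact on deep alignments -- the
#'     loss-of-function anti-signature (conjugate specificity `-Inf` when
#'     noise never introduced the residue).}
#'   \item{`switch_of_function`}{a mutation at a specificity column from the
#'     query subfamily's diagnostic residue to another subfamily's: high
#'     specificity, high conjugate specificity, low conservation.}
#'   \item{`toward_plurality`}{a mutation at a specificity column toward the
#'     diagnostic residue of the largest other subfamily: negative
#'     conservation score whenever that subfamily outnumbers the query's.}
#' }
#'
#' @param truth a `planted_msa_truth` from [generate_planted_msa()]
#' @return data.frame with columns `protein_id`, `position`, `wt_aa`,
#'   `mut_aa`, `case` (cases needing K >= 2 are omitted for K = 1)
#' @export
generate_variant_panel <- function(truth) {
  stopifnot(inherits(truth, "planted_msa_truth"))
  p <- truth$params
  anc <- do.call(rbind, strsplit(truth$ancestors, ""))
  spec_cols <- truth$true_specificity_columns
  cons_cols <- setdiff(seq_len(p$n_columns), spec_cols)
  rows <- list()

  if (length(cons_cols)) {
    col <- cons_cols[1]
    wt <- anc[1, col]
    mut <- setdiff(AA_LETTERS, anc[, col])[1]
    rows$conserved_to_absent <- data.frame(
      protein_id = p$query_id, position = col, wt_aa = wt, mut_aa = mut,
      case = "conserved_to_absent", stringsAsFactors = FALSE)
  }
  if (p$n_subfamilies >= 2 && length(spec_cols)) {
    col <- spec_cols[1]
    rows$switch <- data.frame(
      protein_id = p$query_id, position = col,
      wt_aa = anc[1, col], mut_aa = anc[2, col],
      case = "switch_of_function", stringsAsFactors = FALSE)
    biggest <- which.max(replace(p$rows_per_subfamily, 1L, -1L))
    col2 <- spec_cols[min(2, length(spec_cols))]
    rows$plurality <- data.frame(
      protein_id = p$query_id, position = col2,
      wt_aa = anc[1, col2], mut_aa = anc[biggest, col2],
      case = "toward_plurality", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a planted alignment and its truth to disk
#'
#' @param gen the list returned by [generate_planted_msa()]
#' @param fasta_path output path for the aligned FASTA
#' @param truth_path output path for the truth TSV (`sequence_id`,
#'   `true_label`)
#' @return invisibly, a character vector of the two paths
#' @export
write_planted_msa <- function(gen, fasta_path, truth_path) {
  write_fasta(gen$alignment, fasta_path)
  utils::write.table(
    data.frame(sequence_id = names(gen$truth$true_labels),
               true_label = unname(gen$truth$true_labels)),
    truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta_path, truth_path))
}
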