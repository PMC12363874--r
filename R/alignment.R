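# Protein-family multiple sequence alignment: construction, validation,
# query coordinate system, and the standard pre-clustering filters.

#' Construct a protein alignment object
#'
#' The container used throughout the package: a set of equal-length gapped
#' amino-acid sequences with one designated query (reference) row, typically
#' the canonical human protein. Residues are uppercased and both `-` and `.`
#' are accepted as gap characters (`.` and lowercase letters are the usual
#' profile-HMM insert-state conventions); gaps are normalized to `-`.
#'
#' @param seqs named character vector of aligned (gapped) sequences, all the
#'   same length; names are the sequence identifiers and must be unique
#' @param query_id identifier of the query/reference sequence
#' @return an object of class `protein_alignment` with elements:
#'   \describe{
#'     \item{ids}{character vector of sequence identifiers}
#'     \item{mat}{character matrix, one row per sequence, one column per
#'       alignment column}
#'     \item{query_index}{row index of the query sequence}
#'     \item{col_to_query}{integer vector mapping each alignment column to a
#'       1-based position in the ungapped query (`NA` where the query has a
#'       gap); strictly increasing over query columns}
#'   }
#' @export
#' @examples
#' aln <- alignment(c(q = "AC-DE", h1 = "ACKDE", h2 = "GC-D-"), "q")
#' aln$col_to_query  # 1 2 NA 3 4
alignment <- function(seqs, query_id) {
  if (length(seqs) == 0) stop("empty alignment")
  ids <- names(seqs)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    stop("all sequences must be named")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) stop("rows have unequal lengths")
  if (widths[1] < 1L) stop("alignment has zero columns")
  qi <- match(query_id, ids)
  if (is.na(qi)) stop("query_id '", query_id, "' not found in alignment")

  mat <- matrix(unlist(strsplit(toupper(seqs), ""), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE)
  mat[mat == "."] <- GAP_CHAR
  rownames(mat) <- ids

  qrow <- mat[qi, ]
  nongap <- qrow != GAP_CHAR
  if (!any(nongap)) stop("query row is all gaps")
  col_to_query <- rep(NA_integer_, ncol(mat))
  col_to_query[nongap] <- seq_len(sum(nongap))

  structure(
    list(ids = ids, mat = mat, query_index = qi, col_to_query = col_to_query),
    class = "protein_alignment"
  )
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("protein_alignment: %d sequences x %d columns (query: %s, %d residues)\n",
              nrow(x$mat), ncol(x$mat), x$ids[x$query_index],
              max(x$col_to_query, na.rm = TRUE)))
  invisible(x)
}

#' Number of sequences / columns in an alignment
#' @param aln a `protein_alignment`
#' @return integer scalar
#' @export
n_sequences <- function(aln) nrow(aln$mat)

#' @rdname n_sequences
#' @export
n_columns <- function(aln) ncol(aln$mat)

#' Ungapped query sequence of an alignment
#' @param aln a `protein_alignment`
#' @return character scalar
#' @export
query_sequence <- function(aln) {
  q <- aln$mat[aln$query_index, ]
  paste(q[q != GAP_CHAR], collapse = "")
}

# Keep a subset of rows; the column set (and hence query coordinates) is
# unchanged. Internal: callers guarantee the query row is retained.
subset_rows <- function(aln, keep) {
  keep <- sort(unique(keep))
  out <- aln
  out$ids <- aln$ids[keep]
  out$mat <- aln$mat[keep, , drop = FALSE]
  out$query_index <- match(aln$query_index, keep)
  stopifnot(!is.na(out$query_index))
  out
}

#' Read a protein-family alignment from FASTA or Stockholm
#'
#' @param path file path
#' @param format `"fasta"` (aligned, gapped) or `"stockholm"`
#' @param query_id identifier of the query sequence; matched against the
#'   first whitespace-delimited token of each record name
#' @return a [alignment()] object
#' @export
read_alignment <- function(path, format = c("fasta", "stockholm"), query_id) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  msa <- Biostrings::readAAMultipleAlignment(path, format = format)
  seqs <- as.character(Biostrings::unmasked(msa))
  if (length(seqs) == 0) stop("empty alignment: ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  alignment(seqs, query_id)
}

#' Write an alignment as gapped FASTA
#'
#' @param aln a `protein_alignment`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_fasta <- function(aln, path) {
  seqs <- apply(aln$mat, 1, paste, collapse = "")
  ss <- Biostrings::AAStringSet(seqs)
  names(ss) <- aln$ids
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Per-sequence identity to the query
#'
#' Fraction of the query's non-gap columns where a row carries exactly the
#' query residue. Gaps never match, so an all-gap row scores 0; the query
#' itself scores 1.
#'
#' @param aln a `protein_alignment`
#' @return named numeric vector in \[0, 1\], one entry per sequence
#' @export
identity_to_query <- function(aln) {
  qcols <- which(!is.na(aln$col_to_query))
  qres <- aln$mat[aln$query_index, qcols]
  sub <- aln$mat[, qcols, drop = FALSE]
  ident <- rowMeans(sub == matrix(qres, nrow(sub), length(qcols), byrow = TRUE))
  names(ident) <- aln$ids
  ident
}

#' Remove sequences with poor query coverage
#'
#' Drops rows that carry a residue at fewer than `min_frac` of the query's
#' non-gap columns. The query row is exempt and always retained. The report
#' summarizes what survived, including the identity-to-query statistics used
#' to judge alignment quality.
#'
#' @param aln a `protein_alignment`
#' @param min_frac minimum fraction of query positions covered, in (0, 1];
#'   a row at exactly the threshold is retained (the removal rule is
#'   strictly-below)
#' @return list with elements `alignment` (filtered) and `report`, a list
#'   with `n_input`, `n_removed_coverage`, `min_identity_retained`,
#'   `fraction_above_30pct_identity`
#' @export
filter_by_query_coverage <- function(aln, min_frac = 0.70) {
  if (!is.numeric(min_frac) || length(min_frac) != 1 ||
      min_frac <= 0 || min_frac > 1) {
    stop("min_frac must be a single value in (0, 1]")
  }
  qcols <- which(!is.na(aln$col_to_query))
  cov <- rowMeans(aln$mat[, qcols, drop = FALSE] != GAP_CHAR)
  keep <- cov >= min_frac
  keep[aln$query_index] <- TRUE
  out <- subset_rows(aln, which(keep))
  ident <- identity_to_query(out)
  report <- list(
    n_input = n_sequences(aln),
    n_removed_coverage = sum(!keep),
    min_identity_retained = min(ident),
    fraction_above_30pct_identity = mean(ident >= 0.30)
  )
  list(alignment = out, report = report)
}

#' Columns eligible for entropy analysis and scoring
#'
#' A column qualifies when the fraction of non-gap characters across all
#' rows is at least `min_occupancy` (boundary inclusive) and the query has a
#' residue there, so every scoring column maps to a query position.
#'
#' @param aln a `protein_alignment`
#' @param min_occupancy minimum non-gap fraction, default 0.70
#' @return sorted integer vector of alignment column indices
#' @export
select_scoring_columns <- function(aln, min_occupancy = 0.70) {
  occ <- colMeans(aln$mat != GAP_CHAR)
  which(occ >= min_occupancy & !is.na(aln$col_to_query))
}

#' Cap alignment depth by seeded uniform subsampling
#'
#' Deep alignments are reduced to at most `max_n` rows before clustering.
#' The query row always survives; the remaining rows are a uniform random
#' subset, reproducible for a fixed seed. Row order is preserved.
#'
#' @param aln a `protein_alignment`
#' @param max_n maximum number of sequences to keep (default 20000)
#' @param seed integer seed
#' @return a `protein_alignment` with at most `max_n` rows
#' @export
subsample_alignment <- function(aln, max_n = 20000, seed = 1L) {
  stopifnot(max_n >= 1)
  n <- n_sequences(aln)
  if (n <= max_n) return(aln)
  others <- setdiff(seq_len(n), aln$query_index)
  keep <- local_seed(seed, sample(others, max_n - 1L))
  subset_rows(aln, c(aln$query_index, keep))
}
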