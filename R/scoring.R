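# Variant scoring: conservation, specificity, conjugate specificity, FIS,
# impact categories and the switch-of-function rule.
#
# For an alpha -> beta substitution at query position i the mutation adds
# one alpha and removes one beta from the observed residue multiset, so the
# change in combinatorial entropy reduces to the count log-ratio
# ln(n(alpha) / (n(beta) + 1)). Evaluated over the whole family it is the
# conservation score; over the subfamily containing the query it is the
# specificity score; the FIS is their mean. Positive scores mean the variant
# moves against the observed conservation pattern (likely deleterious),
# negative scores mean it moves toward the consensus.

#' Construct a substitution variant
#'
#' @param position 1-based position in the ungapped query sequence
#' @param wt_aa,mut_aa wildtype and mutant residues (single standard
#'   amino-acid letters; must differ)
#' @param protein_id optional protein identifier; when given it is checked
#'   against the alignment's query id at scoring time
#' @return object of class `mutation`
#' @export
#' @examples
#' mutation(12, "G", "D")
#' parse_mutation("G12D")
mutation <- function(position, wt_aa, mut_aa, protein_id = NA_character_) {
  wt_aa <- toupper(wt_aa); mut_aa <- toupper(mut_aa)
  if (!wt_aa %in% AA_LETTERS) stop("unknown wildtype residue: ", wt_aa)
  if (!mut_aa %in% AA_LETTERS) stop("unknown mutant residue: ", mut_aa)
  if (wt_aa == mut_aa) stop("wildtype and mutant residues must differ")
  position <- as.integer(position)
  if (is.na(position) || position < 1) stop("position must be a positive integer")
  structure(list(protein_id = protein_id, position = position,
                 wt_aa = wt_aa, mut_aa = mut_aa),
            class = "mutation")
}

#' @rdname mutation
#' @param token a string such as `"G12D"` (wildtype letter, position,
#'   mutant letter)
#' @export
parse_mutation <- function(token, protein_id = NA_character_) {
  m <- regmatches(token, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", token))[[1]]
  if (length(m) != 4) stop("malformed variant token: '", token, "'")
  mutation(as.integer(m[3]), m[2], m[4], protein_id = protein_id)
}

#' Read a variant list from TSV
#'
#' Expects tab-separated columns `protein_id`, `position`, `wt_aa`,
#' `mut_aa`.
#'
#' @param path file path
#' @return list of [mutation()] objects
#' @export
read_variants <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "wt_aa", "mut_aa")
  if (!all(need %in% names(df))) {
    stop("variant TSV must have columns: ", paste(need, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    tryCatch(
      mutation(df$position[i], df$wt_aa[i], df$mut_aa[i],
               protein_id = df$protein_id[i]),
      error = function(e) stop("variant line ", i, ": ", conditionMessage(e),
                               call. = FALSE)
    )
  })
}

count_of <- function(counts, aa) {
  cv <- as_count_vector(counts)
  n <- unname(cv[aa])
  if (is.na(n)) 0 else n   # residues absent from a sparse count vector
}

#' Conservation score of a substitution
#'
#' `ln(n(wt) / (n(mut) + 1))` on the family-wide residue counts at the
#' mutated column. Returns `-Inf` when the wildtype residue is absent (which
#' upstream code reports as a wildtype mismatch: the query's own residue is
#' always counted).
#'
#' @param family_counts a [column_counts()] object (or named count vector)
#'   over the whole family at the mutated column
#' @param wt,mut wildtype and mutant residue letters (must differ)
#' @return score in nats
#' @export
#' @examples
#' conservation_score(c(G = 90, D = 9, A = 1), "G", "D") # ln 9
conservation_score <- function(family_counts, wt, mut) {
  if (wt == mut) stop("wildtype and mutant residues must differ")
  log(count_of(family_counts, wt) / (count_of(family_counts, mut) + 1))
}

#' Specificity score of a substitution
#'
#' The same count log-ratio as [conservation_score()], computed on the
#' residue counts of the subfamily that contains the query protein.
#'
#' @param ref_subfamily_counts a [column_counts()] object restricted to the
#'   query's subfamily
#' @inheritParams conservation_score
#' @return score in nats
#' @export
specificity_score <- function(ref_subfamily_counts, wt, mut) {
  conservation_score(ref_subfamily_counts, wt, mut)
}

#' Functional impact score
#'
#' The mean of the conservation and specificity scores. Approximately equal
#' weighting of the two components is also what maximizes benign/pathogenic
#' classification performance on curated labels, so no weights are exposed.
#'
#' @param conservation,specificity component scores in nats (vectorized)
#' @return FIS in nats
#' @export
#' @examples
#' fis(5.05, 1.98) # 3.515
fis <- function(conservation, specificity) {
  (conservation + specificity) / 2
}

#' Conjugate specificity score
#'
#' The specificity-style score of the reverse (mutant -> wildtype)
#' substitution, evaluated in a subfamily where the mutant residue is
#' conserved: among subfamilies whose plurality residue at the column is the
#' mutant, `ln(n_s(mut) / (n_s(wt) + 1))` is computed and the maximum
#' returned. If no subfamily has the mutant as plurality, the subfamily with
#' the largest mutant count (> 0) is used; if the mutant residue is absent
#' from every subfamily the score is `-Inf`. A high conjugate specificity
#' means some subfamily is built around the variant residue -- the
#' signature, together with a high specificity score, of a possible
#' switch of functional specificity rather than a plain loss of function.
#'
#' @param subfamily_counts a list of [column_counts()] objects (or a
#'   20 x K count matrix), one per subfamily, at the mutated column
#' @inheritParams conservation_score
#' @return score in nats, or `-Inf`
#' @export
conjugate_specificity_score <- function(subfamily_counts, wt, mut) {
  if (wt == mut) stop("wildtype and mutant residues must differ")
  cnts <- if (is.matrix(subfamily_counts)) {
    subfamily_counts
  } else {
    vapply(subfamily_counts, as_count_vector, numeric(20))
  }
  stopifnot(nrow(cnts) == 20)
  rownames(cnts) <- AA_LETTERS
  n_mut <- cnts[mut, ]
  n_wt <- cnts[wt, ]
  if (all(n_mut == 0)) return(-Inf)
  plurality <- n_mut > 0 & n_mut == apply(cnts, 2, max)
  idx <- if (any(plurality)) which(plurality) else which.max(n_mut)
  max(log(n_mut[idx] / (n_wt[idx] + 1)))
}

#' Impact category cutoffs
#'
#' FIS thresholds between the four impact categories, calibrated against
#' curated benign/pathogenic labels: neutral/low at 2.6, low/medium at 5.25
#' (where false positive and false negative rates balance), medium/high
#' at 7.
#'
#' @param neutral_low,low_medium,medium_high increasing FIS cutoffs
#' @return object of class `impact_cutoffs`
#' @export
impact_cutoffs <- function(neutral_low = 2.6, low_medium = 5.25,
                           medium_high = 7.0) {
  if (!(neutral_low < low_medium && low_medium < medium_high)) {
    stop("cutoffs must be strictly increasing")
  }
  structure(list(neutral_low = neutral_low, low_medium = low_medium,
                 medium_high = medium_high),
            class = "impact_cutoffs")
}

#' Assign an impact category from a FIS value
#'
#' A FIS exactly at a cutoff takes the higher-impact category: neutral
#' `< 2.6 <=` low `< 5.25 <=` medium `< 7 <=` high (default cutoffs).
#'
#' @param fis_value numeric vector of FIS values
#' @param cutoffs an [impact_cutoffs()] object
#' @return character vector of categories
#' @export
#' @examples
#' classify_impact(c(2.04, 3.52, 5.25, 7.66)) # neutral low medium high
classify_impact <- function(fis_value, cutoffs = impact_cutoffs()) {
  breaks <- c(-Inf, cutoffs$neutral_low, cutoffs$low_medium,
              cutoffs$medium_high, Inf)
  as.character(cut(fis_value, breaks = breaks,
                   labels = c("neutral", "low", "medium", "high"),
                   right = FALSE, include.lowest = TRUE))
}

#' Switch-of-function thresholds
#'
#' A substitution is flagged as a putative switch of function when its
#' wildtype and mutant residues are conserved in distinct subfamilies:
#' specificity and conjugate specificity both high, conservation below the
#' medium-impact boundary. Defaults are chosen so that experimentally
#' characterized specificity-swap substitutions between closely related
#' small GTPases pass while active-site losses with very high conservation
#' and negative conjugate specificity fail.
#'
#' @param spec_min minimum specificity score (nats)
#' @param conj_min minimum conjugate specificity score (nats)
#' @param cons_max conservation score must be strictly below this (nats)
#' @return object of class `sof_thresholds`
#' @export
sof_thresholds <- function(spec_min = 4.5, conj_min = 4.5, cons_max = 5.25) {
  structure(list(spec_min = spec_min, conj_min = conj_min,
                 cons_max = cons_max),
            class = "sof_thresholds")
}

#' Flag putative switch-of-function substitutions
#'
#' @param conservation,specificity,conjugate_specificity score vectors in
#'   nats (`-Inf` conjugate specificity never flags)
#' @param thresholds a [sof_thresholds()] object
#' @return logical vector
#' @export
flag_switch_of_function <- function(conservation, specificity,
                                    conjugate_specificity,
                                    thresholds = sof_thresholds()) {
  specificity >= thresholds$spec_min &
    conjugate_specificity >= thresholds$conj_min &
    conservation < thresholds$cons_max
}

# Scoring kernel for one alignment column: all requested mutant residues
# against one wildtype. Returns a data.frame.
score_column <- function(aln, partition, column, wt, muts, cutoffs,
                         sof, min_occupancy) {
  wt <- unname(wt); muts <- unname(muts)
  labels <- partition$labels
  qlab <- partition$query_label
  v <- aln$mat[, column]
  cd <- match(v, AA_LETTERS)
  keep <- !is.na(cd)
  fam <- tabulate(cd[keep], 20L)
  sub <- tabulate(cd[keep & labels == qlab], 20L)
  ks <- sort(unique(labels))
  cnts <- vapply(ks, function(k) tabulate(cd[keep & labels == k], 20L),
                 numeric(20))
  rownames(cnts) <- names(fam) <- names(sub) <- AA_LETTERS

  occupancy_ok <- mean(v != GAP_CHAR) >= min_occupancy
  qres <- unname(v[aln$query_index])
  wt_mismatch <- !identical(qres, wt)

  cons <- log(fam[wt] / (fam[muts] + 1))
  spec <- log(sub[wt] / (sub[muts] + 1))
  conj <- vapply(muts, function(b) conjugate_specificity_score(cnts, wt, b),
                 numeric(1))
  f <- fis(cons, spec)
  cat_ok <- occupancy_ok && !wt_mismatch
  category <- if (cat_ok) classify_impact(f, cutoffs) else
    rep("not_scorable", length(muts))
  sofl <- flag_switch_of_function(cons, spec, conj, sof) & cat_ok

  data.frame(
    protein_id = aln$ids[aln$query_index],
    position = aln$col_to_query[column],
    wt = wt, mut = muts,
    conservation = unname(cons), specificity = unname(spec),
    conjugate_specificity = unname(conj), fis = unname(f),
    category = category, switch_of_function = unname(sofl),
    wt_mismatch = wt_mismatch,
    stringsAsFactors = FALSE
  )
}

#' Score one substitution variant
#'
#' Maps the variant's query position to its alignment column, assembles the
#' family and reference-subfamily residue counts, and computes the
#' conservation, specificity, conjugate specificity and FIS scores, the
#' impact category and the switch-of-function flag. A variant whose claimed
#' wildtype residue disagrees with the query (`wt_mismatch`), or whose
#' column fails the occupancy threshold, is still scored against the claimed
#' residues but categorized `not_scorable`.
#'
#' @param aln a [alignment()] object
#' @param partition a `subfamily_partition` of `aln`'s rows
#' @param m a [mutation()]
#' @param cutoffs an [impact_cutoffs()] object
#' @param sof a [sof_thresholds()] object
#' @param min_occupancy minimum non-gap fraction for a scorable column
#' @return one-row data.frame (see [score_all_substitutions()] for columns)
#' @export
score_variant <- function(aln, partition, m, cutoffs = impact_cutoffs(),
                          sof = sof_thresholds(), min_occupancy = 0.70) {
  stopifnot(inherits(m, "mutation"))
  qid <- aln$ids[aln$query_index]
  if (!is.na(m$protein_id) && m$protein_id != qid) {
    stop("variant protein_id '", m$protein_id,
         "' does not match query '", qid, "'")
  }
  column <- which(aln$col_to_query == m$position)
  if (length(column) != 1) {
    stop("position ", m$position, " exceeds the query length (",
         max(aln$col_to_query, na.rm = TRUE), ")")
  }
  score_column(aln, partition, column, m$wt_aa, m$mut_aa,
               cutoffs, sof, min_occupancy)
}

#' Score every substitution at every query position
#'
#' The complete substitution table: for each query position whose residue is
#' a standard amino acid, all 19 alternative residues are scored. Positions
#' on low-occupancy columns are retained with category `not_scorable`.
#'
#' @inheritParams score_variant
#' @return data.frame with columns `protein_id`, `position`, `wt`, `mut`,
#'   `conservation`, `specificity`, `conjugate_specificity`, `fis`,
#'   `category`, `switch_of_function`, `wt_mismatch`
#' @export
score_all_substitutions <- function(aln, partition,
                                    cutoffs = impact_cutoffs(),
                                    sof = sof_thresholds(),
                                    min_occupancy = 0.70) {
  cols <- which(!is.na(aln$col_to_query))
  out <- lapply(cols, function(column) {
    wt <- aln$mat[aln$query_index, column]
    if (!wt %in% AA_LETTERS) return(NULL)  # non-standard query residue
    score_column(aln, partition, column, wt, setdiff(AA_LETTERS, wt),
                 cutoffs, sof, min_occupancy)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a score table as TSV
#'
#' Serializes `-Inf` scores as `"-inf"`.
#'
#' @param scores data.frame from [score_variant()] /
#'   [score_all_substitutions()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_scores_tsv <- function(scores, path) {
  fmt <- scores
  for (cn in c("conservation", "specificity", "conjugate_specificity", "fis")) {
    x <- scores[[cn]]
    fmt[[cn]] <- ifelse(is.infinite(x), ifelse(x < 0, "-inf", "inf"),
                        sprintf("%.6g", x))
  }
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
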