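# End-to-end pipeline surface used by the `ceofis` command-line script:
# configuration, the cluster and score runs, and the bundled reference-score
# demo. All randomness (subsampling, permutation nulls) is governed by the
# single seed in the configuration, which is echoed into the run metadata.

#' Pipeline run configuration
#'
#' Bundles every tunable of the pipeline with the standard defaults: 70%
#' column occupancy, 70% query coverage, a 20,000-sequence cap, the
#' granularity grid 0.5..0.975 in steps of 0.025, 100 null permutations.
#'
#' @param input path to the protein-family alignment
#' @param query_id identifier of the query/reference sequence
#' @param format `"fasta"` or `"stockholm"`
#' @param occupancy minimum column occupancy for scoring columns
#' @param coverage minimum per-sequence query coverage
#' @param max_sequences depth cap before clustering
#' @param a_grid granularity values to scan
#' @param n_perm permutations per column for the null table
#' @param seed integer seed for subsampling and the permutation null
#' @param cutoffs an [impact_cutoffs()] object
#' @param sof a [sof_thresholds()] object
#' @param output_dir directory for output files (created if missing)
#' @return object of class `run_config`
#' @export
run_config <- function(input, query_id, format = c("fasta", "stockholm"),
                       occupancy = 0.70, coverage = 0.70,
                       max_sequences = 20000L,
                       a_grid = seq(0.5, 0.975, by = 0.025),
                       n_perm = 100L, seed = 1L,
                       cutoffs = impact_cutoffs(), sof = sof_thresholds(),
                       output_dir = ".") {
  format <- match.arg(format)
  stopifnot(occupancy > 0, occupancy <= 1, coverage > 0, coverage <= 1,
            max_sequences >= 1, length(a_grid) >= 1,
            all(a_grid > 0), all(a_grid <= 1), n_perm >= 1)
  structure(list(input = input, query_id = query_id, format = format,
                 occupancy = occupancy, coverage = coverage,
                 max_sequences = as.integer(max_sequences),
                 a_grid = a_grid, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), cutoffs = cutoffs, sof = sof,
                 output_dir = output_dir),
            class = "run_config")
}

# Read + filter + column selection + depth cap; shared by cluster and score.
prepare_alignment <- function(config) {
  aln <- read_alignment(config$input, config$format, config$query_id)
  message(sprintf("read %d sequences x %d columns (query: %s)",
                  n_sequences(aln), n_columns(aln), config$query_id))
  flt <- filter_by_query_coverage(aln, config$coverage)
  message(sprintf("coverage filter (< %.0f%%): removed %d of %d sequences",
                  100 * config$coverage, flt$report$n_removed_coverage,
                  flt$report$n_input))
  aln <- subsample_alignment(flt$alignment, config$max_sequences, config$seed)
  if (n_sequences(aln) < n_sequences(flt$alignment)) {
    message(sprintf("subsampled to %d sequences (seed %d)",
                    n_sequences(aln), config$seed))
  }
  columns <- select_scoring_columns(aln, config$occupancy)
  if (length(columns) == 0) {
    stop("no scoring columns survive the ", 100 * config$occupancy,
         "% occupancy threshold")
  }
  message(sprintf("%d of %d columns pass %.0f%% occupancy",
                  length(columns), n_columns(aln), 100 * config$occupancy))
  list(alignment = aln, columns = columns, report = flt$report)
}

#' Run the clustering stage and write the partition to disk
#'
#' Reads and filters the alignment, scans the granularity grid, and writes
#' `partition.tsv` (`sequence_id`, `subfamily`) plus `partition_meta.json`
#' (all parameters, the filter report, the chosen granularity, objective and
#' specificity columns) into the configured output directory.
#'
#' @param config a [run_config()]
#' @return invisibly, a list with `alignment`, `columns`, `partition`, and
#'   `paths` of the written files
#' @export
run_cluster <- function(config) {
  stopifnot(inherits(config, "run_config"))
  prep <- prepare_alignment(config)
  part <- scan_a(prep$alignment, prep$columns, grid = config$a_grid,
                 n_perm = config$n_perm, seed = config$seed)
  message(sprintf(
    "CEO: %d subfamilies at a = %.3f (objective %.4f nats)",
    part$n_subfamilies, part$a_value, part$objective))

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(config$output_dir, "partition.tsv")
  meta <- file.path(config$output_dir, "partition_meta.json")
  utils::write.table(
    data.frame(sequence_id = names(part$labels),
               subfamily = unname(part$labels)),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(a_value = part$a_value, objective = part$objective,
         n_subfamilies = part$n_subfamilies,
         specificity_columns = part$specificity_columns,
         query_label = part$query_label,
         filter_report = prep$report,
         config = list(input = config$input, query_id = config$query_id,
                       format = config$format, occupancy = config$occupancy,
                       coverage = config$coverage,
                       max_sequences = config$max_sequences,
                       a_grid = config$a_grid, n_perm = config$n_perm,
                       seed = config$seed)),
    meta, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(alignment = prep$alignment, columns = prep$columns,
                 partition = part, paths = c(tsv, meta)))
}

#' Run the scoring stage and write a score table
#'
#' Scores the requested variants (or, with `all = TRUE`, every substitution
#' at every query position) against a subfamily partition, computing the
#' partition first via [run_cluster()] when one is not supplied. Writes
#' `scores.tsv` into the configured output directory.
#'
#' @param config a [run_config()]
#' @param variants variants to score: a TSV path (see [read_variants()]), a
#'   character vector of tokens such as `"G12D"`, or a list of [mutation()]
#'   objects; ignored when `all = TRUE`
#' @param all score the full substitution table
#' @param cluster_run an optional previous [run_cluster()] result to reuse
#' @return invisibly, the score data.frame (also written to disk)
#' @export
run_score <- function(config, variants = NULL, all = FALSE,
                      cluster_run = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(cluster_run)) cluster_run <- run_cluster(config)
  aln <- cluster_run$alignment
  part <- cluster_run$partition

  if (all) {
    scores <- score_all_substitutions(aln, part, config$cutoffs, config$sof,
                                      config$occupancy)
  } else {
    muts <- if (is.character(variants) && length(variants) == 1 &&
                file.exists(variants)) {
      read_variants(variants)
    } else if (is.character(variants)) {
      lapply(variants, parse_mutation)
    } else if (is.list(variants) && all(vapply(variants, inherits,
                                               logical(1), "mutation"))) {
      variants
    } else {
      stop("variants must be a TSV path, variant tokens, or mutation objects")
    }
    scores <- do.call(rbind, lapply(muts, function(m) {
      score_variant(aln, part, m, config$cutoffs, config$sof,
                    config$occupancy)
    }))
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(config$output_dir, "scores.tsv")
  write_scores_tsv(scores, path)
  message(sprintf("wrote %d scored substitutions to %s", nrow(scores), path))
  invisible(scores)
}

#' Bundled reference component scores for recurrent cancer mutations
#'
#' Conservation/specificity component pairs and the released two-decimal FIS
#' for well-known recurrent somatic mutations (KRAS, BRAF, PIK3CA, TP53),
#' shipped as a validation fixture for the score-combination step.
#'
#' @return data.frame with columns `gene`, `mutation`, `clinvar_label`,
#'   `conservation`, `specificity`, `fis_reported`
#' @export
reference_fis_components <- function() {
  utils::read.delim(
    system.file("extdata", "reference_fis_components.tsv", package = "ceofis"),
    stringsAsFactors = FALSE)
}

#' Bundled reference scores for specificity-switch and active-site variants
#'
#' Conservation, specificity and conjugate specificity scores for
#' experimentally characterized residue swaps between the small GTPases RAC1
#' and CDC42 (specificity switches), for IDH1 active-site substitutions
#' (high conservation, negative or `-Inf` conjugate specificity), and for
#' putative switch-of-function recurrent cancer mutations. Shipped as a
#' validation fixture for the switch-of-function rule; `-Inf` is encoded as
#' `-inf` in the TSV.
#'
#' @return data.frame with columns `gene`, `mutation`, `group`,
#'   `conservation`, `specificity`, `conjugate_specificity`,
#'   `expected_switch`
#' @export
sof_reference_scores <- function() {
  df <- utils::read.delim(
    system.file("extdata", "sof_reference_scores.tsv", package = "ceofis"),
    stringsAsFactors = FALSE)
  df$conjugate_specificity <- ifelse(df$conjugate_specificity == "-inf", -Inf,
                                     as.numeric(df$conjugate_specificity))
  df$expected_switch <- as.logical(df$expected_switch)
  df
}

#' Recompute FIS for the bundled reference mutations
#'
#' Applies the package's score combination and categorization to the bundled
#' component scores and compares against the released two-decimal FIS values
#' row by row. Because the stored components are themselves rounded to two
#' decimals, agreement is judged on the unrounded mean to within half a unit
#' of the printed precision (0.005 nats).
#'
#' @param quiet suppress the printed table
#' @return data.frame with the recomputed `fis`, its half-up two-decimal
#'   rounding `fis_2dp`, the released value, the impact `category` and a
#'   logical `agrees` column
#' @export
check_reference_fis <- function(quiet = FALSE) {
  ref <- reference_fis_components()
  ref$fis <- fis(ref$conservation, ref$specificity)
  ref$fis_2dp <- round_half_up(ref$fis, 2)
  ref$category <- classify_impact(ref$fis)
  ref$agrees <- abs(ref$fis - ref$fis_reported) <= 0.005 + 1e-9
  if (!quiet) {
    print(ref[, c("gene", "mutation", "conservation", "specificity",
                  "fis_2dp", "fis_reported", "category", "agrees")],
          row.names = FALSE)
    cat(sprintf("%d/%d reference FIS values reproduced\n",
                sum(ref$agrees), nrow(ref)))
  }
  invisible(ref)
}
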