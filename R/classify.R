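#' Taxonomy-supervised classification of long reads
#'
#' The phylotyping rule: every read is aligned locally against every
#' reference under the affine scheme and the highest-scoring reference
#' wins; the read inherits that reference's lineage. Reads whose best
#' alignment covers less than `min_query_cover` of the read are reported
#' unassigned. When several references tie for the best score, the
#' assigned lineage is truncated to the lowest common ancestor of the tied
#' references (`tie_count` records how many) -- a conservative, reproducible
#' alternative to picking an arbitrary first hit.
#'
#' @param reads Data frame with `id` and `seq` columns.
#' @param db A `reference_db`.
#' @param scheme A [scoring_scheme()].
#' @param min_query_cover Minimum fraction of the read inside the aligned
#'   span (default 0.5).
#' @return A list with `assignments` (data frame `read_id`, `ref_id`,
#'   `score`, `tie_count`, `query_cover`, `ref_cover`, plus a `lineage`
#'   list column) and `unassigned` (character vector of read ids).
#' @export
classify_reads <- function(reads, db, scheme = scoring_scheme(),
                           min_query_cover = 0.5) {
  stopifnot(inherits(db, "reference_db"))
  if (nrow(db$records) == 0L) stop("reference database is empty")
  refs <- db$records
  keep <- nzchar(reads$seq)
  if (any(!keep)) {
    warning("skipping ", sum(!keep), " empty read(s)")
    reads <- reads[keep, , drop = FALSE]
  }
  n <- nrow(reads)
  rows <- vector("list", n)
  unassigned <- character(0)
  for (i in seq_len(n)) {
    scores <- align_scores(reads$seq[i], refs$seq, scheme, local = TRUE)
    best <- max(scores)
    tied <- which(scores == best)
    aln <- align_local(reads$seq[i], refs$seq[tied[1]], scheme)
    if (aln$query_cover < min_query_cover) {
      unassigned <- c(unassigned, reads$id[i])
      next
    }
    lin <- if (length(tied) > 1L) {
      lineage_lca(refs$lineage[tied])
    } else {
      refs$lineage[[tied]]
    }
    rows[[i]] <- list(read_id = reads$id[i], ref_id = refs$id[tied[1]],
                      score = best, tie_count = length(tied),
                      query_cover = aln$query_cover,
                      ref_cover = aln$ref_cover, lineage = lin)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  assignments <- data.frame(
    read_id = vapply(rows, `[[`, character(1), "read_id"),
    ref_id = vapply(rows, `[[`, character(1), "ref_id"),
    score = vapply(rows, function(r) as.integer(r$score), integer(1)),
    tie_count = vapply(rows, function(r) as.integer(r$tie_count), integer(1)),
    query_cover = vapply(rows, `[[`, numeric(1), "query_cover"),
    ref_cover = vapply(rows, `[[`, numeric(1), "ref_cover"))
  assignments$lineage <- lapply(rows, `[[`, "lineage")
  list(assignments = assignments, unassigned = unassigned)
}

#' Discard taxa supported by too few reads
#'
#' Removes every taxon (keyed by the deepest assigned lineage) supported by
#' fewer than `min_reads_per_taxon` reads -- by default the singleton
#' discard used to suppress spurious taxonomic units.
#'
#' @param assignments The `assignments` data frame from [classify_reads()].
#' @param min_reads_per_taxon Minimum supporting reads (default 2).
#' @return The filtered assignments data frame.
#' @export
filter_low_abundance <- function(assignments, min_reads_per_taxon = 2L) {
  if (min_reads_per_taxon <= 1L || nrow(assignments) == 0L) {
    return(assignments)
  }
  key <- vapply(assignments$lineage, format_lineage, character(1))
  counts <- table(key)
  keep <- key %in% names(counts)[counts >= min_reads_per_taxon]
  out <- assignments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pooled accuracy statistics
#'
#' Accuracy is micro-averaged over reads: operation counts are pooled and
#' accuracy = matches / (matches + mismatches + insertions + deletions),
#' so accuracy and the three error rates share one denominator and sum to
#' exactly 1.
#'
#' @param matches,mismatches,insertions,deletions Pooled aligned-column
#'   counts.
#' @param n_reads_used Number of reads contributing to the pool.
#' @return A list of class `"accuracy_stats"` with the counts, `accuracy`,
#'   `mismatch_rate`, `insertion_rate`, `deletion_rate` and `error_rate`.
#' @examples
#' s <- accuracy_stats(796, 90, 64, 50, n_reads_used = 1)
#' s$accuracy # 0.796
#' @export
accuracy_stats <- function(matches, mismatches, insertions, deletions,
                           n_reads_used) {
  total <- matches + mismatches + insertions + deletions
  if (total <= 0) stop("no aligned columns: cannot compute accuracy")
  structure(list(
    n_reads_used = n_reads_used, matches = matches, mismatches = mismatches,
    insertions = insertions, deletions = deletions,
    accuracy = matches / total, mismatch_rate = mismatches / total,
    insertion_rate = insertions / total, deletion_rate = deletions / total,
    error_rate = 1 - matches / total), class = "accuracy_stats")
}

#' @export
print.accuracy_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "<accuracy_stats> %d reads | accuracy %.1f%% | mismatches %.1f%% | ",
    "insertions %.1f%% | deletions %.1f%%\n"),
    x$n_reads_used, 100 * x$accuracy, 100 * x$mismatch_rate,
    100 * x$insertion_rate, 100 * x$deletion_rate))
  invisible(x)
}

#' Estimate platform error rates from spike-in control reads
#'
#' Each control read is aligned locally to the control reference; reads
#' whose alignment spans less than `min_ref_span` of the reference
#' (default 80%, computed on the reference by default -- switch
#' `coverage_on = "query"` to filter on the read instead) are excluded,
#' and the per-column operation counts of the remaining reads are pooled
#' into [accuracy_stats()].
#'
#' @param control_reads Data frame of reads (`id`, `seq`).
#' @param control_ref The control (list with `seq`, e.g.
#'   [control_sequence()]).
#' @param scheme A [scoring_scheme()].
#' @param min_ref_span Span-filter threshold (default 0.8).
#' @param coverage_on `"reference"` (default) or `"query"`.
#' @return An `"accuracy_stats"` object; its `n_reads_used` counts the
#'   reads passing the span filter.
#' @export
assess_accuracy <- function(control_reads, control_ref,
                            scheme = scoring_scheme(), min_ref_span = 0.8,
                            coverage_on = c("reference", "query")) {
  coverage_on <- match.arg(coverage_on)
  if (nrow(control_reads) == 0L) stop("no control reads supplied")
  M <- X <- I <- D <- 0L; used <- 0L
  for (i in seq_len(nrow(control_reads))) {
    a <- align_local(control_reads$seq[i], control_ref$seq, scheme)
    cov <- if (coverage_on == "reference") a$ref_cover else a$query_cover
    if (cov < min_ref_span) next
    M <- M + a$matches; X <- X + a$mismatches
    I <- I + a$insertions; D <- D + a$deletions
    used <- used + 1L
  }
  if (used == 0L) {
    stop("no control read passed the ", min_ref_span * 100, "% span filter")
  }
  accuracy_stats(M, X, I, D, used)
}
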