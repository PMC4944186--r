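#' Scoring scheme for pairwise alignment
#'
#' The cost model mirrors the LAST aligner's: a match earns `match`, a
#' mismatch costs `mismatch_cost`, and a gap of length k costs
#' `gap_open_cost + k * gap_extend_cost`. The default `(1, 1, 1, 1)` is the
#' parameter set used throughout the pipeline for read-to-reference
#' alignment (LAST flags `-q 1 -a 1 -b 1`, with the default match score of
#' +1): note that in LAST `-q` is the mismatch *cost*, not the match score.
#'
#' @param match,mismatch_cost,gap_open_cost,gap_extend_cost Non-negative
#'   integers.
#' @return A list of class `"scoring_scheme"`.
#' @export
scoring_scheme <- function(match = 1L, mismatch_cost = 1L,
                           gap_open_cost = 1L, gap_extend_cost = 1L) {
  v <- c(match, mismatch_cost, gap_open_cost, gap_extend_cost)
  if (any(v < 0) || any(v != as.integer(v))) {
    stop("all scoring parameters must be non-negative integers")
  }
  structure(list(match = as.integer(match),
                 mismatch_cost = as.integer(mismatch_cost),
                 gap_open_cost = as.integer(gap_open_cost),
                 gap_extend_cost = as.integer(gap_extend_cost)),
            class = "scoring_scheme")
}

check_dna <- function(s, what = "sequence") {
  if (!nzchar(s)) stop(what, " must be non-empty")
  if (grepl("[^ACGTN]", s)) {
    stop(what, " contains characters other than A/C/G/T/N")
  }
  s
}

align_impl <- function(query, ref, scheme, local,
                       query_id = NA_character_, ref_id = NA_character_) {
  query <- check_dna(toupper(query), "query")
  ref <- check_dna(toupper(ref), "reference")
  a <- .align_pair_cpp(query, ref, scheme$match, scheme$mismatch_cost,
                       scheme$gap_open_cost, scheme$gap_extend_cost, local)
  qlen <- nchar(query); rlen <- nchar(ref)
  qspan <- if (is.na(a$query_start)) 0L else a$query_end - a$query_start + 1L
  rspan <- if (is.na(a$ref_start)) 0L else a$ref_end - a$ref_start + 1L
  structure(list(
    query_id = query_id, ref_id = ref_id, score = a$score,
    matches = a$matches, mismatches = a$mismatches,
    insertions = a$insertions, deletions = a$deletions,
    query_cover = qspan / qlen, ref_cover = rspan / rlen,
    query_start = a$query_start, query_end = a$query_end,
    ref_start = a$ref_start, ref_end = a$ref_end,
    aligned_query = a$aligned_query, aligned_ref = a$aligned_ref),
    class = "alignment_result")
}

#' Pairwise DNA alignment with affine gap costs
#'
#' `align_local()` computes the optimal Smith-Waterman-style local
#' alignment, `align_global()` the optimal end-to-end (Needleman-Wunsch)
#' alignment, both under the affine cost model of [scoring_scheme()] and
#' both returning exact per-column operation counts: `matches`,
#' `mismatches`, `insertions` (query base absent from the reference) and
#' `deletions` (reference base absent from the query). `N` never matches
#' anything, including another `N`. Among equal-scoring tracebacks the
#' diagonal is preferred over a deletion over an insertion, so counts are
#' reproducible.
#'
#' @param query,ref,a,b DNA strings over A/C/G/T/N.
#' @param scheme A [scoring_scheme()].
#' @param query_id,ref_id Optional ids carried into the result.
#' @return An object of class `"alignment_result"`: a list with the counts
#'   above plus `score`, `query_cover`/`ref_cover` (fraction of each
#'   sequence inside the aligned span), 1-based span coordinates, and the
#'   two gapped alignment strings.
#' @examples
#' align_local("ACGTACGT", "ACGTACGT")$score # 8
#' align_global("ACGT", "AGT")$deletions     # 1
#' @export
align_local <- function(query, ref, scheme = scoring_scheme(),
                        query_id = NA_character_, ref_id = NA_character_) {
  align_impl(query, ref, scheme, local = TRUE, query_id, ref_id)
}

#' @rdname align_local
#' @export
align_global <- function(a, b, scheme = scoring_scheme(),
                         query_id = NA_character_, ref_id = NA_character_) {
  align_impl(a, b, scheme, local = FALSE, query_id, ref_id)
}

# score-only ranking of one query against many references (C++ kernel,
# linear memory; used by the classifier before the single full traceback)
align_scores <- function(query, refs, scheme = scoring_scheme(),
                         local = TRUE) {
  .align_scores_many_cpp(toupper(query), toupper(refs), scheme$match,
                         scheme$mismatch_cost, scheme$gap_open_cost,
                         scheme$gap_extend_cost, local)
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "<alignment> score %d | M %d X %d I %d D %d | qcov %.3f rcov %.3f\n",
    x$score, x$matches, x$mismatches, x$insertions, x$deletions,
    x$query_cover, x$ref_cover))
  invisible(x)
}

#' Tabulate alignment results
#'
#' @param results A list of `alignment_result` objects.
#' @return A data frame with one row per alignment (query, ref, score,
#'   counts, covers), suitable for [write_tsv] dumps.
#' @export
alignment_table <- function(results) {
  do.call(rbind, lapply(results, function(x) {
    data.frame(query_id = x$query_id, ref_id = x$ref_id, score = x$score,
               matches = x$matches, mismatches = x$mismatches,
               insertions = x$insertions, deletions = x$deletions,
               query_cover = x$query_cover, ref_cover = x$ref_cover)
  }))
}
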