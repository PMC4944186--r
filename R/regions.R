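#' Multiple alignment of reference sequences
#'
#' Two sequences get the optimal affine-gap global alignment. More than two
#' are aligned star-progressively on the first (anchor) sequence: each
#' other sequence is aligned globally to the anchor and the per-junction
#' gap runs are merged, which is adequate for the handful of closely
#' related references this analysis ever sees and is fully deterministic.
#'
#' @param seqs Data frame of records (`id`, `seq`) or named character
#'   vector, at least 2 sequences; the first is the anchor.
#' @param scheme A [scoring_scheme()].
#' @return A named character vector of equal-length gapped rows (class
#'   `"msa"`), anchor first.
#' @export
align_references <- function(seqs, scheme = scoring_scheme()) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$seq, seqs$id)
  if (length(seqs) < 2L) stop("need at least 2 sequences to align")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  anchor <- toupper(seqs[[1]])
  L <- nchar(anchor)
  others <- lapply(seqs[-1], function(s) {
    a <- align_global(toupper(s), anchor, scheme)
    list(gq = strsplit(a$aligned_query, "")[[1]],
         gr = strsplit(a$aligned_ref, "")[[1]])
  })
  # gap runs between anchor positions: junction k = before anchor base k+1,
  # k in 0..L (k = L is after the last base)
  ins_runs <- lapply(others, function(o) {
    runs <- integer(L + 1L)
    k <- 0L
    for (j in seq_along(o$gr)) {
      if (o$gr[j] == "-") runs[k + 1L] <- runs[k + 1L] + 1L else k <- k + 1L
    }
    runs
  })
  master <- Reduce(pmax, ins_runs, integer(L + 1L))

  anchor_chars <- strsplit(anchor, "")[[1]]
  build_anchor_row <- function() {
    out <- character(0)
    for (k in 0:L) {
      out <- c(out, rep("-", master[k + 1L]),
               if (k < L) anchor_chars[k + 1L])
    }
    paste0(out, collapse = "")
  }
  build_row <- function(o, runs) {
    out <- character(0)
    k <- 0L; j <- 1L
    for (k in 0:L) {
      # the sequence's own characters aligned into this junction's gap run
      own <- character(0)
      while (j <= length(o$gr) && o$gr[j] == "-") {
        own <- c(own, o$gq[j]); j <- j + 1L
      }
      out <- c(out, own, rep("-", master[k + 1L] - length(own)))
      if (k < L) { out <- c(out, o$gq[j]); j <- j + 1L }
    }
    paste0(out, collapse = "")
  }
  rows <- c(build_anchor_row(),
            mapply(build_row, others, ins_runs, USE.NAMES = FALSE))
  names(rows) <- names(seqs)
  stopifnot(length(unique(nchar(rows))) == 1L)
  structure(rows, class = "msa")
}

#' Detect variant columns in a multiple alignment
#'
#' A column is a variant when its residues (gaps count as an allele) are
#' not all identical -- equivalently, when some allele is present in less
#' than 50% of the rows. The minor allele frequency reported is the
#' frequency of the second-most-common allele, which lies in (0, 0.5] for
#' every variant column. Each site carries an anchor coordinate (0-based
#' position on the first row; columns where the anchor is gapped inherit
#' the preceding anchored position) and the hypervariable-region label
#' containing that coordinate, or `"inter-region"`.
#'
#' @param msa An [align_references()] result (or any equal-length character
#'   vector of gapped rows, anchor first).
#' @param region_map A region map (see [default_region_map()]).
#' @return A data frame with columns `column` (1-based alignment column),
#'   `anchor_pos` (0-based), `alleles` (e.g. `"A:3,G:1"`), `maf`,
#'   `has_gap`, `region`; anchor length in bases is attached as attribute
#'   `"anchor_length"`.
#' @export
detect_variants <- function(msa, region_map = default_region_map()) {
  rows <- unclass(msa)
  if (length(unique(nchar(rows))) != 1L) stop("msa rows differ in length")
  region_map <- check_region_map(region_map)
  m <- do.call(rbind, strsplit(rows, ""))
  anchor_gap <- m[1, ] == "-"
  anchor_pos <- cumsum(!anchor_gap) - 1L # gap columns inherit previous base
  anchor_pos[anchor_pos < 0L] <- 0L
  variant_cols <- which(apply(m, 2, function(col) length(unique(col)) > 1L))
  sites <- lapply(variant_cols, function(j) {
    counts <- sort(table(m[, j]), decreasing = TRUE)
    data.frame(
      column = j, anchor_pos = anchor_pos[j],
      alleles = paste0(names(counts), ":", as.integer(counts),
                       collapse = ","),
      maf = as.integer(counts[2]) / nrow(m),
      has_gap = "-" %in% names(counts))
  })
  out <- if (length(sites)) do.call(rbind, sites) else {
    data.frame(column = integer(), anchor_pos = integer(),
               alleles = character(), maf = numeric(), has_gap = logical())
  }
  out$region <- region_of(out$anchor_pos, region_map)
  attr(out, "anchor_length") <- sum(!anchor_gap)
  out
}

region_of <- function(pos, region_map) {
  vapply(pos, function(p) {
    hit <- which(region_map$start <= p & p < region_map$end)
    if (length(hit)) region_map$region[hit[1]] else "inter-region"
  }, character(1))
}

#' Count variant sites per hypervariable region
#'
#' @param sites A [detect_variants()] result.
#' @param region_map The region map used for annotation.
#' @param window Optional 0-based half-open `(start, end)` interval in
#'   anchor coordinates (e.g. an amplicon window located by
#'   [in_silico_pcr()] on the anchor); its variant total is reported
#'   separately.
#' @return A list with `by_region` (named counts over every region label
#'   plus `inter-region`), `total`, and `in_window` (`NA` without a
#'   window).
#' @export
count_variants_by_region <- function(sites, region_map = default_region_map(),
                                     window = NULL) {
  region_map <- check_region_map(region_map)
  labels <- c(region_map$region, "inter-region")
  by_region <- setNames(integer(length(labels)), labels)
  tab <- table(sites$region)
  by_region[names(tab)] <- as.integer(tab)
  in_window <- NA_integer_
  if (!is.null(window)) {
    alen <- attr(sites, "anchor_length")
    if (!is.null(alen) && (window[1] < 0 || window[2] > alen)) {
      stop("window [", window[1], ", ", window[2],
           ") lies outside the anchor (length ", alen, ")")
    }
    in_window <- sum(sites$anchor_pos >= window[1] &
                       sites$anchor_pos < window[2])
  }
  list(by_region = by_region, total = nrow(sites), in_window = in_window)
}

#' Can an amplicon window tell two taxa apart?
#'
#' Aligns the two taxa's reference sequences, detects variant columns, and
#' reports whether at least one variant falls inside the amplicon window --
#' the structural question behind "is V3--V4 enough to separate these
#' species, or does it take the full-length gene?".
#'
#' @param db A `reference_db`.
#' @param taxon_pair Two reference ids or species labels present in `db`.
#' @param amplicon_window 0-based half-open `(start, end)` on the first
#'   taxon's sequence, or `"v34"` / `"full"` to locate the corresponding
#'   primer pair's amplicon by in-silico PCR, or `NULL` for the whole
#'   sequence.
#' @param scheme A [scoring_scheme()].
#' @return A list with `discriminable` (logical), `in_window`, `total`,
#'   `window` and the per-region counts.
#' @export
discriminability <- function(db, taxon_pair, amplicon_window = NULL,
                             scheme = scoring_scheme()) {
  stopifnot(length(taxon_pair) == 2L)
  idx <- vapply(taxon_pair, function(t) {
    i <- match(t, db$records$id)
    if (is.na(i)) {
      sp <- vapply(db$records$lineage, rank_label, character(1), "species")
      i <- match(t, sp)
    }
    if (is.na(i)) stop("unknown taxon '", t, "'")
    i
  }, integer(1))
  recs <- db$records[idx, , drop = FALSE]
  msa <- align_references(recs, scheme)
  sites <- detect_variants(msa, db$region_map)
  window <- amplicon_window
  if (is.character(window) && length(window) == 1L &&
      window %in% c("v34", "full")) {
    p <- db$primers[[window]]
    amp <- in_silico_pcr(recs[1, ], p$fwd, p$rev)
    if (is.null(amp)) stop("no ", window, " amplicon on anchor taxon")
    window <- c(amp$start, amp$end)
  }
  if (is.null(window)) window <- c(0L, attr(sites, "anchor_length"))
  counts <- count_variants_by_region(sites, db$region_map, window)
  list(discriminable = counts$in_window >= 1L,
       in_window = counts$in_window, total = counts$total,
       window = window, by_region = counts$by_region)
}
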