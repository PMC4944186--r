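#' Join a read pair across its overlap
#'
#' R2 is reverse-complemented, then the overlap maximizing the number of
#' matched bases, subject to a mismatch fraction at most
#' `max_mismatch_frac` and length at least `min_overlap`, is chosen. At
#' disagreeing overlap positions the higher-quality base wins. A joined
#' read shorter than 75% of the summed pair length is rejected (returns
#' `NULL`), mirroring the joined-length filter of the short-read pipeline.
#'
#' @param r1,r2 Single-row read records (`id`, `seq`, `qual`); `r2` in
#'   sequencing orientation.
#' @param min_overlap Minimum admissible overlap (default 10).
#' @param max_mismatch_frac Maximum mismatch fraction in the overlap
#'   (default 0.1).
#' @param min_joined_frac Minimum joined length as a fraction of
#'   `len(r1) + len(r2)` (default 0.75).
#' @return A list with `id`, `seq`, `qual`, or `NULL` when no admissible
#'   overlap exists or the joined read is too short.
#' @export
join_pairs <- function(r1, r2, min_overlap = 10L, max_mismatch_frac = 0.1,
                       min_joined_frac = 0.75) {
  s1 <- toupper(r1$seq); q1 <- unlist(r1$qual)
  s2 <- revcomp(toupper(r2$seq))
  q2 <- rev(unlist(r2$qual))
  n1 <- nchar(s1); n2 <- nchar(s2)
  c1 <- strsplit(s1, "")[[1]]; c2 <- strsplit(s2, "")[[1]]
  if (is.null(q1)) q1 <- rep(30L, n1)
  if (is.null(q2)) q2 <- rep(30L, n2)

  best <- NULL; best_matched <- -1L
  for (o in seq(min_overlap, min(n1, n2))) {
    a <- c1[(n1 - o + 1L):n1]
    b <- c2[1:o]
    mm <- sum(a != b)
    if (mm / o > max_mismatch_frac) next
    if (o - mm > best_matched) {
      best_matched <- o - mm
      best <- o
    }
  }
  if (is.null(best)) return(NULL)
  o <- best
  joined_len <- n1 + n2 - o
  if (joined_len < min_joined_frac * (n1 + n2)) return(NULL)

  i1 <- (n1 - o + 1L):n1
  ov_c <- c1[i1]; ov_q <- pmax(q1[i1], q2[1:o])
  take2 <- c2[1:o] != c1[i1] & q2[1:o] > q1[i1]
  ov_c[take2] <- c2[1:o][take2]
  seq <- paste0(c(c1[seq_len(n1 - o)], ov_c, c2[(o + 1L):n2][seq_len(n2 - o)]),
                collapse = "")
  qual <- c(q1[seq_len(n1 - o)], ov_q, q2[(o + 1L):n2][seq_len(n2 - o)])
  list(id = sub("/1$", "", r1$id), seq = seq, qual = as.integer(qual))
}

# vectorized convenience over two read data frames; drops failed joins
join_pair_set <- function(r1, r2, min_overlap = 10L, max_mismatch_frac = 0.1,
                          min_joined_frac = 0.75) {
  out <- vector("list", nrow(r1))
  for (i in seq_len(nrow(r1))) {
    out[[i]] <- join_pairs(list(id = r1$id[i], seq = r1$seq[i],
                                qual = r1$qual[[i]]),
                           list(id = r2$id[i], seq = r2$seq[i],
                                qual = r2$qual[[i]]),
                           min_overlap, max_mismatch_frac, min_joined_frac)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  d <- data.frame(id = vapply(out, `[[`, character(1), "id"),
                  seq = vapply(out, `[[`, character(1), "seq"))
  d$qual <- lapply(out, `[[`, "qual")
  d
}

#' Quality-truncate a read at the first low-quality base
#'
#' The read is truncated at the first base with quality below
#' `q_threshold` (default Q20) and retained only if the truncated length is
#' at least `min_retained_frac` of the original.
#'
#' @param read A read record (`id`, `seq`, `qual`).
#' @param q_threshold Phred threshold (default 20).
#' @param min_retained_frac Minimum retained length fraction (default
#'   0.75).
#' @return The (possibly truncated) read, or `NULL` when too much is lost.
#' @export
quality_filter <- function(read, q_threshold = 20L, min_retained_frac = 0.75) {
  q <- unlist(read$qual)
  if (is.null(q)) stop("read has no qualities")
  n <- nchar(read$seq)
  first_bad <- which(q < q_threshold)[1]
  keep <- if (is.na(first_bad)) n else first_bad - 1L
  if (keep < min_retained_frac * n) return(NULL)
  list(id = read$id, seq = substr(read$seq, 1L, keep),
       qual = q[seq_len(keep)])
}

quality_filter_set <- function(reads, q_threshold = 20L,
                               min_retained_frac = 0.75) {
  out <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    out[[i]] <- quality_filter(list(id = reads$id[i], seq = reads$seq[i],
                                    qual = reads$qual[[i]]),
                               q_threshold, min_retained_frac)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  d <- data.frame(id = vapply(out, `[[`, character(1), "id"),
                  seq = vapply(out, `[[`, character(1), "seq"))
  d$qual <- lapply(out, `[[`, "qual")
  d
}

#' Greedy de novo OTU clustering at an identity threshold
#'
#' Reads are dereplicated and processed in decreasing abundance (ties:
#' longer first, then lexicographic id). Each sequence joins the first
#' existing centroid whose global-alignment identity -- matches divided by
#' total alignment columns, so gaps count against identity -- is at least
#' `identity_threshold` (default 0.97, i.e. the 0.03 dissimilarity level);
#' otherwise it founds a new centroid.
#'
#' @param reads Data frame of reads (`id`, `seq`).
#' @param identity_threshold Identity level (default 0.97).
#' @param scheme A [scoring_scheme()] for the global alignments.
#' @param sample_id Optional sample label carried into the table.
#' @return An object of class `"otu_table"`: a list with `otus` (data
#'   frame `otu_id`, `centroid`, `count`, plus `members` and `lineage`
#'   list columns), `sample_id` and `total` reads.
#' @export
cluster_otus <- function(reads, identity_threshold = 0.97,
                         scheme = scoring_scheme(), sample_id = NA_character_) {
  if (nrow(reads) == 0L) stop("no reads to cluster")
  # dereplicate
  grp <- split(reads$id, reads$seq)
  uniq <- data.frame(seq = names(grp), count = lengths(grp))
  uniq$members <- unname(grp)
  uniq$first_id <- vapply(uniq$members, function(m) sort(m)[1], character(1))
  uniq <- uniq[order(-uniq$count, -nchar(uniq$seq), uniq$first_id), ]

  centroids <- character(0)
  assign_to <- integer(nrow(uniq))
  for (i in seq_len(nrow(uniq))) {
    placed <- 0L
    for (k in seq_along(centroids)) {
      a <- align_global(uniq$seq[i], centroids[k], scheme)
      ident <- a$matches /
        (a$matches + a$mismatches + a$insertions + a$deletions)
      if (ident >= identity_threshold) { placed <- k; break }
    }
    if (placed == 0L) {
      centroids <- c(centroids, uniq$seq[i])
      placed <- length(centroids)
    }
    assign_to[i] <- placed
  }
  otus <- data.frame(otu_id = sprintf("OTU_%04d", seq_along(centroids)),
                     centroid = centroids)
  otus$members <- lapply(seq_along(centroids), function(k) {
    unlist(uniq$members[assign_to == k], use.names = FALSE)
  })
  otus$count <- lengths(otus$members)
  otus$lineage <- rep(list(new_lineage()), nrow(otus))
  structure(list(otus = otus, sample_id = sample_id,
                 total = sum(otus$count)),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> %d OTUs, %d reads%s\n", nrow(x$otus), x$total,
              if (is.na(x$sample_id)) "" else paste0(" [", x$sample_id, "]")))
  invisible(x)
}

#' Assign taxonomy to OTU centroids
#'
#' Each centroid is classified by best local alignment against the V3--V4
#' amplicon database (references truncated to the in-silico PCR window);
#' the OTU inherits the centroid's possibly LCA-truncated lineage. Species
#' sharing an identical V3--V4 amplicon therefore resolve only to genus
#' level -- the short-read arm's structural limitation. Unassignable
#' centroids keep a fully empty lineage.
#'
#' @param otu_table An `otu_table`.
#' @param db A `reference_db`.
#' @param scheme A [scoring_scheme()].
#' @param min_query_cover Passed to [classify_reads()].
#' @return The `otu_table` with its `lineage` column filled in.
#' @export
assign_otu_taxonomy <- function(otu_table, db, scheme = scoring_scheme(),
                                min_query_cover = 0.5) {
  amps <- amplicon_set(db, "v34")
  amp_db <- db
  amp_db$records <- amps[, c("id", "seq")]
  amp_db$records$lineage <- amps$lineage
  cents <- data.frame(id = otu_table$otus$otu_id,
                      seq = otu_table$otus$centroid)
  res <- classify_reads(cents, amp_db, scheme, min_query_cover)
  lin <- rep(list(new_lineage()), nrow(otu_table$otus))
  hit <- match(res$assignments$read_id, otu_table$otus$otu_id)
  lin[hit] <- res$assignments$lineage
  if (length(res$unassigned)) {
    message(length(res$unassigned), " centroid(s) unassignable; left empty")
  }
  otu_table$otus$lineage <- lin
  otu_table
}

#' Rarefy an OTU table to an even depth
#'
#' Subsamples exactly `depth` reads without replacement, re-tallies OTU
#' counts and drops emptied OTUs.
#'
#' @param table An `otu_table`.
#' @param depth Target depth; must not exceed the table total.
#' @param seed Integer seed.
#' @return A rarefied `otu_table` whose counts sum to `depth`.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  if (depth > table$total) {
    stop("depth (", depth, ") exceeds table total (", table$total, ")")
  }
  labels <- rep(seq_len(nrow(table$otus)), table$otus$count)
  withr::with_seed(seed, {
    pick <- sample(labels, depth, replace = FALSE)
  })
  counts <- tabulate(pick, nbins = nrow(table$otus))
  keep <- counts > 0L
  out <- table
  out$otus <- table$otus[keep, , drop = FALSE]
  out$otus$count <- counts[keep]
  out$otus$members <- rep(list(NULL), sum(keep)) # identities not tracked
  rownames(out$otus) <- NULL
  out$total <- depth
  out
}

#' Rarefaction curve of observed OTU richness
#'
#' For each depth, the mean (over `reps` replicates) number of distinct
#' OTUs in a without-replacement subsample. Each replicate draws one random
#' permutation of the reads and reads every depth as a prefix of it, so
#' subsamples are nested and every replicate's curve is monotone
#' non-decreasing by construction.
#'
#' @param table An `otu_table`.
#' @param depths Increasing depths, all at most the table total.
#' @param reps Replicates per depth (default 10).
#' @param seed Integer seed.
#' @return A data frame with columns `depth`, `mean_otus`, `sd_otus`.
#' @export
rarefaction_curve <- function(table, depths, reps = 10L, seed = 1L) {
  if (any(diff(depths) <= 0)) stop("depths must be strictly increasing")
  if (max(depths) > table$total) stop("max depth exceeds table total")
  labels <- rep(seq_len(nrow(table$otus)), table$otus$count)
  withr::with_seed(seed, {
    obs <- matrix(0L, nrow = reps, ncol = length(depths))
    for (r in seq_len(reps)) {
      perm <- sample(labels, length(labels), replace = FALSE)
      for (j in seq_along(depths)) {
        obs[r, j] <- length(unique(perm[seq_len(depths[j])]))
      }
    }
  })
  data.frame(depth = depths, mean_otus = colMeans(obs),
             sd_otus = apply(obs, 2, stats::sd))
}
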