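#' Per-aligned-column sequencing error profile
#'
#' The long-read error process is parameterised per aligned column:
#' scanning the (true) read-to-template alignment column by column, the
#' expected fraction of insertion columns (spurious bases consuming no
#' template) is `p_ins`, of deletion columns `p_del`, and of substitution
#' columns `p_sub`, so the expected alignment-estimated accuracy equals
#' `1 - (p_sub + p_ins + p_del)`. This is what makes simulated error rates
#' recoverable by realigning the reads to the template.
#'
#' @param p_sub,p_ins,p_del Column-type probabilities; each in `[0,1]` and
#'   summing to less than 1.
#' @return A list of class `"error_profile"`.
#' @examples
#' nanopore_error_profile() # the long-read platform profile used throughout
#' @export
error_profile <- function(p_sub, p_ins, p_del) {
  p <- c(p_sub, p_ins, p_del)
  if (any(p < 0) || any(p > 1) || sum(p) >= 1) {
    stop("error probabilities must lie in [0,1] with p_sub+p_ins+p_del < 1")
  }
  structure(list(p_sub = p_sub, p_ins = p_ins, p_del = p_del),
            class = "error_profile")
}

#' @rdname error_profile
#' @export
nanopore_error_profile <- function() error_profile(0.090, 0.064, 0.050)

#' Community composition
#'
#' A community maps reference ids to relative abundances. Weights are
#' normalized to sum to 1; every id must exist in the database.
#'
#' @param weights Named non-negative numeric vector (names are reference
#'   ids).
#' @param db Optional `reference_db` to validate ids against.
#' @return A named numeric vector of class `"community"` summing to 1.
#' @export
community <- function(weights, db = NULL) {
  if (length(weights) == 0L || sum(weights) <= 0) {
    stop("community must contain at least one positive weight")
  }
  if (any(weights < 0)) stop("community weights must be non-negative")
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    stop("community weights must be named by reference id")
  }
  if (!is.null(db)) {
    bad <- setdiff(names(weights), db$records$id)
    if (length(bad)) stop("unknown reference id(s): ",
                          paste(bad, collapse = ", "))
  }
  structure(weights / sum(weights), class = "community")
}

#' @rdname community
#' @export
uniform_community <- function(db) {
  community(setNames(rep(1, nrow(db$records)), db$records$id), db)
}

# Corrupt one template under the per-column error process (the caller
# manages the RNG state). The generated truth alignment is emitted in
# aligner-canonical form: insertion runs are placed only at junctions
# whose two flanking template columns are both retained, because an
# optimal affine-gap alignment never contains an insertion column adjacent
# to a deletion column (pairing the two always scores higher), so a
# realignment of the read sees the same column types the generator drew.
# The per-draw probabilities are calibrated so the expected *fractions of
# alignment columns* equal p_sub / p_ins / p_del exactly.
corrupt_sequence <- function(template, profile) {
  tc <- strsplit(template, "")[[1]]
  L <- length(tc)
  scale <- 1 / (1 - profile$p_ins) # columns per template position
  d <- profile$p_del * scale
  s <- profile$p_sub * scale
  u <- runif(L)
  type <- ifelse(u < d, "del", ifelse(u < d + s, "sub", "match"))
  mc <- tc
  mc[type == "del"] <- ""
  sub_i <- which(type == "sub")
  if (length(sub_i)) {
    off <- sample.int(3L, length(sub_i), replace = TRUE)
    mc[sub_i] <- BASES[(match(tc[sub_i], BASES) + off - 1L) %% 4L + 1L]
    # keep the truth alignment optimal: a substituted base equal to an
    # adjacent *deleted* template base would let a realignment pair it
    # there and report a match where a mismatch was generated
    is_del <- type == "del"
    clash <- sub_i[(sub_i > 1L & is_del[pmax(sub_i - 1L, 1L)] &
                      mc[sub_i] == tc[pmax(sub_i - 1L, 1L)]) |
                     (sub_i < L & is_del[pmin(sub_i + 1L, L)] &
                        mc[sub_i] == tc[pmin(sub_i + 1L, L)])]
    for (j in clash) {
      excl <- tc[j]
      if (j > 1L && is_del[j - 1L]) excl <- c(excl, tc[j - 1L])
      if (j < L && is_del[j + 1L]) excl <- c(excl, tc[j + 1L])
      allowed <- setdiff(BASES, excl)
      mc[j] <- allowed[sample.int(length(allowed), 1L)]
    }
  }
  if (profile$p_ins > 0 && L > 1L) {
    # a junction is insertion-eligible when no deletion sits within
    # INS_DEL_WINDOW template columns on either side; without the guard an
    # optimal realignment pairs nearby insertion/deletion columns into
    # match/mismatch columns and the recovered rates drift off the profile
    del_cs <- c(0L, cumsum(type == "del"))
    j <- seq_len(L - 1L)
    lo <- pmax(j - (INS_DEL_WINDOW - 1L), 1L)
    hi <- pmin(j + INS_DEL_WINDOW, L)
    elig <- (del_cs[hi + 1L] - del_cs[lo]) == 0L
    # calibrated so unconditional E[insertions per junction] = p_ins*scale
    mu <- profile$p_ins * scale / (1 - d)^(2 * INS_DEL_WINDOW)
    ins_counts <- rgeom(L - 1L, 1 / (1 + mu)) * elig
    n_ins <- sum(ins_counts)
    if (n_ins > 0L) {
      # inserted bases differ from both flanking template bases, again so
      # that no realignment can absorb an inserted base as a (chance)
      # match and shift the gap onto a true column
      junc <- rep.int(seq_len(L - 1L), ins_counts)
      ins_b <- character(n_ins)
      u2 <- runif(n_ins)
      for (k in seq_len(n_ins)) {
        j <- junc[k]
        allowed <- setdiff(BASES, c(tc[j], tc[j + 1L]))
        ins_b[k] <- allowed[floor(u2[k] * length(allowed)) + 1L]
      }
      ins_str <- vapply(
        split(ins_b, factor(junc, levels = seq_len(L - 1L))),
        paste0, character(1), collapse = "")
      return(paste0(paste0(mc, c(ins_str, "")), collapse = ""))
    }
  }
  paste0(mc, collapse = "")
}

INS_DEL_WINDOW <- 4L

# expected read length under corrupt_sequence for a length-L template
# (exact for interior junctions; end-window clipping is O(1) bases)
expected_read_length <- function(L, profile) {
  scale <- 1 / (1 - profile$p_ins)
  d <- profile$p_del * scale
  L * (1 - d) + (L - 1) * profile$p_ins * scale
}

#' Simulate noisy long reads from a community
#'
#' Each read's source amplicon is drawn from the community, amplified
#' in silico with the near-full-length primer pair, and corrupted under the
#' per-column [error_profile()]. With probability `p_concat` a read is the
#' concatenation of two independently drawn, independently corrupted
#' amplicons -- the concatemer artifact of hairpin-adapter ligation. Long
#' reads carry a constant placeholder quality (the platform's per-base
#' qualities are not modelled).
#'
#' @param db A `reference_db`.
#' @param community A [community()] over ids in `db`.
#' @param n_reads Number of reads.
#' @param profile An [error_profile()].
#' @param p_concat Concatemer probability (default 0.01).
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list with `reads` (data frame `id`, `seq`, `qual` list column)
#'   and `truth` (data frame `read_id`, `source_id`, `segment` -- one row
#'   per source, so concatemers have two).
#' @export
simulate_long_reads <- function(db, community, n_reads, profile,
                                p_concat = 0.01, seed = 1L) {
  stopifnot(inherits(db, "reference_db"), n_reads >= 1L)
  if (length(community) == 0L) stop("community is empty")
  amps <- amplicon_set(db, "full")
  avail <- intersect(names(community), amps$id)
  if (!length(avail)) stop("no community member yields a full-length amplicon")
  w <- community[avail]
  aseq <- setNames(amps$seq, amps$id)

  withr::with_seed(seed, {
    src1 <- sample(avail, n_reads, replace = TRUE, prob = w)
    is_cat <- runif(n_reads) < p_concat
    src2 <- ifelse(is_cat, sample(avail, n_reads, replace = TRUE, prob = w),
                   NA_character_)
    seqs <- character(n_reads)
    for (i in seq_len(n_reads)) {
      s <- corrupt_sequence(aseq[[src1[i]]], profile)
      if (is_cat[i]) s <- paste0(s, corrupt_sequence(aseq[[src2[i]]], profile))
      seqs[i] <- s
    }
    ids <- sprintf("longread_%05d", seq_len(n_reads))
    reads <- data.frame(id = ids, seq = seqs)
    reads$qual <- lapply(nchar(seqs), function(n) rep(10L, n))
    truth <- data.frame(read_id = c(ids, ids[is_cat]),
                        source_id = c(src1, src2[is_cat]),
                        segment = c(rep(1L, n_reads), rep(2L, sum(is_cat))))
    truth <- truth[order(truth$read_id, truth$segment), ]
    rownames(truth) <- NULL
    list(reads = reads, truth = truth)
  })
}

#' Simulate reads of the spike-in control
#'
#' Identical error process to [simulate_long_reads()] but from the single
#' control template and without concatemers; this is the input to
#' [assess_accuracy()].
#'
#' @param control A list with `id` and `seq` (see [control_sequence()]).
#' @inheritParams simulate_long_reads
#' @param n Number of control reads (>= 1).
#' @return A data frame of reads (`id`, `seq`, `qual`).
#' @export
simulate_control_reads <- function(control, n, profile, seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n),
                   function(i) corrupt_sequence(control$seq, profile),
                   character(1))
    reads <- data.frame(id = sprintf("control_%05d", seq_len(n)), seq = seqs)
    reads$qual <- lapply(nchar(seqs), function(len) rep(10L, len))
    reads
  })
}

#' Simulate paired short reads over the V3--V4 amplicon
#'
#' Sources are drawn from the community and amplified in silico with the
#' V3--V4 primer cores. R1 is the first `read_len` bases of the amplicon;
#' R2 the reverse complement of the last `read_len` bases (so a 469 bp
#' amplicon read at 2x250 leaves a 31-base overlap for joining). Per-base
#' qualities are `q_high` except for a geometric low-quality tail (quality
#' `q_low`, mean length 10) entering with probability `p_lowq_tail` per
#' read; substitution errors are then drawn per base at the Phred rate
#' `10^(-q/10)`.
#'
#' @inheritParams simulate_long_reads
#' @param n_pairs Number of read pairs.
#' @param read_len Read length (default 250).
#' @param quality_model List with `q_high`, `q_low`, `p_lowq_tail`.
#' @return A list with `r1`, `r2` (read data frames) and `truth`
#'   (`read_id`, `source_id`).
#' @export
simulate_short_read_pairs <- function(db, community, n_pairs,
                                      read_len = 250L,
                                      quality_model = list(
                                        q_high = 38L, q_low = 10L,
                                        p_lowq_tail = 0.2),
                                      seed = 1L) {
  stopifnot(inherits(db, "reference_db"))
  if (length(community) == 0L) stop("community is empty")
  amps <- amplicon_set(db, "v34")
  ok <- nchar(amps$seq) >= read_len
  if (any(!ok)) {
    warning("skipping ", sum(!ok), " source(s) with amplicon shorter than ",
            read_len, " bp")
  }
  avail <- intersect(names(community), amps$id[ok])
  if (!length(avail)) stop("no community member yields a usable V3-V4 amplicon")
  w <- community[avail]
  aseq <- setNames(amps$seq, amps$id)

  noisy_read <- function(template, qm) {
    n <- nchar(template)
    qual <- rep(qm$q_high, n)
    if (runif(1) < qm$p_lowq_tail) {
      tail_len <- min(n, rgeom(1, 0.1) + 1L)
      qual[(n - tail_len + 1L):n] <- qm$q_low
    }
    ch <- strsplit(template, "")[[1]]
    err <- which(runif(n) < 10^(-qual / 10))
    if (length(err)) {
      off <- sample.int(3L, length(err), replace = TRUE)
      ch[err] <- BASES[(match(ch[err], BASES) + off - 1L) %% 4L + 1L]
    }
    list(seq = paste0(ch, collapse = ""), qual = as.integer(qual))
  }

  withr::with_seed(seed, {
    if (n_pairs == 0L) {
      empty <- data.frame(id = character(), seq = character())
      empty$qual <- list()
      return(list(r1 = empty, r2 = empty,
                  truth = data.frame(read_id = character(),
                                     source_id = character())))
    }
    src <- sample(avail, n_pairs, replace = TRUE, prob = w)
    ids <- sprintf("pair_%05d", seq_len(n_pairs))
    r1s <- vector("list", n_pairs); r2s <- vector("list", n_pairs)
    for (i in seq_len(n_pairs)) {
      amp <- aseq[[src[i]]]
      t1 <- substr(amp, 1L, read_len)
      t2 <- revcomp(substr(amp, nchar(amp) - read_len + 1L, nchar(amp)))
      r1s[[i]] <- noisy_read(t1, quality_model)
      r2s[[i]] <- noisy_read(t2, quality_model)
    }
    mk <- function(lst, suffix) {
      d <- data.frame(id = paste0(ids, suffix),
                      seq = vapply(lst, `[[`, character(1), "seq"))
      d$qual <- lapply(lst, `[[`, "qual")
      d
    }
    list(r1 = mk(r1s, "/1"), r2 = mk(r2s, "/2"),
         truth = data.frame(read_id = ids, source_id = src))
  })
}
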