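#' Per-rank abundance profile
#'
#' Collapses classified reads (or an OTU table, weighted by OTU counts) to
#' taxon labels at one rank. Reads with an empty label at that rank are
#' excluded from the abundances but remain in the coverage denominator, so
#' `rank_coverage` is the fraction of input reads the rank can account for
#' (never increasing from order to species).
#'
#' @param x The `assignments` data frame from [classify_reads()], or an
#'   `otu_table` with lineages.
#' @param rank One of `"kingdom" ... "species"`.
#' @return An object of class `"abundance_profile"`: a list with `rank`,
#'   `table` (data frame `taxon`, `count`, `rel_abundance`), `total` input
#'   reads and `rank_coverage`.
#' @export
profile_abundance <- function(x, rank) {
  rank <- match.arg(rank, TAX_RANKS)
  if (inherits(x, "otu_table")) {
    lineages <- x$otus$lineage
    weights <- x$otus$count
  } else {
    if (nrow(x) == 0L) stop("no assignments to profile")
    lineages <- x$lineage
    weights <- rep(1L, nrow(x))
  }
  labels <- vapply(lineages, rank_label, character(1), rank = rank)
  total <- sum(weights)
  keep <- nzchar(labels)
  if (any(keep)) {
    tab <- tapply(weights[keep], labels[keep], sum)
    counts <- as.vector(tab)
    d <- data.frame(taxon = names(tab), count = counts,
                    rel_abundance = counts / sum(counts))
    d <- d[order(-d$count, d$taxon), ]
    rownames(d) <- NULL
  } else {
    d <- data.frame(taxon = character(), count = numeric(),
                    rel_abundance = numeric())
  }
  structure(list(rank = rank, table = d, total = total,
                 rank_coverage = sum(weights[keep]) / total),
            class = "abundance_profile")
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat(sprintf("<abundance_profile> rank %s | %d taxa | coverage %.1f%%\n",
              x$rank, nrow(x$table), 100 * x$rank_coverage))
  invisible(x)
}

#' Cross-platform taxon comparison
#'
#' Partitions the union of taxa of two same-rank profiles into detection
#' groups: group I = detected by both platforms, group II = platform B
#' (nanopore) only, group III = platform A (short-read) only. For group I
#' taxa the log2 fold-change `log2(B/A)` of relative abundances is
#' computed, and `|log2fc| > 1` flags a significant abundance deviation.
#' No pseudocounts: fold-changes exist only where both abundances are
#' positive.
#'
#' @param profile_A,profile_B Two [profile_abundance()] results at the same
#'   rank; by convention A is the short-read platform and B the long-read
#'   platform.
#' @return A data frame with columns `taxon`, `rank`, `abundance_A`,
#'   `abundance_B`, `group`, `log2fc`, `significant_deviation`.
#' @export
compare_platforms <- function(profile_A, profile_B) {
  if (profile_A$rank != profile_B$rank) {
    stop("profiles are at different ranks (", profile_A$rank, " vs ",
         profile_B$rank, ")")
  }
  a <- setNames(profile_A$table$rel_abundance, profile_A$table$taxon)
  b <- setNames(profile_B$table$rel_abundance, profile_B$table$taxon)
  taxa <- sort(union(names(a), names(b)))
  av <- ifelse(taxa %in% names(a), a[taxa], 0)
  bv <- ifelse(taxa %in% names(b), b[taxa], 0)
  group <- ifelse(av > 0 & bv > 0, "I", ifelse(bv > 0, "II", "III"))
  log2fc <- ifelse(group == "I", log2(bv / av), NA_real_)
  data.frame(taxon = taxa, rank = profile_A$rank, abundance_A = av,
             abundance_B = bv, group = group, log2fc = log2fc,
             significant_deviation = !is.na(log2fc) & abs(log2fc) > 1,
             row.names = NULL)
}

#' Spearman rank correlation (as rho squared)
#'
#' Spearman's rho with average ranks for ties, reported as rho^2 with a
#' two-sided p-value: exact by enumeration of all rank permutations for
#' n <= 9, otherwise the t approximation with n-2 degrees of freedom.
#'
#' @param x,y Paired abundance vectors, length >= 3.
#' @return A list with `rho`, `rho_squared`, `p_value`, `n`.
#' @examples
#' spearman_r2(c(1, 2, 3), c(2, 1, 3))$rho_squared # 0.25
#' @export
spearman_r2 <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("correlation undefined for a constant vector")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 9L) {
    perms <- permutations_of(n)
    rhos <- apply(perms, 1L, function(p) cor(rx, ry[p]))
    p_value <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p_value <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, rho_squared = rho^2, p_value = p_value, n = n)
}

# all permutations of seq_len(n) as rows (n <= 9 keeps this small)
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Shared and platform-specific taxa (Venn counts)
#'
#' @param taxa_A,taxa_B Character vectors (or `abundance_profile`s, from
#'   which taxa and read weights are taken).
#' @return A list with `shared`, `only_A`, `only_B` counts, the shared
#'   taxon labels, and -- when profiles were supplied -- the fraction of
#'   reads carried by shared taxa in each sample
#'   (`shared_read_frac_A/_B`).
#' @export
venn_counts <- function(taxa_A, taxa_B) {
  wa <- wb <- NULL
  if (inherits(taxa_A, "abundance_profile")) {
    wa <- setNames(taxa_A$table$count, taxa_A$table$taxon)
    taxa_A <- taxa_A$table$taxon
  }
  if (inherits(taxa_B, "abundance_profile")) {
    wb <- setNames(taxa_B$table$count, taxa_B$table$taxon)
    taxa_B <- taxa_B$table$taxon
  }
  taxa_A <- unique(taxa_A); taxa_B <- unique(taxa_B)
  shared <- intersect(taxa_A, taxa_B)
  out <- list(shared = length(shared),
              only_A = length(setdiff(taxa_A, taxa_B)),
              only_B = length(setdiff(taxa_B, taxa_A)),
              shared_taxa = sort(shared))
  if (!is.null(wa)) out$shared_read_frac_A <- sum(wa[shared]) / sum(wa)
  if (!is.null(wb)) out$shared_read_frac_B <- sum(wb[shared]) / sum(wb)
  out
}
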