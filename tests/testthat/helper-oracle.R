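# Independent brute-force affine-gap DP oracle (plain R, no shared code
# with the package's aligner). Scores only; quadratic time, used on short
# random sequences to cross-check both alignment modes.
oracle_align_score <- function(q, r, match = 1, mismatch = 1,
                               gap_open = 1, gap_extend = 1,
                               local = TRUE) {
  qc <- strsplit(q, "")[[1]]
  rc <- strsplit(r, "")[[1]]
  n <- length(qc); m <- length(rc)
  NEG <- -1e9
  H <- matrix(NEG, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1) # gap in reference (consumes query)
  F_ <- matrix(NEG, n + 1, m + 1) # gap in query (consumes reference)
  H[1, 1] <- 0
  for (j in 2:(m + 1)) {
    F_[1, j] <- -(gap_open + gap_extend * (j - 1))
    H[1, j] <- if (local) 0 else F_[1, j]
  }
  for (i in 2:(n + 1)) {
    E[i, 1] <- -(gap_open + gap_extend * (i - 1))
    H[i, 1] <- if (local) 0 else E[i, 1]
  }
  sub <- function(a, b) {
    if (a == b && a %in% c("A", "C", "G", "T")) match else -mismatch
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                     E[i - 1, j] - gap_extend)
      F_[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                      F_[i, j - 1] - gap_extend)
      h <- max(H[i - 1, j - 1] + sub(qc[i - 1], rc[j - 1]),
               E[i, j], F_[i, j])
      H[i, j] <- if (local) max(h, 0) else h
    }
  }
  if (local) max(H) else H[n + 1, m + 1]
}

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_lineage_string <- function() {
  pres <- c("k", "p", "c", "o", "f", "g", "s")
  depth <- sample(seq_along(pres), 1)
  labs <- replicate(depth, paste0(sample(LETTERS, 5, TRUE), collapse = ""))
  paste0(pres[seq_len(depth)], "__", labs, collapse = "; ")
}

# tiny 2-genus x 2-species db used across tests (divergence only in V1-V2
# for the region tests; generous V-region rates elsewhere via arguments)
tiny_db <- function(seed = 7L, per_region = NULL, n_genera = 2L,
                    species_per_genus = 2L) {
  generate_reference_db(n_genera, species_per_genus,
                        per_region_divergence = per_region, seed = seed)
}
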