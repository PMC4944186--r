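#' @name refdb
#' @title Synthetic 16S-like reference databases
#'
#' @description
#' The generator emulates the structure that makes full-length 16S
#' profiling informative: a ~1.5 kb gene in which nine hypervariable
#' regions (V1--V9) are interleaved with conserved regions, genera and
#' species that diverge only inside the hypervariable regions, and
#' conserved primer binding sites so in-silico PCR recovers amplicons from
#' every record. All divergence is applied per position, per region, so the
#' ground truth of "which columns can distinguish these taxa, and which
#' amplicon windows contain them" is known exactly.
NULL

BASES <- c("A", "C", "G", "T")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# one deterministic concrete realization of an IUPAC primer (first member
# of each ambiguity set), used when planting binding sites into references
concretize_iupac <- function(primer) {
  ch <- strsplit(toupper(primer), "")[[1]]
  bad <- setdiff(ch, names(IUPAC_SETS))
  if (length(bad)) stop("not an IUPAC DNA string: '", primer, "'")
  paste0(vapply(ch, function(c) IUPAC_SETS[[c]][1], character(1)),
         collapse = "")
}

#' Default hypervariable region map
#'
#' Conventional V1--V9 boundaries (E. coli numbering, 0-based half-open
#' intervals) on a 1,500 bp reference coordinate system. This is plumbing
#' configuration, not a result: all region analyses are relative to
#' whatever map is in use, and a custom map can be supplied anywhere a
#' `region_map` is accepted.
#'
#' @return A data frame with columns `region`, `start`, `end`.
#' @export
default_region_map <- function() {
  data.frame(
    region = paste0("V", 1:9),
    start = c(69L, 137L, 433L, 576L, 822L, 986L, 1117L, 1243L, 1435L),
    end   = c(99L, 242L, 497L, 682L, 879L, 1043L, 1173L, 1294L, 1465L))
}

check_region_map <- function(rm, length = NULL) {
  stopifnot(all(c("region", "start", "end") %in% names(rm)))
  rm <- rm[order(rm$start), ]
  if (any(rm$end <= rm$start)) stop("region map has an empty/negative interval")
  if (nrow(rm) > 1 && any(rm$start[-1] < rm$end[-nrow(rm)])) {
    stop("region map intervals overlap")
  }
  if (!is.null(length) && any(rm$end > length)) {
    stop("region map extends beyond the reference length (", length, ")")
  }
  rm
}

#' Default primer sets
#'
#' Two primer pairs drive the two sequencing arms. The short-read arm uses
#' the printed V3--V4 primer cores (341F `CCTACGGGNGGCWGCAG` / 805R
#' `GACTACHVGGGTATCTAATCC`, ~469 bp amplicon). The long-read arm targets
#' near-full-length 16S with the S-D-Bact-0008-c-S-20 / S-D-Bact-1391-a-A-17
#' pair, defaulting to the Klindworth et al. standard sequences
#' (`AGRGTTYGATYMTGGCTCAG` / `GACGGGCGGTGTGTRCA`); both pairs are
#' config values and can be overridden. `fwd_start` / `rev_end` give the
#' 0-based half-open span where the generator plants the binding sites on
#' the reference coordinate system.
#'
#' @return A list with elements `full` and `v34`, each a list with `fwd`,
#'   `rev` (primer orientation), `fwd_start`, `rev_end`.
#' @export
default_primers <- function() {
  list(
    full = list(fwd = "AGRGTTYGATYMTGGCTCAG", rev = "GACGGGCGGTGTGTRCA",
                fwd_start = 8L, rev_end = 1492L),
    v34 = list(fwd = "CCTACGGGNGGCWGCAG", rev = "GACTACHVGGGTATCTAATCC",
               fwd_start = 337L, rev_end = 806L))
}

# positions (1-based) occupied by planted primer sites, masked from mutation
primer_site_positions <- function(primers) {
  pos <- integer(0)
  for (p in primers) {
    fl <- nchar(p$fwd); rl <- nchar(p$rev)
    pos <- c(pos, seq(p$fwd_start + 1L, p$fwd_start + fl),
             seq(p$rev_end - rl + 1L, p$rev_end))
  }
  unique(pos)
}

mutate_positions <- function(chars, positions, rate) {
  if (!length(positions) || rate == 0) return(chars)
  hit <- positions[runif(length(positions)) < rate]
  if (length(hit)) {
    off <- sample.int(3L, length(hit), replace = TRUE)
    chars[hit] <- BASES[(match(chars[hit], BASES) + off - 1L) %% 4L + 1L]
  }
  chars
}

#' Generate a synthetic reference database
#'
#' A root 16S-like sequence is drawn uniformly over A/C/G/T and both primer
#' pairs' binding sites are written into it verbatim. Each genus ancestor
#' then mutates the root only inside hypervariable intervals at
#' `between_genus_divergence`; each species mutates its genus ancestor only
#' inside hypervariable intervals at the per-region rates. Conserved
#' (non-V) positions, including the primer sites, are identical across all
#' records. Every record carries a complete 7-rank synthetic lineage
#' (genus `G<g>`, species `G<g>_S<s>`).
#'
#' @param n_genera,species_per_genus At least 1 each.
#' @param length Reference length in bp; must contain the region map and
#'   primer sites.
#' @param per_region_divergence Named numeric, per-position substitution
#'   rate per region for species within a genus. Defaults to 0.02
#'   everywhere (16S species within a genus typically differ by a few
#'   percent, concentrated in the variable regions).
#' @param between_genus_divergence Per-position rate separating genus
#'   ancestors from the root (default 0.10).
#' @param seed Integer; the single source of randomness for the call.
#' @param region_map,primers Overrides for [default_region_map()] /
#'   [default_primers()].
#' @return An object of class `"reference_db"`: a list with `records` (data
#'   frame `id`, `seq`, plus a `lineage` list column), `region_map`,
#'   `primers` and `length`.
#' @export
generate_reference_db <- function(n_genera, species_per_genus,
                                  length = 1500L,
                                  per_region_divergence = NULL,
                                  between_genus_divergence = 0.10,
                                  seed = 1L,
                                  region_map = default_region_map(),
                                  primers = default_primers()) {
  stopifnot(n_genera >= 1L, species_per_genus >= 1L)
  region_map <- check_region_map(region_map, length)
  if (is.null(per_region_divergence)) {
    per_region_divergence <- setNames(rep(0.02, nrow(region_map)),
                                      region_map$region)
  }
  rates <- c(per_region_divergence, between_genus_divergence)
  if (any(rates < 0) || any(rates > 0.75)) {
    stop("divergence rates must lie in [0, 0.75] (substitution saturation)")
  }
  missing_r <- setdiff(region_map$region, names(per_region_divergence))
  if (length(missing_r)) {
    per_region_divergence[missing_r] <- 0
  }
  for (p in primers) {
    if (p$fwd_start < 0L || p$rev_end > length ||
        p$rev_end - p$fwd_start < nchar(p$fwd) + nchar(p$rev)) {
      stop("primer sites do not fit the reference length")
    }
  }

  withr::with_seed(seed, {
    root <- sample(BASES, length, replace = TRUE)
    for (p in primers) {
      fs <- strsplit(concretize_iupac(p$fwd), "")[[1]]
      root[(p$fwd_start + 1L):(p$fwd_start + length(fs))] <- fs
      rs <- strsplit(revcomp(concretize_iupac(p$rev)), "")[[1]]
      root[(p$rev_end - length(rs) + 1L):p$rev_end] <- rs
    }
    masked <- primer_site_positions(primers)
    # 1-based mutable positions per region (V intervals minus primer sites)
    region_pos <- lapply(seq_len(nrow(region_map)), function(i) {
      setdiff(seq(region_map$start[i] + 1L, region_map$end[i]), masked)
    })
    names(region_pos) <- region_map$region
    all_vpos <- unlist(region_pos, use.names = FALSE)

    ids <- character(0); seqs <- character(0); lins <- list()
    for (g in seq_len(n_genera)) {
      ganc <- mutate_positions(root, all_vpos, between_genus_divergence)
      for (s in seq_len(species_per_genus)) {
        sp <- ganc
        for (r in region_map$region) {
          sp <- mutate_positions(sp, region_pos[[r]],
                                 per_region_divergence[[r]])
        }
        sp_name <- sprintf("G%d_S%d", g, s)
        ids <- c(ids, paste0("ref_", sp_name))
        seqs <- c(seqs, paste0(sp, collapse = ""))
        lins <- c(lins, list(new_lineage(c(
          kingdom = "Bacteria", phylum = "Synthicutes", class = "Synthia",
          order = "Synthetales", family = "Syntheticaceae",
          genus = sprintf("G%d", g), species = sp_name))))
      }
    }
    records <- data.frame(id = ids, seq = seqs)
    records$lineage <- lins
    structure(list(records = records, region_map = region_map,
                   primers = primers, length = length,
                   root = paste0(root, collapse = "")),
              class = "reference_db")
  })
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("<reference_db> %d records, %d bp, %d regions\n",
              nrow(x$records), x$length, nrow(x$region_map)))
  invisible(x)
}

#' In-silico PCR with degenerate primers
#'
#' Locates the leftmost forward-primer binding site and the rightmost site
#' matching the reverse complement of the reverse primer downstream of it,
#' each allowing up to `max_mismatch` IUPAC-aware mismatches, and extracts
#' the inclusive span from forward-primer start to reverse-site end.
#' Degenerate matching is delegated to [Biostrings::matchPattern()].
#'
#' @param record A data-frame row or list with `id` and `seq`, or a bare
#'   DNA string.
#' @param fwd_primer,rev_primer IUPAC DNA strings; `rev_primer` is given in
#'   primer orientation.
#' @param max_mismatch Maximum mismatches per site (default 0).
#' @return A list with `id`, `seq` (the amplicon), and the 0-based
#'   half-open template coordinates `start`, `end`; or `NULL` when either
#'   site is absent or the sites overlap.
#' @export
in_silico_pcr <- function(record, fwd_primer, rev_primer, max_mismatch = 0L) {
  if (is.character(record) && length(record) == 1L) {
    record <- list(id = NA_character_, seq = record)
  }
  template <- Biostrings::DNAString(toupper(record$seq))
  fhits <- Biostrings::matchPattern(Biostrings::DNAString(toupper(fwd_primer)),
                                    template, max.mismatch = max_mismatch,
                                    fixed = FALSE)
  if (length(fhits) == 0L) return(NULL)
  fstart <- min(Biostrings::start(fhits))
  rsite <- Biostrings::reverseComplement(
    Biostrings::DNAString(toupper(rev_primer)))
  rhits <- Biostrings::matchPattern(rsite, template,
                                    max.mismatch = max_mismatch,
                                    fixed = FALSE)
  rhits <- rhits[Biostrings::start(rhits) >= fstart]
  if (length(rhits) == 0L) return(NULL)
  rend <- max(Biostrings::end(rhits))
  if (rend - fstart + 1L < nchar(fwd_primer) + nchar(rev_primer)) {
    return(NULL) # overlapping sites cannot bracket a real product
  }
  list(id = record$id,
       seq = as.character(Biostrings::subseq(template, fstart, rend)),
       start = fstart - 1L, end = rend)
}

# amplicons for every record in the db under one primer pair; drops
# records without a product
amplicon_set <- function(db, pair = c("full", "v34"), max_mismatch = 0L) {
  pair <- match.arg(pair)
  p <- db$primers[[pair]]
  amps <- lapply(seq_len(nrow(db$records)), function(i) {
    in_silico_pcr(db$records[i, ], p$fwd, p$rev, max_mismatch)
  })
  keep <- !vapply(amps, is.null, logical(1))
  out <- db$records[keep, , drop = FALSE]
  out$seq <- vapply(amps[keep], `[[`, character(1), "seq")
  out$amp_start <- vapply(amps[keep], `[[`, integer(1), "start")
  out$amp_end <- vapply(amps[keep], `[[`, integer(1), "end")
  out
}

#' Packaged spike-in control sequence
#'
#' A fixed 1,400 bp sequence standing in for the internal control DNA
#' (DNA CS, the lambda-phage-derived spike-in) used to estimate platform
#' error rates. It is synthetic -- built once from a hard-coded seed, so it
#' is identical in every installation -- and carries no primer sites or
#' region structure.
#'
#' @param length Control length in bp (default 1400).
#' @return A list with `id` and `seq`.
#' @export
control_sequence <- function(length = 1400L) {
  withr::with_seed(1416L, {
    list(id = "control_synthetic",
         seq = paste0(sample(BASES, length, replace = TRUE), collapse = ""))
  })
}
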