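#' Pipeline run configuration
#'
#' Collects every knob of an end-to-end run. All analysis thresholds
#' default to the study values: 97% OTU identity (0.03 dissimilarity),
#' Q20 quality truncation, 75% joined-length retention, an 80% span filter
#' for control-read accuracy, |log2 fold-change| > 1 for abundance
#' deviations, and discard of taxa supported by fewer than 2 reads. A
#' serialized config plus the package version fully determines all
#' outputs.
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param n_genera,species_per_genus,ref_length,per_region_divergence,between_genus_divergence
#'   Reference-generator parameters (see [generate_reference_db()]).
#' @param samples Named list of community weight vectors, or `NULL` to
#'   build two replicate samples with geometric (rank-abundance) weights
#'   over all species.
#' @param long_profile [error_profile()] for the long-read platform
#'   (default: the study rates 0.090/0.064/0.050).
#' @param n_long_reads,n_control_reads,p_concat Long-read arm sizes.
#' @param n_pairs,read_len,quality_model Short-read arm sizes.
#' @param identity_threshold,q_threshold,min_joined_frac,min_overlap,max_mismatch_frac,min_ref_span,min_reads_per_taxon,min_query_cover,log2fc_threshold
#'   Analysis thresholds.
#' @param rarefy_depth Even depth for rarefying, or `NULL` for the
#'   smallest sample total.
#' @param compare_ranks Ranks at which platform profiles are compared.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(seed = 1L,
                       n_genera = 4L, species_per_genus = 3L,
                       ref_length = 1500L,
                       per_region_divergence = NULL,
                       between_genus_divergence = 0.10,
                       samples = NULL,
                       long_profile = nanopore_error_profile(),
                       n_long_reads = 300L, n_control_reads = 100L,
                       p_concat = 0.01,
                       n_pairs = 300L, read_len = 250L,
                       quality_model = list(q_high = 38L, q_low = 10L,
                                            p_lowq_tail = 0.2),
                       identity_threshold = 0.97, q_threshold = 20L,
                       min_joined_frac = 0.75, min_overlap = 10L,
                       max_mismatch_frac = 0.1, min_ref_span = 0.8,
                       min_reads_per_taxon = 2L, min_query_cover = 0.5,
                       log2fc_threshold = 1,
                       rarefy_depth = NULL,
                       compare_ranks = c("genus", "species")) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with any subset of [run_config()] fields.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  if (!is.null(vals$long_profile)) {
    vals$long_profile <- do.call(error_profile, vals$long_profile)
  }
  do.call(run_config, vals)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  required <- c("seed", "n_genera", "species_per_genus", "n_long_reads",
                "n_pairs", "identity_threshold")
  for (f in required) {
    if (is.null(cfg[[f]])) stop("config is missing required field '", f, "'")
  }
  if (!inherits(cfg$long_profile, "error_profile")) {
    stop("config field 'long_profile' must be an error_profile")
  }
  invisible(cfg)
}

# deterministic per-stage seed stream (kept below 2^31)
stage_seed <- function(master, k) (as.integer(master) * 7919L + k * 104729L) %% 2000000011L

#' Run the full simulate / classify / cluster / compare / regions pipeline
#'
#' Stages run in dependency order and every intermediate artifact is
#' written to `out_dir` (FASTA/FASTQ for sequences, TSV for tables, JSON
#' for the run summary), so each stage can be re-run in isolation from its
#' files. Identical configs give byte-identical summaries.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, the summary list (also written to
#'   `out_dir/summary.json`).
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("run_"),
                         quiet = FALSE) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## reference database
  db <- stage("reference", generate_reference_db(
    config$n_genera, config$species_per_genus, config$ref_length,
    config$per_region_divergence, config$between_genus_divergence,
    seed = stage_seed(config$seed, 1L)))
  write_fasta(db$records, file.path(out_dir, "references.fasta"))
  write_taxonomy_map(db, file.path(out_dir, "taxonomy.tsv"))
  say("reference", "%d records (seed %d)", nrow(db$records), config$seed)

  ## communities
  samples <- config$samples
  if (is.null(samples)) {
    w <- 0.7^(seq_len(nrow(db$records)) - 1L)
    base <- community(setNames(w, db$records$id), db)
    samples <- list(A = base, B = base) # biological duplicates
  } else {
    samples <- lapply(samples, community, db = db)
  }

  ## long-read arm: control accuracy + per-sample classification
  ctrl <- control_sequence()
  ctrl_reads <- stage("control", simulate_control_reads(
    ctrl, config$n_control_reads, config$long_profile,
    seed = stage_seed(config$seed, 2L)))
  acc <- stage("accuracy", assess_accuracy(
    ctrl_reads, ctrl, min_ref_span = config$min_ref_span))
  say("accuracy", "%d/%d reads used, accuracy %.1f%%", acc$n_reads_used,
      nrow(ctrl_reads), 100 * acc$accuracy)

  long_profiles <- list(); long_assign <- list()
  for (si in seq_along(samples)) {
    nm <- names(samples)[si]
    sim <- stage("simulate_long", simulate_long_reads(
      db, samples[[si]], config$n_long_reads, config$long_profile,
      config$p_concat, seed = stage_seed(config$seed, 10L + si)))
    write_fastq(sim$reads, file.path(out_dir, paste0("long_", nm, ".fastq")))
    write_tsv(sim$truth, file.path(out_dir, paste0("long_", nm, "_truth.tsv")))
    cls <- stage("classify", classify_reads(
      sim$reads, db, min_query_cover = config$min_query_cover))
    kept <- filter_low_abundance(cls$assignments, config$min_reads_per_taxon)
    say("classify", "sample %s: %d assigned, %d unassigned, %d after filter",
        nm, nrow(cls$assignments), length(cls$unassigned), nrow(kept))
    tab <- data.frame(read_id = kept$read_id,
                      lineage = vapply(kept$lineage, format_lineage,
                                       character(1)),
                      score = kept$score, tie_count = kept$tie_count)
    write_tsv(tab, file.path(out_dir, paste0("assignments_", nm, ".tsv")))
    long_assign[[nm]] <- kept
    long_profiles[[nm]] <- lapply(
      setNames(config$compare_ranks, config$compare_ranks),
      function(r) profile_abundance(kept, r))
  }

  ## short-read arm
  short_profiles <- list(); otu_summaries <- list()
  for (si in seq_along(samples)) {
    nm <- names(samples)[si]
    pairs <- stage("simulate_short", simulate_short_read_pairs(
      db, samples[[si]], config$n_pairs, config$read_len,
      config$quality_model, seed = stage_seed(config$seed, 20L + si)))
    joined <- stage("join", join_pair_set(
      pairs$r1, pairs$r2, config$min_overlap, config$max_mismatch_frac,
      config$min_joined_frac))
    filtered <- stage("quality_filter", quality_filter_set(
      joined, config$q_threshold, 0.75))
    say("shortread", "sample %s: %d pairs -> %d joined -> %d after Q%d",
        nm, config$n_pairs, nrow(joined), nrow(filtered), config$q_threshold)
    otus <- stage("cluster", cluster_otus(
      filtered, config$identity_threshold, sample_id = nm))
    otus <- stage("otu_taxonomy", assign_otu_taxonomy(
      otus, db, min_query_cover = config$min_query_cover))
    otu_summaries[[nm]] <- list(n_otus = nrow(otus$otus), total = otus$total)
    tab <- data.frame(otu_id = otus$otus$otu_id, count = otus$otus$count,
                      lineage = vapply(otus$otus$lineage, format_lineage,
                                       character(1)),
                      centroid = otus$otus$centroid)
    write_tsv(tab, file.path(out_dir, paste0("otus_", nm, ".tsv")))
    short_profiles[[nm]] <- otus
  }

  ## even-depth rarefying
  depth <- config$rarefy_depth
  if (is.null(depth)) {
    depth <- min(vapply(short_profiles, `[[`, numeric(1), "total"))
  }
  short_rar <- lapply(seq_along(short_profiles), function(si) {
    rarefy(short_profiles[[si]], depth, seed = stage_seed(config$seed, 30L + si))
  })
  names(short_rar) <- names(short_profiles)
  short_prof <- lapply(short_rar, function(t) {
    lapply(setNames(config$compare_ranks, config$compare_ranks),
           function(r) profile_abundance(t, r))
  })

  ## cross-platform concordance, per sample and rank
  concordance <- list()
  for (nm in names(samples)) {
    per_rank <- list()
    for (r in config$compare_ranks) {
      cmpd <- compare_platforms(short_prof[[nm]][[r]],
                                long_profiles[[nm]][[r]])
      write_tsv(cmpd, file.path(out_dir,
                                paste0("compare_", nm, "_", r, ".tsv")))
      both <- cmpd[cmpd$group == "I", ]
      rho <- if (nrow(both) >= 3L &&
                 length(unique(both$abundance_A)) > 1L &&
                 length(unique(both$abundance_B)) > 1L) {
        spearman_r2(both$abundance_A, both$abundance_B)
      } else list(rho = NA_real_, rho_squared = NA_real_,
                  p_value = NA_real_, n = nrow(both))
      vn <- venn_counts(short_prof[[nm]][[r]], long_profiles[[nm]][[r]])
      per_rank[[r]] <- list(
        groups = as.list(table(factor(cmpd$group, c("I", "II", "III")))),
        n_significant = sum(cmpd$significant_deviation),
        rho_squared = rho$rho_squared, p_value = rho$p_value,
        venn = vn[c("shared", "only_A", "only_B")])
    }
    concordance[[nm]] <- per_rank
  }

  ## region discriminability on the first genus' first two species
  sp <- vapply(db$records$lineage, rank_label, character(1), "species")
  pair <- db$records$id[match(c("G1_S1", "G1_S2"), sp)]
  region_res <- NULL
  if (!anyNA(pair)) {
    d_v34 <- stage("regions", discriminability(db, pair, "v34"))
    d_full <- stage("regions", discriminability(db, pair, "full"))
    region_res <- list(
      pair = as.list(pair),
      v34 = list(discriminable = d_v34$discriminable,
                 in_window = d_v34$in_window, total = d_v34$total),
      full = list(discriminable = d_full$discriminable,
                  in_window = d_full$in_window, total = d_full$total),
      by_region = as.list(d_full$by_region))
    say("regions", "pair %s/%s: %d variants, %d inside V3-V4",
        pair[1], pair[2], d_full$total, d_v34$in_window)
  }

  summary <- list(
    seed = config$seed,
    n_references = nrow(db$records),
    accuracy = list(n_reads_used = acc$n_reads_used,
                    accuracy = acc$accuracy,
                    mismatch_rate = acc$mismatch_rate,
                    insertion_rate = acc$insertion_rate,
                    deletion_rate = acc$deletion_rate),
    otus = otu_summaries,
    rarefy_depth = depth,
    concordance = concordance,
    regions = region_res)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
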