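test_that("reference generator honors divergence structure and determinism", {
  # single record at zero divergence: identical to the root (primer sites
  # are part of the root)
  db1 <- generate_reference_db(1, 1, per_region_divergence = setNames(
    rep(0, 9), paste0("V", 1:9)), between_genus_divergence = 0, seed = 3)
  expect_equal(db1$records$seq[[1]], db1$root)

  # zero divergence: identical sequences, distinct lineages
  db0 <- generate_reference_db(2, 2, per_region_divergence = setNames(
    rep(0, 9), paste0("V", 1:9)), between_genus_divergence = 0, seed = 5)
  expect_equal(length(unique(db0$records$seq)), 1L)
  sp <- vapply(db0$records$lineage, function(l) l[["species"]], character(1))
  expect_equal(length(unique(sp)), 4L)

  # determinism
  again <- generate_reference_db(2, 2, seed = 7)
  expect_identical(tiny_db(seed = 7), again)

  expect_error(generate_reference_db(1, 1, between_genus_divergence = 0.9),
               "saturation")
})

test_that("divergence confined to V1-V2 only changes V1-V2 columns", {
  pr <- setNames(c(0.3, 0.3, rep(0, 7)), paste0("V", 1:9))
  db <- generate_reference_db(1, 2, per_region_divergence = pr, seed = 11)
  s1 <- strsplit(db$records$seq[1], "")[[1]]
  s2 <- strsplit(db$records$seq[2], "")[[1]]
  diff_pos <- which(s1 != s2) - 1L # 0-based
  expect_gt(length(diff_pos), 0L)
  rm <- db$region_map
  v12 <- c(seq(rm$start[rm$region == "V1"], rm$end[rm$region == "V1"] - 1L),
           seq(rm$start[rm$region == "V2"], rm$end[rm$region == "V2"] - 1L))
  expect_true(all(diff_pos %in% v12))
})

test_that("in-silico PCR finds degenerate sites and spans the amplicon", {
  # template assembled from the printed V3-V4 cores with IUPAC-compatible
  # concrete sites: N matches any base, W matches A/T, H/V their sets
  fwd <- "CCTACGGGNGGCWGCAG"
  rev <- "GACTACHVGGGTATCTAATCC"
  fwd_site <- "CCTACGGGAGGCTGCAG" # N->A, W->T
  insert <- strrep("ACGT", 30)
  tmpl <- paste0(fwd_site, insert,
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString("GACTACACGGGTATCTAATCC"))))
  amp <- in_silico_pcr(tmpl, fwd, rev, max_mismatch = 0)
  expect_equal(amp$seq, tmpl) # whole template, inclusive of both sites
  expect_equal(amp$start, 0L)

  # absent reverse site
  expect_null(in_silico_pcr(paste0(fwd_site, insert), fwd, rev))

  # the default db yields the 469 bp V3-V4 product and a near-full product
  db <- tiny_db()
  p <- db$primers
  a34 <- in_silico_pcr(db$records[1, ], p$v34$fwd, p$v34$rev)
  expect_equal(nchar(a34$seq), 469L)
  afl <- in_silico_pcr(db$records[1, ], p$full$fwd, p$full$rev)
  expect_equal(c(afl$start, afl$end), c(8L, 1492L))
})

test_that("noiseless long reads copy amplicons and record their sources", {
  db <- tiny_db()
  sim <- simulate_long_reads(db, uniform_community(db), 25,
                             error_profile(0, 0, 0), p_concat = 0, seed = 9)
  amps <- setNames(nanotax:::amplicon_set(db, "full")$seq, db$records$id)
  expect_equal(nrow(sim$truth), 25L)
  expect_true(all(sim$reads$seq == amps[sim$truth$source_id]))
})

test_that("forced concatemers carry two forward-primer sites", {
  db <- tiny_db()
  sim <- simulate_long_reads(db, uniform_community(db), 10,
                             error_profile(0, 0, 0), p_concat = 1, seed = 13)
  expect_true(all(table(sim$truth$read_id) == 2L))
  fwd <- Biostrings::DNAString(db$primers$full$fwd)
  nsites <- vapply(sim$reads$seq, function(s) {
    length(Biostrings::matchPattern(fwd, Biostrings::DNAString(s),
                                    fixed = FALSE))
  }, integer(1))
  expect_true(all(nsites == 2L))
})

test_that("mean long-read length matches the error-process expectation", {
  prof <- nanopore_error_profile()
  ctrl <- control_sequence()
  reads <- simulate_control_reads(ctrl, 400, prof, seed = 17)
  lens <- nchar(reads$seq)
  expected <- nanotax:::expected_read_length(nchar(ctrl$seq), prof)
  se <- stats::sd(lens) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - expected), 3 * se)
  # and the first-order form L(1 - p_del + p_ins) is close by construction
  expect_lt(abs(expected - nchar(ctrl$seq) * (1 - prof$p_del + prof$p_ins)),
            0.005 * nchar(ctrl$seq))
})

test_that("truth-label composition converges to the community weights", {
  db <- generate_reference_db(2, 2, seed = 19)
  w <- community(setNames(c(0.4, 0.3, 0.2, 0.1), db$records$id), db)
  sim <- simulate_long_reads(db, w, 5000, error_profile(0, 0, 0),
                             p_concat = 0, seed = 21)
  obs <- table(factor(sim$truth$source_id, levels = names(w)))
  p <- stats::chisq.test(obs, p = as.numeric(w))$p.value
  expect_gt(p, 0.01)
})

test_that("simulation is deterministic given the seed", {
  db <- tiny_db()
  prof <- nanopore_error_profile()
  ctrl <- control_sequence()
  expect_identical(simulate_control_reads(ctrl, 3, prof, seed = 23),
                   simulate_control_reads(ctrl, 3, prof, seed = 23))
  a <- simulate_long_reads(db, uniform_community(db), 5, prof, 0.2, seed = 25)
  b <- simulate_long_reads(db, uniform_community(db), 5, prof, 0.2, seed = 25)
  expect_identical(a, b)
  p <- simulate_short_read_pairs(db, uniform_community(db), 5, seed = 27)
  q <- simulate_short_read_pairs(db, uniform_community(db), 5, seed = 27)
  expect_identical(p, q)
})

test_that("short-read pairs tile the V3-V4 amplicon with a 31-base overlap", {
  db <- tiny_db()
  sim <- simulate_short_read_pairs(db, uniform_community(db), 8,
                                   quality_model = list(q_high = 40L,
                                                        q_low = 10L,
                                                        p_lowq_tail = 0),
                                   seed = 29)
  amps <- setNames(nanotax:::amplicon_set(db, "v34")$seq, db$records$id)
  expect_true(all(nchar(sim$r1$seq) == 250L))
  for (i in seq_len(8)) {
    amp <- amps[[sim$truth$source_id[i]]]
    expect_equal(nchar(amp), 469L)
    # overlap between R1 and revcomp(R2) templates = 2*250 - 469 = 31
    expect_equal(2L * 250L - nchar(amp), 31L)
    # q_high = 40 means ~1e-4 per-base errors; allow a handful
    r2rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(sim$r2$seq[i])))
    mism <- sum(strsplit(sim$r1$seq[i], "")[[1]] !=
                  strsplit(substr(amp, 1, 250), "")[[1]]) +
      sum(strsplit(r2rc, "")[[1]] !=
            strsplit(substr(amp, 220, 469), "")[[1]])
    expect_lte(mism, 3L)
  }
  empty <- simulate_short_read_pairs(db, uniform_community(db), 0, seed = 1)
  expect_equal(nrow(empty$r1), 0L)
})

test_that("error profile validates its probabilities", {
  expect_error(error_profile(0.5, 0.4, 0.2), "< 1")
  expect_error(error_profile(-0.1, 0, 0), "\\[0,1\\]")
  p <- nanopore_error_profile()
  expect_equal(1 - (p$p_sub + p$p_ins + p$p_del), 0.796)
})
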