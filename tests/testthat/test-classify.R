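test_that("noiseless reads classify to their exact source species", {
  db <- tiny_db(seed = 31)
  expect_equal(length(unique(db$records$seq)), nrow(db$records))
  sim <- simulate_long_reads(db, uniform_community(db), 40,
                             error_profile(0, 0, 0), p_concat = 0, seed = 33)
  res <- classify_reads(sim$reads, db)
  expect_equal(length(res$unassigned), 0L)
  truth <- setNames(sim$truth$source_id, sim$truth$read_id)
  expect_equal(res$assignments$ref_id,
               unname(truth[res$assignments$read_id]))
  expect_true(all(res$assignments$tie_count == 1L))
  expect_true(all(vapply(res$assignments$lineage, lineage_depth,
                         character(1)) == "species"))
})

test_that("equal-scoring ties truncate the lineage to the LCA", {
  # two same-genus species, each one isolated substitution away from their
  # common ancestor at a different position; the ancestor itself is then a
  # read exactly one mismatch from both references, a perfect score tie
  db <- generate_reference_db(1, 2, per_region_divergence = setNames(
    rep(0, 9), paste0("V", 1:9)), between_genus_divergence = 0, seed = 35)
  root <- strsplit(db$root, "")[[1]]
  flip <- function(chars, pos) {
    chars[pos] <- setdiff(c("A", "C", "G", "T"), chars[pos])[1]
    chars
  }
  db$records$seq[1] <- paste0(flip(root, 500L), collapse = "")
  db$records$seq[2] <- paste0(flip(root, 900L), collapse = "")
  reads <- data.frame(id = "tie_read", seq = db$root)
  res <- classify_reads(reads, db)
  expect_equal(res$assignments$tie_count[1], 2L)
  expect_equal(lineage_depth(res$assignments$lineage[[1]]), "genus")
  expect_equal(res$assignments$lineage[[1]][["genus"]], "G1")
})

test_that("junk reads fall below the query-cover threshold", {
  db <- tiny_db(seed = 45)
  set.seed(46)
  reads <- data.frame(id = "junk", seq = random_dna(1400))
  res <- classify_reads(reads, db, min_query_cover = 0.8)
  expect_equal(res$unassigned, "junk")
  expect_equal(nrow(res$assignments), 0L)
})

test_that("empty reads are skipped with a warning", {
  db <- tiny_db(seed = 45)
  reads <- data.frame(id = c("ok", "empty"),
                      seq = c(db$records$seq[1], ""))
  expect_warning(res <- classify_reads(reads, db), "empty read")
  expect_equal(res$assignments$read_id, "ok")
})

test_that("low-abundance taxa are discarded wholesale", {
  mk <- function(n, species) {
    lin <- parse_lineage(paste0("k__B; p__P; c__C; o__O; f__F; g__G; s__",
                                species))
    d <- data.frame(read_id = paste0(species, "_", seq_len(n)))
    d$lineage <- rep(list(lin), n)
    d
  }
  a <- rbind(mk(5, "A"), mk(1, "B"))
  kept <- filter_low_abundance(a, 2L)
  expect_equal(nrow(kept), 5L)
  expect_false(any(grepl("^B", kept$read_id)))

  b <- rbind(mk(2, "A"), mk(3, "B"))
  expect_equal(nrow(filter_low_abundance(b, 2L)), 5L)
  expect_identical(filter_low_abundance(a, 1L), a)

  # never removes a taxon at/above the threshold, never adds taxa
  set.seed(47)
  for (i in 1:10) {
    counts <- sample(1:4, 3, replace = TRUE)
    d <- do.call(rbind, Map(mk, counts, c("X", "Y", "Z")))
    kept <- filter_low_abundance(d, 2L)
    keys <- vapply(kept$lineage, format_lineage, character(1))
    expect_true(all(table(keys) >= 2L))
    expect_lte(length(unique(keys)), 3L)
  }
})

test_that("accuracy statistics share one denominator and sum to one", {
  s <- accuracy_stats(796, 90, 64, 50, n_reads_used = 1)
  expect_equal(s$accuracy, 0.796)
  expect_equal(s$mismatch_rate, 0.090)
  expect_equal(s$insertion_rate, 0.064)
  expect_equal(s$deletion_rate, 0.050)
  set.seed(48)
  for (i in 1:10) {
    v <- sample(0:500, 4, replace = TRUE)
    if (v[1] == 0) v[1] <- 1
    s <- accuracy_stats(v[1], v[2], v[3], v[4], 1)
    expect_equal(s$accuracy + s$mismatch_rate + s$insertion_rate +
                   s$deletion_rate, 1)
    expect_equal(s$error_rate, 1 - s$accuracy)
  }
  expect_error(accuracy_stats(0, 0, 0, 0, 0), "no aligned columns")
})

test_that("error-free control reads give perfect accuracy", {
  ctrl <- control_sequence(300L)
  reads <- simulate_control_reads(ctrl, 5, error_profile(0, 0, 0), seed = 49)
  s <- assess_accuracy(reads, ctrl)
  expect_equal(s$accuracy, 1)
  expect_equal(s$error_rate, 0)
  expect_equal(s$n_reads_used, 5L)
})

test_that("the span filter excludes short fragments of the control", {
  ctrl <- control_sequence(400L)
  frag <- substr(ctrl$seq, 1, 120) # 30% of the reference
  reads <- data.frame(id = c("full", "frag"), seq = c(ctrl$seq, frag))
  s <- assess_accuracy(reads, ctrl, min_ref_span = 0.8)
  expect_equal(s$n_reads_used, 1L)
  expect_error(assess_accuracy(reads[2, , drop = FALSE], ctrl),
               "span filter")
  # the same fragment passes when filtering on the read instead
  s2 <- assess_accuracy(reads, ctrl, coverage_on = "query")
  expect_equal(s2$n_reads_used, 2L)
})

test_that("recovered error rates track the generative profile", {
  ctrl <- control_sequence()
  prof <- error_profile(0.04, 0.02, 0.03)
  reads <- simulate_control_reads(ctrl, 60, prof, seed = 50)
  s <- assess_accuracy(reads, ctrl)
  expect_lt(abs(s$mismatch_rate - prof$p_sub), 0.01)
  expect_lt(abs(s$insertion_rate - prof$p_ins), 0.01)
  expect_lt(abs(s$deletion_rate - prof$p_del), 0.01)
})

test_that("classification accuracy does not improve as noise increases", {
  db <- tiny_db(seed = 51)
  comm <- uniform_community(db)
  acc <- vapply(c(0, 0.10, 0.25), function(ps) {
    prof <- error_profile(ps, 0.01, 0.01)
    sim <- simulate_long_reads(db, comm, 30, prof, p_concat = 0, seed = 52)
    res <- classify_reads(sim$reads, db)
    truth <- setNames(sim$truth$source_id, sim$truth$read_id)
    if (nrow(res$assignments) == 0L) return(0)
    mean(res$assignments$ref_id == truth[res$assignments$read_id]) *
      nrow(res$assignments) / 30
  }, numeric(1))
  expect_true(all(diff(acc) <= 0.1)) # non-increasing within sampling noise
  expect_equal(acc[1], 1)
})
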