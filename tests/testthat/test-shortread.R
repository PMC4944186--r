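mkread <- function(id, seq, qual = rep(40L, nchar(seq))) {
  list(id = id, seq = seq, qual = qual)
}

test_that("pair joining finds the overlap and applies the length rule", {
  set.seed(61)
  amp <- random_dna(469)
  r1 <- mkread("p/1", substr(amp, 1, 250))
  r2 <- mkread("p/2", nanotax:::revcomp(substr(amp, 220, 469)))
  j <- join_pairs(r1, r2)
  expect_equal(j$seq, amp) # 31-base exact overlap, joined length 469
  expect_equal(nchar(j$seq), 469L)
  expect_gte(nchar(j$seq), 0.75 * 500)

  # non-overlapping random reads
  r3 <- mkread("q/1", random_dna(100))
  r4 <- mkread("q/2", random_dna(100))
  expect_null(join_pairs(r3, r4, min_overlap = 10))

  # an overlap so large the joined read shrinks below 75% is rejected
  short_amp <- random_dna(260)
  s1 <- mkread("s/1", substr(short_amp, 1, 250))
  s2 <- mkread("s/2", nanotax:::revcomp(substr(short_amp, 11, 260)))
  expect_null(join_pairs(s1, s2))
})

test_that("join mismatch tolerance acts on the overlap fraction", {
  set.seed(62)
  left <- random_dna(70)
  ov <- random_dna(30)
  right <- random_dna(70)
  r1 <- mkread("m/1", paste0(left, ov))
  ov_mut <- strsplit(ov, "")[[1]]
  for (k in c(5L, 20L)) {
    ov_mut[k] <- setdiff(c("A", "C", "G", "T"), ov_mut[k])[1]
  }
  r2seq <- paste0(paste0(ov_mut, collapse = ""), right)
  r2 <- mkread("m/2", nanotax:::revcomp(r2seq))
  # 2 mismatches in 30 bases: 6.7% fails a 5% cap, passes a 10% cap
  expect_null(join_pairs(r1, r2, max_mismatch_frac = 0.05))
  j <- join_pairs(r1, r2, max_mismatch_frac = 0.10)
  expect_equal(nchar(j$seq), 70L + 30L + 70L)
})

test_that("disagreeing overlap positions take the higher-quality base", {
  seqA <- "ACGTACGTACGTACGTACGT"
  seqB <- sub("^ACG", "ACC", seqA) # differs at position 3
  r1 <- mkread("c/1", seqA, rep(20L, 20))
  r2 <- mkread("c/2", nanotax:::revcomp(seqB), rep(35L, 20))
  j <- join_pairs(r1, r2, min_overlap = 20, max_mismatch_frac = 0.1,
                  min_joined_frac = 0)
  expect_equal(substr(j$seq, 3, 3), "C") # r2's base, higher quality
  expect_equal(j$qual[3], 35L)
})

test_that("quality truncation keeps or drops reads by retained fraction", {
  r <- mkread("a", strrep("ACGT", 25))
  expect_equal(quality_filter(r)$seq, r$seq)

  qual <- rep(40L, 100); qual[81:100] <- 10L
  r <- mkread("b", strrep("ACGT", 25), qual)
  f <- quality_filter(r)
  expect_equal(nchar(f$seq), 80L)

  qual <- rep(40L, 100); qual[51:100] <- 10L
  r <- mkread("c", strrep("ACGT", 25), qual)
  expect_null(quality_filter(r))
})

test_that("identical reads collapse to one OTU and identity splits at 97%", {
  reads <- data.frame(id = paste0("r", 1:10),
                      seq = rep(strrep("ACGT", 25), 10))
  tab <- cluster_otus(reads)
  expect_equal(nrow(tab$otus), 1L)
  expect_equal(tab$otus$count, 10L)

  set.seed(63)
  base <- random_dna(100)
  mutate_at <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    for (p in seq(10, by = 17, length.out = k)) {
      ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    }
    paste0(ch, collapse = "")
  }
  # 2 mismatches in 100: identity 0.98 -> same OTU
  two <- data.frame(id = c("a1", "a2", "a3"),
                    seq = c(base, base, mutate_at(base, 2)))
  expect_equal(nrow(cluster_otus(two)$otus), 1L)
  # 4 mismatches: identity 0.96 -> two OTUs
  four <- data.frame(id = c("b1", "b2", "b3"),
                     seq = c(base, base, mutate_at(base, 4)))
  expect_equal(nrow(cluster_otus(four)$otus), 2L)
})

test_that("OTUs partition reads from two well-separated species by source", {
  pr <- setNames(rep(0.12, 9), paste0("V", 1:9))
  db <- generate_reference_db(2, 1, per_region_divergence = pr, seed = 64)
  sim <- simulate_short_read_pairs(db, uniform_community(db), 40,
                                   quality_model = list(q_high = 40L,
                                                        q_low = 10L,
                                                        p_lowq_tail = 0),
                                   seed = 65)
  joined <- nanotax:::join_pair_set(sim$r1, sim$r2)
  tab <- cluster_otus(joined)
  expect_equal(nrow(tab$otus), 2L)
  src <- setNames(sim$truth$source_id, sim$truth$read_id)
  for (k in 1:2) {
    expect_equal(length(unique(src[tab$otus$members[[k]]])), 1L)
  }
})

test_that("OTU taxonomy is inherited from best-hit centroids", {
  db <- tiny_db(seed = 66)
  amps <- nanotax:::amplicon_set(db, "v34")
  reads <- data.frame(id = paste0("r", 1:6),
                      seq = rep(amps$seq[c(1, 3)], 3))
  tab <- assign_otu_taxonomy(cluster_otus(reads), db)
  sp <- vapply(tab$otus$lineage, function(l) l[["species"]], character(1))
  expect_setequal(sp, vapply(amps$lineage[c(1, 3)], function(l)
    l[["species"]], character(1)))
})

test_that("species with identical V3-V4 amplicons resolve only to genus", {
  # no V3/V4 divergence within the genus, plenty elsewhere
  pr <- setNames(c(0.1, 0.1, 0, 0, 0.1, 0.1, 0.1, 0.1, 0.1),
                 paste0("V", 1:9))
  db <- generate_reference_db(1, 2, per_region_divergence = pr, seed = 67)
  amps <- nanotax:::amplicon_set(db, "v34")
  expect_equal(amps$seq[1], amps$seq[2])
  reads <- data.frame(id = paste0("r", 1:4), seq = rep(amps$seq[1], 4))
  tab <- assign_otu_taxonomy(cluster_otus(reads), db)
  expect_equal(lineage_depth(tab$otus$lineage[[1]]), "genus")
})

test_that("junk centroids keep an empty lineage", {
  db <- tiny_db(seed = 68)
  set.seed(69)
  reads <- data.frame(id = paste0("r", 1:2), seq = rep(random_dna(200), 2))
  expect_message(tab <- assign_otu_taxonomy(cluster_otus(reads), db),
                 "unassignable")
  expect_true(is.na(lineage_depth(tab$otus$lineage[[1]])))
})

test_that("rarefying subsamples to the exact depth, reproducibly", {
  set.seed(70)
  reads <- data.frame(id = paste0("r", 1:60),
                      seq = sample(c(strrep("A", 50), strrep("C", 50),
                                     strrep("G", 50)), 60, replace = TRUE))
  tab <- cluster_otus(reads)
  expect_identical(rarefy(tab, tab$total, seed = 1)$otus$count,
                   tab$otus$count)
  r1 <- rarefy(tab, 1L, seed = 2)
  expect_equal(nrow(r1$otus), 1L)
  expect_equal(r1$otus$count, 1L)
  expect_identical(rarefy(tab, 20L, seed = 3)$otus$count,
                   rarefy(tab, 20L, seed = 3)$otus$count)
  for (d in c(5L, 17L, 43L)) {
    expect_equal(sum(rarefy(tab, d, seed = 4)$otus$count), d)
  }
  expect_error(rarefy(tab, tab$total + 1L), "exceeds")
})

test_that("rarefaction curves are monotone for every replicate", {
  set.seed(71)
  reads <- data.frame(id = paste0("r", 1:80),
                      seq = sample(vapply(1:10, function(i) random_dna(60),
                                          character(1)),
                                   80, replace = TRUE))
  tab <- cluster_otus(reads)
  cur <- rarefaction_curve(tab, c(1L, 5L, 20L, 40L, 80L), reps = 8L,
                           seed = 72)
  expect_equal(cur$mean_otus[1], 1)
  expect_equal(cur$mean_otus[nrow(cur)], nrow(tab$otus))
  expect_equal(cur$sd_otus[nrow(cur)], 0)
  expect_true(all(diff(cur$mean_otus) >= 0))
  # nested-prefix construction makes every replicate monotone, which the
  # zero-variance top end plus mean monotonicity witnesses across seeds
  for (s in 73:75) {
    cur <- rarefaction_curve(tab, c(2L, 10L, 30L, 60L), reps = 3L, seed = s)
    expect_true(all(diff(cur$mean_otus) >= 0))
  }
})
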