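test_that("pairwise identity tracks a full-DP global alignment on
           substitution-only pairs", {
  set.seed(31)
  for (i in 1:20) {
    a <- random_dna(60)
    b <- inject_mismatches(a, sample(0:10, 1))
    expect_equal(pair_identity(a, b, both_strands = FALSE),
                 nw_identity(a, b), tolerance = 1e-9)
  }
})

test_that("greedy clustering separates unrelated and joins identical or
           reverse-complemented sequences", {
  set.seed(32)
  s <- random_dna(500)
  seqs <- data.frame(id = c("a", "b", "c"),
                     sequence = c(s, s, random_dna(480)),
                     stringsAsFactors = FALSE)
  cl <- cluster_by_identity(seqs, 0.95)
  expect_equal(length(unique(cl$cluster)), 2L)
  expect_equal(cl$representative_id[cl$id == "b"],
               cl$representative_id[cl$id == "a"])

  seqs_rc <- data.frame(id = c("a", "rc"), sequence = c(s, revcomp(s)),
                        stringsAsFactors = FALSE)
  expect_equal(length(unique(cluster_by_identity(seqs_rc, 0.95)$cluster)), 1L)
})

test_that("8 percent divergence splits at 0.95 and joins at 0.90", {
  set.seed(33)
  src <- random_dna(500)
  copy <- inject_mismatches(substr(src, 1, 490), 39)   # 8% of 490
  seqs <- data.frame(id = c("src", "copy"), sequence = c(src, copy),
                     stringsAsFactors = FALSE)
  expect_equal(length(unique(cluster_by_identity(seqs, 0.95)$cluster)), 2L)
  expect_equal(length(unique(cluster_by_identity(seqs, 0.90)$cluster)), 1L)
})

test_that("clustering partitions the input and is threshold-monotone", {
  sim <- simulate_transcriptome(n = 45, n_parents = 15,
                                members_per_parent = 3,
                                family_mode = "copy", divergence = 0.03,
                                length_mean = 400, length_sd = 60,
                                length_min = 200, seed = 34)
  cl95 <- cluster_by_identity(sim$transcripts, 0.95)
  expect_setequal(cl95$id, sim$transcripts$id)
  expect_equal(anyDuplicated(cl95$id), 0L)
  cl90 <- cluster_by_identity(sim$transcripts, 0.90)
  expect_gte(length(unique(cl95$cluster)), length(unique(cl90$cluster)))

  fam <- sim$truth$families
  truthv <- fam$parent[match(cl95$id, fam$member_id)]
  expect_equal(mclust::adjustedRandIndex(cl95$cluster, truthv), 1)
})

test_that("the cascade composes memberships over all input ids", {
  sim <- simulate_transcriptome(n = 30, n_parents = 10,
                                members_per_parent = 3,
                                family_mode = "copy", divergence = 0.03,
                                length_mean = 300, length_sd = 40,
                                length_min = 150, seed = 35)
  cc <- cluster_cascade(sim$transcripts, thresholds = c(0.95, 0.90))
  expect_setequal(cc$id, sim$transcripts$id)
  expect_true(all(cc$representative_id %in% sim$transcripts$id))
  expect_lte(length(unique(cc$representative_id)), 10L)
})

test_that("terminal overlaps merge by the stated length and identity
           thresholds", {
  set.seed(36)
  a <- random_dna(300)
  b <- paste0(substr(a, 251, 300), random_dna(210))   # exact 50 bp overlap
  m <- merge_terminal_overlaps(data.frame(id = c("A", "B"),
                                          sequence = c(a, b)))
  expect_equal(nrow(m$seqs), 1L)
  expect_equal(nchar(m$seqs$sequence), 510L)
  expect_equal(nrow(m$log), 1L)
  expect_setequal(c(m$log$id_a, m$log$id_b), c("A", "B"))

  b30 <- paste0(substr(a, 271, 300), random_dna(210))  # 30 bp only
  m30 <- merge_terminal_overlaps(data.frame(id = c("A", "B"),
                                            sequence = c(a, b30)))
  expect_equal(nrow(m30$seqs), 2L)

  ov <- inject_mismatches(substr(a, 261, 300), 5)      # 35/40 = 87.5%
  b5 <- paste0(ov, random_dna(210))
  m5 <- merge_terminal_overlaps(data.frame(id = c("A", "B"),
                                           sequence = c(a, b5)))
  expect_equal(nrow(m5$seqs), 2L)

  ov4 <- inject_mismatches(substr(a, 261, 300), 4)     # 36/40 = 90%
  b4 <- paste0(ov4, random_dna(210))
  m4 <- merge_terminal_overlaps(data.frame(id = c("A", "B"),
                                           sequence = c(a, b4)))
  expect_equal(nrow(m4$seqs), 1L)
})

test_that("merging reaches a fixed point and merges across strands", {
  set.seed(37)
  core <- random_dna(400)
  parts <- data.frame(
    id = c("p1", "p2", "p3"),
    sequence = c(substr(core, 1, 180),
                 revcomp(substr(core, 140, 300)),
                 substr(core, 260, 400)),
    stringsAsFactors = FALSE)
  m <- merge_terminal_overlaps(parts)
  expect_equal(nrow(m$seqs), 1L)
  expect_true(m$seqs$sequence %in% c(core, revcomp(core)))
  # fixed point: nothing left to merge
  again <- merge_terminal_overlaps(m$seqs)
  expect_equal(nrow(again$log), 0L)
  # log conserves all source ids
  expect_setequal(unique(c(m$log$id_a, m$log$id_b)), parts$id)
})

test_that("best-hit selection keeps max bitscore with e-value and subject
           tie-breaks under the cutoff", {
  h <- data.frame(query_id = c("q1", "q1", "q2", "q3", "q3"),
                  subject_id = c("s1", "s2", "s9", "sA", "sB"),
                  pct_identity = 90, aln_len = 100L, mismatches = 0L,
                  gap_opens = 0L, qstart = 1L, qend = 100L, sstart = 1L,
                  send = 100L,
                  evalue = c(1e-50, 1e-30, 1e-3, 1e-20, 1e-10),
                  bitscore = c(200, 150, 40, 99, 99),
                  stringsAsFactors = FALSE)
  best <- select_best_hit(h, evalue_cutoff = 1e-5)
  expect_equal(best$subject_id[best$query_id == "q1"], "s1")
  expect_false("q2" %in% best$query_id)       # sole hit above cutoff
  expect_equal(best$subject_id[best$query_id == "q3"], "sA")  # 1e-20 wins
})

test_that("grouping partitions queries by subject with longest-member
           representatives", {
  seqs <- data.frame(id = c("q1", "q2", "q3", "q4"),
                     sequence = c(strrep("A", 100), strrep("C", 300),
                                  strrep("G", 150), strrep("T", 120)),
                     stringsAsFactors = FALSE)
  bh <- data.frame(query_id = c("q1", "q2", "q3"),
                   subject_id = c("S", "S", "T"),
                   pct_identity = 90, aln_len = 10L, mismatches = 0L,
                   gap_opens = 0L, qstart = 1L, qend = 30L,
                   sstart = c(1L, 50L, 1L), send = c(30L, 90L, 30L),
                   evalue = 1e-40, bitscore = 100, stringsAsFactors = FALSE)
  g <- group_by_subject(bh, seqs)
  expect_equal(nrow(g$table), 2L)
  expect_equal(g$table$representative_id[g$table$subject_id == "S"], "q2")
  expect_equal(g$ungrouped, "q4")
  expect_equal(sum(g$table$n_members) + length(g$ungrouped), 4L)
})

test_that("planted families are regrouped exactly from simulated hits", {
  sim <- simulate_transcriptome(n = 180, n_parents = 50,
                                members_per_parent = 3,
                                family_mode = "fragment", seed = 38)
  hits <- simulate_hits(sim$transcripts, sim$truth,
                        unknown_fraction = 0.30, decoy_rate = 0.25,
                        seed = 39)
  best <- select_best_hit(hits, 1e-5)
  g <- group_by_subject(best, sim$transcripts)
  famg <- g$table[grepl("^SUBJ_fam", g$table$subject_id), ]
  expect_equal(nrow(famg), 50L)
  expect_true(all(famg$n_members == 3L))
  expect_equal(sum(g$table$n_members) + length(g$ungrouped),
               nrow(sim$transcripts))
  # representatives really are the longest members
  lens <- setNames(nchar(sim$transcripts$sequence), sim$transcripts$id)
  for (r in seq_len(nrow(famg))) {
    mem <- strsplit(famg$members[r], ";")[[1]]
    expect_equal(unname(lens[famg$representative_id[r]]), max(lens[mem]))
  }
})
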