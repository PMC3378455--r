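test_that("six-frame ORFs match direct translation on small cases", {
  orfs <- six_frame_orfs("ATGAAATAG", min_aa = 1)
  f1 <- orfs[orfs$frame == 1, ]
  expect_equal(f1$peptide, "MK")
  expect_equal(c(f1$start, f1$end), c(1L, 6L))

  # a frame without stops translates end to end
  no_stop <- strrep("GCT", 30)   # poly-alanine
  o <- six_frame_orfs(no_stop, min_aa = 1)
  expect_equal(o$aa_len[o$frame == 1], 30L)
  expect_equal(o$peptide[o$frame == 1], strrep("A", 30))
})

test_that("six-frame ORFs equal a naive stop-delimited scan on random
           sequences", {
  set.seed(41)
  for (rep in 1:10) {
    s <- random_dna(600)
    orfs <- six_frame_orfs(s, min_aa = 1)
    for (strand in c(1L, -1L)) {
      for (off in 1:3) {
        want <- naive_longest_orf(s, off, strand)
        got <- orfs[orfs$frame == strand * off, ]
        if (is.null(want)) {
          expect_equal(nrow(got), 0L)
        } else {
          expect_equal(got$aa_len, want$aa_len)
          expect_equal(got$peptide, want$peptide)
          expect_equal(got$end - got$start + 1L, 3L * got$aa_len)
        }
      }
    }
  }
})

test_that("ORF spans map back to the forward strand correctly", {
  set.seed(42)
  s <- random_dna(300)
  orfs <- six_frame_orfs(s, min_aa = 5)
  for (r in seq_len(nrow(orfs))) {
    span <- substr(s, orfs$start[r], orfs$end[r])
    nt <- if (orfs$frame[r] > 0) span else revcomp(span)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
    expect_equal(aa, orfs$peptide[r])
  }
})

test_that("annotation transfer copies the best subject's terms and flags
           unknown subjects", {
  bh <- data.frame(query_id = c("g1", "g2", "g3"),
                   subject_id = c("s1", "s9", "s1"),
                   stringsAsFactors = FALSE)
  smap <- data.frame(subject_id = "s1", go = "GO:0008150;GO:0003674",
                     ec = "EC:1.1.1.1", kegg = "",
                     stringsAsFactors = FALSE)
  ann <- transfer_annotations(bh, smap)
  expect_equal(ann$go[ann$gene_id == "g1"], "GO:0008150;GO:0003674")
  expect_true(ann$unannotated[ann$gene_id == "g2"])
  expect_equal(ann$go[ann$gene_id == "g2"], "")
  expect_equal(ann$go[ann$gene_id == "g1"], ann$go[ann$gene_id == "g3"])
})

test_that("subject maps round-trip through the tab-separated layout", {
  f <- tempfile()
  writeLines(c("s1\tGO:0000001;GO:0000002\tEC:1.1.1.1\tko:K00001",
               "s2\t\t\t", "s3\tGO:0000003"), f)
  m <- read_subject_map(f)
  expect_equal(nrow(m), 3L)
  expect_equal(m$go[1], "GO:0000001;GO:0000002")
  expect_equal(m$go[2], "")
  expect_equal(m$kegg[3], "")
})

test_that("GO-slim classification dedupes within and multi-counts across
           categories", {
  slim <- data.frame(go = c("GO:1", "GO:2", "GO:3"),
                     slim = c("S1", "S1", "S2"), stringsAsFactors = FALSE)
  rec <- data.frame(gene_id = c("g1", "g2", "g3"),
                    go = c("GO:1;GO:2",        # both map to S1: counted once
                           "GO:1;GO:3",        # S1 and S2: counted in both
                           "GO:9"),            # unmapped bucket
                    stringsAsFactors = FALSE)
  out <- classify_go_slim(rec, slim)
  expect_equal(out$count[out$slim == "S1"], 2L)
  expect_equal(out$count[out$slim == "S2"], 1L)
  expect_equal(out$count[out$slim == "unmapped"], 1L)
})

test_that("simulated annotation tables reproduce their planted slim
           composition", {
  subj <- sprintf("S%03d", 1:120)
  ann <- simulate_annotations(subj, n_go = 24, n_slims = 6, seed = 43)
  rec <- data.frame(gene_id = ann$subject_map$subject_id,
                    go = ann$subject_map$go, stringsAsFactors = FALSE)
  got <- classify_go_slim(rec, ann$slim_map)
  # recount from the long table: genes per slim, deduped
  long <- ann$term_long
  long$slim <- ann$slim_map$slim[match(long$term, ann$slim_map$go)]
  want <- aggregate(subject_id ~ slim, data = unique(long[, c("subject_id",
                                                              "slim")]),
                    FUN = length)
  expect_equal(setNames(got$count, got$slim)[want$slim],
               setNames(want$subject_id, want$slim))
})

test_that("hypergeometric tail matches the combinatorial sum on the stated
           example and at scale", {
  tm <- data.frame(gene_id = paste0("g", c(1:4, 18)), term = "T1",
                   stringsAsFactors = FALSE)
  e <- enrich_terms(paste0("g", 1:5), paste0("g", 1:20), tm)
  expect_equal(e$k, 4L)
  expect_equal(e$K, 5L)
  expect_equal(e$p_raw, 76 / 15504, tolerance = 1e-12)

  # all genes annotated, study = population
  tm2 <- data.frame(gene_id = paste0("g", 1:8), term = "T1")
  e2 <- enrich_terms(paste0("g", 1:8), paste0("g", 1:8), tm2)
  expect_equal(e2$p_raw, 1)

  # Bonferroni arithmetic across m tested terms
  set.seed(44)
  tm3 <- do.call(rbind, lapply(1:10, function(t)
    data.frame(gene_id = sample(paste0("g", 1:50), 20), term = paste0("T", t))))
  e3 <- enrich_terms(paste0("g", 1:12), paste0("g", 1:50), tm3)
  expect_equal(nrow(e3), 10L)
  expect_equal(e3$p_adj, pmin(1, 10 * e3$p_raw))
  expect_true(all(e3$p_adj >= e3$p_raw))
})

test_that("tail probabilities are enumeration-exact and monotone in k", {
  for (N in c(5, 12, 25)) {
    for (K in c(1, N %/% 2, N - 1)) {
      for (n in c(1, N %/% 2, N)) {
        ks <- 1:min(n, K)
        p_impl <- phyper(ks - 1, K, N - K, n, lower.tail = FALSE)
        p_enum <- vapply(ks, hyper_tail_enum, numeric(1), K = K, n = n, N = N)
        expect_equal(p_impl, p_enum, tolerance = 1e-12)
        expect_true(all(diff(p_impl) <= 1e-15))
      }
    }
  }
})

test_that("significance sets shrink as alpha decreases and bad input
           errors", {
  set.seed(45)
  pop <- paste0("g", 1:100)
  tm <- do.call(rbind, lapply(1:8, function(t)
    data.frame(gene_id = sample(pop, 30), term = paste0("T", t))))
  st <- sample(pop, 20)
  e1 <- enrich_terms(st, pop, tm, alpha = 0.05)
  e2 <- enrich_terms(st, pop, tm, alpha = 0.01)
  expect_true(all(e2$term[e2$significant] %in% e1$term[e1$significant]))
  expect_error(enrich_terms(c(st, "not_there"), pop, tm), "absent")
})
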