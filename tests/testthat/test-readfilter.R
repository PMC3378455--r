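mk_pairs <- function(n, len = 36, q = 35, seed = 1) {
  set.seed(seed)
  read_pairs(sprintf("p%d", 1:n),
             vapply(rep(len, n), random_dna, character(1)),
             vapply(rep(len, n), random_dna, character(1)),
             lapply(1:n, function(i) rep(q, len)),
             lapply(1:n, function(i) rep(q, len)))
}

test_that("positional quality profile is the per-position mean over mates", {
  p <- read_pairs("x", "AC", "GT", list(c(30L, 20L)), list(c(10L, 40L)))
  prof <- profile_quality(p)
  expect_equal(prof$position_means, c(20, 30))
  expect_equal(prof$n_reads, 2L)

  p2 <- mk_pairs(50, q = 33)
  expect_equal(profile_quality(p2)$position_means, rep(33, 36))
  expect_error(profile_quality(read_pairs(character(), character(),
                                          character(), list(), list())),
               "empty")
})

test_that("simulated quality decay is recovered by the profile", {
  sim <- simulate_transcriptome(n = 20, length_mean = 500, length_sd = 50,
                                length_min = 300, seed = 4)
  rd <- simulate_reads(sim$transcripts, n_pairs = 5000, q_start = 38,
                       q_end = 20, seed = 5)
  prof <- profile_quality(rd$pairs)
  mu <- prof$position_means
  expect_lt(coef(lm(mu ~ seq_along(mu)))[2], 0)   # decaying
  expect_lt(abs(mu[1] - 38), 0.5)
  expect_lt(abs(mu[length(mu)] - 20), 0.5)
})

test_that("cutoff recommendation follows the two-consecutive rule and
           brute-force mean cutoff", {
  prof <- structure(list(position_means = c(35, 35, 12, 11), n_reads = 10L,
                         read_length = 4L), class = "quality_profile")
  expect_equal(recommend_cutoff(prof, 20)$trim_to, 2L)

  prof2 <- structure(list(position_means = c(35, 35, 12, 30), n_reads = 10L,
                          read_length = 4L), class = "quality_profile")
  expect_equal(recommend_cutoff(prof2, 20)$trim_to, 4L)  # single dip ignored

  prof3 <- structure(list(position_means = rep(30, 36), n_reads = 10L,
                          read_length = 36L), class = "quality_profile")
  expect_equal(recommend_cutoff(prof3, 20)$trim_to, 36L)

  rmq <- c(rep(30, 75), rep(15, 25))
  got <- recommend_cutoff(prof3, 20, keep_fraction = 0.75,
                          read_mean_quals = rmq)$mean_cutoff
  brute <- max(Filter(function(q) mean(rmq >= q) >= 0.75, 0:45))
  expect_equal(got, brute)
  expect_equal(got, 30L)
})

test_that("adapter detection matches a brute-force overlap scan", {
  ad <- "AGATCGGAAGAGC"
  set.seed(6)
  r <- random_dna(36)
  r_hit <- paste0(substr(r, 1, 26), substr(ad, 1, 10))
  expect_equal(detect_adapter(r_hit, c(ada = ad))$start, 26L)

  r12 <- paste0(substr(r, 1, 24), inject_mismatches(substr(ad, 1, 12), 1))
  expect_equal(detect_adapter(r12, ad, max_mismatch_rate = 0.10)$start, 24L)

  brute <- function(read, adapter, min_o, rate) {
    L <- nchar(read)
    for (o in min(L, nchar(adapter)):min_o) {
      mm <- sum(strsplit(substr(read, L - o + 1, L), "")[[1]] !=
                strsplit(substr(adapter, 1, o), "")[[1]])
      if (mm <= rate * o + 1e-9) return(L - o)
    }
    NA_integer_
  }
  for (i in 1:200) {
    read <- random_dna(36)
    if (i %% 3 == 0) {
      o <- sample(5:13, 1)
      read <- paste0(substr(read, 1, 36 - o),
                     inject_mismatches(substr(ad, 1, o),
                                       sample(0:1, 1)))
    }
    got <- detect_adapter(read, ad)$start
    want <- brute(read, ad, 5L, 0.10)
    expect_identical(got, want)
  }
})

test_that("no-adapter reads return no match", {
  set.seed(7)
  hits <- detect_adapter(vapply(rep(36, 50), random_dna, character(1)),
                         "GGGGGGGGGGGGGGGGGGGG")
  expect_true(all(is.na(hits$start) | hits$start >= 0))
})

test_that("3' tail trim leaves 33 bp of a 36 bp pair; pair rule and
           attribution hold", {
  p <- mk_pairs(20)
  res <- filter_pairs(p, filter_config(tail_trim = 3,
                                       mean_quality_cutoff = 0,
                                       min_read_len = 0))
  expect_equal(unique(nchar(res$pairs$seq1)), 33L)
  expect_equal(unique(nchar(res$pairs$seq2)), 33L)
  expect_equal(res$report$pairs_out, 20L)

  # mate 2 below the quality cutoff sinks the whole pair
  p2 <- read_pairs("p", random_dna(36), random_dna(36),
                   list(rep(35L, 36)), list(rep(10L, 36)))
  res2 <- filter_pairs(p2, filter_config(tail_trim = 0))
  expect_equal(res2$report$pairs_out, 0L)
  expect_equal(res2$report$dropped_by_quality, 1L)
})

test_that("reads made of singleton k-mers fail the frequency filter", {
  set.seed(9)
  common <- random_dna(36)
  pairs <- read_pairs(c("dup1", "dup2", "lone"),
                      c(common, common, random_dna(36)),
                      rep(common, 3),
                      lapply(1:3, function(i) rep(35L, 36)),
                      lapply(1:3, function(i) rep(35L, 36)))
  res <- filter_pairs(pairs, filter_config(tail_trim = 0, kmer_filter = TRUE,
                                           kmer_k = 23, kmer_min_freq = 2))
  expect_equal(res$report$dropped_by_kmer_freq, 1L)
  expect_false("lone" %in% res$pairs$id)
})

test_that("filter report conserves pairs and is monotone in the cutoff", {
  sim <- simulate_transcriptome(n = 30, length_mean = 400, length_sd = 50,
                                length_min = 200, seed = 10)
  rd <- simulate_reads(sim$transcripts, n_pairs = 2000, q_start = 36,
                       q_end = 12, seed = 11)
  kept_prev <- Inf
  for (cut in c(10, 20, 25, 30)) {
    res <- filter_pairs(rd$pairs, filter_config(mean_quality_cutoff = cut))
    r <- res$report
    expect_equal(r$pairs_out + r$dropped_by_length + r$dropped_by_adapter +
                   r$dropped_by_quality + r$dropped_by_kmer_freq, r$pairs_in)
    expect_lte(r$pairs_out, kept_prev)
    kept_prev <- r$pairs_out
  }
})

test_that("trimmed lengths do not depend on stream order", {
  sim <- simulate_transcriptome(n = 10, length_mean = 300, length_sd = 30,
                                length_min = 200, seed = 12)
  rd <- simulate_reads(sim$transcripts, n_pairs = 500, adapter = "AGATCGGAAGAGC",
                       adapter_rate = 0.2, seed = 13)
  cfg <- filter_config(adapters = c(a1 = "AGATCGGAAGAGC"), min_read_len = 10)
  res1 <- filter_pairs(rd$pairs, cfg)
  perm <- sample(length(rd$pairs))
  shuffled <- read_pairs(rd$pairs$id[perm], rd$pairs$seq1[perm],
                         rd$pairs$seq2[perm], rd$pairs$qual1[perm],
                         rd$pairs$qual2[perm])
  res2 <- filter_pairs(shuffled, cfg)
  l1 <- setNames(nchar(res1$pairs$seq1), res1$pairs$id)
  l2 <- setNames(nchar(res2$pairs$seq1), res2$pairs$id)
  expect_equal(l1[sort(names(l1))], l2[sort(names(l2))])
})

test_that("planted adapter read-through is detected at its planted rate", {
  ad <- "AGATCGGAAGAGCACACGTC"
  sim <- simulate_transcriptome(n = 20, length_mean = 400, length_sd = 40,
                                length_min = 250, seed = 14)
  rate <- 0.15
  rd <- simulate_reads(sim$transcripts, n_pairs = 4000, adapter = ad,
                       adapter_rate = rate, error_rate = 0, seed = 15)
  det <- detect_adapter(rd$pairs$seq1, ad, min_overlap = 5)
  frac <- mean(!is.na(det$start) & det$start < 36)
  ci <- qbinom(c(0.005, 0.995), 4000, rate) / 4000
  expect_gte(frac, ci[1])
  # chance overlaps can only add detections; planted flags must all be found
  planted <- rd$truth$adapter_readthrough
  expect_true(all(!is.na(det$start[planted])))
})
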