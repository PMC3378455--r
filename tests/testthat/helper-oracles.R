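# Independent oracles and small generators used across the suite. Each
# oracle deliberately uses a different algorithm (or a different library)
# than the implementation it checks.

random_dna <- function(len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

inject_mismatches <- function(seq, n) {
  if (n == 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in sample.int(length(ch), n)) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

# nested-loop k-mer recount
naive_kmer_count <- function(seqs, k, canonical = FALSE) {
  out <- new.env(hash = TRUE)
  for (s in seqs) {
    if (nchar(s) < k) next
    for (i in 1:(nchar(s) - k + 1)) {
      km <- substr(s, i, i + k - 1)
      if (grepl("[^ACGT]", km)) next
      if (canonical) {
        rc <- denovokit::revcomp(km)
        if (rc < km) km <- rc
      }
      out[[km]] <- (if (is.null(out[[km]])) 0L else out[[km]]) + 1L
    }
  }
  keys <- sort(ls(out))
  list(kmer = keys,
       count = vapply(keys, function(k2) out[[k2]], integer(1),
                      USE.NAMES = FALSE))
}

# Needleman-Wunsch global alignment identity (matches / shorter length),
# match 1 / mismatch -1 / gap -2, full DP -- small inputs only
nw_identity <- function(a, b) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0L, n + 1, m + 1)
  M <- matrix(0L, n + 1, m + 1)   # matches along the best path
  S[, 1] <- -2L * (0:n); S[1, ] <- -2L * (0:m)
  for (i in 1:n) for (j in 1:m) {
    d <- S[i, j] + ifelse(A[i] == B[j], 1L, -1L)
    u <- S[i, j + 1] - 2L
    l <- S[i + 1, j] - 2L
    best <- max(d, u, l)
    S[i + 1, j + 1] <- best
    M[i + 1, j + 1] <- if (best == d) M[i, j] + (A[i] == B[j])
                       else if (best == u) M[i, j + 1] else M[i + 1, j]
  }
  M[n + 1, m + 1] / min(n, m)
}

# rle-based maximal-tandem-repeat scan: for period p, positions where
# s[i] == s[i+p] are computed in one vector; runs of TRUE give repeat
# stretches. Independent of the position-scan in the implementation.
naive_ssr_scan <- function(seq, min_repeats = c("1" = 10, "2" = 6, "3" = 5,
                                                "4" = 5, "5" = 5)) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(ch)
  res <- list()
  for (p in as.integer(names(min_repeats))) {
    thr <- min_repeats[[as.character(p)]]
    if (L < p * 2) next
    eq <- ch[1:(L - p)] == ch[(p + 1):L] & ch[1:(L - p)] %in%
      c("A", "C", "G", "T") & ch[(p + 1):L] %in% c("A", "C", "G", "T")
    r <- rle(eq)
    pos <- cumsum(c(1, r$lengths))
    for (j in seq_along(r$values)) {
      if (!r$values[j]) next
      i <- pos[j]                       # first index with s[i] == s[i+p]
      stretch <- r$lengths[j] + p       # matched region length
      reps <- stretch %/% p
      if (reps < thr) next
      motif <- paste(ch[i:(i + p - 1)], collapse = "")
      periodic <- FALSE
      for (d in seq_len(p - 1)) {
        if (p %% d == 0 &&
            motif == strrep(substr(motif, 1, d), p / d)) periodic <- TRUE
      }
      if (periodic) next
      res[[length(res) + 1L]] <- data.frame(
        motif = motif, period = p, n_repeats = reps,
        start = i, end = i + p * reps - 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(motif = character(), period = integer(),
                      n_repeats = integer(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out[order(out$period, out$start), , drop = FALSE]
}

# exact upper-tail hypergeometric by explicit combinatorial sum
hyper_tail_enum <- function(k, K, n, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# naive six-frame longest-ORF scan using a literal codon loop
naive_longest_orf <- function(seq, frame_off, strand) {
  s <- if (strand > 0) seq else denovokit::revcomp(seq)
  codons <- substring(s, seq(frame_off, nchar(s) - 2, by = 3),
                      seq(frame_off + 2, nchar(s), by = 3))
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  best_len <- 0L; best_start <- NA_integer_; cur <- 0L
  for (i in seq_along(aa)) {
    if (aa[i] == "*") cur <- 0L
    else {
      cur <- cur + 1L
      if (cur > best_len) { best_len <- cur; best_start <- i - cur + 1L }
    }
  }
  if (best_len == 0L) return(NULL)
  list(aa_len = best_len,
       peptide = paste(aa[best_start:(best_start + best_len - 1)],
                       collapse = ""))
}

sort_placements <- function(df) {
  df[order(df$read, df$transcript_id, df$pos, df$strand, df$mismatches), ,
     drop = FALSE]
}
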