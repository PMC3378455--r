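# Paired-end read filtering: fixed 3' trimming, positional quality
# profiling with cutoff recommendation, adapter read-through detection,
# per-read mean-quality and k-mer-frequency filters, with strict pair
# synchronization (a pair survives only when both mates do).

#' Filter configuration
#'
#' @param tail_trim bases removed unconditionally from every mate's 3' end.
#' @param mean_quality_cutoff minimum mean phred per (trimmed) mate.
#' @param adapters named character vector of adapter sequences (may be empty).
#' @param adapter_min_overlap minimum adapter-prefix/read-suffix overlap.
#' @param adapter_max_mismatch_rate maximum mismatch fraction in the overlap.
#' @param kmer_filter enable the k-mer frequency filter.
#' @param kmer_k k-mer size for the frequency filter.
#' @param kmer_min_freq minimum median dataset frequency of a mate's k-mers.
#' @param min_read_len minimum post-trim mate length.
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(tail_trim = 3L, mean_quality_cutoff = 20,
                          adapters = character(), adapter_min_overlap = 5L,
                          adapter_max_mismatch_rate = 0.10,
                          kmer_filter = FALSE, kmer_k = 23L,
                          kmer_min_freq = 2L, min_read_len = 20L) {
  stopifnot(tail_trim >= 0, mean_quality_cutoff >= 0,
            adapter_max_mismatch_rate >= 0, adapter_max_mismatch_rate <= 1,
            adapter_min_overlap >= 1, kmer_k >= 1, kmer_min_freq >= 0,
            min_read_len >= 0)
  structure(list(tail_trim = as.integer(tail_trim),
                 mean_quality_cutoff = mean_quality_cutoff,
                 adapters = adapters,
                 adapter_min_overlap = as.integer(adapter_min_overlap),
                 adapter_max_mismatch_rate = adapter_max_mismatch_rate,
                 kmer_filter = isTRUE(kmer_filter),
                 kmer_k = as.integer(kmer_k),
                 kmer_min_freq = as.integer(kmer_min_freq),
                 min_read_len = as.integer(min_read_len)),
            class = "filter_config")
}

#' Positional quality profile
#'
#' Mean phred score per read position, pooled over both mates.
#'
#' @param pairs a [read_pairs] object.
#' @return list of class `quality_profile` with `position_means`, `n_reads`
#'   and `read_length`.
#' @export
profile_quality <- function(pairs) {
  quals <- c(pairs$qual1, pairs$qual2)
  if (!length(quals)) stop("cannot profile an empty read stream")
  lens <- unique(lengths(quals))
  if (length(lens) != 1L)
    stop("reads have unequal lengths (", paste(lens, collapse = ", "),
         "); positional profiling needs a uniform read length")
  m <- matrix(unlist(quals, use.names = FALSE), ncol = lens, byrow = TRUE)
  structure(list(position_means = colMeans(m),
                 n_reads = nrow(m), read_length = lens),
            class = "quality_profile")
}

#' Recommend a trim point and mean-quality cutoff
#'
#' The trim point is the first position where the positional mean drops
#' below `position_quality_threshold` for at least two consecutive
#' positions; reads are kept up to (excluding) that position. The
#' mean-quality cutoff is the largest integer phred Q retaining at least
#' `keep_fraction` of reads with mean quality >= Q.
#'
#' @param profile a [profile_quality()] result.
#' @param position_quality_threshold phred threshold on positional means.
#' @param keep_fraction target fraction of reads to retain.
#' @param read_mean_quals per-read mean qualities (optional; without it only
#'   the trim point is recommended).
#' @return list with `trim_to` (number of leading positions kept) and
#'   `mean_cutoff` (integer phred, or NA).
#' @export
recommend_cutoff <- function(profile, position_quality_threshold = 20,
                             keep_fraction = 0.75, read_mean_quals = NULL) {
  mu <- profile$position_means
  below <- mu < position_quality_threshold
  run2 <- which(below & c(below[-1], FALSE))
  trim_to <- if (length(run2)) run2[1] - 1L else profile$read_length
  mean_cutoff <- NA_integer_
  if (!is.null(read_mean_quals) && length(read_mean_quals)) {
    qs <- 0:45
    frac <- vapply(qs, function(q) mean(read_mean_quals >= q), numeric(1))
    ok <- qs[frac >= keep_fraction]
    mean_cutoff <- if (length(ok)) max(ok) else NA_integer_
  }
  list(trim_to = as.integer(trim_to), mean_cutoff = mean_cutoff)
}

#' Detect 3' adapter read-through
#'
#' Finds the longest overlap of an adapter prefix with the read's 3' suffix
#' of length at least `min_overlap` and mismatch fraction at most
#' `max_mismatch_rate`; the longest qualifying overlap (earliest start)
#' wins, ties going to the first adapter listed.
#'
#' @param read_seq character vector of read sequences.
#' @param adapters character vector of adapter sequences (optionally named).
#' @param min_overlap,max_mismatch_rate overlap acceptance thresholds.
#' @return data.frame with per-read `start` (0-based match start, NA when no
#'   adapter was found) and `adapter` (name or index, NA when none).
#' @export
detect_adapter <- function(read_seq, adapters, min_overlap = 5L,
                           max_mismatch_rate = 0.10) {
  stopifnot(length(adapters) >= 1)
  res <- detect_adapter_cpp(read_seq, unname(adapters),
                            as.integer(min_overlap), max_mismatch_rate)
  nm <- if (!is.null(names(adapters))) names(adapters)
        else as.character(seq_along(adapters))
  data.frame(start = ifelse(res$start < 0, NA_integer_, res$start),
             adapter = ifelse(res$adapter == 0, NA_character_,
                              nm[pmax(res$adapter, 1L)]),
             stringsAsFactors = FALSE)
}

trim_tail <- function(seq, qual, n) {
  if (n <= 0) return(list(seq = seq, qual = qual))
  len <- pmax(nchar(seq) - n, 0L)
  list(seq = substr(seq, 1L, len),
       qual = mapply(function(q, l) q[seq_len(l)], qual, len,
                     SIMPLIFY = FALSE))
}

#' Filter paired-end reads
#'
#' Per mate: fixed 3' tail trim, then adapter trimming at the detected
#' read-through start, then the survival rules in a fixed attribution order
#' -- post-tail-trim length, adapter trim leaving the mate too short, mean
#' phred below the cutoff, median k-mer dataset frequency below the minimum.
#' A pair is kept only when both mates pass; a dropped pair is attributed to
#' the first failing rule, so the report counts every pair exactly once.
#'
#' @param pairs a [read_pairs] object.
#' @param config a [filter_config()].
#' @param kmer_counts optional precomputed k-mer table (list with `kmer`,
#'   `count`) as returned by [count_kmers()]; built from the post-trim mates
#'   when the k-mer filter is enabled and no table is given.
#' @return list with `pairs` (kept, trimmed [read_pairs]) and `report`
#'   (class `filter_report`).
#' @export
filter_pairs <- function(pairs, config = filter_config(), kmer_counts = NULL) {
  n <- length(pairs)
  m1 <- trim_tail(pairs$seq1, pairs$qual1, config$tail_trim)
  m2 <- trim_tail(pairs$seq2, pairs$qual2, config$tail_trim)

  fail_len <- nchar(m1$seq) < config$min_read_len |
              nchar(m2$seq) < config$min_read_len

  trim_at <- function(m) {
    if (!length(config$adapters)) return(m)
    hit <- detect_adapter(m$seq, config$adapters,
                          config$adapter_min_overlap,
                          config$adapter_max_mismatch_rate)
    keep_len <- ifelse(is.na(hit$start), nchar(m$seq), hit$start)
    list(seq = substr(m$seq, 1L, keep_len),
         qual = mapply(function(q, l) q[seq_len(l)], m$qual, keep_len,
                       SIMPLIFY = FALSE))
  }
  a1 <- trim_at(m1); a2 <- trim_at(m2)
  fail_adapter <- !fail_len &
    (nchar(a1$seq) < config$min_read_len | nchar(a2$seq) < config$min_read_len)

  meanq <- function(q) vapply(q, function(v)
    if (length(v)) mean(v) else -Inf, numeric(1))
  fail_qual <- !fail_len & !fail_adapter &
    (meanq(a1$qual) < config$mean_quality_cutoff |
     meanq(a2$qual) < config$mean_quality_cutoff)

  fail_kmer <- rep(FALSE, n)
  if (config$kmer_filter) {
    if (is.null(kmer_counts))
      kmer_counts <- count_kmers(c(a1$seq, a2$seq), config$kmer_k,
                                 canonical = TRUE)
    med1 <- read_median_kmer_freq_cpp(a1$seq, config$kmer_k,
                                      kmer_counts$kmer, kmer_counts$count,
                                      TRUE)
    med2 <- read_median_kmer_freq_cpp(a2$seq, config$kmer_k,
                                      kmer_counts$kmer, kmer_counts$count,
                                      TRUE)
    med1[is.na(med1)] <- 0; med2[is.na(med2)] <- 0
    fail_kmer <- !fail_len & !fail_adapter & !fail_qual &
      (med1 < config$kmer_min_freq | med2 < config$kmer_min_freq)
  }

  kept <- !fail_len & !fail_adapter & !fail_qual & !fail_kmer
  out <- read_pairs(pairs$id[kept], a1$seq[kept], a2$seq[kept],
                    a1$qual[kept], a2$qual[kept], pairs$pass_filter[kept])

  recommender <- NULL
  if (n > 0 && length(unique(c(lengths(pairs$qual1),
                               lengths(pairs$qual2)))) == 1L) {
    prof <- profile_quality(pairs)
    rmq <- c(vapply(pairs$qual1, mean, numeric(1)),
             vapply(pairs$qual2, mean, numeric(1)))
    recommender <- c(list(profile = prof),
                     recommend_cutoff(prof, read_mean_quals = rmq))
  }

  report <- structure(list(
    pairs_in = n, pairs_out = sum(kept),
    dropped_by_length = sum(fail_len),
    dropped_by_adapter = sum(fail_adapter),
    dropped_by_quality = sum(fail_qual),
    dropped_by_kmer_freq = sum(fail_kmer),
    recommender = recommender), class = "filter_report")
  stopifnot(report$pairs_out + report$dropped_by_length +
            report$dropped_by_adapter + report$dropped_by_quality +
            report$dropped_by_kmer_freq == report$pairs_in)
  list(pairs = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:", x$pairs_in, "pairs in,", x$pairs_out, "kept\n")
  cat("  dropped: length", x$dropped_by_length,
      "| adapter", x$dropped_by_adapter,
      "| quality", x$dropped_by_quality,
      "| kmer", x$dropped_by_kmer_freq, "\n")
  invisible(x)
}
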