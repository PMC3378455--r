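# Desk-scale de Bruijn unitig assembler plus the k-mer sweep selection
# logic used to pick an assembly k. The assembler builds maximal
# non-branching paths over (k-1)-mer nodes after discarding low-frequency
# k-mers; no pair-distance scaffolding or gap filling is attempted.

#' Count k-mers in a set of sequences
#'
#' @param seqs character vector of nucleotide sequences.
#' @param k k-mer size; must not exceed the longest sequence.
#' @param canonical merge each k-mer with its reverse complement under the
#'   lexicographically smaller representative.
#' @return list with parallel `kmer` (character) and `count` (integer),
#'   sorted by k-mer.
#' @export
count_kmers <- function(seqs, k, canonical = FALSE) {
  k <- as.integer(k)
  stopifnot(k >= 1)
  if (!length(seqs) || all(nchar(seqs) < k))
    stop("k = ", k, " exceeds every sequence length")
  count_kmers_cpp(toupper(seqs), k, isTRUE(canonical))
}

#' Build unitigs from a k-mer table
#'
#' K-mers below `min_count` are discarded; the survivors form a de Bruijn
#' graph whose nodes are (k-1)-mers, and every maximal non-branching path is
#' reported once, under the lexicographically smaller of its two strands.
#' Coverage is the mean count of the path's k-mers.
#'
#' @param kmer_table list with `kmer`/`count` from
#'   [count_kmers()] (canonical counting recommended).
#' @param min_count minimum k-mer frequency kept.
#' @param min_len minimum unitig length in bp.
#' @return data.frame with `id`, `sequence`, `coverage`, `length`.
#' @export
build_unitigs <- function(kmer_table, min_count = 2L, min_len = 100L) {
  stopifnot(length(kmer_table$kmer) > 0)
  keep <- kmer_table$count >= min_count
  kms <- kmer_table$kmer[keep]
  cnt <- kmer_table$count[keep]
  if (!length(kms)) return(empty_contigs())
  k <- nchar(kms[1])

  # double the graph: every kept k-mer contributes both strands
  rc <- revcomp(kms)
  edge_seq <- c(kms, rc)
  edge_cnt <- c(cnt, cnt)
  dup <- duplicated(edge_seq)   # palindromic k-mers appear once
  edge_seq <- edge_seq[!dup]
  edge_cnt <- edge_cnt[!dup]
  ne <- length(edge_seq)

  pre <- substr(edge_seq, 1L, k - 1L)
  suf <- substr(edge_seq, 2L, k)
  nodes <- unique(c(pre, suf))
  pi <- match(pre, nodes)
  si <- match(suf, nodes)
  outdeg <- tabulate(pi, length(nodes))
  indeg <- tabulate(si, length(nodes))
  thru <- outdeg == 1L & indeg == 1L   # 1-in-1-out nodes
  out_edge <- integer(length(nodes))
  out_edge[pi] <- seq_len(ne)          # valid only where outdeg == 1

  visited <- logical(ne)
  paths <- list()
  walk <- function(e0) {
    path <- integer(0)
    e <- e0
    repeat {
      visited[e] <<- TRUE
      path <- c(path, e)
      s <- si[e]
      if (!thru[s]) break
      nxt <- out_edge[s]
      if (visited[nxt]) break
      e <- nxt
    }
    path
  }
  starts <- which(!thru[pi])
  for (e0 in starts) if (!visited[e0]) paths[[length(paths) + 1L]] <- walk(e0)
  # leftover edges sit on isolated cycles
  for (e0 in seq_len(ne)) if (!visited[e0]) paths[[length(paths) + 1L]] <- walk(e0)

  seqs <- vapply(paths, function(p) {
    paste0(substr(edge_seq[p[1]], 1L, k - 1L),
           paste(substr(edge_seq[p], k, k), collapse = ""))
  }, character(1))
  cov <- vapply(paths, function(p) mean(edge_cnt[p]), numeric(1))

  # a unitig and its reverse complement are the same contig
  canon <- pmin(seqs, revcomp(seqs))
  first <- !duplicated(canon)
  seqs <- canon[first]
  cov <- cov[first]
  long <- nchar(seqs) >= min_len
  seqs <- seqs[long]
  cov <- cov[long]
  if (!length(seqs)) return(empty_contigs())
  ord <- order(-nchar(seqs), seqs, method = "radix")
  data.frame(id = sprintf("unitig_%d", seq_along(ord)),
             sequence = seqs[ord], coverage = cov[ord],
             length = nchar(seqs[ord]), stringsAsFactors = FALSE)
}

empty_contigs <- function() {
  data.frame(id = character(), sequence = character(), coverage = numeric(),
             length = integer(), stringsAsFactors = FALSE)
}

#' Summary statistics of an assembly
#'
#' @param contigs data.frame with `sequence` and optionally `coverage`.
#' @param length_threshold length used for the "percent over" column.
#' @param k k-mer size to report alongside the stats (optional).
#' @return one-row data.frame: `k`, `avg_coverage`, `avg_length`,
#'   `max_length`, `n_transcripts`, `pct_over_1000`.
#' @export
assembly_stats <- function(contigs, length_threshold = 1000L, k = NA_integer_) {
  if (!nrow(contigs)) {
    return(data.frame(k = k, avg_coverage = 0, avg_length = 0, max_length = 0,
                      n_transcripts = 0L, pct_over_1000 = 0))
  }
  len <- nchar(contigs$sequence)
  cov <- if ("coverage" %in% names(contigs)) contigs$coverage else NA_real_
  data.frame(k = k,
             avg_coverage = mean(cov),
             avg_length = mean(len),
             max_length = max(len),
             n_transcripts = nrow(contigs),
             pct_over_1000 = 100 * mean(len > length_threshold))
}

#' Assemble at several k and pick the best
#'
#' Assembles the read set at every k in `k_values`, tabulates the summary
#' statistics, and selects the k with the largest average contig length
#' (ties: larger percent of contigs over 1 kb, then smaller k).
#'
#' @param reads character vector of read sequences.
#' @param k_values candidate k-mer sizes.
#' @param min_count minimum k-mer frequency kept.
#' @param min_len minimum contig length.
#' @return list with `stats` (one row per k), `chosen_k`, and `assemblies`
#'   (named list of contig data.frames).
#' @export
kmer_sweep <- function(reads, k_values, min_count = 2L, min_len = 100L) {
  stopifnot(length(k_values) >= 1)
  assemblies <- list()
  stats <- vector("list", length(k_values))
  for (i in seq_along(k_values)) {
    k <- as.integer(k_values[i])
    tab <- count_kmers(reads, k, canonical = TRUE)
    ctg <- build_unitigs(tab, min_count = min_count, min_len = min_len)
    assemblies[[as.character(k)]] <- ctg
    stats[[i]] <- assembly_stats(ctg, k = k)
  }
  stats <- do.call(rbind, stats)
  list(stats = stats, chosen_k = select_k(stats), assemblies = assemblies)
}

#' Select k from a table of assembly statistics
#'
#' @param stats data.frame with columns `k`, `avg_length`, `pct_over_1000`.
#' @return the selected k (integer).
#' @export
select_k <- function(stats) {
  stopifnot(all(c("k", "avg_length", "pct_over_1000") %in% names(stats)),
            nrow(stats) >= 1)
  ord <- order(-stats$avg_length, -stats$pct_over_1000, stats$k,
               method = "radix")
  as.integer(stats$k[ord[1]])
}
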