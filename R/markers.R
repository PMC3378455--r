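# Microsatellite (SSR) detection -- maximal perfect tandem repeats of 1-5 bp
# units at the canonical MISA-style thresholds -- and GC-content profiling.

ssr_class_names <- c("mono", "di", "tri", "tetra", "penta", "hexa")

#' Find SSRs (perfect tandem repeats)
#'
#' Reports every maximal perfect tandem repeat whose unit size has an entry
#' in `min_repeats` and whose full-unit count meets that class threshold. A
#' repeat whose unit is itself periodic is reported under its smallest
#' period; the motif is reported as it occurs at the repeat start and
#' coordinates are 1-based inclusive.
#'
#' @param seqs data.frame (`id`, `sequence`) or (named) character vector.
#' @param min_repeats named integer vector: minimum repeat count per unit
#'   size (names "1".."6"); the canonical defaults are 10/6/5/5/5 for
#'   mono- through penta-nucleotide.
#' @return data.frame `seq_id`, `motif`, `motif_class`, `n_repeats`,
#'   `start`, `end`.
#' @export
find_ssrs <- function(seqs,
                      min_repeats = c("1" = 10L, "2" = 6L, "3" = 5L,
                                      "4" = 5L, "5" = 5L)) {
  tx <- as_transcript_df(seqs)
  ps <- as.integer(names(min_repeats))
  stopifnot(!anyNA(ps), all(ps >= 1), all(ps <= 6), all(min_repeats >= 2))
  maxp <- max(ps)
  thr <- rep.int(.Machine$integer.max, maxp)
  thr[ps] <- as.integer(min_repeats)
  rows <- lapply(seq_len(nrow(tx)), function(i) {
    d <- find_ssrs_cpp(toupper(tx$sequence[i]), thr)
    if (!nrow(d)) return(NULL)
    data.frame(seq_id = tx$id[i], motif = d$motif,
               motif_class = ssr_class_names[d$period],
               n_repeats = d$n_repeats, start = d$start, end = d$end,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(seq_id = character(), motif = character(),
                      motif_class = character(), n_repeats = integer(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize an SSR record set
#'
#' @param records data.frame from [find_ssrs()].
#' @param top_n motifs reported per class.
#' @return list with `by_class` (class, count, pct) and `top_motifs`
#'   (class, motif, count).
#' @export
ssr_summary <- function(records, top_n = 5L) {
  if (!nrow(records)) {
    return(list(by_class = data.frame(motif_class = character(),
                                      count = integer(), pct = numeric(),
                                      stringsAsFactors = FALSE),
                top_motifs = data.frame(motif_class = character(),
                                        motif = character(),
                                        count = integer(),
                                        stringsAsFactors = FALSE),
                total = 0L))
  }
  cnt <- table(records$motif_class)
  by_class <- data.frame(motif_class = names(cnt), count = as.integer(cnt),
                         pct = 100 * as.integer(cnt) / nrow(records),
                         stringsAsFactors = FALSE)
  by_class <- by_class[order(-by_class$count, by_class$motif_class,
                             method = "radix"), , drop = FALSE]
  tops <- lapply(split(records$motif, records$motif_class), function(m) {
    t <- sort(table(m), decreasing = TRUE)
    t[seq_len(min(top_n, length(t)))]
  })
  top_motifs <- do.call(rbind, lapply(names(tops), function(cl)
    data.frame(motif_class = cl, motif = names(tops[[cl]]),
               count = as.integer(tops[[cl]]), stringsAsFactors = FALSE)))
  rownames(by_class) <- rownames(top_motifs) <- NULL
  list(by_class = by_class, top_motifs = top_motifs, total = nrow(records))
}

#' GC content of nucleotide sequences
#'
#' Fraction (G+C)/(A+C+G+T); ambiguity codes are excluded from the
#' denominator.
#'
#' @param seq character vector of sequences.
#' @return numeric vector of fractions (NaN when a sequence has no
#'   unambiguous base).
#' @export
gc_content <- function(seq) {
  seq <- toupper(seq)
  gc <- nchar(gsub("[^GC]", "", seq))
  acgt <- nchar(gsub("[^ACGT]", "", seq))
  gc / acgt
}

#' GC profile of a sequence set
#'
#' @param seqs data.frame (`id`, `sequence`) or character vector.
#' @param bin_width histogram bin width as a fraction (default 0.10).
#' @return list with `fractions` (per sequence), `histogram` (bin, count),
#'   `mean_pct` (mean GC in percent, 1 decimal), `n_excluded`.
#' @export
gc_profile <- function(seqs, bin_width = 0.10) {
  tx <- as_transcript_df(seqs)
  fr <- gc_content(tx$sequence)
  bad <- !is.finite(fr)
  if (any(bad))
    warning(sum(bad), " sequence(s) without unambiguous bases excluded")
  ok <- fr[!bad]
  brk <- seq(0, 1, by = bin_width)
  if (brk[length(brk)] < 1) brk <- c(brk, 1)
  h <- hist(ok, breaks = brk, plot = FALSE)
  list(fractions = setNames(fr, tx$id),
       histogram = data.frame(bin_low = h$breaks[-length(h$breaks)],
                              bin_high = h$breaks[-1],
                              count = h$counts),
       mean_pct = round(100 * mean(ok), 1),
       n_excluded = sum(bad))
}
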