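# Mismatch-tolerant read mapping (pigeonhole seed index over an 11-mer
# positional index, exhaustive-scan equivalent), RPKM quantification per
# condition aggregated to gene-group representatives, and the six
# fold-change classes used for between-condition comparison.

as_transcript_df <- function(transcripts) {
  if (is.data.frame(transcripts)) {
    stopifnot(all(c("id", "sequence") %in% names(transcripts)))
    transcripts
  } else {
    data.frame(id = if (is.null(names(transcripts)))
                 sprintf("tx_%d", seq_along(transcripts)) else
                 names(transcripts),
               sequence = unname(as.character(transcripts)),
               stringsAsFactors = FALSE)
  }
}

#' Map short reads to transcripts with a mismatch budget
#'
#' Finds every placement of every read (both strands) with at most
#' `max_mismatches` mismatches. The default engine splits each read into
#' `max_mismatches + 1` segments and seeds an 11-mer positional index
#' (pigeonhole: one segment of any qualifying placement is error-free),
#' then verifies candidates by full Hamming comparison; its output is
#' identical to the exhaustive `"brute"` engine, which scans every
#' (transcript, offset, strand). A read maps uniquely when exactly one
#' placement attains its best (fewest-mismatch) score.
#'
#' @param reads character vector of read sequences (reads shorter than
#'   `11 * (max_mismatches + 1)` are skipped and counted).
#' @param transcripts data.frame (`id`, `sequence`) or named character
#'   vector.
#' @param max_mismatches mismatch budget per placement.
#' @param engine `"seed"` (default) or `"brute"`.
#' @param all_placements return every qualifying placement instead of the
#'   per-read best summary.
#' @return With `all_placements = FALSE` (default) a data.frame with one row
#'   per read: `read`, `mapped`, `transcript_id`, `pos` (0-based), `strand`
#'   (`+`/`-`), `mismatches`, `n_best`, `n_hits`, `unique`, `skipped`; the
#'   number of uniquely mapped reads is in `attr(, "n_unique_mapped")`.
#'   Otherwise a data.frame of all placements.
#' @export
map_reads <- function(reads, transcripts, max_mismatches = 2L,
                      engine = c("seed", "brute"), all_placements = FALSE) {
  engine <- match.arg(engine)
  tx <- as_transcript_df(transcripts)
  stopifnot(nrow(tx) > 0)
  fn <- if (engine == "seed") ph_map_cpp else brute_map_cpp
  res <- fn(toupper(reads), toupper(tx$sequence),
            as.integer(max_mismatches), isTRUE(all_placements))
  if (all_placements) {
    out <- data.frame(read = res$read,
                      transcript_id = tx$id[res$tid],
                      pos = res$pos,
                      strand = ifelse(res$strand > 0, "+", "-"),
                      mismatches = res$mm, stringsAsFactors = FALSE)
    attr(out, "skipped") <- sum(res$skipped)
    return(out)
  }
  out <- data.frame(read = seq_along(reads),
                    mapped = res$mapped,
                    transcript_id = ifelse(res$mapped, tx$id[res$tid],
                                           NA_character_),
                    pos = res$pos,
                    strand = ifelse(is.na(res$strand), NA_character_,
                                    ifelse(res$strand > 0, "+", "-")),
                    mismatches = res$mm,
                    n_best = res$n_best, n_hits = res$n_hits,
                    unique = res$unique, skipped = res$skipped,
                    stringsAsFactors = FALSE)
  if (any(out$skipped))
    warning(sum(out$skipped), " read(s) shorter than the segment scheme",
            " were skipped")
  attr(out, "n_unique_mapped") <- sum(out$unique)
  out
}

#' Per-transcript unique-read counts
#'
#' @param mapping a [map_reads()] summary.
#' @return named integer vector, transcript id to count of uniquely mapped
#'   reads.
#' @export
unique_counts <- function(mapping) {
  u <- mapping[mapping$unique, , drop = FALSE]
  tab <- table(u$transcript_id)
  setNames(as.integer(tab), names(tab))
}

#' RPKM expression per gene group in two conditions
#'
#' Unique-read counts are aggregated over each group's member transcripts
#' onto the group representative; RPKM = 1e9 * C / (N * L) with C the
#' aggregated unique count, N the condition's total uniquely mapped reads
#' and L the representative's length. Records are produced for every group,
#' including zero-count ones; transcripts outside every group are
#' quantified as their own gene.
#'
#' @param mapping_a,mapping_b [map_reads()] summaries for conditions a and b
#'   against the same transcript set.
#' @param groups a `gene_groups` object, or a data.frame `id`, `gene_id`
#'   mapping member transcripts to representatives; `NULL` treats every
#'   transcript as its own gene.
#' @param transcripts the transcript set that was mapped against.
#' @return data.frame `gene_id`, `L`, `C_a`, `C_b`, `N_a`, `N_b`, `rpkm_a`,
#'   `rpkm_b`.
#' @export
quantify_rpkm <- function(mapping_a, mapping_b, groups = NULL, transcripts) {
  tx <- as_transcript_df(transcripts)
  membership <- if (is.null(groups)) {
    data.frame(id = tx$id, gene_id = tx$id, stringsAsFactors = FALSE)
  } else if (inherits(groups, "gene_groups")) {
    group_membership(groups)
  } else {
    stopifnot(all(c("id", "gene_id") %in% names(groups)))
    groups[, c("id", "gene_id")]
  }
  # transcripts outside every group are quantified as their own gene
  loose <- setdiff(tx$id, membership$id)
  if (length(loose))
    membership <- rbind(membership,
                        data.frame(id = loose, gene_id = loose,
                                   stringsAsFactors = FALSE))
  N_a <- sum(mapping_a$unique)
  N_b <- sum(mapping_b$unique)
  if (N_a == 0 || N_b == 0)
    stop("a condition has zero uniquely mapped reads")
  ca <- unique_counts(mapping_a)
  cb <- unique_counts(mapping_b)
  agg <- function(cv) {
    v <- cv[membership$id]
    v[is.na(v)] <- 0L
    tapply(v, membership$gene_id, sum)
  }
  Ca <- agg(ca); Cb <- agg(cb)
  genes <- sort(unique(membership$gene_id), method = "radix")
  L <- setNames(nchar(tx$sequence), tx$id)[genes]
  out <- data.frame(gene_id = genes, L = as.integer(L),
                    C_a = as.integer(Ca[genes]), C_b = as.integer(Cb[genes]),
                    N_a = N_a, N_b = N_b, stringsAsFactors = FALSE)
  out$rpkm_a <- 1e9 * out$C_a / (N_a * out$L)
  out$rpkm_b <- 1e9 * out$C_b / (N_b * out$L)
  rownames(out) <- NULL
  out
}

#' Fold change and the six expression classes
#'
#' Fold = rpkm_a / rpkm_b with a pseudo-RPKM added only to zero-valued
#' sides so the ratio stays finite. Classes (fold of condition a over b):
#' `>10`, `(5,10]`, `(2,5]`, `(1,2]`, `(0.5,1]`, `<=0.5`. The `>=2`-fold
#' gene sets of each condition (fold >= 2, fold <= 0.5) are returned for
#' enrichment input.
#'
#' @param records data.frame from [quantify_rpkm()].
#' @param pseudo pseudo-RPKM applied to zero values.
#' @return list with `records` (input plus `fold`, `fold_class`),
#'   `two_fold_a` and `two_fold_b` (character id sets).
#' @export
fold_classes <- function(records, pseudo = 0.5) {
  a <- ifelse(records$rpkm_a == 0, pseudo, records$rpkm_a)
  b <- ifelse(records$rpkm_b == 0, pseudo, records$rpkm_b)
  fold <- a / b
  cls <- cut(fold, breaks = c(-Inf, 0.5, 1, 2, 5, 10, Inf),
             labels = c("<=0.5", "(0.5,1]", "(1,2]", "(2,5]", "(5,10]",
                        ">10"))
  records$fold <- fold
  records$fold_class <- as.character(cls)
  list(records = records,
       two_fold_a = records$gene_id[fold >= 2],
       two_fold_b = records$gene_id[fold <= 0.5])
}
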