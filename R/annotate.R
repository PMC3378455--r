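# Annotation transfer from best similarity hits, six-frame longest-ORF
# extraction, GO-slim classification, and one-sided hypergeometric term
# enrichment with Bonferroni family-wise correction.

#' Longest open reading frame in each of the six frames
#'
#' Per frame (three forward, three on the reverse complement) the longest
#' stop-free codon run is translated with the standard code; no initiator
#' codon is required (stop-to-stop convention). Spans are reported in
#' forward-strand 1-based inclusive coordinates.
#'
#' @param seq a nucleotide sequence (single string, length >= 3).
#' @param min_aa minimum peptide length reported.
#' @return data.frame with `frame` (+1..+3, -1..-3), `start`, `end`,
#'   `aa_len`, `peptide`; up to six rows.
#' @export
six_frame_orfs <- function(seq, min_aa = 20L) {
  seq <- normalize_seq(seq)
  L <- nchar(seq)
  stopifnot(L >= 3)
  rc <- revcomp(seq)
  rows <- list()
  for (strand in c(1L, -1L)) {
    s <- if (strand > 0) seq else rc
    for (off in 1:3) {
      ncod <- (L - off + 1L) %/% 3L
      if (ncod < 1L) next
      sub <- substr(s, off, off + 3L * ncod - 1L)
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(sub), if.fuzzy.codon = "X"))
      runs <- gregexpr("[^*]+", aa)[[1]]
      if (runs[1] == -1L) next
      rl <- attr(runs, "match.length")
      best <- which.max(rl)
      if (rl[best] < min_aa) next
      a0 <- runs[best]
      nt_start <- off + 3L * (a0 - 1L)
      nt_end <- nt_start + 3L * rl[best] - 1L
      if (strand < 0) {
        tmp <- nt_start
        nt_start <- L - nt_end + 1L
        nt_end <- L - tmp + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        frame = strand * off, start = nt_start, end = nt_end,
        aa_len = rl[best],
        peptide = substr(aa, a0, a0 + rl[best] - 1L),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(frame = integer(), start = integer(), end = integer(),
                      aa_len = integer(), peptide = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(match(out$frame, c(1, 2, 3, -1, -2, -3))), , drop = FALSE]
}

#' Read a subject-to-terms mapping table
#'
#' Tab-separated `subject<TAB>GO:..[;GO:..]<TAB>EC:..[;..]<TAB>ko:..[;..]`,
#' empty fields allowed.
#'
#' @param path file path.
#' @return data.frame `subject_id`, `go`, `ec`, `kegg` (each a `;`-joined
#'   string, possibly empty).
#' @export
read_subject_map <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(subject_id = character(), go = character(),
                      ec = character(), kegg = character(),
                      stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 1L | nf > 4L))
    stop("malformed mapping row ", which(nf < 1L | nf > 4L)[1], " in ", path)
  get <- function(i) vapply(f, function(x)
    if (length(x) >= i) x[[i]] else "", character(1))
  data.frame(subject_id = get(1), go = get(2), ec = get(3), kegg = get(4),
             stringsAsFactors = FALSE)
}

split_terms <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE),
         function(v) unique(v[nzchar(v)]))
}

#' Transfer annotations from best hits
#'
#' Each gene receives exactly the term sets of its best hit's subject;
#' subjects missing from the mapping yield empty sets flagged unannotated.
#'
#' @param best_hits data.frame from [select_best_hit()].
#' @param subject_map data.frame from [read_subject_map()].
#' @return data.frame `gene_id`, `source_subject`, `go`, `ec`, `kegg`
#'   (`;`-joined strings) and `unannotated`.
#' @export
transfer_annotations <- function(best_hits, subject_map) {
  i <- match(best_hits$subject_id, subject_map$subject_id)
  found <- !is.na(i)
  pick <- function(col) ifelse(found, subject_map[[col]][i], "")
  data.frame(gene_id = best_hits$query_id,
             source_subject = best_hits$subject_id,
             go = pick("go"), ec = pick("ec"), kegg = pick("kegg"),
             unannotated = !found, stringsAsFactors = FALSE)
}

#' Classify annotated genes into GO-slim categories
#'
#' Uses a precomputed child-to-slim mapping (`GO:child<TAB>GO:slim`); no
#' ontology-graph traversal. A gene counts at most once per slim category
#' but may appear in several; genes holding a term with no slim mapping are
#' additionally counted once under `"unmapped"`.
#'
#' @param records data.frame from [transfer_annotations()] (needs `gene_id`
#'   and `go`).
#' @param slim_map data.frame with columns `go` and `slim` (optionally
#'   `ontology`).
#' @param ontology optional ontology filter applied to `slim_map$ontology`.
#' @return data.frame `slim`, `count`, sorted by decreasing count.
#' @export
classify_go_slim <- function(records, slim_map, ontology = NULL) {
  if (!is.null(ontology) && "ontology" %in% names(slim_map))
    slim_map <- slim_map[slim_map$ontology == ontology, , drop = FALSE]
  terms <- split_terms(records$go)
  per_gene <- lapply(terms, function(tv) {
    if (!length(tv)) return(character())
    sl <- slim_map$slim[match(tv, slim_map$go)]
    out <- unique(sl[!is.na(sl)])
    if (anyNA(sl)) out <- c(out, "unmapped")
    out
  })
  cnt <- table(unlist(per_gene))
  if (!length(cnt))
    return(data.frame(slim = character(), count = integer(),
                      stringsAsFactors = FALSE))
  out <- data.frame(slim = names(cnt), count = as.integer(cnt),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$slim, method = "radix"), , drop = FALSE]
}

#' Hypergeometric term enrichment with Bonferroni correction
#'
#' For every term annotated to at least one study gene, the upper-tail
#' hypergeometric probability of seeing as many or more study genes with the
#' term is computed and Bonferroni-corrected over the number of tested
#' terms.
#'
#' @param study_ids study gene ids (must be a subset of the population).
#' @param population_ids population gene ids.
#' @param term_map long-format data.frame `gene_id`, `term`.
#' @param alpha family-wise significance level.
#' @return data.frame `term`, `k`, `n`, `K`, `N`, `p_raw`, `p_adj`,
#'   `significant`, sorted by ascending adjusted p.
#' @export
enrich_terms <- function(study_ids, population_ids, term_map, alpha = 0.05) {
  study_ids <- unique(study_ids)
  population_ids <- unique(population_ids)
  stopifnot(length(study_ids) > 0, length(population_ids) > 0)
  missing <- setdiff(study_ids, population_ids)
  if (length(missing))
    stop("study genes absent from the population: ",
         paste(head(missing, 5), collapse = ", "))
  tm <- unique(term_map[term_map$gene_id %in% population_ids,
                        c("gene_id", "term")])
  N <- length(population_ids)
  n <- length(study_ids)
  Kt <- table(tm$term)
  kt <- table(tm$term[tm$gene_id %in% study_ids])
  terms <- names(kt)[kt >= 1L]             # tested terms: k >= 1 (and K >= 1)
  m <- length(terms)
  if (!m)
    return(data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_raw = numeric(),
                      p_adj = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  k <- as.integer(kt[terms])
  K <- as.integer(Kt[terms])
  p_raw <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  p_adj <- pmin(1, m * p_raw)
  out <- data.frame(term = terms, k = k, n = n, K = K, N = N,
                    p_raw = p_raw, p_adj = p_adj,
                    significant = p_adj <= alpha, stringsAsFactors = FALSE)
  out <- out[order(out$p_adj, out$p_raw, out$term, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
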