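# Redundancy reduction: greedy longest-first identity clustering (both
# strands, identity = matching columns / shorter sequence length), iterative
# terminal-overlap merging, and grouping of dissimilar transcripts that share
# a common best similarity hit ("unique gene" groups).

# identity of a vs b (a may be revcomp'ed by the caller): global on the
# shorter sequence, local on the longer, matches / shorter length
pair_identity_one <- function(shorter, longer) {
  al <- Biostrings::pairwiseAlignment(
    pattern = shorter, subject = longer, type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 5, gapExtension = 2)
  Biostrings::nmatch(al) / nchar(shorter)
}

#' Pairwise sequence identity
#'
#' Identity between two nucleotide sequences: matching columns of a global
#' alignment of the shorter sequence against the (locally anchored) longer
#' one, divided by the shorter length. Both strands are tried and the better
#' one is reported.
#'
#' @param a,b nucleotide sequences (single strings).
#' @param both_strands also try the reverse complement of `a`.
#' @return identity fraction in `[0, 1]`.
#' @export
pair_identity <- function(a, b, both_strands = TRUE) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  ident <- pair_identity_one(a, b)
  if (both_strands && ident < 1)
    ident <- max(ident, pair_identity_one(revcomp(a), b))
  ident
}

seq_kmer_set <- function(s, k = 10L) {
  if (nchar(s) < k) return(s)
  unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)))
}

#' Greedy identity clustering
#'
#' Longest-first greedy clustering: sequences are visited in decreasing
#' length order (ties: id); each is compared on both strands against the
#' representatives of existing clusters (after a shared 10-mer pre-screen)
#' and joins the best-identity cluster at or above the threshold, otherwise
#' founds a new cluster. Representatives are therefore each cluster's
#' longest member.
#'
#' @param seqs data.frame with `id` and `sequence`.
#' @param identity_threshold minimum identity fraction in `(0, 1]`.
#' @return data.frame with one row per input sequence: `id`,
#'   `representative_id`, `cluster` (integer index).
#' @export
cluster_by_identity <- function(seqs, identity_threshold = 0.95) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1,
            all(c("id", "sequence") %in% names(seqs)))
  n <- nrow(seqs)
  ord <- order(-nchar(seqs$sequence), seqs$id, method = "radix")
  rep_idx <- integer(0)          # row index of each cluster representative
  rep_kmers <- list()
  assign <- integer(n)
  for (i in ord) {
    s <- seqs$sequence[i]
    qk <- unique(c(seq_kmer_set(s), seq_kmer_set(revcomp(s))))
    best_c <- 0L
    best_id <- -1
    for (ci in seq_along(rep_idx)) {
      if (!any(qk %in% rep_kmers[[ci]])) next
      ident <- pair_identity(s, seqs$sequence[rep_idx[ci]])
      if (ident >= identity_threshold && ident > best_id) {
        best_id <- ident
        best_c <- ci
      }
    }
    if (best_c > 0L) {
      assign[i] <- best_c
    } else {
      rep_idx <- c(rep_idx, i)
      rep_kmers[[length(rep_idx)]] <- seq_kmer_set(s)
      assign[i] <- length(rep_idx)
    }
  }
  data.frame(id = seqs$id, representative_id = seqs$id[rep_idx[assign]],
             cluster = assign, stringsAsFactors = FALSE)
}

#' Two-stage clustering cascade
#'
#' Clusters at each threshold in turn, carrying only the representatives of
#' one stage into the next, and composes the memberships, mirroring a
#' 95 percent then 90 percent redundancy-removal cascade.
#'
#' @param seqs data.frame with `id` and `sequence`.
#' @param thresholds identity thresholds, applied in order.
#' @return data.frame `id`, `representative_id` covering all input ids.
#' @export
cluster_cascade <- function(seqs, thresholds = c(0.95, 0.90)) {
  map <- setNames(seqs$id, seqs$id)
  cur <- seqs
  for (th in thresholds) {
    cl <- cluster_by_identity(cur, th)
    step <- setNames(cl$representative_id, cl$id)
    map <- setNames(unname(step[map]), names(map))
    cur <- cur[cur$id %in% unique(cl$representative_id), , drop = FALSE]
  }
  data.frame(id = names(map), representative_id = unname(map),
             stringsAsFactors = FALSE)
}

# best qualifying merge between two oriented sequences across the four
# distinct end-to-end orientations (up to strand)
best_pair_overlap <- function(sa, sb, min_overlap, min_identity) {
  combos <- list(list(x = sa, y = sb, o = "AB"),
                 list(x = sb, y = sa, o = "BA"),
                 list(x = sa, y = revcomp(sb), o = "ArB"),
                 list(x = revcomp(sb), y = sa, o = "rBA"))
  best <- NULL
  for (cm in combos) {
    ov <- best_overlap_cpp(cm$x, cm$y, as.integer(min_overlap), min_identity)
    if (ov > 0 && (is.null(best) || ov > best$ov))
      best <- list(x = cm$x, y = cm$y, ov = ov, orientation = cm$o)
  }
  best
}

merge_two <- function(x, y, ov, x_is_longer) {
  nx <- nchar(x)
  sx <- substr(x, nx - ov + 1L, nx)
  sy <- substr(y, 1L, ov)
  cons <- if (x_is_longer) sx else sy   # disagreeing columns take the longer
  paste0(substr(x, 1L, nx - ov), cons, substr(y, ov + 1L, nchar(y)))
}

#' Merge contigs by terminal overlap
#'
#' Iteratively merges sequence pairs whose suffix/prefix overlap (either
#' orientation) spans at least `min_overlap` bases at `min_identity` or
#' better, taking at each step the first qualifying pair in a fixed order
#' (longer sequences first, then id) and the longest overlap among the
#' orientations. At disagreeing overlap columns the base of the longer
#' sequence wins. Repeats until no pair qualifies.
#'
#' @param seqs data.frame with `id` and `sequence`.
#' @param min_overlap minimum terminal overlap in bp.
#' @param min_identity minimum overlap identity fraction.
#' @return list with `seqs` (merged set; a merged contig keeps the longer
#'   parent's id) and `log` (one row per merge with both source ids).
#' @export
merge_terminal_overlaps <- function(seqs, min_overlap = 40L,
                                    min_identity = 0.90) {
  stopifnot(min_overlap > 0, min_identity > 0)
  work <- seqs[, c("id", "sequence")]
  log <- list()
  repeat {
    ordv <- order(-nchar(work$sequence), work$id, method = "radix")
    merged <- FALSE
    for (ii in seq_along(ordv)) {
      if (merged) break
      for (jj in seq_along(ordv)) {
        if (jj <= ii) next
        i <- ordv[ii]; j <- ordv[jj]
        hit <- best_pair_overlap(work$sequence[i], work$sequence[j],
                                 min_overlap, min_identity)
        if (is.null(hit)) next
        longer_is_x <- nchar(hit$x) >= nchar(hit$y)
        newseq <- merge_two(hit$x, hit$y, hit$ov, longer_is_x)
        keep_id <- work$id[i]    # i is the longer (or earlier-id) parent
        log[[length(log) + 1L]] <- data.frame(
          id_a = work$id[i], id_b = work$id[j], orientation = hit$orientation,
          overlap = hit$ov, merged_id = keep_id, merged_len = nchar(newseq),
          stringsAsFactors = FALSE)
        work$sequence[i] <- newseq
        work <- work[-j, , drop = FALSE]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  rownames(work) <- NULL
  list(seqs = work,
       log = if (length(log)) do.call(rbind, log) else
         data.frame(id_a = character(), id_b = character(),
                    orientation = character(), overlap = integer(),
                    merged_id = character(), merged_len = integer(),
                    stringsAsFactors = FALSE))
}

#' Select the best hit per query
#'
#' Hits above the e-value cutoff are discarded; per query the hit with the
#' highest bitscore survives, ties broken by smaller e-value, then
#' lexicographic subject id. Queries with no surviving hit are absent.
#'
#' @param hits data.frame from [read_hits()].
#' @param evalue_cutoff maximum e-value retained.
#' @return data.frame with one row per query.
#' @export
select_best_hit <- function(hits, evalue_cutoff = 1e-5) {
  h <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  if (!nrow(h)) return(h)
  ord <- order(h$query_id, -h$bitscore, h$evalue, h$subject_id,
               method = "radix")
  h <- h[ord, , drop = FALSE]
  h <- h[!duplicated(h$query_id), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Group transcripts by shared best-hit subject
#'
#' Queries are partitioned by their best hit's subject; each group's
#' representative is its longest member (ties: lexicographically smaller
#' id). Whether member subject intervals overlap is recorded but not acted
#' on. Sequences without a best hit are returned ungrouped.
#'
#' @param best_hits data.frame from [select_best_hit()].
#' @param seqs data.frame with `id` and `sequence` for all queries.
#' @return list of class `gene_groups`: `table` (subject_id,
#'   representative_id, n_members, members as `;`-joined ids,
#'   subject_intervals_overlap) and `ungrouped` (character ids).
#' @export
group_by_subject <- function(best_hits, seqs) {
  len <- setNames(nchar(seqs$sequence), seqs$id)
  known <- best_hits$query_id %in% seqs$id
  bh <- best_hits[known, , drop = FALSE]
  ungrouped <- setdiff(seqs$id, bh$query_id)
  if (!nrow(bh)) {
    tab <- data.frame(subject_id = character(), representative_id = character(),
                      n_members = integer(), members = character(),
                      subject_intervals_overlap = logical(),
                      stringsAsFactors = FALSE)
    return(structure(list(table = tab, ungrouped = ungrouped),
                     class = "gene_groups"))
  }
  sp <- split(seq_len(nrow(bh)), bh$subject_id)
  rows <- lapply(names(sp), function(s) {
    idx <- sp[[s]]
    ids <- bh$query_id[idx]
    o <- order(-len[ids], ids, method = "radix")
    iv <- cbind(pmin(bh$sstart[idx], bh$send[idx]),
                pmax(bh$sstart[idx], bh$send[idx]))
    ivo <- FALSE
    if (length(idx) > 1) {
      os <- order(iv[, 1])
      ivo <- any(iv[os, 1][-1] <= cummax(iv[os, 2])[-length(idx)])
    }
    data.frame(subject_id = s, representative_id = ids[o][1],
               n_members = length(ids),
               members = paste(ids[o], collapse = ";"),
               subject_intervals_overlap = ivo, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$subject_id, method = "radix"), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, ungrouped = sort(ungrouped, method = "radix")),
            class = "gene_groups")
}

#' @export
print.gene_groups <- function(x, ...) {
  cat("gene_groups:", nrow(x$table), "groups,",
      length(x$ungrouped), "ungrouped sequences\n")
  invisible(x)
}

#' Member-to-representative map of a gene_groups object
#' @param groups a `gene_groups` object.
#' @return data.frame `id`, `gene_id` (the representative).
#' @export
group_membership <- function(groups) {
  if (!nrow(groups$table))
    return(data.frame(id = character(), gene_id = character(),
                      stringsAsFactors = FALSE))
  mem <- strsplit(groups$table$members, ";", fixed = TRUE)
  data.frame(id = unlist(mem),
             gene_id = rep(groups$table$representative_id, lengths(mem)),
             stringsAsFactors = FALSE)
}
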