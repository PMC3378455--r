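# Seeded synthetic-data generation with planted ground truth: a
# transcriptome with gene families and planted SSRs, paired-end reads with
# positional quality decay / adapter read-through, similarity-hit tables
# with the shared-best-hit structure, and annotation tables with a known
# GO-slim composition. Every generator is deterministic for a fixed seed.

random_seq <- function(len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

# exactly round(rate * L) substitutions, so "x percent divergence" is the
# realized (not just expected) per-copy divergence
mutate_seq <- function(seq, rate) {
  L <- nchar(seq)
  nmut <- round(rate * L)
  if (nmut == 0) return(seq)
  pos <- sample.int(L, nmut)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

#' Simulate a transcriptome with planted structure
#'
#' Generates `n` transcripts at a target GC content and mean length, with
#' optional planted gene families and SSR loci recorded in a truth object.
#' Family mode `"fragment"` cuts each parent gene into members covering
#' distinct parent regions (they share a reference gene but little
#' sequence, exercising best-hit grouping); mode `"copy"` emits the parent
#' plus slightly shortened divergent copies (exercising identity
#' clustering; the full-length parent is each family's longest member).
#'
#' @param n total number of transcripts (family members included).
#' @param length_mean,length_sd,length_min transcript length model (bp).
#' @param gc_target target GC fraction.
#' @param n_parents number of planted gene families.
#' @param members_per_parent members per family.
#' @param family_mode `"fragment"` or `"copy"`.
#' @param divergence per-base substitution rate applied to family members.
#' @param parent_length parent gene length for `"fragment"` mode; defaults
#'   to `members_per_parent * length_mean`.
#' @param ssr_plants optional data.frame `seq` (1-based transcript index),
#'   `motif`, `n_repeats`, `position` of repeats to plant.
#' @param seed RNG seed.
#' @return list with `transcripts` (id, sequence, description) and `truth`
#'   (class `sim_truth`).
#' @export
simulate_transcriptome <- function(n = 200, length_mean = 440,
                                   length_sd = 250, length_min = 100,
                                   gc_target = 0.446, n_parents = 0,
                                   members_per_parent = 3,
                                   family_mode = c("fragment", "copy"),
                                   divergence = 0.03, parent_length = NULL,
                                   ssr_plants = NULL, seed = 1) {
  family_mode <- match.arg(family_mode)
  stopifnot(n >= 1, length_min <= length_mean,
            n >= n_parents * members_per_parent)
  set.seed(seed)
  draw_len <- function(k) pmax(length_min,
                               round(rnorm(k, length_mean, length_sd)))
  ids <- character(0); seqs <- character(0)
  fam <- data.frame(member_id = character(), parent = character(),
                    region_start = integer(), region_end = integer(),
                    stringsAsFactors = FALSE)
  if (n_parents > 0) {
    if (is.null(parent_length))
      parent_length <- members_per_parent * length_mean
    for (p in seq_len(n_parents)) {
      pid <- sprintf("fam%03d", p)
      if (family_mode == "fragment") {
        pl <- max(parent_length, members_per_parent * length_min)
        parent <- random_seq(pl, gc_target)
        cut <- round(seq(1, pl + 1, length.out = members_per_parent + 1))
        for (j in seq_len(members_per_parent)) {
          frag <- substr(parent, cut[j], cut[j + 1] - 1)
          frag <- mutate_seq(frag, divergence)
          mid <- sprintf("%s_m%d", pid, j)
          ids <- c(ids, mid); seqs <- c(seqs, frag)
          fam <- rbind(fam, data.frame(member_id = mid, parent = pid,
                                       region_start = cut[j],
                                       region_end = cut[j + 1] - 1L,
                                       stringsAsFactors = FALSE))
        }
      } else {
        pl <- draw_len(1)
        pl <- max(pl, length_min + 20)
        parent <- random_seq(pl, gc_target)
        for (j in seq_len(members_per_parent)) {
          if (j == 1) {
            member <- parent       # the family's longest member
          } else {
            trim <- max(2L, round(0.02 * pl))
            member <- mutate_seq(substr(parent, 1, pl - trim), divergence)
          }
          mid <- sprintf("%s_m%d", pid, j)
          ids <- c(ids, mid); seqs <- c(seqs, member)
          fam <- rbind(fam, data.frame(member_id = mid, parent = pid,
                                       region_start = 1L,
                                       region_end = nchar(member),
                                       stringsAsFactors = FALSE))
        }
      }
    }
  }
  n_single <- n - length(ids)
  if (n_single > 0) {
    sl <- draw_len(n_single)
    ids <- c(ids, sprintf("tx%05d", seq_len(n_single)))
    seqs <- c(seqs, vapply(sl, random_seq, character(1), gc = gc_target))
  }
  tx <- data.frame(id = ids, sequence = seqs, description = "",
                   stringsAsFactors = FALSE)

  planted_ssrs <- data.frame(seq_id = character(), motif = character(),
                             n_repeats = integer(), start = integer(),
                             end = integer(), stringsAsFactors = FALSE)
  if (!is.null(ssr_plants) && nrow(ssr_plants)) {
    for (r in seq_len(nrow(ssr_plants))) {
      i <- ssr_plants$seq[r]
      motif <- toupper(ssr_plants$motif[r])
      nr <- ssr_plants$n_repeats[r]
      pos <- ssr_plants$position[r]
      tx$sequence[i] <- plant_ssr(tx$sequence[i], motif, nr, pos)
      planted_ssrs <- rbind(planted_ssrs, data.frame(
        seq_id = tx$id[i], motif = motif, n_repeats = nr,
        start = pos, end = pos + nchar(motif) * nr - 1L,
        stringsAsFactors = FALSE))
    }
  }
  truth <- structure(list(seed = seed, families = fam,
                          ssrs = planted_ssrs,
                          params = list(n = n, length_mean = length_mean,
                                        length_sd = length_sd,
                                        length_min = length_min,
                                        gc_target = gc_target,
                                        family_mode = family_mode,
                                        divergence = divergence)),
                     class = "sim_truth")
  list(transcripts = tx, truth = truth)
}

# plant a maximal perfect repeat: flanking bases are forced off-period so
# the repeat is recovered at exactly the planted coordinates
plant_ssr <- function(seq, motif, n_repeats, pos) {
  p <- nchar(motif)
  block <- strrep(motif, n_repeats)
  end <- pos + nchar(block) - 1L
  stopifnot(pos >= 1, end <= nchar(seq))
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ch[pos:end] <- strsplit(block, "", fixed = TRUE)[[1]]
  last <- substr(motif, p, p)
  first <- substr(motif, 1, 1)
  if (pos > 1 && ch[pos - 1] == last)
    ch[pos - 1] <- setdiff(c("A", "C", "G", "T"), last)[1]
  if (end < length(ch) && ch[end + 1] == first)
    ch[end + 1] <- setdiff(c("A", "C", "G", "T"), first)[1]
  paste(ch, collapse = "")
}

#' Simulate per-condition abundances with planted fold changes
#'
#' Baseline abundances are log-normal (sdlog 1); `n_up` genes get `fold`
#' times the baseline in condition a, `n_down` genes get it in condition b.
#' The default planted fold of 2.5 sits inside the two-to-five-fold
#' expression class, so a planted gene's true fold class is well defined
#' (a multiplier of exactly 2 would lie on the class boundary, where
#' sampling noise makes class membership a coin flip).
#'
#' @param ids transcript/gene ids.
#' @param n_up,n_down number of planted up-/down-regulated genes.
#' @param fold planted fold change (> 1).
#' @param sdlog log-normal spread of baseline abundance.
#' @param seed RNG seed.
#' @return data.frame `id`, `abund_a`, `abund_b`, `planted`
#'   (`"up"`/`"down"`/`"none"`).
#' @export
simulate_abundances <- function(ids, n_up = 25, n_down = 25, fold = 2.5,
                                sdlog = 1, seed = 1) {
  stopifnot(n_up + n_down <= length(ids), fold > 1)
  set.seed(seed)
  base <- rlnorm(length(ids), meanlog = 0, sdlog = sdlog)
  planted <- rep("none", length(ids))
  pick <- sample(seq_along(ids), n_up + n_down)
  planted[pick[seq_len(n_up)]] <- "up"
  planted[pick[n_up + seq_len(n_down)]] <- "down"
  a <- base * ifelse(planted == "up", fold, 1)
  b <- base * ifelse(planted == "down", fold, 1)
  data.frame(id = ids, abund_a = a, abund_b = b, planted = planted,
             stringsAsFactors = FALSE)
}

#' Simulate paired-end reads
#'
#' Fragments are drawn from transcripts proportional to abundance times
#' length; mates of `read_len` bases are taken from the fragment ends, the
#' second mate reverse-complemented. Per-base qualities follow a linear
#' positional decay from `q_start` to `q_end` with Gaussian jitter (sd
#' `q_jitter_sd`), clamped to [2, 41]; sequencing errors are drawn per base
#' from the phred error probability (or a flat `error_rate` when given).
#' With probability `adapter_rate` a fragment is drawn shorter than the
#' read length so both mates run through into the adapter.
#'
#' @param transcripts data.frame (`id`, `sequence`) or character vector.
#' @param n_pairs number of pairs to emit.
#' @param abundance optional data.frame (`id`, abundance column named by
#'   `condition`: `abund_a`/`abund_b`) or named numeric vector; uniform
#'   when NULL.
#' @param condition `"a"` or `"b"` (selects the abundance column).
#' @param read_len,insert_mean,insert_sd fragment geometry (bp).
#' @param q_start,q_end,q_jitter_sd positional quality model (phred).
#' @param error_rate flat per-base error probability overriding the
#'   quality-derived one; 0 disables errors.
#' @param adapter adapter sequence for read-through (NULL disables).
#' @param adapter_rate fraction of fragments drawn shorter than `read_len`.
#' @param seed RNG seed.
#' @return list with `pairs` ([read_pairs]) and `truth` (data.frame `id`,
#'   `transcript`, `start`, `insert_len`, `adapter_readthrough`).
#' @export
simulate_reads <- function(transcripts, n_pairs, abundance = NULL,
                           condition = "a", read_len = 36L,
                           insert_mean = 200, insert_sd = 20,
                           q_start = 38, q_end = 20, q_jitter_sd = 2,
                           error_rate = NULL, adapter = NULL,
                           adapter_rate = 0, seed = 1) {
  tx <- as_transcript_df(transcripts)
  if (!nrow(tx)) stop("empty transcriptome")
  stopifnot(insert_mean >= read_len, n_pairs >= 1)
  set.seed(seed)
  len <- nchar(tx$sequence)
  ok <- len >= read_len
  if (!any(ok)) stop("no transcript is as long as the read length")
  ab <- rep(1, nrow(tx))
  if (!is.null(abundance)) {
    if (is.data.frame(abundance)) {
      col <- paste0("abund_", condition)
      ab <- abundance[[col]][match(tx$id, abundance$id)]
    } else {
      ab <- unname(abundance[tx$id])
    }
    ab[is.na(ab)] <- 0
  }
  w <- ab * len * ok
  if (sum(w) <= 0) stop("all sampling weights are zero")
  ti <- sample.int(nrow(tx), n_pairs, replace = TRUE, prob = w)

  ins <- pmax(read_len, round(rnorm(n_pairs, insert_mean, insert_sd)))
  thru <- rep(FALSE, n_pairs)
  if (!is.null(adapter) && adapter_rate > 0) {
    thru <- runif(n_pairs) < adapter_rate
    # read-through inserts leave at least 8 adapter bases on each mate, so
    # every planted contamination is long enough to be detected
    ins[thru] <- sample(seq(ceiling(read_len / 2), read_len - 8L),
                        sum(thru), replace = TRUE)
  }
  ins <- pmin(ins, len[ti])
  start <- 1L + floor(runif(n_pairs) * (len[ti] - ins + 1))
  frag <- substr(tx$sequence[ti], start, start + ins - 1L)

  pad <- function(reads) {
    short <- nchar(reads) < read_len
    if (any(short)) {
      fill <- strrep(paste0(adapter, strrep("A", read_len)), 1)
      reads[short] <- substr(paste0(reads[short], fill), 1, read_len)
    }
    substr(reads, 1, read_len)
  }
  r1 <- pad(frag)
  r2 <- pad(revcomp(frag))

  qbase <- q_start + (q_end - q_start) * (seq_len(read_len) - 1) /
    max(read_len - 1, 1)
  qmat <- function() {
    m <- matrix(round(rep(qbase, each = n_pairs) +
                        rnorm(n_pairs * read_len, 0, q_jitter_sd)),
                nrow = n_pairs)
    m[m < 2] <- 2L; m[m > 41] <- 41L
    storage.mode(m) <- "integer"
    m
  }
  q1 <- qmat(); q2 <- qmat()
  apply_err <- function(reads, qm) {
    p <- if (!is.null(error_rate)) matrix(error_rate, n_pairs, read_len)
         else 10^(-qm / 10)
    hit <- matrix(runif(n_pairs * read_len) < p, n_pairs)
    rows <- which(rowSums(hit) > 0)
    for (i in rows) {
      ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
      for (j in which(hit[i, ])) {
        if (ch[j] %in% c("A", "C", "G", "T"))
          ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
      }
      reads[i] <- paste(ch, collapse = "")
    }
    reads
  }
  r1 <- apply_err(r1, q1)
  r2 <- apply_err(r2, q2)

  ids <- sprintf("pair%07d", seq_len(n_pairs))
  pairs <- read_pairs(ids, r1, r2,
                      lapply(seq_len(n_pairs), function(i) q1[i, ]),
                      lapply(seq_len(n_pairs), function(i) q2[i, ]))
  truth <- data.frame(id = ids, transcript = tx$id[ti], start = start,
                      insert_len = ins, adapter_readthrough = thru,
                      stringsAsFactors = FALSE)
  list(pairs = pairs, truth = truth)
}

#' Deterministic tiled single-end reads
#'
#' Emits reads whose starts are evenly spaced along each transcript so that
#' consecutive starts differ by at most a couple of bases, at the requested
#' fold depth; every other read is reverse-complemented. Used for
#' reconstruction experiments where coverage continuity must hold by
#' construction.
#'
#' @param transcripts data.frame (`id`, `sequence`) or character vector.
#' @param read_len read length (bp).
#' @param depth target fold coverage.
#' @return list with `reads` (character) and `truth` (data.frame
#'   `transcript`, `start`, `strand`).
#' @export
simulate_tiled_reads <- function(transcripts, read_len = 36L, depth = 30) {
  tx <- as_transcript_df(transcripts)
  out_r <- character(0)
  out_t <- list()
  for (i in seq_len(nrow(tx))) {
    L <- nchar(tx$sequence[i])
    if (L < read_len) next
    nr <- ceiling(L * depth / read_len)
    starts <- round(seq(1, L - read_len + 1, length.out = nr))
    # terminal starts twice, so the outermost k-mers clear frequency cutoffs
    starts <- sort(c(starts, 1L, L - read_len + 1L))
    reads <- substr(rep(tx$sequence[i], length(starts)), starts,
                    starts + read_len - 1L)
    flip <- seq_along(reads) %% 2L == 0L
    strand <- ifelse(flip, "-", "+")
    reads[flip] <- revcomp(reads[flip])
    out_r <- c(out_r, reads)
    out_t[[i]] <- data.frame(transcript = tx$id[i], start = starts,
                             strand = strand, stringsAsFactors = FALSE)
  }
  list(reads = out_r, truth = do.call(rbind, out_t))
}

#' Simulate a similarity-hit table with planted best-hit structure
#'
#' Every family member receives a best hit to its parent's subject id, with
#' subject intervals reflecting the member's parent region; singleton
#' transcripts receive a hit to their own subject except for an "unknown"
#' fraction left without hits. Decoy hits with strictly worse bitscores are
#' added at `decoy_rate`.
#'
#' @param transcripts data.frame (`id`, `sequence`).
#' @param truth a `sim_truth` from [simulate_transcriptome()].
#' @param unknown_fraction fraction of singletons with no hit.
#' @param decoy_rate per-query probability of one extra, worse hit.
#' @param seed RNG seed.
#' @return data.frame in 12-column hit layout (see [read_hits()]).
#' @export
simulate_hits <- function(transcripts, truth, unknown_fraction = 0.30,
                          decoy_rate = 0, seed = 1) {
  tx <- as_transcript_df(transcripts)
  set.seed(seed)
  fam <- truth$families
  rows <- list()
  mk <- function(q, s, qlen, ss, se, bit) {
    data.frame(query_id = q, subject_id = s,
               pct_identity = round(runif(1, 85, 100), 1),
               aln_len = max(1L, qlen %/% 3L), mismatches = 0L,
               gap_opens = 0L, qstart = 1L, qend = qlen,
               sstart = ss, send = se,
               evalue = 10^(-bit / 10), bitscore = bit,
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(tx))) {
    id <- tx$id[i]
    qlen <- nchar(tx$sequence[i])
    fi <- match(id, fam$member_id)
    if (!is.na(fi)) {
      ss <- max(1L, fam$region_start[fi] %/% 3L + 1L)
      se <- max(ss, fam$region_end[fi] %/% 3L)
      bit <- round(runif(1, 200, 300), 1)
      rows[[length(rows) + 1L]] <-
        mk(id, paste0("SUBJ_", fam$parent[fi]), qlen, ss, se, bit)
    } else if (runif(1) >= unknown_fraction) {
      bit <- round(runif(1, 150, 250), 1)
      rows[[length(rows) + 1L]] <-
        mk(id, paste0("SUBJ_", id), qlen, 1L, max(1L, qlen %/% 3L), bit)
    } else {
      next
    }
    if (decoy_rate > 0 && runif(1) < decoy_rate) {
      bit <- rows[[length(rows)]]$bitscore - round(runif(1, 20, 80), 1)
      decoy_subject <- paste0("SUBJ_decoy", sample.int(1000, 1))
      rows[[length(rows) + 1L]] <-
        mk(id, decoy_subject, qlen, 1L, max(1L, qlen %/% 3L), bit)
    }
  }
  if (!length(rows)) return(read_hits(tempfile_empty_hits()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

tempfile_empty_hits <- function() {
  f <- tempfile(fileext = ".tsv")
  writeLines("# empty", f)
  f
}

#' Simulate annotation and GO-slim tables with known composition
#'
#' Each subject gets 1..`max_terms` GO terms from a pool; every pool term
#' maps to exactly one slim category (balanced round-robin), and slims are
#' split between biological_process and molecular_function.
#'
#' @param subject_ids subjects to annotate.
#' @param n_go size of the GO term pool.
#' @param n_slims number of slim categories.
#' @param max_terms maximum GO terms per subject.
#' @param seed RNG seed.
#' @return list with `subject_map` (subject_id, go, ec, kegg), `slim_map`
#'   (go, slim, ontology) and `term_long` (subject_id, term).
#' @export
simulate_annotations <- function(subject_ids, n_go = 30, n_slims = 6,
                                 max_terms = 3, seed = 1) {
  set.seed(seed)
  go_pool <- sprintf("GO:%07d", seq_len(n_go))
  slims <- sprintf("GO:%07d", 1000000 + seq_len(n_slims))
  slim_map <- data.frame(
    go = go_pool,
    slim = slims[(seq_len(n_go) - 1L) %% n_slims + 1L],
    ontology = rep(c("biological_process", "molecular_function"),
                   length.out = n_slims)[(seq_len(n_go) - 1L) %% n_slims + 1L],
    stringsAsFactors = FALSE)
  per <- sample.int(max_terms, length(subject_ids), replace = TRUE)
  gos <- lapply(per, function(k) sample(go_pool, k))
  subject_map <- data.frame(
    subject_id = subject_ids,
    go = vapply(gos, paste, character(1), collapse = ";"),
    ec = ifelse(runif(length(subject_ids)) < 0.5,
                sprintf("EC:1.1.1.%d", sample.int(99, length(subject_ids),
                                                  replace = TRUE)), ""),
    kegg = ifelse(runif(length(subject_ids)) < 0.5,
                  sprintf("ko:K%05d", sample.int(999, length(subject_ids),
                                                 replace = TRUE)), ""),
    stringsAsFactors = FALSE)
  term_long <- data.frame(
    subject_id = rep(subject_ids, lengths(gos)),
    term = unlist(gos), stringsAsFactors = FALSE)
  list(subject_map = subject_map, slim_map = slim_map,
       term_long = term_long)
}

#' Write / read a truth object as JSON
#' @param truth a `sim_truth` object.
#' @param path file path.
#' @return `read_truth`: the reloaded truth list.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "sim_truth")
}
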