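# Readers/writers for the on-disk formats the pipeline touches.
#
# Sequences are upper-cased on read and U is normalized to T so one internal
# alphabet is used everywhere. Quality strings decode to integer phred scores
# at an explicit offset (33 for modern FASTQ, 64 for the qseq era).

normalize_seq <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

#' Decode / encode phred quality strings
#'
#' @param qual character vector of quality strings.
#' @param q list of integer phred vectors.
#' @param offset ASCII offset, 33 or 64.
#' @return `phred_decode`: a list of integer vectors; `phred_encode`: a
#'   character vector.
#' @export
phred_decode <- function(qual, offset = 33L) {
  lapply(qual, function(s) utf8ToInt(s) - as.integer(offset))
}

#' @rdname phred_decode
#' @export
phred_encode <- function(q, offset = 33L) {
  vapply(q, function(v) intToUtf8(v + as.integer(offset)), character(1))
}

#' Read and write FASTA files
#'
#' `read_fasta()` returns one row per entry with the first whitespace token
#' of the header as `id` and the remainder as `description`. `write_fasta()`
#' wraps sequence lines at `width` columns.
#'
#' @param path file path (plain or gzip).
#' @param records data.frame with columns `id`, `sequence` and optionally
#'   `description`.
#' @param width line-wrap width on write.
#' @return `read_fasta`: data.frame with columns `id`, `sequence`,
#'   `description`.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  # read as raw strings first: RNA letters (u/U) are normalized to T below,
  # which a DNA-typed reader would reject or drop
  x <- Biostrings::readBStringSet(path, format = "fasta")
  hdr <- names(x)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  if (anyDuplicated(id))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  data.frame(id = id, sequence = normalize_seq(as.character(x)),
             description = desc, stringsAsFactors = FALSE)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else
    rep("", nrow(records))
  x <- Biostrings::DNAStringSet(records$sequence)
  names(x) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(x, path, format = "fasta", width = as.integer(width))
  invisible(path)
}

#' Paired-end read container
#'
#' A `read_pairs` object holds two parallel mates per fragment: a shared pair
#' id, both mate sequences, and both mates' integer phred vectors (one list
#' element per read, same length as its sequence).
#'
#' @param id character vector of pair identifiers.
#' @param seq1,seq2 character vectors of mate sequences.
#' @param qual1,qual2 lists of integer phred vectors.
#' @param pass_filter optional logical vector (qseq chastity flag).
#' @return an object of class `read_pairs`.
#' @export
read_pairs <- function(id, seq1, seq2, qual1, qual2, pass_filter = NULL) {
  n <- length(id)
  stopifnot(length(seq1) == n, length(seq2) == n,
            length(qual1) == n, length(qual2) == n)
  ok1 <- nchar(seq1) == lengths(qual1)
  ok2 <- nchar(seq2) == lengths(qual2)
  if (!all(ok1 & ok2)) {
    bad <- which(!(ok1 & ok2))[1]
    stop("sequence/quality length mismatch for pair '", id[bad],
         "' (record ", bad, ")")
  }
  structure(list(id = as.character(id),
                 seq1 = as.character(seq1), seq2 = as.character(seq2),
                 qual1 = lapply(unname(qual1), as.integer),
                 qual2 = lapply(unname(qual2), as.integer),
                 pass_filter = if (is.null(pass_filter)) rep(TRUE, n)
                               else as.logical(pass_filter)),
            class = "read_pairs")
}

#' @export
length.read_pairs <- function(x) length(x$id)

#' @export
print.read_pairs <- function(x, ...) {
  cat("read_pairs:", length(x), "pairs; mate lengths",
      paste(range(c(nchar(x$seq1), nchar(x$seq2))), collapse = "-"), "bp\n")
  invisible(x)
}

subset_pairs <- function(x, i) {
  read_pairs(x$id[i], x$seq1[i], x$seq2[i], x$qual1[i], x$qual2[i],
             x$pass_filter[i])
}

#' Read paired FASTQ files
#'
#' Mates are matched by record order across the two files; differing record
#' counts are an error.
#'
#' @param path1,path2 R1 / R2 FASTQ paths.
#' @param offset quality ASCII offset, 33 (default for FASTQ) or 64.
#' @return a [read_pairs] object.
#' @export
read_pairs_fastq <- function(path1, path2, offset = 33L) {
  r1 <- read_fastq_one(path1, offset)
  r2 <- read_fastq_one(path2, offset)
  if (length(r1$id) != length(r2$id))
    stop("mate files differ in record count: ", length(r1$id), " vs ",
         length(r2$id))
  read_pairs(r1$id, r1$seq, r2$seq, r1$qual, r2$qual)
}

read_fastq_one <- function(path, offset = 33L) {
  stopifnot(file.exists(path), offset %in% c(33L, 64L))
  scoring <- if (offset == 33L) "phred" else "illumina"
  # Biostrings warns about dropped metadata columns during the quality
  # conversion; nothing we keep is affected
  x <- suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = scoring))
  qual <- suppressWarnings(
    lapply(as(Biostrings::quality(x), "IntegerList"), as.integer))
  list(id = sub("\\s.*$", "", names(x)),
       seq = suppressWarnings(normalize_seq(as.character(x))),
       qual = unname(qual))
}

#' Write paired FASTQ files
#'
#' Round-trips [read_pairs_fastq()]: records come back field-for-field.
#'
#' @param pairs a [read_pairs] object.
#' @param path1,path2 output paths.
#' @param offset quality ASCII offset on write.
#' @export
write_pairs_fastq <- function(pairs, path1, path2, offset = 33L) {
  write_fastq_one(pairs$id, pairs$seq1, pairs$qual1, path1, offset)
  write_fastq_one(pairs$id, pairs$seq2, pairs$qual2, path2, offset)
  invisible(c(path1, path2))
}

write_fastq_one <- function(id, seq, qual, path, offset = 33L) {
  qs <- phred_encode(qual, offset)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", id, "\n", seq, "\n+\n", qs), con)
  invisible(path)
}

#' Read paired qseq files
#'
#' Accepts the 10- and 11-field tab-separated qseq dialects (field 9 =
#' sequence, field 10 = quality, optional field 11 = pass-filter flag).
#' Uncalled bases ('.') become N. Pairs failing the chastity filter are kept
#' but flagged via `pass_filter`.
#'
#' @param path1,path2 mate files.
#' @param offset quality ASCII offset; the qseq era encoded phred+64.
#' @return a [read_pairs] object.
#' @export
read_pairs_qseq <- function(path1, path2, offset = 64L) {
  r1 <- read_qseq_one(path1, offset)
  r2 <- read_qseq_one(path2, offset)
  if (length(r1$id) != length(r2$id))
    stop("mate files differ in record count: ", length(r1$id), " vs ",
         length(r2$id))
  read_pairs(r1$id, r1$seq, r2$seq, r1$qual, r2$qual,
             pass_filter = r1$pass & r2$pass)
}

read_qseq_one <- function(path, offset = 64L) {
  stopifnot(file.exists(path))
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 10L | nf > 11L))
    stop("malformed qseq line ", which(nf < 10L | nf > 11L)[1], " in ", path,
         ": expected 10 or 11 tab-separated fields")
  id <- vapply(fields, function(f)
    paste(f[1:6], collapse = ":"), character(1))
  seq <- normalize_seq(chartr(".", "N", vapply(fields, `[[`, character(1), 9L)))
  qual <- phred_decode(vapply(fields, `[[`, character(1), 10L), offset)
  bad <- which(nchar(seq) != lengths(qual))
  if (length(bad))
    stop("sequence/quality length mismatch at qseq line ", bad[1], " in ", path)
  pass <- vapply(fields, function(f)
    if (length(f) == 11L) f[[11L]] == "1" else TRUE, logical(1))
  list(id = id, seq = seq, qual = qual, pass = pass)
}

#' Write paired qseq files
#'
#' Emits 11-field qseq lines (machine, run, lane, tile, x, y, index, read
#' number, sequence, quality, pass-filter flag) with the pair index as the
#' x coordinate, so [read_pairs_qseq()] round-trips the pairing.
#'
#' @param pairs a [read_pairs] object.
#' @param path1,path2 output paths.
#' @param offset quality ASCII offset on write (qseq era: 64).
#' @export
write_pairs_qseq <- function(pairs, path1, path2, offset = 64L) {
  n <- length(pairs)
  flag <- ifelse(pairs$pass_filter, "1", "0")
  one <- function(seq, qual, readno, path) {
    lines <- paste("SIM", "1", "1", "1", seq_len(n), "0", "0", readno,
                   seq, phred_encode(qual, offset), flag, sep = "\t")
    writeLines(lines, path)
  }
  one(pairs$seq1, pairs$qual1, "1", path1)
  one(pairs$seq2, pairs$qual2, "2", path2)
  invisible(c(path1, path2))
}

#' Read a 12-column tabular similarity-hit file
#'
#' The standard tabular output of common similarity-search tools: query,
#' subject, percent identity, alignment length, mismatches, gap opens,
#' qstart, qend, sstart, send, e-value, bitscore. Lines starting with `#`
#' are skipped.
#'
#' @param path tab-separated file.
#' @return data.frame with typed columns, one row per hit.
#' @export
read_hits <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  cols <- c("query_id", "subject_id", "pct_identity", "aln_len", "mismatches",
            "gap_opens", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore")
  if (!any(keep)) {
    out <- as.data.frame(setNames(
      c(list(character(), character()),
        replicate(10, numeric(), simplify = FALSE)),
      cols), stringsAsFactors = FALSE)
    return(out)
  }
  nf <- vapply(strsplit(lines[keep], "\t", fixed = TRUE), length, integer(1))
  if (any(nf != 12L))
    stop("hit file ", path, ": line ", which(keep)[nf != 12L][1],
         " has ", nf[nf != 12L][1], " tab-separated columns, expected 12")
  dt <- data.table::fread(text = lines[keep], sep = "\t", header = FALSE,
                          col.names = cols,
                          colClasses = list(character = 1:2, numeric = 3:12),
                          data.table = FALSE)
  num <- dt[, 3:12]
  if (anyNA(num))
    stop("hit file ", path, ": unparseable numeric field(s) in row ",
         which(rowSums(is.na(num)) > 0)[1])
  for (cc in c("aln_len", "mismatches", "gap_opens", "qstart", "qend",
               "sstart", "send"))
    dt[[cc]] <- as.integer(dt[[cc]])
  if (any(dt$aln_len < 1L)) stop("hit with alignment length < 1")
  if (any(dt$evalue < 0)) stop("hit with negative e-value")
  dt
}

#' Write hits in the 12-column tabular format
#' @param hits data.frame as returned by [read_hits()].
#' @param path output path.
#' @export
write_hits <- function(hits, path) {
  data.table::fwrite(hits, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
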