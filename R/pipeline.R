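# End-to-end pipeline: filter -> k-mer sweep assembly -> identity cascade
# and terminal-overlap merging -> best-hit grouping -> annotation ->
# mapping/RPKM/fold classes -> SSR & GC reports -> enrichment, with a
# manifest of input hashes and effective parameters.

#' Pipeline configuration
#'
#' Defaults mirror the study settings the toolkit is built around: 3-base
#' 3' trimming, k-mer sweep 19-29 step 2, 100 bp contig cutoff, 0.95/0.90
#' clustering cascade, 40 bp / 90 percent terminal-overlap merging, 1e-5
#' grouping and 1e-1 annotation e-value cutoffs, 2-mismatch mapping, alpha
#' 0.05.
#'
#' @param ... overrides of the defaults listed above (unknown keys are
#'   rejected).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    quality_offset = 33L,
    tail_trim = 3L,
    mean_quality_cutoff = 20,
    min_read_len = 20L,
    kmer_filter = FALSE,
    kmer_k = 23L,
    kmer_min_freq = 2L,
    adapters = character(),
    k_values = seq(19L, 29L, by = 2L),
    assembly_min_count = 2L,
    assembly_min_len = 100L,
    cascade = c(0.95, 0.90),
    merge_min_overlap = 40L,
    merge_min_identity = 0.90,
    group_evalue = 1e-5,
    annot_evalue = 1e-1,
    max_mismatches = 2L,
    alpha = 0.05)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(defaults))
  if (length(unknown))
    stop("unknown pipeline_config key(s): ", paste(unknown, collapse = ", "))
  structure(modifyList(defaults, ov), class = "pipeline_config")
}

write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Run the full pipeline on paired-end reads
#'
#' Stages run in workflow order; every artifact is written into `out_dir`
#' together with a JSON manifest of input checksums, effective parameters
#' and per-stage counts. Reruns with identical inputs, config and seed are
#' byte-identical.
#'
#' @param inputs list with `reads_a` and `reads_b` (each `c(R1, R2)` FASTQ
#'   paths, or qseq when `format = "qseq"`), optional `format`, `hits`
#'   (12-column hit table path), `subject_map` and `slim_map` (annotation
#'   tables).
#' @param out_dir output directory (created).
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(inputs, out_dir, config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  cat("", file = logf)
  t0 <- proc.time()[["elapsed"]]
  say <- function(...) {
    # elapsed seconds only, so identical reruns differ in no artifact but
    # the timing column of this log
    cat(sprintf("[%8.2fs] ", proc.time()[["elapsed"]] - t0), paste0(...),
        "\n", file = logf, append = TRUE)
  }
  counts <- list()
  fmt <- if (is.null(inputs$format)) "fastq" else inputs$format

  read_cond <- function(paths) {
    if (fmt == "qseq")
      read_pairs_qseq(paths[1], paths[2],
                      offset = if (config$quality_offset == 33L) 64L
                               else config$quality_offset)
    else read_pairs_fastq(paths[1], paths[2], offset = config$quality_offset)
  }

  say("stage filter")
  fc <- filter_config(tail_trim = config$tail_trim,
                      mean_quality_cutoff = config$mean_quality_cutoff,
                      adapters = config$adapters,
                      kmer_filter = config$kmer_filter,
                      kmer_k = config$kmer_k,
                      kmer_min_freq = config$kmer_min_freq,
                      min_read_len = config$min_read_len)
  filt <- lapply(list(a = inputs$reads_a, b = inputs$reads_b),
                 function(p) filter_pairs(read_cond(p), fc))
  for (cond in names(filt)) {
    write_pairs_fastq(filt[[cond]]$pairs,
                      file.path(out_dir, paste0("filtered_", cond, "_R1.fastq")),
                      file.path(out_dir, paste0("filtered_", cond, "_R2.fastq")),
                      offset = 33L)
    rep <- filt[[cond]]$report
    counts[[paste0("pairs_in_", cond)]] <- rep$pairs_in
    counts[[paste0("pairs_out_", cond)]] <- rep$pairs_out
    jsonlite::write_json(
      rep[c("pairs_in", "pairs_out", "dropped_by_length",
            "dropped_by_adapter", "dropped_by_quality",
            "dropped_by_kmer_freq")],
      file.path(out_dir, paste0("filter_report_", cond, ".json")),
      auto_unbox = TRUE)
  }

  say("stage assemble (k-mer sweep)")
  reads_pool <- c(filt$a$pairs$seq1, revcomp(filt$a$pairs$seq2),
                  filt$b$pairs$seq1, revcomp(filt$b$pairs$seq2))
  sweep <- kmer_sweep(reads_pool, config$k_values,
                      min_count = config$assembly_min_count,
                      min_len = config$assembly_min_len)
  write_tsv(sweep$stats, file.path(out_dir, "assembly_stats.tsv"))
  for (kk in names(sweep$assemblies))
    write_fasta(sweep$assemblies[[kk]],
                file.path(out_dir, paste0("assembly_k", kk, ".fasta")))
  contigs <- sweep$assemblies[[as.character(sweep$chosen_k)]]
  counts$chosen_k <- sweep$chosen_k
  counts$contigs <- nrow(contigs)

  say("stage cluster (cascade ", paste(config$cascade, collapse = "/"), ")")
  casc <- cluster_cascade(contigs, thresholds = config$cascade)
  write_tsv(casc, file.path(out_dir, "clusters.tsv"))
  reps <- contigs[contigs$id %in% unique(casc$representative_id), ,
                  drop = FALSE]
  merged <- merge_terminal_overlaps(reps,
                                    min_overlap = config$merge_min_overlap,
                                    min_identity = config$merge_min_identity)
  write_fasta(cbind(merged$seqs, description = ""),
              file.path(out_dir, "transcripts.fasta"))
  write_tsv(merged$log, file.path(out_dir, "merge_log.tsv"))
  transcripts <- merged$seqs
  counts$clustered <- nrow(reps)
  counts$transcripts <- nrow(transcripts)

  groups <- NULL
  annots <- NULL
  if (!is.null(inputs$hits)) {
    say("stage group (best hits)")
    hits <- read_hits(inputs$hits)
    best <- select_best_hit(hits, evalue_cutoff = config$group_evalue)
    groups <- group_by_subject(best, transcripts)
    write_tsv(groups$table, file.path(out_dir, "groups.tsv"))
    writeLines(groups$ungrouped, file.path(out_dir, "ungrouped.txt"))
    counts$groups <- nrow(groups$table)
    counts$ungrouped <- length(groups$ungrouped)
    stopifnot(sum(groups$table$n_members) + length(groups$ungrouped) ==
                nrow(transcripts))
    if (!is.null(inputs$subject_map)) {
      say("stage annotate")
      smap <- read_subject_map(inputs$subject_map)
      best_ann <- select_best_hit(hits, evalue_cutoff = config$annot_evalue)
      annots <- transfer_annotations(best_ann, smap)
      write_tsv(annots, file.path(out_dir, "annotations.tsv"))
      if (!is.null(inputs$slim_map)) {
        slim <- data.table::fread(inputs$slim_map, sep = "\t",
                                  header = FALSE, data.table = FALSE)
        names(slim) <- c("go", "slim", "ontology")[seq_len(ncol(slim))]
        write_tsv(classify_go_slim(annots, slim),
                  file.path(out_dir, "go_slim_counts.tsv"))
      }
    }
  }

  say("stage expression (mapping + RPKM)")
  map_a <- map_reads(c(filt$a$pairs$seq1, filt$a$pairs$seq2), transcripts,
                     max_mismatches = config$max_mismatches)
  map_b <- map_reads(c(filt$b$pairs$seq1, filt$b$pairs$seq2), transcripts,
                     max_mismatches = config$max_mismatches)
  expr <- NULL
  if (sum(map_a$unique) > 0 && sum(map_b$unique) > 0) {
    expr <- quantify_rpkm(map_a, map_b, groups, transcripts)
    fc2 <- fold_classes(expr)
    write_tsv(fc2$records, file.path(out_dir, "expression.tsv"))
    counts$genes_quantified <- nrow(fc2$records)
    if (!is.null(annots)) {
      say("stage enrichment (two-fold sets)")
      term_long <- with(annots, data.frame(
        gene_id = rep(gene_id, lengths(split_terms(go))),
        term = unlist(split_terms(go)), stringsAsFactors = FALSE))
      pop <- unique(fc2$records$gene_id)
      for (side in c("a", "b")) {
        st <- intersect(fc2[[paste0("two_fold_", side)]], pop)
        if (length(st))
          write_tsv(enrich_terms(st, pop, term_long, alpha = config$alpha),
                    file.path(out_dir, paste0("enrichment_", side, ".tsv")))
      }
    }
  }

  say("stage markers (SSR + GC)")
  ssrs <- find_ssrs(transcripts)
  write_tsv(ssrs, file.path(out_dir, "ssr.tsv"))
  ssum <- ssr_summary(ssrs)
  jsonlite::write_json(list(total = ssum$total, by_class = ssum$by_class),
                       file.path(out_dir, "ssr_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  gp <- gc_profile(transcripts)
  jsonlite::write_json(list(mean_pct = gp$mean_pct,
                            histogram = gp$histogram),
                       file.path(out_dir, "gc_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  counts$ssrs <- nrow(ssrs)
  counts$gc_mean_pct <- gp$mean_pct

  say("write manifest")
  in_files <- unlist(inputs[names(inputs) != "format"], use.names = FALSE)
  manifest <- list(
    version = 1L,
    inputs = lapply(setNames(in_files, in_files),
                    function(f) unname(tools::md5sum(f))),
    config = unclass(config),
    counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done")
  invisible(list(filter = filt, sweep = sweep, transcripts = transcripts,
                 groups = groups, annotations = annots, expression = expr,
                 ssrs = ssrs, gc = gp, manifest = manifest))
}
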