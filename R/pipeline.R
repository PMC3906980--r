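# Orchestration: dataset simulation to disk, configuration validation,
# and the full filter -> map -> classify -> rarefy -> count -> DE ->
# cross-platform -> novel-region -> miRNA-annotation run with TSV/GFF3/BED
# outputs and a checksummed manifest.

#' Write a complete synthetic dataset to disk
#'
#' Genome FASTA, annotation GFF3, truth tables (TSV), a known-mature
#' catalog built from the planted miRNA loci, a simulated microarray
#' table, and two FASTQ files (poly-A+ and sRNA) for each of the four
#' samples (2 conditions x 2 replicates).
#'
#' @param spec a [genome_spec()].
#' @param out_dir output directory.
#' @param force overwrite a non-empty directory.
#' @return the dataset directory path, invisibly.
#' @export
simulate_dataset <- function(spec, out_dir, force = FALSE) {
  stopifnot(inherits(spec, "genome_spec"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force)
    stopf("output directory %s is not empty (use force = TRUE)", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gen <- make_genome(spec)
  counts <- simulate_counts(gen$truth, n_replicates = 2L, spec)
  reads <- simulate_reads(gen$genome, gen$annotation, gen$truth, counts,
                          spec)
  Biostrings::writeXStringSet(gen$genome, file.path(out_dir, "genome.fasta"))
  write_annotation_gff3(gen$annotation,
                        file.path(out_dir, "annotation.gff3"))
  w <- function(df, f) utils::write.table(
    df, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  w(gen$truth$genes, "truth_genes.tsv")
  w(gen$truth$clusters, "truth_clusters.tsv")
  w(gen$truth$mirna, "truth_mirna.tsv")
  if (nrow(gen$truth$mirna))
    w(data.frame(name = gen$truth$mirna$name,
                 sequence = chartr("T", "U", gen$truth$mirna$mature_seq)),
      "known_srna_catalog.tsv")
  w(simulate_array_table(gen$truth, spec), "array_table.tsv")
  for (s in names(reads)) {
    write_fastq(reads[[s]]$polya,
                file.path(out_dir, sprintf("%s_polyA.fastq", s)))
    write_fastq(reads[[s]]$srna,
                file.path(out_dir, sprintf("%s_sRNA.fastq", s)))
  }
  invisible(out_dir)
}

#' Pipeline configuration
#'
#' @param data_dir directory produced by [simulate_dataset()] (or laid
#'   out identically: genome.fasta, annotation.gff3, per-sample
#'   `<sample>_polyA.fastq` / `<sample>_sRNA.fastq`, optional
#'   known_srna_catalog.tsv and array_table.tsv).
#' @param out_dir directory for pipeline outputs.
#' @param samples sample names; conditions are taken from the prefix
#'   before the last underscore (KCl_1 ... KNO3_2 by default).
#' @param min_cluster_len minimum novel-cluster span (bases).
#' @param alpha FDR threshold for differential calls.
#' @param agc_thresholds AGC grid for the platform-concordance curve.
#' @param read_length_mrna nominal poly-A+ read length (AGC numerator).
#' @param adaptor 3' adaptor for trimming.
#' @param seed seed for the rarefaction subsampling.
#' @return validated object of class `pipeline_config`.
#' @export
pipeline_config <- function(data_dir, out_dir,
                            samples = c("KCl_1", "KCl_2",
                                        "KNO3_1", "KNO3_2"),
                            min_cluster_len = 300L, alpha = 0.05,
                            agc_thresholds = c(0, 0.2, 0.4, 0.8, 1.6, 3.2),
                            read_length_mrna = 50L,
                            adaptor = "CTGTAGGCACCATCAAT",
                            seed = 1L) {
  req <- c("genome.fasta", "annotation.gff3",
           sprintf("%s_polyA.fastq", samples),
           sprintf("%s_sRNA.fastq", samples))
  missing <- req[!file.exists(file.path(data_dir, req))]
  if (length(missing))
    stopf("missing input file(s): %s", paste(missing, collapse = ", "))
  if (min_cluster_len <= 0 || alpha <= 0)
    stopf("thresholds must be positive")
  structure(list(data_dir = data_dir, out_dir = out_dir, samples = samples,
                 conditions = factor(sub("_[^_]+$", "", samples)),
                 min_cluster_len = as.integer(min_cluster_len),
                 alpha = alpha, agc_thresholds = agc_thresholds,
                 read_length_mrna = as.integer(read_length_mrna),
                 adaptor = adaptor, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages, in order: read filtering (both libraries), perfect-match
#' mapping, genomic-origin classification (all and unique scope),
#' sRNA size distribution, known-sRNA detection, rarefaction, gene
#' counting, NB differential expression with BH calling, replicate
#' correlation QC, AGC/array concordance (when an array table is
#' present), novel transcribed-region discovery and quantification with
#' end-to-end DE on clusters, and miRNA-locus context annotation of the
#' planted loci.  Every stage writes TSV/GFF3/BED outputs under
#' `cfg$out_dir` and is checksummed in the returned manifest.
#'
#' @param cfg a [pipeline_config()].
#' @return the run manifest (list with the config, per-file md5 checksums
#'   and a per-stage log), invisibly; written as manifest.tsv.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character()
  note <- function(fmt, ...) {
    log <<- c(log, sprintf(fmt, ...))
    message(log[length(log)])
  }
  out <- function(f) file.path(cfg$out_dir, f)
  w <- function(df, f) utils::write.table(df, out(f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)

  note("stage filter: processing %d samples", length(cfg$samples))
  cfg_polya <- filter_config("polyA", adaptor = cfg$adaptor)
  cfg_srna <- filter_config("sRNA", adaptor = cfg$adaptor)
  polya_sets <- srna_sets <- list()
  for (s in cfg$samples) {
    polya_sets[[s]] <- process_reads(
      read_fastq(file.path(cfg$data_dir, sprintf("%s_polyA.fastq", s))),
      cfg_polya)
    srna_sets[[s]] <- process_reads(
      read_fastq(file.path(cfg$data_dir, sprintf("%s_sRNA.fastq", s))),
      cfg_srna)
  }
  fstats <- rbind(filter_stats(polya_sets), filter_stats(srna_sets))
  w(fstats, "filter_stats.tsv")

  note("stage map: building index and mapping")
  idx <- build_index(file.path(cfg$data_dir, "genome.fasta"))
  ann <- read_annotation_gff3(file.path(cfg$data_dir, "annotation.gff3"))
  polya_aln <- lapply(polya_sets, map_reads, index = idx)
  srna_aln <- lapply(srna_sets, map_reads, index = idx)
  for (s in cfg$samples)
    export_bed(polya_aln[[s]], out(sprintf("%s_polyA.bed", s)))

  note("stage classify: weighted category breakdowns")
  pooled_srna_aln <- list(alignments =
    do.call(rbind, lapply(srna_aln, `[[`, "alignments")))
  class(pooled_srna_aln) <- "alignment_set"
  pooled_polya_aln <- list(alignments =
    do.call(rbind, lapply(polya_aln, `[[`, "alignments")))
  class(pooled_polya_aln) <- "alignment_set"
  w(weighted_category_counts(pooled_srna_aln, ann, "all"),
    "breakdown_sRNA_all.tsv")
  w(weighted_category_counts(pooled_polya_aln, ann, "all"),
    "breakdown_polyA_all.tsv")
  w(weighted_category_counts(pooled_polya_aln, ann, "unique"),
    "breakdown_polyA_unique.tsv")
  for (s in cfg$samples)
    w(size_distribution(srna_sets[[s]]),
      sprintf("size_distribution_%s.tsv", s))

  cat_path <- file.path(cfg$data_dir, "known_srna_catalog.tsv")
  if (file.exists(cat_path)) {
    catalog <- read_srna_catalog(cat_path)
    pooled_seqs <- stats::aggregate(
      count ~ seq, do.call(rbind, lapply(srna_sets, `[[`, "sequences")),
      sum)
    ks <- known_srna_expression(pooled_seqs, catalog)
    w(ks$table, "known_srna_expression.tsv")
    note("stage classify: %d of %d catalog entries detected (%d families)",
         ks$n_detected, nrow(ks$table), ks$n_families_detected)
  }

  note("stage rarefy: rarefaction curves")
  for (s in cfg$samples) {
    cur <- rarefaction_curve(srna_sets[[s]], seed = cfg$seed)
    w(cur, sprintf("rarefaction_sRNA_%s.tsv", s))
    note("stage rarefy: %s saturation ratio %.3f", s,
         saturation_assessment(cur))
  }

  note("stage counts/DE: gene-level differential expression")
  gc <- gene_counts(polya_aln, ann)
  sf <- size_factors(gc)
  rc <- replicate_correlation(gc, cfg$conditions, sf)
  note("stage QC: replicate correlations %s",
       paste(sprintf("%s=%.3f", names(rc), rc), collapse = ", "))
  de <- adjust_and_call(nb_exact_test(gc, cfg$conditions, sf),
                        alpha = cfg$alpha)
  w(de, "differential_genes.tsv")
  note("stage DE: %d induced, %d repressed at FDR %g",
       sum(de$call == "induced"), sum(de$call == "repressed"), cfg$alpha)

  arr_path <- file.path(cfg$data_dir, "array_table.tsv")
  if (file.exists(arr_path)) {
    note("stage xplatform: AGC-stratified array concordance")
    arr <- read_array_table(arr_path)
    glen <- stats::setNames(IRanges::width(ann$genes),
                            S4Vectors::mcols(ann$genes)$gene_id)
    total_counts <- rowSums(gc[S4Vectors::mcols(ann$genes)$gene_id, ,
                               drop = FALSE])
    agc <- compute_agc(total_counts, glen, cfg$read_length_mrna)
    w(agc, "agc.tsv")
    sig <- as.matrix(arr[grep("^signal_", names(arr))])
    is_kno3 <- grepl("^signal_KNO3", colnames(sig))
    arr_ratio <- stats::setNames(rowMeans(sig[, is_kno3, drop = FALSE]) -
                                   rowMeans(sig[, !is_kno3, drop = FALSE]),
                                 arr$gene_id)
    seq_ratio <- stats::setNames(de$log2_ratio, de$id)
    seq_ratio <- seq_ratio[!is.na(seq_ratio)]
    curve <- ratio_correlation_by_agc(seq_ratio, arr_ratio, agc,
                                      cfg$agc_thresholds)
    w(curve, "agc_correlation.tsv")
    det <- detection_comparison(arr, total_counts)
    w(data.frame(metric = names(det), value = unlist(det)),
      "detection_comparison.tsv")
  }

  note("stage novel: transcribed-region discovery")
  pooled <- pool_unannotated(polya_aln, ann)
  clusters <- classify_clusters(
    call_clusters(pooled, min_length = cfg$min_cluster_len), ann)
  export_clusters_gff3(clusters, out("novel_clusters.gff3"))
  export_clusters_bed(clusters, out("novel_clusters.bed"))
  if (nrow(clusters)) {
    cc <- cluster_counts(clusters, polya_aln)
    de_cl <- adjust_and_call(nb_exact_test(cc, cfg$conditions, sf),
                             alpha = cfg$alpha)
    w(de_cl, "differential_clusters.tsv")
    note("stage novel: %d clusters (%d antisense), %d differential",
         nrow(clusters), sum(clusters$relation == "antisense_to"),
         sum(de_cl$call != "unchanged"))
  }

  truth_mirna <- file.path(cfg$data_dir, "truth_mirna.tsv")
  if (file.exists(truth_mirna)) {
    note("stage mirna: genomic-context annotation")
    loci <- utils::read.delim(truth_mirna, stringsAsFactors = FALSE)
    if (nrow(loci)) {
      loci$mature_sequence <- loci$mature_seq
      # the planted loci are the predictions under annotation here, so no
      # precursor is "known": contexts resolve to intron/intergenic
      anno <- classify_mirna_loci(
        loci[c("name", "chrom", "strand", "start", "end",
               "mature_sequence")], ann,
        known_stem_loops = GenomicRanges::GRanges())
      w(anno, "mirna_contexts.tsv")
      export_mirna_gff3(anno, out("mirna_loci.gff3"))
    }
  }

  writeLines(log, out("run.log"))
  files <- sort(setdiff(list.files(cfg$out_dir), "manifest.tsv"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(cfg$out_dir, files))),
    stringsAsFactors = FALSE)
  w(manifest, "manifest.tsv")
  invisible(list(config = cfg, checksums = manifest, log = log))
}
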