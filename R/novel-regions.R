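# Discovery of candidate novel transcribed regions: pool unannotated
# uniquely mapping poly-A+ alignments across samples, call same-strand
# zero-gap clusters of at least 300 bp, classify each as intergenic or
# antisense to a gene (NAT), and quantify clusters for DE testing.

#' Pool unannotated unique alignments across samples
#'
#' Retains uniquely mapping alignments with zero same-strand overlap with
#' any annotated feature.  Overlap with a feature on the opposite strand
#' does not exclude a read -- that is precisely what allows natural
#' antisense transcripts to be discovered.
#'
#' @param aln_by_sample named list of `alignment_set`s (or alignment data
#'   frames), one per sample.
#' @param ann an [annotation_set()].
#' @return data frame of pooled alignments (columns `seq`, `count`,
#'   `chrom`, `start`, `end`, `strand`, `n_loci`, `sample`).
#' @export
pool_unannotated <- function(aln_by_sample, ann) {
  stopifnot(inherits(ann, "annotation_set"))
  rows <- lapply(names(aln_by_sample), function(s) {
    a <- unique_alignments(aln_by_sample[[s]])
    if (!nrow(a)) return(NULL)
    a$sample <- s
    gr <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start, a$end),
                                 strand = a$strand)
    ov <- GenomicRanges::findOverlaps(gr, ann$features,
                                      ignore.strand = FALSE)
    hit <- unique(S4Vectors::queryHits(ov))
    a[setdiff(seq_len(nrow(a)), hit), , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(seq = character(), count = integer(),
                      chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_loci = integer(), sample = character())
  rownames(out) <- NULL
  out
}

#' Call transcribed clusters from pooled alignments
#'
#' Per chromosome and strand, maximal runs of overlapping or abutting
#' alignments (gaps up to `max_gap` bases are bridged; the default 0
#' requires zero-gap coverage) whose span reaches `min_length`.  Span
#' endpoints are the outermost read edges.
#'
#' @param pooled data frame from [pool_unannotated()].
#' @param min_length minimum cluster span in bases (inclusive,
#'   default 300 -- just above the genome's average exon length).
#' @param max_gap largest coverage gap bridged within a cluster.
#' @return data frame of clusters (columns `cluster_id`, `chrom`,
#'   `start`, `end`, `strand`, `span`).
#' @export
call_clusters <- function(pooled, min_length = 300L, max_gap = 0L) {
  if (!nrow(pooled))
    return(data.frame(cluster_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), span = integer()))
  gr <- GenomicRanges::GRanges(pooled$chrom,
                               IRanges::IRanges(pooled$start, pooled$end),
                               strand = pooled$strand)
  red <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1L,
                               ignore.strand = FALSE)
  red <- red[IRanges::width(red) >= min_length]
  red <- sort(red, ignore.strand = TRUE)
  data.frame(cluster_id = sprintf("NTR%03d", seq_along(red)),
             chrom = as.character(GenomicRanges::seqnames(red)),
             start = IRanges::start(red), end = IRanges::end(red),
             strand = as.character(GenomicRanges::strand(red)),
             span = IRanges::width(red), stringsAsFactors = FALSE)
}

#' Classify clusters as antisense or intergenic
#'
#' A cluster overlapping a gene span on the opposite strand is
#' `antisense_to` that gene (the longest-overlap gene on ties); otherwise
#' it is `intergenic` and the nearest upstream/downstream gene ids are
#' recorded as flanks.
#'
#' @param clusters data frame from [call_clusters()].
#' @param ann an [annotation_set()].
#' @return `clusters` with extra columns `relation`, `antisense_gene`,
#'   `flank_upstream`, `flank_downstream`.
#' @export
classify_clusters <- function(clusters, ann) {
  stopifnot(inherits(ann, "annotation_set"))
  n <- nrow(clusters)
  clusters$relation <- rep("intergenic", n)
  clusters$antisense_gene <- NA_character_
  clusters$flank_upstream <- NA_character_
  clusters$flank_downstream <- NA_character_
  if (!n) return(clusters)
  g <- ann$genes
  gid <- S4Vectors::mcols(g)$gene_id
  cg <- GenomicRanges::GRanges(clusters$chrom,
                               IRanges::IRanges(clusters$start,
                                                clusters$end),
                               strand = clusters$strand)
  flip <- cg
  GenomicRanges::strand(flip) <-
    ifelse(clusters$strand == "+", "-", "+")
  ov <- GenomicRanges::findOverlaps(flip, g, ignore.strand = FALSE)
  if (length(ov)) {
    inter <- GenomicRanges::pintersect(cg[S4Vectors::queryHits(ov)],
                                       g[S4Vectors::subjectHits(ov)],
                                       ignore.strand = TRUE)
    ow <- IRanges::width(inter)
    for (q in unique(S4Vectors::queryHits(ov))) {
      sel <- which(S4Vectors::queryHits(ov) == q)
      best <- sel[which.max(ow[sel])]
      clusters$relation[q] <- "antisense_to"
      clusters$antisense_gene[q] <- gid[S4Vectors::subjectHits(ov)[best]]
    }
  }
  inter_rows <- which(clusters$relation == "intergenic")
  for (q in inter_rows) {
    same_chr <- as.character(GenomicRanges::seqnames(g)) ==
      clusters$chrom[q]
    up <- which(same_chr & IRanges::end(g) < clusters$start[q])
    dn <- which(same_chr & IRanges::start(g) > clusters$end[q])
    if (length(up))
      clusters$flank_upstream[q] <- gid[up[which.max(IRanges::end(g)[up])]]
    if (length(dn))
      clusters$flank_downstream[q] <- gid[dn[which.min(IRanges::start(g)[dn])]]
  }
  clusters
}

#' Per-sample counts over clusters
#'
#' For each sample, the multiplicity sum of uniquely mapping reads
#' overlapping the cluster on the cluster's strand; rows are suitable for
#' appending to the DE count matrix.
#'
#' @param clusters classified cluster data frame.
#' @param aln_by_sample named list of `alignment_set`s per sample.
#' @return integer matrix, clusters by samples.
#' @export
cluster_counts <- function(clusters, aln_by_sample) {
  gr <- GenomicRanges::GRanges(clusters$chrom,
                               IRanges::IRanges(clusters$start,
                                                clusters$end),
                               strand = clusters$strand,
                               cluster_id = clusters$cluster_id)
  feature_counts(aln_by_sample, gr, id_col = "cluster_id")
}

#' Export clusters as GFF3 or BED6
#' @param clusters classified cluster data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_clusters_gff3 <- function(clusters, path) {
  attrs <- sprintf("ID=%s;relation=%s%s", clusters$cluster_id,
                   clusters$relation,
                   ifelse(clusters$relation == "antisense_to",
                          paste0(";antisense_gene=", clusters$antisense_gene),
                          sprintf(";flanks=%s-%s", clusters$flank_upstream,
                                  clusters$flank_downstream)))
  writeLines(c("##gff-version 3",
               sprintf("%s\tnitroseq\ttranscribed_region\t%d\t%d\t.\t%s\t.\t%s",
                       clusters$chrom, clusters$start, clusters$end,
                       clusters$strand, attrs)),
             path)
  invisible(path)
}

#' @rdname export_clusters_gff3
#' @export
export_clusters_bed <- function(clusters, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                     clusters$chrom, clusters$start - 1L, clusters$end,
                     clusters$cluster_id, clusters$span, clusters$strand),
             path)
  invisible(path)
}
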