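# Strand-aware genomic annotation container and GFF3 round trip.
#
# Internally every feature is held at the resolution the classifier needs
# (protein_coding_exon / protein_coding_intron / UTRs / mature_miRNA /
# miRNA_stem_loop / tasiRNA_locus / rRNA / tRNA / pseudogene /
# transposable_element) together with a gene-span table used by gene-level
# operations (counting, antisense classification, flank lookup).
# Coordinates are 1-based inclusive throughout (GFF3 convention).

.feature_classes <- c("protein_coding_exon", "protein_coding_intron",
                      "five_prime_UTR", "three_prime_UTR",
                      "mature_miRNA", "miRNA_stem_loop", "tasiRNA_locus",
                      "rRNA", "tRNA", "pseudogene", "transposable_element")

#' Build an annotation set
#'
#' @param features data frame with columns `class` (one of the supported
#'   feature classes), `id`, `start`, `end`, `strand`, `gene_id`
#'   (parent-gene linkage or NA), and optionally `chrom` (default "Chr1").
#' @param genes data frame of gene spans with columns `gene_id`, `start`,
#'   `end`, `strand` and optionally `chrom`.
#' @param seqlengths named integer vector of chromosome lengths.
#' @return object of class `annotation_set`: list with GRanges `features`
#'   (mcols `class`, `id`, `gene_id`) and `genes` (mcols `gene_id`).
#' @export
annotation_set <- function(features, genes, seqlengths = NULL) {
  if (is.null(features$chrom)) features$chrom <- "Chr1"
  if (is.null(genes$chrom)) genes$chrom <- "Chr1"
  bad <- setdiff(unique(features$class), .feature_classes)
  if (length(bad))
    stopf("unsupported feature class(es): %s", paste(bad, collapse = ", "))
  fgr <- GenomicRanges::GRanges(
    features$chrom, IRanges::IRanges(features$start, features$end),
    strand = features$strand,
    class = features$class, id = features$id, gene_id = features$gene_id)
  ggr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand, gene_id = genes$gene_id)
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(fgr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(fgr) <- seqlengths
    GenomeInfoDb::seqlevels(ggr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(ggr) <- seqlengths
  }
  structure(list(features = fgr, genes = ggr), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d features, %d genes\n",
              length(x$features), length(x$genes)))
  print(table(S4Vectors::mcols(x$features)$class))
  invisible(x)
}

# internal class -> GFF3 type mapping (introns are implicit in GFF3 and
# re-derived on import)
.gff3_type <- c(protein_coding_exon = "exon",
                five_prime_UTR = "five_prime_UTR",
                three_prime_UTR = "three_prime_UTR",
                mature_miRNA = "miRNA",
                miRNA_stem_loop = "miRNA_primary_transcript",
                tasiRNA_locus = "tasiRNA_locus",
                rRNA = "rRNA", tRNA = "tRNA",
                pseudogene = "pseudogene",
                transposable_element = "transposable_element")

#' Write an annotation set to GFF3
#'
#' Emits `gene` and `mRNA` rows for every gene plus typed child features
#' (`exon`, `five_prime_UTR`, `three_prime_UTR`); introns are implicit.
#' Non-genic classes use their own types (`miRNA_primary_transcript`,
#' `miRNA`, `rRNA`, `tRNA`, `pseudogene`, `transposable_element`,
#' `tasiRNA_locus`).
#'
#' @param ann an [annotation_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  f <- ann$features
  fm <- S4Vectors::mcols(f)
  g <- ann$genes
  esc <- function(x) gsub("[;=\t\n]", "_", x)
  lines <- c("##gff-version 3")
  sl <- GenomeInfoDb::seqlengths(f)
  if (length(sl) && !anyNA(sl))
    lines <- c(lines,
               sprintf("##sequence-region %s 1 %d", names(sl), sl))
  row9 <- function(chrom, type, start, end, strand, attrs)
    sprintf("%s\tnitroseq\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, start, end, strand, attrs)
  for (i in seq_along(g)) {
    gid <- S4Vectors::mcols(g)$gene_id[i]
    chrom <- as.character(GenomicRanges::seqnames(g))[i]
    st <- as.character(GenomicRanges::strand(g))[i]
    lines <- c(lines,
               row9(chrom, "gene", IRanges::start(g)[i], IRanges::end(g)[i],
                    st, sprintf("ID=%s", esc(gid))),
               row9(chrom, "mRNA", IRanges::start(g)[i], IRanges::end(g)[i],
                    st, sprintf("ID=%s.1;Parent=%s", esc(gid), esc(gid))))
    child <- which(!is.na(fm$gene_id) & fm$gene_id == gid &
                     fm$class %in% c("protein_coding_exon",
                                     "five_prime_UTR", "three_prime_UTR"))
    for (k in child)
      lines <- c(lines, row9(chrom, .gff3_type[[fm$class[k]]],
                             IRanges::start(f)[k], IRanges::end(f)[k],
                             as.character(GenomicRanges::strand(f))[k],
                             sprintf("ID=%s;Parent=%s.1", esc(fm$id[k]),
                                     esc(gid))))
  }
  other <- which(!(fm$class %in% c("protein_coding_exon",
                                   "protein_coding_intron",
                                   "five_prime_UTR", "three_prime_UTR")))
  for (k in other) {
    attrs <- sprintf("ID=%s", esc(fm$id[k]))
    if (!is.na(fm$gene_id[k]))
      attrs <- paste0(attrs, sprintf(";host_gene=%s", esc(fm$gene_id[k])))
    lines <- c(lines, row9(as.character(GenomicRanges::seqnames(f))[k],
                           .gff3_type[[fm$class[k]]],
                           IRanges::start(f)[k], IRanges::end(f)[k],
                           as.character(GenomicRanges::strand(f))[k], attrs))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an annotation set from GFF3
#'
#' Inverse of [write_annotation_gff3()]: gene spans come from `gene` rows,
#' exon/UTR children are attached to their parent gene, and introns are
#' derived as the within-mRNA gaps not covered by exons or UTRs.
#'
#' @param path GFF3 file.
#' @return an [annotation_set()].
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  m <- S4Vectors::mcols(gr)
  get_parent <- function(i) {
    p <- m$Parent[[i]]
    if (length(p)) sub("\\.1$", "", p[1]) else NA_character_
  }
  typ <- as.character(m$type)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = IRanges::start(gr), end = IRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = typ, id = as.character(m$ID),
    parent = vapply(seq_along(gr), get_parent, character(1)),
    stringsAsFactors = FALSE)
  if (!is.null(m$host_gene))
    df$host <- as.character(m$host_gene) else df$host <- NA_character_

  genes <- df[df$type == "gene", ]
  genes <- data.frame(gene_id = genes$id, chrom = genes$chrom,
                      start = genes$start, end = genes$end,
                      strand = genes$strand, stringsAsFactors = FALSE)

  inv <- names(.gff3_type); names(inv) <- unname(.gff3_type)
  fr <- df[df$type %in% names(inv), ]
  feats <- data.frame(class = unname(inv[fr$type]), id = fr$id,
                      chrom = fr$chrom, start = fr$start, end = fr$end,
                      strand = fr$strand,
                      gene_id = ifelse(is.na(fr$parent), fr$host, fr$parent),
                      stringsAsFactors = FALSE)

  # derive introns: per gene, gaps between sorted exon/UTR parts
  intr <- list()
  genic <- feats[feats$class %in% c("protein_coding_exon",
                                    "five_prime_UTR", "three_prime_UTR"), ]
  for (gid in unique(stats::na.omit(genic$gene_id))) {
    p <- genic[genic$gene_id == gid & !is.na(genic$gene_id), ]
    p <- p[order(p$start), ]
    if (nrow(p) < 2L) next
    gap_s <- p$end[-nrow(p)] + 1L
    gap_e <- p$start[-1L] - 1L
    keep <- gap_e >= gap_s
    if (!any(keep)) next
    intr[[gid]] <- data.frame(
      class = "protein_coding_intron",
      id = sprintf("%s.i%d", gid, seq_len(sum(keep))),
      chrom = p$chrom[1L], start = gap_s[keep], end = gap_e[keep],
      strand = p$strand[1L], gene_id = gid, stringsAsFactors = FALSE)
  }
  feats <- rbind(feats, do.call(rbind, intr))

  sr <- grep("^##sequence-region", readLines(path, n = 50L), value = TRUE)
  sl <- NULL
  if (length(sr)) {
    parts <- strsplit(sr, "[ \t]+")
    sl <- stats::setNames(vapply(parts, function(p) as.integer(p[4]),
                                 integer(1)),
                          vapply(parts, `[`, character(1), 2))
  }
  annotation_set(feats, genes, seqlengths = sl)
}
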