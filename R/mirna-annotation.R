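# Genomic-context annotation of miRNA loci (from an external hairpin
# predictor or the bundled curated tables), novelty flagging against a
# known-mature catalog, and per-context summary counting.

.mirna_contexts <- c("known_stem_loop", "five_prime_UTR", "intron",
                     "pseudogene", "intergenic")

#' Classify miRNA loci by genomic context
#'
#' Context priority: `known_stem_loop` (overlap with a known precursor
#' span on either strand -- a sequence inside a known hairpin belongs to
#' that hairpin even when the hairpin itself is intronic) >
#' `five_prime_UTR` > `intron` > `pseudogene` > `intergenic`.
#' Gene-hosted contexts (UTR/intron/pseudogene) require same-strand
#' overlap.  A locus overlapping a protein-coding exon in sense is not a
#' recognized context and is reported as `unclassifiable`.
#'
#' @param loci data frame with columns `name`, `chrom`, `strand`,
#'   `start`, `end`.
#' @param ann an [annotation_set()].
#' @param known_stem_loops GRanges of known precursor spans (defaults to
#'   the annotation's `miRNA_stem_loop` features).
#' @return `loci` with extra columns `context` and `context_detail`
#'   (host transcript / precursor / flanking gene ids).
#' @export
classify_mirna_loci <- function(loci, ann, known_stem_loops = NULL) {
  stopifnot(inherits(ann, "annotation_set"))
  if (is.null(known_stem_loops)) {
    f <- ann$features
    known_stem_loops <-
      f[S4Vectors::mcols(f)$class == "miRNA_stem_loop"]
  }
  n <- nrow(loci)
  loci$context <- rep("intergenic", n)
  loci$context_detail <- NA_character_
  if (!n) return(loci)
  lg <- GenomicRanges::GRanges(loci$chrom,
                               IRanges::IRanges(loci$start, loci$end),
                               strand = loci$strand)
  f <- ann$features
  fm <- S4Vectors::mcols(f)
  g <- ann$genes
  gid <- S4Vectors::mcols(g)$gene_id

  ov_sl <- if (length(known_stem_loops))
    suppressWarnings(GenomicRanges::findOverlaps(lg, known_stem_loops,
                                                 ignore.strand = TRUE))
  else S4Vectors::Hits()
  ov_same <- GenomicRanges::findOverlaps(lg, f, ignore.strand = FALSE)

  for (q in seq_len(n)) {
    sl_hit <- S4Vectors::subjectHits(ov_sl)[S4Vectors::queryHits(ov_sl) == q]
    if (length(sl_hit)) {
      loci$context[q] <- "known_stem_loop"
      det <- S4Vectors::mcols(known_stem_loops)$id
      loci$context_detail[q] <-
        if (!is.null(det)) det[sl_hit[1L]] else NA_character_
      next
    }
    cls <- fm$class[S4Vectors::subjectHits(ov_same)[
      S4Vectors::queryHits(ov_same) == q]]
    host <- fm$gene_id[S4Vectors::subjectHits(ov_same)[
      S4Vectors::queryHits(ov_same) == q]]
    if ("five_prime_UTR" %in% cls) {
      loci$context[q] <- "five_prime_UTR"
      loci$context_detail[q] <- host[match("five_prime_UTR", cls)]
    } else if ("protein_coding_intron" %in% cls) {
      loci$context[q] <- "intron"
      loci$context_detail[q] <- host[match("protein_coding_intron", cls)]
    } else if ("pseudogene" %in% cls) {
      loci$context[q] <- "pseudogene"
      loci$context_detail[q] <-
        fm$id[S4Vectors::subjectHits(ov_same)[
          S4Vectors::queryHits(ov_same) == q]][match("pseudogene", cls)]
    } else if (any(cls %in% c("protein_coding_exon", "three_prime_UTR"))) {
      loci$context[q] <- "unclassifiable"
      warnf("locus %s overlaps an exonic feature in sense; not a recognized context",
            loci$name[q])
    } else {
      loci$context[q] <- "intergenic"
      same_chr <- as.character(GenomicRanges::seqnames(g)) == loci$chrom[q]
      up <- which(same_chr & IRanges::end(g) < loci$start[q])
      dn <- which(same_chr & IRanges::start(g) > loci$end[q])
      fl_up <- if (length(up))
        gid[up[which.max(IRanges::end(g)[up])]] else NA_character_
      fl_dn <- if (length(dn))
        gid[dn[which.min(IRanges::start(g)[dn])]] else NA_character_
      loci$context_detail[q] <- paste0(fl_up, "-", fl_dn)
    }
  }
  loci
}

#' Flag novel mature sequences against a known catalog
#'
#' @param loci data frame with a `mature_sequence` column.
#' @param catalog data frame with columns `name`, `sequence` (the known
#'   mature catalog).
#' @return character vector: `"Novel"` or the matching catalog name;
#'   comparison is U/T- and case-insensitive.
#' @export
flag_novel <- function(loci, catalog) {
  idx <- match(normalize_seq(loci$mature_sequence),
               normalize_seq(catalog$sequence))
  ifelse(is.na(idx), "Novel", catalog$name[idx])
}

#' Summarize miRNA-locus contexts
#'
#' @param loci data frame with columns `context` and optionally
#'   `prior_report` (`"Novel"` or a citation/name; non-Novel entries count
#'   as cross-validated).
#' @return list with `by_context` (named counts over the recognized
#'   context classes), `total`, `n_novel`, `n_cross_validated`.
#' @export
summarize_contexts <- function(loci) {
  if (nrow(loci) && (is.null(loci$context) || anyNA(loci$context)))
    stopf("every locus must carry a context label")
  by_ctx <- vapply(.mirna_contexts, function(ctx)
    sum(loci$context == ctx), integer(1))
  n_cv <- if (!is.null(loci$prior_report))
    sum(loci$prior_report != "Novel") else NA_integer_
  list(by_context = by_ctx, total = nrow(loci),
       n_novel = if (!is.null(loci$prior_report))
         sum(loci$prior_report == "Novel") else NA_integer_,
       n_cross_validated = n_cv)
}

# map a free-text "located in" description onto a context class
.context_from_text <- function(txt) {
  ifelse(grepl("stem loop", txt, ignore.case = TRUE), "known_stem_loop",
  ifelse(grepl("intron", txt, ignore.case = TRUE), "intron",
  ifelse(grepl("5'UTR", txt, fixed = TRUE), "five_prime_UTR",
  ifelse(grepl("pseudogene", txt, ignore.case = TRUE), "pseudogene",
  ifelse(grepl("intergenic", txt, ignore.case = TRUE), "intergenic",
         NA_character_)))))
}

#' Load the bundled curated tables
#'
#' Two plain-text tables ship with the package: the nitrate-responsive
#' protein-coding genes absent from the ATH1 array (AGI id, description,
#' log2 KNO3/KCl ratio) and the predicted novel miRNA loci (coordinates,
#' mature sequence, star-strand detection, prior report, genomic
#' context).  Rows whose coordinates disagree with the mature-sequence
#' length are reported (message), not dropped: the tables are transcribed
#' as published.
#'
#' @return list with data frames `genes` and `mirna_loci` (the latter
#'   with derived `context` column).
#' @export
load_fixture_tables <- function() {
  gpath <- system.file("extdata", "nitrate_responsive_genes.tsv",
                       package = "nitroseq", mustWork = TRUE)
  mpath <- system.file("extdata", "novel_mirna_loci.tsv",
                       package = "nitroseq", mustWork = TRUE)
  genes <- utils::read.delim(gpath, stringsAsFactors = FALSE)
  need <- c("gene_id", "description", "log2_ratio")
  if (!all(need %in% names(genes)))
    stopf("malformed gene table: expected columns %s",
          paste(need, collapse = ", "))
  bad <- which(!grepl("^AT[1-5CM]G[0-9]+$", genes$gene_id) |
                 is.na(genes$log2_ratio))
  if (length(bad)) stopf("malformed gene table row %d", bad[1L])

  loci <- utils::read.delim(mpath, stringsAsFactors = FALSE)
  need <- c("name", "chrom", "strand", "start", "end", "mature_sequence",
            "star_detected", "prior_report", "located_in")
  if (!all(need %in% names(loci)))
    stopf("malformed miRNA table: expected columns %s",
          paste(need, collapse = ", "))
  bad <- which(is.na(loci$start) | is.na(loci$end) |
                 !nzchar(loci$mature_sequence))
  if (length(bad)) stopf("malformed miRNA table row %d", bad[1L])
  loci$context <- .context_from_text(loci$located_in)
  if (anyNA(loci$context))
    stopf("malformed miRNA table row %d: unrecognized context",
          which(is.na(loci$context))[1L])
  mism <- which(loci$end - loci$start + 1L != nchar(loci$mature_sequence))
  if (length(mism))
    message(sprintf(
      "%d miRNA locus row(s) have coordinates inconsistent with the mature length (kept as published): %s",
      length(mism), paste(loci$name[mism], collapse = ", ")))
  list(genes = genes, mirna_loci = loci)
}

#' Write miRNA loci to TSV / GFF3
#' @param loci miRNA locus data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mirna_tsv <- function(loci, path) {
  utils::write.table(loci, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_mirna_tsv
#' @export
export_mirna_gff3 <- function(loci, path) {
  writeLines(c("##gff-version 3",
               sprintf("%s\tnitroseq\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s;context=%s",
                       loci$chrom, loci$start, loci$end, loci$strand,
                       loci$name, loci$context)),
             path)
  invisible(path)
}
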