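# Genomic-origin classification of alignments with 1/n_loci weighting,
# sRNA size distributions and known-sRNA (miRNA / ta-siRNA) expression.

# priority order for overlapping same-strand features; a placement gets
# the highest-priority category it overlaps by >= 1 base, else intergenic.
# The exon/intron/UTR classes collapse into "protein_coding".
.category_priority <- c("mature_miRNA", "miRNA_stem_loop", "tasiRNA_locus",
                        "rRNA", "tRNA", "protein_coding", "pseudogene",
                        "transposable_element", "intergenic")

.class_to_category <- c(
  protein_coding_exon = "protein_coding",
  protein_coding_intron = "protein_coding",
  five_prime_UTR = "protein_coding",
  three_prime_UTR = "protein_coding",
  mature_miRNA = "mature_miRNA", miRNA_stem_loop = "miRNA_stem_loop",
  tasiRNA_locus = "tasiRNA_locus", rRNA = "rRNA", tRNA = "tRNA",
  pseudogene = "pseudogene", transposable_element = "transposable_element")

#' Classify alignments by genomic origin
#'
#' Each placement receives the single highest-priority category among the
#' same-strand features it overlaps by at least one base (priority:
#' mature_miRNA > miRNA_stem_loop > tasiRNA_locus > rRNA > tRNA >
#' protein_coding > pseudogene > transposable_element).  Placements with
#' no same-strand feature overlap are `intergenic` -- in particular,
#' antisense placements over genes, which is what feeds novel-region
#' discovery.
#'
#' @param aln an `alignment_set` or alignments data frame.
#' @param ann an [annotation_set()].
#' @param priority optional custom category priority (highest first).
#' @return character vector of categories, one per alignment row.
#' @export
classify_alignments <- function(aln, ann, priority = .category_priority) {
  a <- if (inherits(aln, "alignment_set")) aln$alignments else aln
  stopifnot(inherits(ann, "annotation_set"))
  if (nrow(a) == 0L) return(character())
  sl <- GenomeInfoDb::seqlengths(ann$features)
  known <- a$chrom %in% GenomeInfoDb::seqlevels(ann$features)
  if (!all(known))
    stopf("alignment on unknown chromosome '%s'", a$chrom[!known][1L])
  if (length(sl) && !anyNA(sl)) {
    lim <- sl[a$chrom]
    if (any(a$start < 1L | a$end > lim))
      stopf("alignment outside chromosome bounds")
  }
  gr <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start, a$end),
                               strand = a$strand)
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(ann$features)
  ov <- GenomicRanges::findOverlaps(gr, ann$features, ignore.strand = FALSE)
  cls <- S4Vectors::mcols(ann$features)$class[S4Vectors::subjectHits(ov)]
  cat_hit <- .class_to_category[cls]
  pr <- match(cat_hit, priority)
  best <- tapply(pr, S4Vectors::queryHits(ov), min)
  out <- rep("intergenic", nrow(a))
  out[as.integer(names(best))] <- priority[best]
  out
}

#' Locus-weighted category breakdown
#'
#' Each placement of a read mapping to `n_loci` loci contributes
#' `multiplicity / n_loci` to the category of that placement, so the total
#' weighted count equals the number of mapped reads.  `scope =
#' "unique"` restricts to reads with a single genome-wide placement.
#'
#' @inheritParams classify_alignments
#' @param scope `"all"` placements or `"unique"` (n_loci == 1) only.
#' @return object of class `category_breakdown`: data frame with columns
#'   `category`, `weighted_count`, `percent`, with attributes `scope` and
#'   `total`.
#' @export
weighted_category_counts <- function(aln, ann, scope = c("all", "unique"),
                                     priority = .category_priority) {
  scope <- match.arg(scope)
  a <- if (inherits(aln, "alignment_set")) aln$alignments else aln
  if (scope == "unique") a <- a[a$n_loci == 1L, , drop = FALSE]
  cats <- classify_alignments(a, ann, priority)
  w <- if (nrow(a)) a$count / a$n_loci else numeric()
  agg <- tapply(w, factor(cats, levels = priority), sum, default = 0)
  out <- data.frame(category = priority,
                    weighted_count = as.numeric(agg),
                    stringsAsFactors = FALSE)
  total <- sum(out$weighted_count)
  out$percent <- if (total > 0) 100 * out$weighted_count / total else 0
  attr(out, "scope") <- scope
  attr(out, "total") <- total
  class(out) <- c("category_breakdown", "data.frame")
  out
}

#' Insert-size distribution of an sRNA read set
#'
#' @param reads a [read_set()] (post-trim sRNA library).
#' @param range inclusive length range of the histogram bins.
#' @return data frame with columns `length` and `count`; counts include
#'   multiplicities and sum to the retained reads of the set.
#' @export
size_distribution <- function(reads, range = c(18L, 28L)) {
  stopifnot(inherits(reads, "read_set"))
  lens <- range[1]:range[2]
  len <- nchar(reads$sequences$seq)
  cnt <- vapply(lens, function(l)
    sum(reads$sequences$count[len == l]), numeric(1))
  data.frame(length = lens, count = as.integer(cnt))
}

#' Read a known-sRNA catalog (name, sequence TSV)
#' @param path two-column TSV with header columns `name` and `sequence`
#'   (RNA or DNA alphabet).
#' @return data frame with columns `name`, `sequence`.
#' @export
read_srna_catalog <- function(path) {
  cat <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "sequence") %in% names(cat)))
  cat
}

# derive a family label from a miRNA-style name: strip trailing
# letter/locus suffixes (miR156a-5p -> miR156, TAS1a -> TAS1)
.srna_family <- function(name) {
  fam <- sub("(-[35]p)(\\.\\d+)?$", "", name)
  sub("([0-9]+)[a-z]+.*$", "\\1", fam)
}

#' Expression of known small RNAs in a read set
#'
#' A catalog entry is detected iff at least one retained read equals its
#' sequence exactly (U/T and case normalized); counts are read
#' multiplicities.
#'
#' @param reads a [read_set()] or its `sequences` data frame.
#' @param catalog data frame with columns `name`, `sequence` and
#'   optionally `family` (derived from the name when absent).
#' @return list with `table` (data frame `name`, `family`, `sequence`,
#'   `count`, `detected`), `n_detected` and `n_families_detected`.
#' @export
known_srna_expression <- function(reads, catalog) {
  seqs <- if (inherits(reads, "read_set")) reads$sequences else reads
  if (!nrow(catalog)) stopf("catalog is empty")
  if (anyDuplicated(catalog$name))
    stopf("duplicate catalog names: %s",
          paste(unique(catalog$name[duplicated(catalog$name)]),
                collapse = ", "))
  key <- normalize_seq(catalog$sequence)
  fam <- catalog$family %||% .srna_family(catalog$name)
  idx <- match(key, normalize_seq(seqs$seq))
  cnt <- ifelse(is.na(idx), 0L, seqs$count[idx])
  tab <- data.frame(name = catalog$name, family = fam,
                    sequence = catalog$sequence, count = as.integer(cnt),
                    detected = cnt > 0L, stringsAsFactors = FALSE)
  list(table = tab, n_detected = sum(tab$detected),
       n_families_detected = length(unique(tab$family[tab$detected])))
}
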