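# Perfect-match placement of reads on both genome strands with full
# multi-locus reporting.  Matching is exact: a read is placed wherever it
# equals the forward genome substring (strand +) or the reverse complement
# of the genome substring (strand -).  Biostrings preprocessed dictionaries
# (PDict) provide the constant-width exact search; reads are grouped by
# width.

#' Build a genome index for perfect-match lookup
#'
#' @param genome a named [Biostrings::DNAStringSet], a named character
#'   vector of chromosome sequences, or the path to a FASTA file.
#' @return object of class `genome_index`.
#' @export
build_index <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (is.character(genome))
    genome <- Biostrings::DNAStringSet(genome)
  if (is.null(names(genome)) || anyNA(names(genome)) ||
      !all(nzchar(names(genome))))
    stopf("all chromosomes must be named")
  names(genome) <- sub("\\s.*$", "", names(genome))  # FASTA description
  if (anyDuplicated(names(genome)))
    stopf("duplicate chromosome names in genome")
  if (any(Biostrings::width(genome) == 0L))
    stopf("genome contains an empty chromosome")
  structure(list(seqs = genome,
                 lengths = stats::setNames(Biostrings::width(genome),
                                           names(genome))),
            class = "genome_index")
}

#' Map a read set to the genome, perfect matches only
#'
#' Every distinct sequence is searched on both strands of every
#' chromosome; all placements are reported and `n_loci` is the genome-wide
#' placement count of the read.  Reads containing N and reads with zero
#' placements are returned in the unmapped table.  A configurable
#' multi-mapping cap (default none) excludes pathological reads, which
#' are logged in the `capped` table.
#'
#' @param reads a [read_set()], or a character vector of sequences
#'   (multiplicity 1 each), or a data frame with columns `seq`, `count`.
#' @param index a [build_index()] result.
#' @param max_loci reads with more placements than this are excluded and
#'   reported in `capped` (default `Inf`: no cap).
#' @return object of class `alignment_set`: list with `alignments` (data
#'   frame `seq`, `count`, `chrom`, `start`, `end`, `strand`, `n_loci`),
#'   `unmapped` (data frame `seq`, `count`) and `capped` (same shape).
#' @export
map_reads <- function(reads, index, max_loci = Inf) {
  stopifnot(inherits(index, "genome_index"))
  if (inherits(reads, "read_set")) reads <- reads$sequences
  if (is.character(reads))
    reads <- data.frame(seq = reads, count = 1L, stringsAsFactors = FALSE)
  stopifnot(all(c("seq", "count") %in% names(reads)))
  reads <- stats::aggregate(count ~ seq, reads, sum)  # ensure distinct
  reads$seq <- toupper(reads$seq)

  has_n <- grepl("[^ACGT]", reads$seq)
  searchable <- reads[!has_n, , drop = FALSE]
  hits <- list()
  if (nrow(searchable)) {
    by_width <- split(seq_len(nrow(searchable)), nchar(searchable$seq))
    for (chrom in names(index$seqs)) {
      subject <- index$seqs[[chrom]]
      clen <- length(subject)
      for (w_idx in by_width) {
        w <- nchar(searchable$seq[w_idx[1L]])
        if (w > clen) next
        fwd <- Biostrings::DNAStringSet(searchable$seq[w_idx])
        rev <- Biostrings::reverseComplement(fwd)
        for (strand in c("+", "-")) {
          pd <- Biostrings::PDict(if (strand == "+") fwd else rev)
          m <- Biostrings::matchPDict(pd, subject)
          n_per <- S4Vectors::elementNROWS(m)
          if (sum(n_per) == 0L) next
          st <- IRanges::start(unlist(m))
          hits[[length(hits) + 1L]] <- data.frame(
            ri = rep(w_idx, n_per), chrom = chrom,
            start = st, end = st + w - 1L, strand = strand,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(hits)) {
    h <- do.call(rbind, hits)
    n_loci <- tabulate(h$ri, nbins = nrow(searchable))
    aln <- data.frame(seq = searchable$seq[h$ri],
                      count = searchable$count[h$ri],
                      chrom = h$chrom, start = h$start, end = h$end,
                      strand = h$strand, n_loci = n_loci[h$ri],
                      stringsAsFactors = FALSE)
    aln <- aln[order(aln$chrom, aln$start, aln$strand, aln$seq), ,
               drop = FALSE]
    rownames(aln) <- NULL
    mapped_seqs <- unique(aln$seq)
  } else {
    aln <- data.frame(seq = character(), count = integer(),
                      chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_loci = integer(), stringsAsFactors = FALSE)
    mapped_seqs <- character()
  }
  capped <- aln[aln$n_loci > max_loci, c("seq", "count"), drop = FALSE]
  capped <- unique(capped)
  if (nrow(capped)) {
    warnf("%d read(s) exceed the multi-mapping cap (%s) and are excluded",
          nrow(capped), format(max_loci))
    aln <- aln[aln$n_loci <= max_loci, , drop = FALSE]
  }
  unmapped <- reads[!(reads$seq %in% mapped_seqs),
                    c("seq", "count"), drop = FALSE]
  rownames(unmapped) <- NULL
  structure(list(alignments = aln, unmapped = unmapped, capped = capped),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf("alignment_set: %d placements of %d distinct reads; %d unmapped\n",
              nrow(x$alignments), length(unique(x$alignments$seq)),
              nrow(x$unmapped)))
  invisible(x)
}

#' Restrict to uniquely mapping reads
#' @param aln an `alignment_set` or its `alignments` data frame.
#' @return the alignments data frame restricted to `n_loci == 1`.
#' @export
unique_alignments <- function(aln) {
  a <- if (inherits(aln, "alignment_set")) aln$alignments else aln
  a[a$n_loci == 1L, , drop = FALSE]
}

#' Export alignments as minimal SAM
#'
#' Header plus the mandatory fields; `NH:i:` carries the genome-wide
#' placement count and `XC:i:` the read multiplicity.  Minus-strand
#' records store the reverse-complemented (reference-forward) sequence,
#' per SAM convention.
#'
#' @param aln an `alignment_set`.
#' @param index the [build_index()] used for mapping (chromosome lengths).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_sam <- function(aln, index, path) {
  a <- aln$alignments
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(index$lengths),
                   index$lengths))
  flag <- ifelse(a$strand == "-", 16L, 0L)
  seq_out <- ifelse(a$strand == "-", revcomp_chr(a$seq), a$seq)
  rec <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNH:i:%d\tXC:i:%d",
                 paste0("read_", match(a$seq, unique(a$seq))), flag,
                 a$chrom, a$start, nchar(a$seq), seq_out, a$n_loci, a$count)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read perfect-match alignments from a SAM file
#'
#' Lets externally produced alignments enter the pipeline.  Records with
#' mismatches (`NM` tag > 0), unmapped records and records lacking
#' a sequence are rejected.  `NH` supplies `n_loci` (default 1) and `XC`
#' the multiplicity (default 1).
#'
#' @param path SAM file.
#' @return an `alignment_set` (with an empty `unmapped` table).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(structure(list(alignments = data.frame(), unmapped = data.frame(),
                          capped = data.frame()), class = "alignment_set"))
  f <- strsplit(lines, "\t", fixed = TRUE)
  get_tag <- function(fields, tag, default) {
    hit <- grep(paste0("^", tag, ":i:"), fields[-(1:11)], value = TRUE)
    if (length(hit)) as.integer(sub(".*:", "", hit[1])) else default
  }
  rows <- lapply(f, function(x) {
    if (length(x) < 11L) stopf("malformed SAM record")
    flag <- as.integer(x[2])
    if (bitwAnd(flag, 4L) > 0L) return(NULL)          # unmapped
    if (x[10] == "*") stopf("SAM record without sequence")
    nm <- get_tag(x, "NM", 0L)
    if (nm > 0L) return(NULL)                          # mismatches rejected
    s <- toupper(x[10])
    strand <- if (bitwAnd(flag, 16L) > 0L) "-" else "+"
    if (strand == "-") s <- revcomp_chr(s)             # back to read strand
    data.frame(seq = s, count = get_tag(x, "XC", 1L), chrom = x[3],
               start = as.integer(x[4]),
               end = as.integer(x[4]) + nchar(s) - 1L,
               strand = strand, n_loci = get_tag(x, "NH", 1L),
               stringsAsFactors = FALSE)
  })
  aln <- do.call(rbind, rows)
  if (is.null(aln))
    aln <- data.frame(seq = character(), count = integer(),
                      chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_loci = integer(), stringsAsFactors = FALSE)
  structure(list(alignments = aln,
                 unmapped = data.frame(seq = character(), count = integer()),
                 capped = aln[0, c("seq", "count")]),
            class = "alignment_set")
}

#' Export alignments as BED6
#'
#' Converts the internal 1-based inclusive coordinates to BED's 0-based
#' half-open convention.  The score column carries `n_loci`.
#'
#' @param aln an `alignment_set` or alignments data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_bed <- function(aln, path) {
  a <- if (inherits(aln, "alignment_set")) aln$alignments else aln
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                     a$chrom, a$start - 1L, a$end,
                     paste0("read_", seq_len(nrow(a))), a$n_loci, a$strand),
             path)
  invisible(path)
}
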