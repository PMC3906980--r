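# Raw-read processing: Phred-quality filtering, 3' adaptor trimming, size
# and polynucleotide (homopolymer) filtering, and collapsing survivors into
# a distinct-sequence read set with full per-filter accounting.

#' Filtering configuration
#'
#' @param library `"sRNA"` (size window 18-28 nt) or `"polyA"`
#'   (>= 18 nt, no upper bound).
#' @param phred_min minimum Phred score counted as a good base (Q20: an
#'   incorrect-call probability of 1 in 100).
#' @param min_frac_at_phred a read passes the quality filter iff at least
#'   this fraction of its bases reaches `phred_min`.
#' @param adaptor 3' adaptor sequence searched for by the trimmer.
#' @param min_adaptor_overlap minimum adaptor-prefix length accepted at
#'   the read's 3' end.
#' @param size_min,size_max inclusive post-trim length window; `size_max =
#'   NA` means unbounded.  Defaults follow `library`.
#' @param homopolymer_max_frac reads whose most frequent single base
#'   exceeds this fraction of the read length are discarded.
#' @return object of class `filter_config`.
#' @export
filter_config <- function(library = c("sRNA", "polyA"),
                          phred_min = 20L, min_frac_at_phred = 0.9,
                          adaptor = "CTGTAGGCACCATCAAT",
                          min_adaptor_overlap = 5L,
                          size_min = 18L, size_max = NULL,
                          homopolymer_max_frac = 0.8) {
  library <- match.arg(library)
  if (is.null(size_max))
    size_max <- if (library == "sRNA") 28L else NA_integer_
  if (min_frac_at_phred <= 0 || min_frac_at_phred > 1)
    stopf("min_frac_at_phred must lie in (0, 1]")
  if (!is.na(size_max) && size_min > size_max)
    stopf("size_min must be <= size_max")
  if (!nzchar(adaptor)) stopf("adaptor must be non-empty")
  structure(list(library = library, phred_min = as.integer(phred_min),
                 min_frac_at_phred = min_frac_at_phred,
                 adaptor = toupper(adaptor),
                 min_adaptor_overlap = as.integer(min_adaptor_overlap),
                 size_min = as.integer(size_min),
                 size_max = as.integer(size_max),
                 homopolymer_max_frac = homopolymer_max_frac),
            class = "filter_config")
}

# Phred scores (integer list) from Phred+33 quality strings
.phred_scores <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

#' Quality-filter reads
#'
#' A read passes iff at least `min_frac_at_phred` of its bases have a
#' Phred score >= `phred_min`.  Reads containing N are discarded here as
#' well (they cannot perfectly match the genome) and are counted as
#' quality failures.
#'
#' @param reads read table (columns `id`, `seq`, `qual`).
#' @param cfg a [filter_config()].
#' @return the passing subset of `reads`, with attribute `n_fail`.
#' @export
filter_quality <- function(reads, cfg) {
  stopifnot(inherits(cfg, "filter_config"))
  if (!all(c("id", "seq", "qual") %in% names(reads)))
    stopf("reads must have columns id, seq, qual")
  bad_len <- nchar(reads$seq) != nchar(reads$qual)
  if (any(bad_len))
    stopf("malformed record %d: sequence and quality lengths differ",
          which(bad_len)[1L])
  frac_ok <- vapply(.phred_scores(reads$qual), function(q)
    mean(q >= cfg$phred_min), numeric(1))
  pass <- frac_ok >= cfg$min_frac_at_phred & !grepl("N", reads$seq,
                                                   fixed = TRUE)
  out <- reads[pass, , drop = FALSE]
  attr(out, "n_fail") <- sum(!pass)
  out
}

#' Trim the 3' adaptor from reads
#'
#' The sequence (and its qualities) is truncated at the leftmost exact
#' occurrence of the full adaptor; when the full adaptor is absent, at the
#' longest adaptor prefix of length >= `min_adaptor_overlap` that ends
#' flush with the read's 3' end.  Reads without either are returned
#' unchanged (a valid outcome: the insert may simply fill the cycle
#' length).
#'
#' @inheritParams filter_quality
#' @return `reads` with trimmed `seq`/`qual`.
#' @export
trim_adaptor <- function(reads, cfg) {
  stopifnot(inherits(cfg, "filter_config"))
  if (nrow(reads) == 0L) return(reads)
  keep_len <- rep(NA_integer_, nrow(reads))
  hit <- regexpr(cfg$adaptor, reads$seq, fixed = TRUE)
  full <- hit > 0L
  keep_len[full] <- hit[full] - 1L
  # suffix = adaptor prefix, longest first
  todo <- which(!full)
  kmax <- nchar(cfg$adaptor) - 1L
  if (kmax >= cfg$min_adaptor_overlap) {
    for (k in rev(seq.int(cfg$min_adaptor_overlap, kmax))) {
      if (!length(todo)) break
      pre <- substr(cfg$adaptor, 1L, k)
      m <- endsWith(reads$seq[todo], pre) & nchar(reads$seq[todo]) >= k
      keep_len[todo[m]] <- nchar(reads$seq[todo[m]]) - k
      todo <- todo[!m]
    }
  }
  tr <- !is.na(keep_len)
  reads$seq[tr] <- substr(reads$seq[tr], 1L, keep_len[tr])
  reads$qual[tr] <- substr(reads$qual[tr], 1L, keep_len[tr])
  reads
}

# fraction of the most frequent single base
.homopolymer_frac <- function(seqs) {
  vapply(seqs, function(s) {
    if (!nzchar(s)) return(1)
    tab <- table(strsplit(s, "", fixed = TRUE)[[1L]])
    max(tab) / nchar(s)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Size/composition filtering and collapse to a distinct-sequence set
#'
#' Discards reads outside the inclusive size window and reads whose most
#' frequent single base exceeds `homopolymer_max_frac` of the length, then
#' collapses survivors into distinct sequences with multiplicities.
#'
#' @inheritParams filter_quality
#' @param n_raw,n_quality_fail accounting carried over from the earlier
#'   stages (defaults assume `reads` is the raw input).
#' @return object of class `read_set`: list with `sequences` (data frame
#'   `seq`, `count`, ordered by decreasing count then sequence), `library`
#'   and `stats` (named vector raw / quality_fail / size_fail /
#'   composition_fail / retained).
#' @export
filter_size_and_composition <- function(reads, cfg,
                                        n_raw = nrow(reads),
                                        n_quality_fail = 0L) {
  stopifnot(inherits(cfg, "filter_config"))
  len <- nchar(reads$seq)
  size_ok <- len >= cfg$size_min &
    (is.na(cfg$size_max) | len <= cfg$size_max)
  comp_ok <- .homopolymer_frac(reads$seq) <= cfg$homopolymer_max_frac
  keep <- size_ok & comp_ok
  n_size <- sum(!size_ok)
  n_comp <- sum(size_ok & !comp_ok)  # size filter takes precedence
  surv <- reads$seq[keep]
  if (!length(surv))
    warnf("no reads survive filtering (%s library)", cfg$library)
  tab <- table(surv)
  seqs <- data.frame(seq = as.character(names(tab) %||% character()),
                     count = as.integer(tab),
                     stringsAsFactors = FALSE)
  seqs <- seqs[order(-seqs$count, seqs$seq), , drop = FALSE]
  rownames(seqs) <- NULL
  read_set(seqs, cfg$library,
           stats = c(raw = as.integer(n_raw),
                     quality_fail = as.integer(n_quality_fail),
                     size_fail = n_size, composition_fail = n_comp,
                     retained = sum(keep)))
}

#' Construct a read set
#' @param sequences data frame with columns `seq`, `count`.
#' @param library library label (`"sRNA"` or `"polyA"`).
#' @param stats named integer vector raw / quality_fail / size_fail /
#'   composition_fail / retained.
#' @return object of class `read_set`.
#' @export
read_set <- function(sequences, library,
                     stats = c(raw = sum(sequences$count),
                               quality_fail = 0L, size_fail = 0L,
                               composition_fail = 0L,
                               retained = sum(sequences$count))) {
  stopifnot(all(c("seq", "count") %in% names(sequences)),
            all(sequences$count >= 1L))
  if (stats[["raw"]] != stats[["retained"]] + stats[["quality_fail"]] +
      stats[["size_fail"]] + stats[["composition_fail"]])
    stopf("read accounting does not balance: raw != retained + failures")
  structure(list(sequences = sequences, library = library, stats = stats),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set (%s): %d distinct sequences, %d reads retained of %d raw\n",
              x$library, nrow(x$sequences), x$stats[["retained"]],
              x$stats[["raw"]]))
  invisible(x)
}

#' Run the full filter chain on raw reads
#'
#' Quality filter, adaptor trimming, then size/composition filtering, with
#' conserved accounting (`raw == retained + quality_fail + size_fail +
#' composition_fail`).
#'
#' @inheritParams filter_quality
#' @return a [read_set()].
#' @export
process_reads <- function(reads, cfg) {
  n_raw <- nrow(reads)
  q <- filter_quality(reads, cfg)
  n_qfail <- attr(q, "n_fail")
  t <- trim_adaptor(q, cfg)
  filter_size_and_composition(t, cfg, n_raw = n_raw,
                              n_quality_fail = n_qfail)
}

#' Filter-accounting report
#' @param read_sets named list of [read_set()] objects (one per library).
#' @return data frame with one row per read set (columns library, raw,
#'   quality_fail, size_fail, composition_fail, retained,
#'   distinct_sequences).
#' @export
filter_stats <- function(read_sets) {
  if (inherits(read_sets, "read_set")) read_sets <- list(read_sets)
  do.call(rbind, lapply(seq_along(read_sets), function(i) {
    rs <- read_sets[[i]]
    data.frame(sample = names(read_sets)[i] %||% as.character(i),
               library = rs$library,
               raw = rs$stats[["raw"]],
               quality_fail = rs$stats[["quality_fail"]],
               size_fail = rs$stats[["size_fail"]],
               composition_fail = rs$stats[["composition_fail"]],
               retained = rs$stats[["retained"]],
               distinct_sequences = nrow(rs$sequences),
               stringsAsFactors = FALSE)
  }))
}
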