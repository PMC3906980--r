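# Rarefaction (saturation) analysis: distinct-sequence discovery as a
# function of sampling depth, by repeated subsampling without replacement
# from the multiplicity-expanded library.

#' Rarefaction curve of a read set
#'
#' At each depth, draws that many reads without replacement from the
#' multiplicity-expanded library and counts distinct sequences, averaged
#' over `n_resamples` draws.  The default depth grid is 10 logarithmically
#' spaced points from 1 to the library size.
#'
#' @param reads a [read_set()] or a data frame with columns `seq`,
#'   `count`.
#' @param depths increasing vector of depths (<= total read count).
#' @param n_resamples resampling repetitions per depth (>= 1).
#' @param seed integer seed for the subsampling.
#' @return object of class `rarefaction_curve`: data frame with columns
#'   `depth`, `mean_distinct`, `sd_distinct`; attributes `n_resamples`,
#'   `total_reads`, `distinct_sequences`, `seed`.
#' @export
rarefaction_curve <- function(reads, depths = NULL, n_resamples = 10L,
                              seed = 1L) {
  seqs <- if (inherits(reads, "read_set")) reads$sequences else reads
  stopifnot(all(c("seq", "count") %in% names(seqs)), n_resamples >= 1L)
  total <- sum(seqs$count)
  if (total == 0L) stopf("empty read set")
  if (is.null(depths)) {
    depths <- unique(round(exp(seq(0, log(total), length.out = 10L))))
  }
  depths <- sort(unique(as.integer(depths)))
  if (any(depths < 1L) || any(depths > total))
    stopf("depths must lie in [1, %d]", total)
  pool <- rep.int(seq_len(nrow(seqs)), seqs$count)
  res <- withr::with_seed(seed, {
    vapply(depths, function(d) {
      draws <- vapply(seq_len(n_resamples), function(i) {
        if (d == total) length(unique(pool))
        else length(unique(pool[sample.int(total, d)]))
      }, numeric(1))
      c(mean(draws), stats::sd(draws))
    }, numeric(2))
  })
  out <- data.frame(depth = depths, mean_distinct = res[1, ],
                    sd_distinct = ifelse(is.na(res[2, ]), 0, res[2, ]))
  attr(out, "n_resamples") <- n_resamples
  attr(out, "total_reads") <- total
  attr(out, "distinct_sequences") <- nrow(seqs)
  attr(out, "seed") <- seed
  class(out) <- c("rarefaction_curve", "data.frame")
  out
}

#' Saturation ratio of a rarefaction curve
#'
#' The slope of the final depth segment divided by the slope of the
#' initial segment: a library sequenced to saturation accumulates almost
#' no new sequences at full depth (ratio near 0), while an undersampled
#' library keeps accumulating linearly (ratio near 1).
#'
#' @param curve a [rarefaction_curve()].
#' @return the ratio in `[0, 1]`, or `NA` (with a warning) when the
#'   initial slope is zero.
#' @export
saturation_assessment <- function(curve) {
  stopifnot(inherits(curve, "rarefaction_curve"))
  n <- nrow(curve)
  if (n < 3L) stopf("need at least 3 depths to assess saturation")
  slope <- function(i, j)
    (curve$mean_distinct[j] - curve$mean_distinct[i]) /
      (curve$depth[j] - curve$depth[i])
  s0 <- slope(1L, 2L)
  s1 <- slope(n - 1L, n)
  if (s1 == 0) return(0)  # flat tail: saturated regardless of the onset
  if (s0 == 0) {
    warnf("initial slope is zero; saturation not assessable")
    return(NA_real_)
  }
  min(max(s1 / s0, 0), 1)
}
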