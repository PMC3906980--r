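# Average-gene-coverage (AGC) computation and sequencing-vs-microarray
# concordance: detection overlap and ratio correlation as a function of
# an AGC threshold.  AGC = reads matching a gene x read length / gene
# length, a dimensionless depth proxy.

#' Average gene coverage
#'
#' @param counts named numeric vector of sense unique-read counts per
#'   gene.
#' @param gene_lengths named numeric vector of gene lengths (bases),
#'   covering every gene in `counts`.
#' @param read_length nominal library read length in bases (default 50).
#' @return data frame with columns `gene_id`, `reads`, `gene_length`,
#'   `agc`.
#' @export
compute_agc <- function(counts, gene_lengths, read_length = 50L) {
  gl <- gene_lengths[names(counts)]
  if (anyNA(gl)) stopf("gene length missing for %s",
                       names(counts)[is.na(gl)][1L])
  if (any(gl <= 0)) stopf("zero-length gene in annotation")
  data.frame(gene_id = names(counts), reads = as.numeric(counts),
             gene_length = as.numeric(gl),
             agc = as.numeric(counts) * read_length / as.numeric(gl),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Platform ratio correlation as a function of AGC threshold
#'
#' For each threshold, the squared Pearson correlation between the
#' sequencing and array log2 (treatment/control) ratios over genes with
#' `AGC >= threshold` present on both platforms.  Thresholds retaining
#' fewer than 3 genes are omitted with a warning.
#'
#' @param seq_ratios named numeric vector of sequencing log2 ratios.
#' @param array_ratios named numeric vector of array log2 ratios.
#' @param agc a [compute_agc()] data frame.
#' @param thresholds increasing vector of AGC thresholds.
#' @param method correlation method (default `"pearson"`).
#' @return data frame with columns `threshold`, `r_squared`, `n_genes`.
#' @export
ratio_correlation_by_agc <- function(seq_ratios, array_ratios, agc,
                                     thresholds = c(0, 0.2, 0.4, 0.8,
                                                    1.6, 3.2),
                                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  shared <- intersect(names(seq_ratios), names(array_ratios))
  shared <- intersect(shared, agc$gene_id)
  if (length(shared) >= 2L && stats::sd(array_ratios[shared]) == 0)
    stopf("array ratios are constant; correlation not assessable")
  agc_v <- stats::setNames(agc$agc, agc$gene_id)[shared]
  rows <- lapply(thresholds, function(t) {
    g <- shared[agc_v >= t]
    if (length(g) < 3L) {
      warnf("fewer than 3 genes at AGC threshold %g; point omitted", t)
      return(NULL)
    }
    x <- seq_ratios[g]; y <- array_ratios[g]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warnf("degenerate ratio variance at AGC threshold %g; point omitted", t)
      return(NULL)
    }
    data.frame(threshold = t,
               r_squared = stats::cor(x, y, method = method)^2,
               n_genes = length(g))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(threshold = numeric(), r_squared = numeric(),
                      n_genes = integer())
  out
}

#' Detection overlap between sequencing and microarray
#'
#' Array-side detection is a present call (`"P"`) in at least
#' `min_present_samples` samples; sequencing-side detection is a count of
#' at least one read.
#'
#' @param array_table data frame with columns `probe`, `gene_id` and one
#'   or more `call_*` columns (values `"P"`/`"A"`).
#' @param seq_counts named numeric vector of per-gene read counts
#'   (the sequencing universe; genes absent from the vector are treated
#'   as observed with zero reads only if named with count 0).
#' @param min_present_samples present calls required for array detection.
#' @return list of partition counts: `array_present_seq_detected`,
#'   `array_present_seq_missed`, `array_absent_seq_detected`,
#'   `array_absent_seq_missed`, `no_probe_seq_detected`, and `n_universe`
#'   (union of both platforms' gene universes).
#' @export
detection_comparison <- function(array_table, seq_counts,
                                 min_present_samples = 1L) {
  call_cols <- grep("^call_", names(array_table), value = TRUE)
  if (!length(call_cols)) stopf("array table has no call_* columns")
  if (!all(c("probe", "gene_id") %in% names(array_table)))
    stopf("array table must have probe and gene_id columns")
  present <- rowSums(array_table[call_cols] == "P") >= min_present_samples
  arr_present <- unique(array_table$gene_id[present])
  arr_all <- unique(array_table$gene_id)
  arr_absent <- setdiff(arr_all, arr_present)
  seq_detected <- names(seq_counts)[seq_counts >= 1]
  seq_all <- names(seq_counts)
  unknown <- setdiff(arr_all, seq_all)
  # probes for genes outside the sequencing universe are a mapping error:
  # the probe-to-gene map must be resolvable against the counted genes
  if (length(unknown))
    stopf("probe maps to unknown gene: %s", unknown[1L])
  list(array_present_seq_detected = length(intersect(arr_present,
                                                     seq_detected)),
       array_present_seq_missed = length(setdiff(arr_present, seq_detected)),
       array_absent_seq_detected = length(intersect(arr_absent,
                                                    seq_detected)),
       array_absent_seq_missed = length(setdiff(arr_absent, seq_detected)),
       no_probe_seq_detected = length(setdiff(seq_detected, arr_all)),
       n_universe = length(union(arr_all, seq_all)))
}

#' Read / write the array expression table
#' @param path TSV with columns `probe`, `gene_id`, `signal_*`, `call_*`.
#' @return data frame.
#' @export
read_array_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe", "gene_id") %in% names(tab)))
    stopf("array table must have probe and gene_id columns")
  tab
}
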