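# Two-condition negative-binomial differential expression on feature
# counts: median-of-ratios size factors, per-feature method-of-moments
# dispersion, an exact conditional NB test on the condition sums, BH-FDR
# calling, and replicate-correlation QC.  This is a documented
# re-implementation of the classical NB exact-test approach for digital
# gene expression at two-replicate scale, not a novel statistic.

#' Count unique sense reads per feature
#'
#' For every feature, sums the multiplicities of uniquely mapping reads
#' (`n_loci == 1`) whose placement overlaps the feature span on the
#' feature's strand.  Antisense and multi-mapping reads contribute
#' nothing.
#'
#' @param aln_by_sample named list of `alignment_set`s (or alignment data
#'   frames), one per sample.
#' @param features a GRanges with an id metadata column, or an
#'   [annotation_set()] (its gene spans are used).
#' @param id_col name of the id metadata column (default `"gene_id"`).
#' @return integer count matrix, features by samples.
#' @export
feature_counts <- function(aln_by_sample, features, id_col = "gene_id") {
  if (inherits(features, "annotation_set")) features <- features$genes
  ids <- S4Vectors::mcols(features)[[id_col]]
  if (is.null(names(aln_by_sample)))
    stopf("aln_by_sample must be a named list (sample labels)")
  m <- matrix(0L, nrow = length(features), ncol = length(aln_by_sample),
              dimnames = list(ids, names(aln_by_sample)))
  for (s in names(aln_by_sample)) {
    a <- unique_alignments(aln_by_sample[[s]])
    if (!nrow(a)) next
    gr <- GenomicRanges::GRanges(a$chrom,
                                 IRanges::IRanges(a$start, a$end),
                                 strand = a$strand)
    ov <- GenomicRanges::findOverlaps(gr, features, ignore.strand = FALSE)
    cnt <- tapply(a$count[S4Vectors::queryHits(ov)],
                  S4Vectors::subjectHits(ov), sum)
    m[as.integer(names(cnt)), s] <- as.integer(cnt)
  }
  m
}

#' @rdname feature_counts
#' @param ann an [annotation_set()].
#' @export
gene_counts <- function(aln_by_sample, ann) {
  feature_counts(aln_by_sample, ann, id_col = "gene_id")
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over features (positive in every sample)
#' of the ratio of its count to the feature's geometric mean across
#' samples.
#'
#' @param m count matrix (features by samples).
#' @return named numeric vector of positive size factors.
#' @export
size_factors <- function(m) {
  if (is.null(dim(m)) || ncol(m) < 2L) stopf("need a matrix of >= 2 samples")
  log_geo <- rowMeans(log(m))
  use <- is.finite(log_geo)
  if (!any(use))
    stopf("no feature has positive counts in every sample; cannot normalize")
  sf <- apply(m[use, , drop = FALSE], 2, function(col)
    exp(stats::median(log(col) - log_geo[use])))
  if (any(!is.finite(sf)) || any(sf <= 0))
    stopf("degenerate size factors")
  sf
}

# NB(mu, var) log-density wrapper falling back to Poisson when var <= mu
.dnb <- function(x, mu, var) {
  if (mu == 0) return(ifelse(x == 0, 0, -Inf))
  if (var <= mu * (1 + 1e-8)) return(stats::dpois(x, mu, log = TRUE))
  size <- mu^2 / (var - mu)
  stats::dnbinom(x, mu = mu, size = size, log = TRUE)
}

# exact conditional two-sided p for condition sums (ka, kb) given models
# for K_A and K_B: the total probability of splits (a, T - a) no more
# likely than the observed one, conditioned on the total T
.exact_nb_p <- function(ka, kb, mu_a, var_a, mu_b, var_b) {
  T <- ka + kb
  if (T == 0L) return(1)
  a <- 0:T
  lp <- .dnb(a, mu_a, var_a) + .dnb(T - a, mu_b, var_b)
  lp_obs <- lp[ka + 1L]
  keep <- lp <= lp_obs + 1e-7        # tolerance absorbs float noise
  denom <- sum(exp(lp - max(lp)))
  min(sum(exp(lp[keep] - max(lp))) / denom, 1)
}

#' Negative-binomial exact test for two conditions
#'
#' Per feature: the common mean and dispersion are estimated from
#' size-factor-normalized counts pooled across conditions (dispersion by
#' method of moments, floored at 1e-8), the condition sums are modelled as
#' negative binomials with matched first two moments under the null of no
#' difference, and the p-value is the total conditional probability --
#' given the observed grand total -- of all condition splits no more
#' probable than the observed one.  The reported log2 ratio is
#' `log2((mean_num + 0.5) / (mean_den + 0.5))` on normalized condition
#' means, with the second condition level as numerator (KNO3 when the
#' levels are KCl/KNO3).
#'
#' @param m count matrix (features by samples).
#' @param conditions factor of length `ncol(m)` with exactly two levels,
#'   each with >= 2 replicates.
#' @param sf size factors (computed from `m` when omitted).
#' @return data frame with columns `id`, `mean_<denominator>`,
#'   `mean_<numerator>`, `log2_ratio`, `pval`.
#' @export
nb_exact_test <- function(m, conditions, sf = NULL) {
  conditions <- as.factor(conditions)
  if (nlevels(conditions) != 2L)
    stopf("exactly two condition levels required")
  if (any(table(conditions) < 2L))
    stopf("need >= 2 replicates per condition")
  if (length(conditions) != ncol(m))
    stopf("conditions must be parallel to the matrix columns")
  if (is.null(sf)) sf <- size_factors(m)
  lv <- levels(conditions)
  ja <- which(conditions == lv[1]); jb <- which(conditions == lv[2])
  z <- sweep(m, 2, sf, "/")

  xim <- mean(1 / sf)
  n_feat <- nrow(m)
  pval <- numeric(n_feat)
  lfc <- numeric(n_feat)
  mean_a <- rowMeans(z[, ja, drop = FALSE])
  mean_b <- rowMeans(z[, jb, drop = FALSE])
  S_a <- sum(sf[ja]); S_b <- sum(sf[jb])
  S2_a <- sum(sf[ja]^2); S2_b <- sum(sf[jb]^2)

  for (i in seq_len(n_feat)) {
    T_i <- sum(m[i, ])
    if (T_i == 0L) { pval[i] <- 1; lfc[i] <- NA_real_; next }
    mu <- mean(z[i, ])
    va <- stats::var(z[i, ja]); vb <- stats::var(z[i, jb])
    v_pooled <- ((length(ja) - 1) * va + (length(jb) - 1) * vb) /
      (length(ja) + length(jb) - 2)
    alpha <- max((v_pooled - mu * xim) / mu^2, 1e-8)
    mu_a <- mu * S_a; mu_b <- mu * S_b
    var_a <- mu * S_a + alpha * mu^2 * S2_a
    var_b <- mu * S_b + alpha * mu^2 * S2_b
    pval[i] <- .exact_nb_p(sum(m[i, ja]), sum(m[i, jb]),
                           mu_a, var_a, mu_b, var_b)
    lfc[i] <- log2((mean_b[i] + 0.5) / (mean_a[i] + 0.5))
  }
  out <- data.frame(id = rownames(m) %||% as.character(seq_len(n_feat)),
                    mean_a = mean_a, mean_b = mean_b,
                    log2_ratio = lfc, pval = pval,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[2:3] <- paste0("mean_", lv)
  attr(out, "numerator") <- lv[2]
  attr(out, "denominator") <- lv[1]
  out
}

#' Benjamini-Hochberg adjustment and differential calls
#'
#' Adds BH-adjusted p-values and a call: `induced` (adjusted p < alpha and
#' positive log2 ratio), `repressed` (negative ratio) or `unchanged`.
#'
#' @param res result of [nb_exact_test()].
#' @param alpha FDR threshold (default 0.05).
#' @return `res` with extra columns `padj` and `call`.
#' @export
adjust_and_call <- function(res, alpha = 0.05) {
  stopifnot(all(res$pval >= 0 & res$pval <= 1))
  res$padj <- stats::p.adjust(res$pval, method = "BH")
  res$call <- "unchanged"
  sig <- !is.na(res$log2_ratio) & res$padj < alpha
  res$call[sig & res$log2_ratio > 0] <- "induced"
  res$call[sig & res$log2_ratio < 0] <- "repressed"
  attr(res, "alpha") <- alpha
  res
}

#' Replicate correlation QC
#'
#' Pearson correlation of `log2(normalized count + 1)` between the two
#' replicates of each condition.
#'
#' @param m count matrix.
#' @param conditions two-level factor parallel to the columns.
#' @param sf size factors (computed when omitted).
#' @return named numeric vector (one r per condition); `NA` with a
#'   warning for a zero-variance condition.
#' @export
replicate_correlation <- function(m, conditions, sf = NULL) {
  conditions <- as.factor(conditions)
  if (is.null(sf)) sf <- size_factors(m)
  z <- log2(sweep(m, 2, sf, "/") + 1)
  vapply(levels(conditions), function(lv) {
    j <- which(conditions == lv)
    if (length(j) != 2L)
      stopf("replicate_correlation expects exactly 2 replicates per condition")
    x <- z[, j[1]]; y <- z[, j[2]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warnf("zero-variance replicate in condition %s", lv)
      return(NA_real_)
    }
    stats::cor(x, y)
  }, numeric(1))
}
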