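# Counting rules, median-of-ratios normalization (with an independent
# cross-check), the NB exact test against brute-force enumeration, BH
# calling and replicate QC.

toy_counts <- function() {
  ann <- toy_annotation()
  aln <- function(start, end, strand, n_loci = 1L, count = 1L)
    data.frame(seq = strrep("A", end - start + 1L), count = count,
               chrom = "Chr1", start = start, end = end, strand = strand,
               n_loci = n_loci, stringsAsFactors = FALSE)
  list(ann = ann, aln = aln)
}

test_that("gene counting keeps only unique sense reads", {
  t <- toy_counts()
  samples <- list(
    s1 = t$aln(1200L, 1249L, "+"),                      # sense in G1
    s2 = rbind(t$aln(1200L, 1249L, "-"),                # antisense to G1
               t$aln(3100L, 3149L, "-", count = 2L),    # sense in G2 (x2)
               t$aln(1300L, 1349L, "+", n_loci = 3L)))  # multimapper
  m <- gene_counts(samples, t$ann)
  expect_equal(m["G1", "s1"], 1L)
  expect_equal(m["G1", "s2"], 0L)   # antisense and multimapper excluded
  expect_equal(m["G2", "s2"], 2L)   # multiplicity-weighted
})

test_that("size factors follow the median-of-ratios closed forms", {
  m <- matrix(c(10L, 20L, 30L, 10L, 20L, 30L), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(1, 1))
  m2 <- cbind(s1 = c(10L, 20L, 30L), s2 = c(20L, 40L, 60L))
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)))
  # depth normalization is relative: a global rescaling cancels against
  # the geometric-mean reference and leaves the factors unchanged
  expect_equal(unname(size_factors(m2 * 3L)), unname(size_factors(m2)))
  expect_error(size_factors(cbind(c(0L, 5L), c(3L, 0L))), "positive")
})

test_that("size factors agree with the independent DESeq2 implementation", {
  skip_if_not_installed("DESeq2")
  withr::with_seed(21L, {
    m <- matrix(rnbinom(400L, mu = 50, size = 10), ncol = 4L)
    m <- sweep(m, 2, c(1L, 2L, 1L, 3L), "*")
    rownames(m) <- paste0("g", 1:100); colnames(m) <- paste0("s", 1:4)
    expect_equal(unname(size_factors(m)),
                 unname(DESeq2::estimateSizeFactorsForMatrix(m)),
                 tolerance = 1e-8)
  })
})

test_that("an even split is the most probable: ratio 0 and p 1", {
  m <- matrix(rep(c(40L, 40L, 40L, 40L), each = 3L), nrow = 3L,
              dimnames = list(c("a", "b", "c"),
                              c("KCl_1", "KCl_2", "KNO3_1", "KNO3_2")))
  res <- nb_exact_test(m, factor(c("KCl", "KCl", "KNO3", "KNO3")))
  expect_equal(res$log2_ratio, rep(0, 3L))
  expect_equal(res$pval, rep(1, 3L))
})

test_that("small-count p-values equal brute-force enumeration", {
  conds <- factor(c("KCl", "KCl", "KNO3", "KNO3"))
  cases <- list(c(2L, 3L, 9L, 8L), c(0L, 1L, 12L, 9L), c(5L, 5L, 5L, 6L),
                c(0L, 0L, 0L, 3L), c(7L, 2L, 1L, 1L))
  filler <- matrix(rep(c(50L, 52L, 49L, 51L), 5L), ncol = 4L,
                   byrow = TRUE)  # keeps size factors well-defined
  for (k in seq_along(cases)) {
    m <- rbind(matrix(cases[[k]], nrow = 1L), filler)
    colnames(m) <- c("KCl_1", "KCl_2", "KNO3_1", "KNO3_2")
    rownames(m) <- paste0("f", seq_len(nrow(m)))
    sf <- size_factors(m)
    res <- nb_exact_test(m, conds, sf)
    # oracle: recompute the moment model and enumerate all splits
    z <- sweep(m, 2, sf, "/")[1, ]
    mu <- mean(z)
    vp <- (var(z[1:2]) + var(z[3:4])) / 2
    alpha <- max((vp - mu * mean(1 / sf)) / mu^2, 1e-8)
    mu_a <- mu * sum(sf[1:2]); mu_b <- mu * sum(sf[3:4])
    var_a <- mu_a + alpha * mu^2 * sum(sf[1:2]^2)
    var_b <- mu_b + alpha * mu^2 * sum(sf[3:4]^2)
    p_oracle <- nb_p_oracle(sum(m[1, 1:2]), sum(m[1, 3:4]),
                            mu_a, var_a, mu_b, var_b)
    expect_equal(res$pval[1], p_oracle, tolerance = 1e-9)
  }
})

test_that("zero-count features report p 1 and an undefined ratio", {
  m <- cbind(KCl_1 = c(0L, 10L), KCl_2 = c(0L, 12L),
             KNO3_1 = c(0L, 9L), KNO3_2 = c(0L, 11L))
  rownames(m) <- c("zero", "ok")
  res <- nb_exact_test(m, factor(c("KCl", "KCl", "KNO3", "KNO3")))
  expect_equal(res$pval[1], 1)
  expect_true(is.na(res$log2_ratio[1]))
})

test_that("swapping condition labels negates ratios and preserves p-values", {
  withr::with_seed(22L, {
    m <- matrix(rnbinom(200L, mu = 60, size = 15), ncol = 4L,
                dimnames = list(paste0("g", 1:50),
                                c("KCl_1", "KCl_2", "KNO3_1", "KNO3_2")))
    c1 <- factor(c("KCl", "KCl", "KNO3", "KNO3"),
                 levels = c("KCl", "KNO3"))
    c2 <- factor(c("KCl", "KCl", "KNO3", "KNO3"),
                 levels = c("KNO3", "KCl"))
    r1 <- nb_exact_test(m, c1)
    r2 <- nb_exact_test(m, c2)
    expect_equal(r1$pval, r2$pval)
    expect_equal(r1$log2_ratio, -r2$log2_ratio)
  })
})

test_that("BH adjustment and calling follow the hand-evaluated formula", {
  res <- data.frame(id = c("a", "b", "c"),
                    mean_KCl = c(1, 1, 1), mean_KNO3 = c(2, 0.5, 1),
                    log2_ratio = c(1, -1, 0.1),
                    pval = c(0.01, 0.02, 0.9))
  out <- adjust_and_call(res)
  expect_equal(out$padj, c(0.03, 0.03, 0.9))
  expect_equal(out$call, c("induced", "repressed", "unchanged"))
  allnull <- adjust_and_call(data.frame(id = "x", mean_KCl = 1,
                                        mean_KNO3 = 1, log2_ratio = 0,
                                        pval = 1))
  expect_equal(allnull$call, "unchanged")
  single <- adjust_and_call(data.frame(id = "x", mean_KCl = 1,
                                       mean_KNO3 = 4, log2_ratio = 2,
                                       pval = 0.01))
  expect_equal(single$padj, 0.01)
  expect_equal(single$call, "induced")
})

test_that("replicate correlation is 1 for duplicates and ~0 for noise", {
  withr::with_seed(23L, {
    base <- rnbinom(300L, mu = 80, size = 5)
    m <- cbind(KCl_1 = base, KCl_2 = base,
               KNO3_1 = base, KNO3_2 = sample(base))
    rownames(m) <- paste0("g", seq_along(base))
    r <- replicate_correlation(m, factor(c("KCl", "KCl", "KNO3", "KNO3")))
    expect_equal(unname(r["KCl"]), 1)
    expect_lt(abs(unname(r["KNO3"])), 0.15)
  })
})

test_that("simulated replicates at the calibrated dispersion are tightly correlated", {
  d <- tiny_dataset()
  r <- replicate_correlation(d$counts$polya, d$counts$conditions)
  expect_true(all(r > 0.9))
})
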