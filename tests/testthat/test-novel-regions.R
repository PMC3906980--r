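# NAT-aware pooling, zero-gap cluster calling with the 300 bp threshold,
# relation classification and cluster quantification.

pool_row <- function(start, end, strand = "+", sample = "s1")
  data.frame(seq = strrep("A", end - start + 1L), count = 1L,
             chrom = "Chr1", start = start, end = end, strand = strand,
             n_loci = 1L, sample = sample, stringsAsFactors = FALSE)

as_aln <- function(df) structure(list(alignments = df),
                                 class = "alignment_set")

test_that("pooling keeps antisense and intergenic reads, drops sense", {
  ann <- toy_annotation()
  aln <- rbind(pool_row(1200L, 1249L, "+"),   # sense inside G1: excluded
               pool_row(1200L, 1249L, "-"),   # antisense over G1: kept
               pool_row(9300L, 9349L, "+"))   # intergenic: kept
  pooled <- pool_unannotated(list(s1 = as_aln(aln[, -8])), ann)
  expect_equal(nrow(pooled), 2L)
  expect_setequal(pooled$start, c(1200L, 9300L))
})

test_that("contiguously tiled reads form a single cluster of their span", {
  reads <- do.call(rbind, lapply(seq(1L, 301L, by = 25L), function(s)
    pool_row(s, s + 49L)))
  cl <- call_clusters(reads, min_length = 300L)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$start, 1L)
  expect_equal(cl$end, 350L)
  expect_equal(cl$span, 350L)
})

test_that("a one-base gap breaks continuity and short runs are dropped", {
  runs <- rbind(do.call(rbind, lapply(seq(1L, 151L, 50L), function(s)
    pool_row(s, s + 49L))),                      # covers 1-200
    do.call(rbind, lapply(seq(202L, 402L, 50L), function(s)
      pool_row(s, s + 49L))))                    # covers 202-451
  expect_equal(nrow(call_clusters(runs, min_length = 300L)), 0L)
  # bridging the gap joins the runs into one >= 300 bp cluster
  expect_equal(nrow(call_clusters(runs, min_length = 300L, max_gap = 1L)),
               1L)
})

test_that("strands are clustered independently", {
  alt <- do.call(rbind, lapply(seq(1L, 351L, 25L), function(s)
    pool_row(s, s + 49L, strand = if ((s %/% 25L) %% 2L) "+" else "-")))
  # alternating 25-bp-offset reads still tile both strands contiguously
  cl <- call_clusters(alt, min_length = 300L)
  expect_equal(sort(unique(cl$strand)), c("+", "-"))
  sparse <- do.call(rbind, lapply(seq(1L, 351L, 70L), function(s)
    pool_row(s, s + 49L, strand = if ((s %/% 70L) %% 2L) "+" else "-")))
  # 70-bp stride with alternating strands leaves per-strand gaps
  expect_equal(nrow(call_clusters(sparse, min_length = 300L)), 0L)
})

test_that("raising min_length never adds clusters", {
  d <- tiny_dataset()
  idx <- build_index(d$genome)
  aln <- lapply(d$reads, function(r) map_reads(
    process_reads(r$polya, filter_config("polyA",
                                         adaptor = d$spec$adaptor)), idx))
  pooled <- pool_unannotated(aln, d$ann)
  n300 <- nrow(call_clusters(pooled, 300L))
  n400 <- nrow(call_clusters(pooled, 400L))
  n500 <- nrow(call_clusters(pooled, 500L))
  expect_true(n500 <= n400 && n400 <= n300)
  # idempotence: re-calling on the cluster-covering reads reproduces them
  cl <- call_clusters(pooled, 300L)
  gr <- GenomicRanges::GRanges(pooled$chrom,
                               IRanges::IRanges(pooled$start, pooled$end),
                               strand = pooled$strand)
  cgr <- GenomicRanges::GRanges(cl$chrom,
                                IRanges::IRanges(cl$start, cl$end),
                                strand = cl$strand)
  keep <- S4Vectors::queryHits(
    GenomicRanges::findOverlaps(gr, cgr, ignore.strand = FALSE))
  cl2 <- call_clusters(pooled[sort(unique(keep)), ], 300L)
  expect_equal(cl2[c("chrom", "start", "end", "strand")],
               cl[c("chrom", "start", "end", "strand")])
})

test_that("clusters are classified antisense or intergenic with flanks", {
  ann <- toy_annotation()
  cl <- data.frame(cluster_id = c("c1", "c2"), chrom = "Chr1",
                   start = c(1100L, 2200L), end = c(1500L, 2800L),
                   strand = c("-", "+"), span = c(401L, 601L),
                   stringsAsFactors = FALSE)
  out <- classify_clusters(cl, ann)
  expect_equal(out$relation, c("antisense_to", "intergenic"))
  expect_equal(out$antisense_gene[1], "G1")
  expect_equal(out$flank_upstream[2], "G1")
  expect_equal(out$flank_downstream[2], "G2")
})

test_that("an antisense cluster over two genes picks the larger overlap", {
  feats <- data.frame(class = "protein_coding_exon",
                      id = c("A.e", "B.e"), start = c(1001L, 2001L),
                      end = c(1900L, 2900L), strand = "+",
                      gene_id = c("A", "B"), stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = c("A", "B"), start = c(1001L, 2001L),
                      end = c(1900L, 2900L), strand = "+",
                      stringsAsFactors = FALSE)
  ann <- annotation_set(feats, genes, seqlengths = c(Chr1 = 5000L))
  cl <- data.frame(cluster_id = "c1", chrom = "Chr1", start = 1700L,
                   end = 2500L, strand = "-", span = 801L,
                   stringsAsFactors = FALSE)
  out <- classify_clusters(cl, ann)
  expect_equal(out$relation, "antisense_to")
  expect_equal(out$antisense_gene, "B")  # 500 bases vs 201
})

test_that("cluster counts are strand-aware and zero for absent samples", {
  cl <- data.frame(cluster_id = "c1", chrom = "Chr1", start = 100L,
                   end = 500L, strand = "+", span = 401L)
  s_with <- as_aln(pool_row(150L, 199L)[, -8])
  s_anti <- as_aln(pool_row(150L, 199L, "-")[, -8])
  s_none <- as_aln(pool_row(2000L, 2049L)[, -8])
  m <- cluster_counts(cl, list(a = s_with, b = s_anti, c = s_none))
  expect_equal(unname(m["c1", ]), c(1L, 0L, 0L))
})
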