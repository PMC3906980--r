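# Generator contracts: determinism, planted-structure truth consistency,
# count moments, and read construction.

test_that("an empty gene complement yields an annotation without genes", {
  spec <- genome_spec(genome_length = 20000L, n_genes = 0L,
                      n_mirna_loci = 0L, n_planted_nats = 0L,
                      n_planted_intergenic_clusters = 2L, seed = 3L)
  g <- make_genome(spec)
  expect_length(g$annotation$genes, 0L)
  cls <- S4Vectors::mcols(g$annotation$features)$class
  expect_false(any(grepl("protein_coding|UTR", cls)))
  expect_equal(nrow(g$truth$genes), 0L)
})

test_that("identical spec and seed reproduce byte-identical outputs", {
  spec <- tiny_spec()
  g1 <- make_genome(spec)
  g2 <- make_genome(spec)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$truth, g2$truth)
  f1 <- tempfile(); f2 <- tempfile()
  write_annotation_gff3(g1$annotation, f1)
  write_annotation_gff3(g2$annotation, f2)
  expect_identical(readLines(f1), readLines(f2))
  c1 <- simulate_counts(g1$truth, 2L, spec)
  c2 <- simulate_counts(g2$truth, 2L, spec)
  expect_identical(c1, c2)
  r1 <- simulate_reads(g1$genome, g1$annotation, g1$truth, c1, spec)
  r2 <- simulate_reads(g2$genome, g2$annotation, g2$truth, c2, spec)
  expect_identical(r1, r2)
})

test_that("planted antisense clusters sit inside genes on the opposite strand", {
  spec <- genome_spec(n_planted_nats = 4L, seed = 9L)
  g <- make_genome(spec)
  nats <- g$truth$clusters[g$truth$clusters$relation == "antisense_to", ]
  expect_equal(nrow(nats), 4L)
  for (i in seq_len(nrow(nats))) {
    host <- g$truth$genes[g$truth$genes$gene_id == nats$host_gene[i], ]
    expect_equal(nrow(host), 1L)
    expect_gte(nats$start[i], host$start)
    expect_lte(nats$end[i], host$end)
    expect_true(nats$strand[i] != host$strand)
  }
})

test_that("planted elements never overlap same-strand annotated features", {
  d <- tiny_dataset()
  cl <- d$truth$clusters
  gr <- GenomicRanges::GRanges(cl$chrom,
                               IRanges::IRanges(cl$start, cl$end),
                               strand = cl$strand)
  ov <- GenomicRanges::findOverlaps(gr, d$ann$features,
                                    ignore.strand = FALSE)
  expect_length(ov, 0L)
})

test_that("feature footprints exceeding the genome length raise a sizing error", {
  expect_error(make_genome(genome_spec(genome_length = 5000L,
                                       n_genes = 30L, seed = 1L)),
               "exceed")
})

test_that("count moments follow the NB model and its Poisson limit", {
  fake_truth <- function(n, mean) {
    structure(list(
      genes = data.frame(gene_id = sprintf("g%05d", 1:n), chrom = "Chr1",
                         start = 1L, end = 2L, strand = "+",
                         base_mean = mean, lfc = 0, is_de = FALSE,
                         mean_KCl = mean, mean_KNO3 = mean),
      clusters = data.frame(), mirna = data.frame()),
      class = "truth_table")
  }
  # Poisson limit: dispersion 0 gives variance ~ mean over 10,000 features
  spec0 <- genome_spec(nb_dispersion = 0, seed = 21L)
  cts <- simulate_counts(fake_truth(10000L, 100), 2L, spec0)
  v <- apply(cts$polya, 1, var); m <- rowMeans(cts$polya)
  expect_equal(mean(v), mean(m), tolerance = 0.1)
  # NB shape: variance ~ mean + alpha mean^2 within 10%
  spec1 <- genome_spec(nb_dispersion = 0.1, seed = 22L)
  cts1 <- simulate_counts(fake_truth(10000L, 100), 2L, spec1)
  expect_equal(mean(apply(cts1$polya, 1, var)), 100 + 0.1 * 100^2,
               tolerance = 0.1)
})

test_that("a null generator produces near-zero empirical log2 ratios", {
  spec <- tiny_spec(lfc_magnitude = 0)
  g <- make_genome(spec)
  expect_true(all(g$truth$genes$lfc == 0))
  cts <- simulate_counts(g$truth, 2L, spec)
  lr <- log2(rowMeans(cts$polya[, 3:4] + 0.5) /
               rowMeans(cts$polya[, 1:2] + 0.5))
  expect_lt(abs(mean(lr)), 0.1)
})

test_that("a planted mean 100 vs 400 gene realizes a log2 ratio near 2", {
  tr <- structure(list(
    genes = data.frame(gene_id = "g1", chrom = "Chr1", start = 1L,
                       end = 2L, strand = "+", base_mean = 200,
                       lfc = 2, is_de = TRUE, mean_KCl = 100,
                       mean_KNO3 = 400),
    clusters = data.frame(), mirna = data.frame()),
    class = "truth_table")
  cts <- simulate_counts(tr, 50L, genome_spec(seed = 23L))
  lr <- log2(mean(cts$polya[1, cts$conditions == "KNO3"]) /
               mean(cts$polya[1, cts$conditions == "KCl"]))
  expect_equal(lr, 2, tolerance = 0.1)
})

test_that("planted miRNA reads carry the mature sequence as post-trim insert", {
  d <- tiny_dataset()
  s <- "KCl_1"
  cfg <- filter_config("sRNA", adaptor = d$spec$adaptor)
  trimmed <- trim_adaptor(d$reads[[s]]$srna, cfg)
  for (k in seq_len(nrow(d$truth$mirna))) {
    mat <- d$truth$mirna$mature_seq[k]
    expect_equal(sum(trimmed$seq == mat),
                 unname(d$counts$srna[d$truth$mirna$name[k], s]))
  }
})

test_that("short sRNA inserts are adaptor-padded starting at insert + 1", {
  d <- tiny_dataset()
  raw <- d$reads$KNO3_1$srna$seq
  cfg <- filter_config("sRNA", adaptor = d$spec$adaptor)
  ins <- trim_adaptor(d$reads$KNO3_1$srna, cfg)$seq
  short <- nchar(ins) < d$spec$srna_cycle_length
  pad <- substring(raw[short], nchar(ins[short]) + 1L,
                   d$spec$srna_cycle_length)
  expect_true(all(pad == substring(d$spec$adaptor, 1L, nchar(pad))))
})

test_that("sRNA insert lengths are bimodal with modes 21 then 24", {
  spec <- tiny_spec(seed = 31L, n_srna_background = 12000L,
                    frac_junk_reads = 0)
  g <- make_genome(spec)
  cts <- simulate_counts(g$truth, 2L, spec)
  rds <- simulate_reads(g$genome, g$annotation, g$truth, cts, spec)
  cfg <- filter_config("sRNA", adaptor = spec$adaptor)
  ins <- trim_adaptor(rds$KCl_1$srna, cfg)$seq
  tab <- table(factor(nchar(ins), levels = 18:28))
  expect_gte(sum(tab), 10000L)
  ord <- order(tab, decreasing = TRUE)
  expect_equal(as.integer(names(tab)[ord[1]]), 21L)
  expect_equal(as.integer(names(tab)[ord[2]]), 24L)
  # empirical frequencies track the configured mixture weights (planted
  # miRNA reads add ~1% extra mass at 21 nt)
  freq <- as.vector(tab) / sum(tab)
  expect_lt(max(abs(freq - spec$srna_length_weights)), 0.03)
})

test_that("FASTQ writing and reading round-trip a read table", {
  d <- tiny_dataset()
  f <- tempfile(fileext = ".fastq")
  write_fastq(d$reads$KCl_1$polya, f)
  back <- read_fastq(f)
  expect_equal(back, d$reads$KCl_1$polya, ignore_attr = TRUE)
})
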