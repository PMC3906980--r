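# Shared fixtures and independent oracles, built in code.

# small dataset spec: fast enough for per-test regeneration
tiny_spec <- function(seed = 101L, ...) {
  args <- list(genome_length = 60000L, n_genes = 14L, n_mirna_loci = 4L,
               n_rrna_loci = 1L, n_trna_loci = 1L, n_pseudogenes = 1L,
               n_transposons = 2L, n_tasirna_loci = 1L,
               n_planted_nats = 2L, n_planted_intergenic_clusters = 3L,
               n_srna_background = 800L, seed = seed)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(genome_spec, args)
}

# cached tiny dataset (genome + annotation + truth + counts + reads),
# built once per test run
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- tiny_spec()
      g <- make_genome(spec)
      cts <- simulate_counts(g$truth, 2L, spec)
      rds <- simulate_reads(g$genome, g$annotation, g$truth, cts, spec)
      cache <<- list(spec = spec, genome = g$genome, ann = g$annotation,
                     truth = g$truth, counts = cts, reads = rds)
    }
    cache
  }
})

# hand-built annotation: two genes, an rRNA, a miRNA locus, a transposon
# on a 10 kb chromosome (coordinates chosen so nothing overlaps)
toy_annotation <- function() {
  feats <- data.frame(
    class = c("five_prime_UTR", "protein_coding_exon",
              "protein_coding_intron", "protein_coding_exon",
              "three_prime_UTR",
              "protein_coding_exon",
              "rRNA", "miRNA_stem_loop", "mature_miRNA",
              "transposable_element", "tRNA", "pseudogene",
              "tasiRNA_locus"),
    id = c("G1.u5", "G1.e1", "G1.i1", "G1.e2", "G1.u3",
           "G2.e1", "R1", "M1", "M1m", "TE1", "T1", "P1", "S1"),
    start = c(1001L, 1101L, 1401L, 1601L, 1901L,
              3001L, 4001L, 5001L, 5021L, 6001L, 7001L, 7501L, 8501L),
    end = c(1100L, 1400L, 1600L, 1900L, 2000L,
            3500L, 4500L, 5120L, 5041L, 6800L, 7080L, 8100L, 8900L),
    strand = c(rep("+", 5L), "-", "+", "+", "+", "+", "-", "+", "-"),
    gene_id = c(rep("G1", 5L), "G2", rep(NA, 7L)),
    stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = c("G1", "G2"),
                      start = c(1001L, 3001L), end = c(2000L, 3500L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  annotation_set(feats, genes, seqlengths = c(Chr1 = 10000L))
}

# reverse complement written independently of the package (oracle use)
rc_oracle <- function(x) vapply(x, function(s)
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = ""),
  character(1), USE.NAMES = FALSE)

# independent mapping oracle: vectorized sliding comparison of every
# window against the read, both strands, 1-based inclusive coordinates
naive_scan <- function(genome_chr, read) {
  w <- nchar(read)
  L <- nchar(genome_chr)
  if (w > L) return(data.frame(start = integer(), end = integer(),
                               strand = character()))
  windows <- substring(genome_chr, 1:(L - w + 1L), w:L)
  fw <- which(windows == read)
  rc <- which(windows == rc_oracle(read))
  data.frame(start = c(fw, rc), end = c(fw, rc) + w - 1L,
             strand = rep(c("+", "-"), c(length(fw), length(rc))),
             stringsAsFactors = FALSE)
}

# closed-form rarefaction oracle: E[distinct at depth d] without
# replacement = sum_s P(species s appears) via hypergeometric tails
expected_distinct <- function(counts, d) {
  N <- sum(counts)
  sum(1 - exp(lchoose(N - counts, d) - lchoose(N, d)))
}

# explicit conditional NB enumeration oracle mirroring the published
# construction: probabilities of all splits of the observed total
nb_p_oracle <- function(ka, kb, mu_a, var_a, mu_b, var_b) {
  dnb <- function(x, mu, var) {
    if (var <= mu) return(dpois(x, mu))
    dnbinom(x, mu = mu, size = mu^2 / (var - mu))
  }
  T <- ka + kb
  p <- vapply(0:T, function(a) dnb(a, mu_a, var_a) * dnb(T - a, mu_b, var_b),
              numeric(1))
  pobs <- p[ka + 1L]
  sum(p[p <= pobs * (1 + 1e-7)]) / sum(p)
}

# random DNA string
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")
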