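# Synthetic dataset generator: toy genome, annotation, ground truth, and
# stranded FASTQ libraries with the statistical structure the downstream
# stages assume (two conditions x two replicates, NB counts with planted
# fold changes, 21/24-nt bimodal sRNA sizes, multi-mapping repeats, planted
# unannotated sense/antisense transcribed regions, intronic/intergenic
# miRNA loci).

#' Specification of a synthetic dataset
#'
#' Collects every knob of the generator.  Defaults describe the study
#' conditions the package is designed around: a two-condition (KNO3 vs KCl)
#' by two-replicate design, 50 bp poly-A+ reads, 35-cycle sRNA reads with a
#' 21/24-nt bimodal insert-size structure, and 17 planted unannotated
#' transcribed regions of which 4 are antisense to genes (one induced
#' four-fold by the treatment).
#'
#' @param genome_length total chromosome length in bases.
#' @param n_genes number of protein-coding genes (UTR/exon/intron models).
#' @param n_mirna_loci number of miRNA loci (stem-loop plus 21-nt mature);
#'   roughly half are placed inside introns of host genes, the rest are
#'   intergenic.
#' @param n_rrna_loci,n_trna_loci,n_pseudogenes,n_transposons,n_tasirna_loci
#'   numbers of the remaining annotated feature classes.  When
#'   `n_transposons >= 2` the first two transposons carry identical
#'   sequence, so their reads map to exactly two loci (multi-mapping).
#' @param frac_de_genes proportion of genes with a planted fold change.
#' @param lfc_magnitude absolute planted log2 fold change (KNO3/KCl);
#'   planted genes alternate induced/repressed.
#' @param nb_dispersion negative-binomial dispersion alpha in
#'   `Var = mu + alpha * mu^2`; 0 gives the Poisson limit.
#' @param n_planted_nats planted antisense clusters (each fully inside a
#'   gene's span on the opposite strand); the first one is induced with a
#'   log2 ratio of 2 (four-fold).
#' @param n_planted_intergenic_clusters planted unannotated sense clusters
#'   in intergenic space.
#' @param cluster_length length in bases of every planted cluster.
#' @param read_length_mrna poly-A+ read length in bases.
#' @param srna_cycle_length sRNA sequencing cycle count; inserts shorter
#'   than this are padded with the 3' adaptor.
#' @param adaptor 3' adaptor (cloning-linker) sequence appended to sRNA
#'   inserts and searched for by the trimmer.
#' @param srna_length_weights named numeric vector of insert-length
#'   probabilities for background sRNA reads (names "18".."28"); the
#'   default peaks at 21 nt with a secondary 24-nt mode.
#' @param n_srna_background background (non-miRNA) sRNA reads per sample.
#' @param frac_low_quality_reads fraction of reads rendered low-quality
#'   (enough Q10 bases to fail the Q20/90% rule).
#' @param frac_junk_reads fraction of extra homopolymer (poly-A insert)
#'   sRNA reads, exercising the polynucleotide filter.
#' @param q_high,q_low the two Phred levels of the quality model.
#' @param base_mean_log,base_mean_sdlog log-normal parameters of gene
#'   base means (counts per sample).
#' @param cluster_mean,mirna_mean base mean counts for planted clusters
#'   and miRNA loci.
#' @param seed integer seed; identical spec + seed gives byte-identical
#'   outputs.
#' @return an object of class `genome_spec` (a validated list).
#' @export
genome_spec <- function(genome_length = 200000L,
                        n_genes = 60L,
                        n_mirna_loci = 8L,
                        n_rrna_loci = 2L,
                        n_trna_loci = 2L,
                        n_pseudogenes = 2L,
                        n_transposons = 3L,
                        n_tasirna_loci = 1L,
                        frac_de_genes = 0.2,
                        lfc_magnitude = 2,
                        nb_dispersion = 0.005,
                        n_planted_nats = 4L,
                        n_planted_intergenic_clusters = 13L,
                        cluster_length = 400L,
                        read_length_mrna = 50L,
                        srna_cycle_length = 35L,
                        adaptor = "CTGTAGGCACCATCAAT",
                        srna_length_weights = c(
                          "18" = 0.02, "19" = 0.03, "20" = 0.08,
                          "21" = 0.30, "22" = 0.12, "23" = 0.10,
                          "24" = 0.20, "25" = 0.06, "26" = 0.04,
                          "27" = 0.03, "28" = 0.02),
                        n_srna_background = 3000L,
                        frac_low_quality_reads = 0.05,
                        frac_junk_reads = 0.01,
                        q_high = 35L, q_low = 10L,
                        base_mean_log = log(80), base_mean_sdlog = 1,
                        cluster_mean = 60, mirna_mean = 30,
                        seed = 1L) {
  spec <- list(
    genome_length = as.integer(genome_length),
    n_genes = as.integer(n_genes),
    n_mirna_loci = as.integer(n_mirna_loci),
    n_rrna_loci = as.integer(n_rrna_loci),
    n_trna_loci = as.integer(n_trna_loci),
    n_pseudogenes = as.integer(n_pseudogenes),
    n_transposons = as.integer(n_transposons),
    n_tasirna_loci = as.integer(n_tasirna_loci),
    frac_de_genes = frac_de_genes,
    lfc_magnitude = lfc_magnitude,
    nb_dispersion = nb_dispersion,
    n_planted_nats = as.integer(n_planted_nats),
    n_planted_intergenic_clusters = as.integer(n_planted_intergenic_clusters),
    cluster_length = as.integer(cluster_length),
    read_length_mrna = as.integer(read_length_mrna),
    srna_cycle_length = as.integer(srna_cycle_length),
    adaptor = toupper(adaptor),
    srna_length_weights = srna_length_weights / sum(srna_length_weights),
    n_srna_background = as.integer(n_srna_background),
    frac_low_quality_reads = frac_low_quality_reads,
    frac_junk_reads = frac_junk_reads,
    q_high = as.integer(q_high), q_low = as.integer(q_low),
    base_mean_log = base_mean_log, base_mean_sdlog = base_mean_sdlog,
    cluster_mean = cluster_mean, mirna_mean = mirna_mean,
    seed = as.integer(seed))
  if (spec$frac_de_genes < 0 || spec$frac_de_genes > 1)
    stopf("frac_de_genes must lie in [0, 1]")
  if (spec$nb_dispersion < 0)
    stopf("nb_dispersion must be >= 0")
  if (spec$n_planted_nats > spec$n_genes)
    stopf("cannot plant more antisense clusters than genes")
  class(spec) <- "genome_spec"
  spec
}

# fixed structural sizes of generated features (bases)
.sizes <- list(utr5 = 100L, utr3 = 100L, intron = 150L,
               exon_min = 250L, exon_max = 350L,
               rrna = 500L, trna = 80L, pseudogene = 600L,
               transposon = 800L, tasirna = 400L, stem_loop = 120L,
               mature = 21L, gap_min = 200L, gap_max = 600L)

#' Generate a toy genome, annotation and ground-truth table
#'
#' Lays out non-overlapping features left-to-right on a single chromosome
#' ("Chr1") with random inter-feature gaps, then plants antisense clusters
#' inside gene spans (opposite strand) and intergenic clusters in the gaps.
#' The first two transposons share identical sequence so their reads
#' multi-map.  True per-condition expression means and planted log2 fold
#' changes are drawn here and recorded in the truth table.
#'
#' @param spec a [genome_spec()].
#' @return a list with elements `genome` (a named [Biostrings::DNAStringSet]
#'   of length 1), `annotation` (an [annotation_set()]), and `truth` (class
#'   `truth_table`: data frames `genes`, `clusters`, `mirna`).
#' @export
make_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  withr::with_seed(spec$seed, .make_genome_impl(spec))
}

.make_genome_impl <- function(spec) {
  sz <- .sizes
  gap <- function() sample(sz$gap_min:sz$gap_max, 1L)

  slots <- c(rep("gene", spec$n_genes),
             rep("rRNA", spec$n_rrna_loci),
             rep("tRNA", spec$n_trna_loci),
             rep("pseudogene", spec$n_pseudogenes),
             rep("transposable_element", spec$n_transposons),
             rep("tasiRNA_locus", spec$n_tasirna_loci),
             rep("mirna_intergenic", ceiling(spec$n_mirna_loci / 2)),
             rep("intergenic_cluster", spec$n_planted_intergenic_clusters))
  slots <- sample(slots)

  feats <- list()    # annotation rows (list of data.frames)
  genes <- list()    # gene bookkeeping incl. intron coords
  clusters <- list() # planted cluster truth rows
  mirna <- list()    # planted miRNA truth rows
  cursor <- 1L + gap()
  gi <- ri <- ti <- pi_ <- xi <- si <- mi <- ci <- 0L

  add_feat <- function(class, id, start, end, strand, gene_id = NA_character_) {
    feats[[length(feats) + 1L]] <<- data.frame(
      class = class, id = id, start = start, end = end,
      strand = strand, gene_id = gene_id, stringsAsFactors = FALSE)
  }

  for (slot in slots) {
    if (slot == "gene") {
      gi <- gi + 1L
      id <- sprintf("GENE%03d", gi)
      strand <- sample(c("+", "-"), 1L)
      n_introns <- sample(1:2, 1L)
      exon_lens <- sample(sz$exon_min:sz$exon_max, n_introns + 1L,
                          replace = TRUE)
      # 5'UTR, alternating exons/introns, 3'UTR laid out along + coords;
      # for - strand genes the 5'UTR is at the right edge.
      parts <- c(sz$utr5, as.vector(rbind(exon_lens,
                                          c(rep(sz$intron, n_introns), 0L))),
                 sz$utr3)
      parts <- parts[parts > 0L]
      starts <- cursor + c(0L, cumsum(parts[-length(parts)]))
      ends <- starts + parts - 1L
      g_start <- cursor; g_end <- ends[length(ends)]
      labels_plus <- c("five_prime_UTR",
                       as.vector(rbind(rep("protein_coding_exon",
                                           n_introns + 1L),
                                       c(rep("protein_coding_intron",
                                             n_introns), ""))),
                       "three_prime_UTR")
      labels_plus <- labels_plus[labels_plus != ""]
      labels <- if (strand == "+") labels_plus else rev(labels_plus)
      # rev() swaps UTR ends for - strand genes; exon/intron labels are
      # symmetric so only the UTRs move.
      for (k in seq_along(parts))
        add_feat(labels[k], sprintf("%s.p%d", id, k),
                 starts[k], ends[k], strand, id)
      introns <- data.frame(start = starts[labels == "protein_coding_intron"],
                            end = ends[labels == "protein_coding_intron"])
      genes[[gi]] <- list(id = id, start = g_start, end = g_end,
                          strand = strand, introns = introns,
                          hosts_mirna = FALSE)
      cursor <- g_end + 1L + gap()
    } else if (slot == "mirna_intergenic") {
      mi <- mi + 1L
      strand <- sample(c("+", "-"), 1L)
      sl_start <- cursor; sl_end <- cursor + sz$stem_loop - 1L
      m_start <- sl_start + 20L; m_end <- m_start + sz$mature - 1L
      name <- sprintf("syn-MIR%03d", mi)
      add_feat("miRNA_stem_loop", name, sl_start, sl_end, strand)
      add_feat("mature_miRNA", paste0(name, "-mature"),
               m_start, m_end, strand, NA_character_)
      mirna[[length(mirna) + 1L]] <- data.frame(
        name = name, chrom = "Chr1", start = m_start, end = m_end,
        strand = strand, context = "intergenic", host_gene = NA_character_,
        sl_start = sl_start, sl_end = sl_end, stringsAsFactors = FALSE)
      cursor <- sl_end + 1L + gap()
    } else if (slot == "intergenic_cluster") {
      ci <- ci + 1L
      strand <- sample(c("+", "-"), 1L)
      clusters[[length(clusters) + 1L]] <- data.frame(
        cluster_id = sprintf("CLST%02d", ci), chrom = "Chr1",
        start = cursor, end = cursor + spec$cluster_length - 1L,
        strand = strand, relation = "intergenic",
        host_gene = NA_character_, stringsAsFactors = FALSE)
      cursor <- cursor + spec$cluster_length + gap()
    } else {
      len <- switch(slot, rRNA = sz$rrna, tRNA = sz$trna,
                    pseudogene = sz$pseudogene,
                    transposable_element = sz$transposon,
                    tasiRNA_locus = sz$tasirna)
      idx <- switch(slot, rRNA = ri <- ri + 1L, tRNA = ti <- ti + 1L,
                    pseudogene = pi_ <- pi_ + 1L,
                    transposable_element = xi <- xi + 1L,
                    tasiRNA_locus = si <- si + 1L)
      id <- sprintf("%s%02d", toupper(substr(slot, 1L, 4L)), idx)
      strand <- sample(c("+", "-"), 1L)
      add_feat(slot, id, cursor, cursor + len - 1L, strand)
      cursor <- cursor + len + gap()
    }
  }
  if (cursor > spec$genome_length)
    stopf("feature footprints (%d bases) exceed genome_length (%d)",
          cursor, spec$genome_length)

  # intronic miRNA loci: hosted in introns of already-placed genes
  n_intronic <- spec$n_mirna_loci - ceiling(spec$n_mirna_loci / 2)
  host_pool <- which(vapply(genes, function(g) nrow(g$introns) > 0L,
                            logical(1)))
  if (n_intronic > length(host_pool))
    stopf("not enough genes with introns to host %d intronic miRNA loci",
          n_intronic)
  hosts <- if (n_intronic > 0L) sample(host_pool, n_intronic) else integer()
  for (h in hosts) {
    mi <- mi + 1L
    g <- genes[[h]]
    genes[[h]]$hosts_mirna <- TRUE
    intr <- g$introns[sample(nrow(g$introns), 1L), ]
    sl_start <- intr$start + 10L
    sl_end <- sl_start + sz$stem_loop - 1L
    stopifnot(sl_end <= intr$end)
    m_start <- sl_start + 20L; m_end <- m_start + sz$mature - 1L
    name <- sprintf("syn-MIR%03d", mi)
    add_feat("miRNA_stem_loop", name, sl_start, sl_end, g$strand, g$id)
    add_feat("mature_miRNA", paste0(name, "-mature"),
             m_start, m_end, g$strand, g$id)
    mirna[[length(mirna) + 1L]] <- data.frame(
      name = name, chrom = "Chr1", start = m_start, end = m_end,
      strand = g$strand, context = "intron", host_gene = g$id,
      sl_start = sl_start, sl_end = sl_end, stringsAsFactors = FALSE)
  }

  # planted antisense clusters inside gene spans, opposite strand;
  # miRNA-hosting genes are avoided to keep truth contexts unambiguous
  nat_pool <- which(!vapply(genes, `[[`, logical(1), "hosts_mirna"))
  nat_hosts <- if (spec$n_planted_nats > 0L)
    sample(nat_pool, spec$n_planted_nats) else integer()
  for (h in nat_hosts) {
    ci <- ci + 1L
    g <- genes[[h]]
    c_start <- g$start + 100L
    c_end <- c_start + spec$cluster_length - 1L
    stopifnot(c_end <= g$end)
    clusters[[length(clusters) + 1L]] <- data.frame(
      cluster_id = sprintf("CLST%02d", ci), chrom = "Chr1",
      start = c_start, end = c_end,
      strand = if (g$strand == "+") "-" else "+",
      relation = "antisense_to", host_gene = g$id, stringsAsFactors = FALSE)
  }

  # genome sequence; transposons 1 and 2 carry identical sequence
  seq <- sample(c("A", "C", "G", "T"), spec$genome_length, replace = TRUE)
  fdf <- do.call(rbind, feats)
  tes <- fdf[fdf$class == "transposable_element", , drop = FALSE]
  if (nrow(tes) >= 2L) {
    src <- tes[1L, ]; dst <- tes[2L, ]
    seq[dst$start:dst$end] <- seq[src$start:src$end]
  }
  genome_chr <- paste(seq, collapse = "")
  genome <- Biostrings::DNAStringSet(stats::setNames(genome_chr, "Chr1"))

  # expression truth
  gdf <- if (length(genes)) do.call(rbind, lapply(genes, function(g)
    data.frame(gene_id = g$id, chrom = "Chr1", start = g$start, end = g$end,
               strand = g$strand, stringsAsFactors = FALSE)))
  else data.frame(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  stringsAsFactors = FALSE)
  gdf <- gdf[order(gdf$start), ]
  n_de <- round(spec$frac_de_genes * nrow(gdf))
  de_idx <- if (n_de > 0L) sample(nrow(gdf), n_de) else integer()
  gdf$base_mean <- rlnorm(nrow(gdf), spec$base_mean_log, spec$base_mean_sdlog)
  gdf$lfc <- rep(0, nrow(gdf))
  if (n_de > 0L)
    gdf$lfc[de_idx] <- rep_len(c(1, -1), n_de) * spec$lfc_magnitude
  gdf$is_de <- gdf$lfc != 0
  gdf$mean_KCl <- gdf$base_mean * 2^(-gdf$lfc / 2)
  gdf$mean_KNO3 <- gdf$base_mean * 2^(gdf$lfc / 2)

  cdf <- if (length(clusters)) do.call(rbind, clusters) else
    data.frame(cluster_id = character(), chrom = character(),
               start = integer(), end = integer(), strand = character(),
               relation = character(), host_gene = character())
  cdf$lfc <- rep(0, nrow(cdf))
  nat_rows <- which(cdf$relation == "antisense_to")
  if (length(nat_rows)) cdf$lfc[nat_rows[1L]] <- 2  # the induced NAT (4x)
  cdf$mean_KCl <- spec$cluster_mean * 2^(-cdf$lfc / 2)
  cdf$mean_KNO3 <- spec$cluster_mean * 2^(cdf$lfc / 2)

  mdf <- if (length(mirna)) do.call(rbind, mirna) else
    data.frame(name = character(), chrom = character(), start = integer(),
               end = integer(), strand = character(), context = character(),
               host_gene = character(), sl_start = integer(),
               sl_end = integer())
  if (nrow(mdf)) {
    mdf$mature_seq <- vapply(seq_len(nrow(mdf)), function(i)
      substr(genome_chr, mdf$start[i], mdf$end[i]), character(1))
    neg <- mdf$strand == "-"
    mdf$mature_seq[neg] <- revcomp_chr(mdf$mature_seq[neg])
    mdf$mean <- spec$mirna_mean
  } else {
    mdf$mature_seq <- character()
    mdf$mean <- numeric()
  }

  truth <- structure(list(genes = gdf, clusters = cdf, mirna = mdf),
                     class = "truth_table")
  ann <- annotation_set(fdf, gdf, seqlengths = c(Chr1 = spec$genome_length))
  list(genome = genome, annotation = ann, truth = truth)
}

#' Simulate per-feature, per-sample NB counts
#'
#' Draws negative-binomial counts (`Var = mu + alpha * mu^2`) for every
#' gene, planted cluster and miRNA locus under the two-condition design,
#' using the true per-condition means in the truth table.  With
#' `nb_dispersion = 0` the Poisson limit is used.
#'
#' @param truth a `truth_table` from [make_genome()].
#' @param n_replicates replicates per condition (>= 2).
#' @param spec the [genome_spec()] (supplies dispersion and seed).
#' @return list with `polya` (matrix, genes + clusters by samples), `srna`
#'   (matrix, miRNA loci by samples) and `conditions` (factor KCl/KNO3
#'   parallel to the matrix columns).
#' @export
simulate_counts <- function(truth, n_replicates = 2L, spec) {
  stopifnot(inherits(truth, "truth_table"), inherits(spec, "genome_spec"))
  if (n_replicates < 2L) stopf("n_replicates must be >= 2")
  withr::with_seed(spec$seed + 1L, {
    conds <- rep(c("KCl", "KNO3"), each = n_replicates)
    samples <- paste0(conds, "_", rep(seq_len(n_replicates), 2L))
    draw <- function(mu, n) {
      if (spec$nb_dispersion == 0) rpois(n, mu)
      else rnbinom(n, mu = mu, size = 1 / spec$nb_dispersion)
    }
    sim_block <- function(ids, mean_kcl, mean_kno3) {
      m <- matrix(0L, nrow = length(ids), ncol = length(samples),
                  dimnames = list(ids, samples))
      for (j in seq_along(samples)) {
        mu <- if (conds[j] == "KCl") mean_kcl else mean_kno3
        m[, j] <- draw(mu, length(ids))
      }
      m
    }
    polya <- rbind(
      sim_block(truth$genes$gene_id, truth$genes$mean_KCl,
                truth$genes$mean_KNO3),
      if (nrow(truth$clusters))
        sim_block(truth$clusters$cluster_id, truth$clusters$mean_KCl,
                  truth$clusters$mean_KNO3))
    srna <- if (nrow(truth$mirna))
      sim_block(truth$mirna$name, truth$mirna$mean, truth$mirna$mean)
    else matrix(0L, 0L, length(samples),
                dimnames = list(NULL, samples))
    list(polya = polya, srna = srna,
         conditions = factor(conds, levels = c("KCl", "KNO3")))
  })
}

# two-level Phred quality strings; "bad" reads carry ~30% Q-low bases and
# therefore fail the >=90%-at-Q20 rule, good reads ~0.5% and pass
.make_quals <- function(lens, bad, q_high, q_low) {
  vapply(seq_along(lens), function(i) {
    p <- if (bad[i]) 0.30 else 0.005
    q <- ifelse(runif(lens[i]) < p, q_low, q_high)
    intToUtf8(q + 33L)
  }, character(1))
}

# evenly spaced start positions guaranteeing zero-gap coverage of
# [start, end] by reads of length rl, plus random extras up to n
.tiling_starts <- function(start, end, rl, n) {
  last <- end - rl + 1L
  if (last < start) return(integer())
  k_min <- max(2L, ceiling((last - start) / (rl - 1L)) + 1L)
  if (n >= k_min) {
    base <- unique(round(seq(start, last, length.out = k_min)))
    extra <- if (n > length(base))
      sample(start:last, n - length(base), replace = TRUE) else integer()
    c(base, extra)
  } else {
    # too few reads to tile: spread what we have
    unique(round(seq(start, last, length.out = max(n, 1L))))
  }
}

#' Simulate stranded FASTQ read sets for every sample
#'
#' Poly-A+ reads are `read_length_mrna`-base genomic fragments of sense
#' transcripts (planted clusters emit reads on their own, possibly
#' antisense, strand; planted clusters are tiled so that coverage is
#' gap-free whenever counts permit).  sRNA reads are miRNA mature
#' sequences (exactly `count` copies each) plus background inserts drawn
#' from the bimodal length mix at random genome positions; inserts shorter
#' than the cycle length are padded with the 3' adaptor.  A configurable
#' fraction of reads carries low qualities and a small fraction of sRNA
#' reads are poly-A homopolymer junk.
#'
#' @param genome named [Biostrings::DNAStringSet] from [make_genome()].
#' @param annotation the matching [annotation_set()] (unused by the
#'   generator itself but kept in the signature for interface symmetry).
#' @param truth the `truth_table`.
#' @param counts output of [simulate_counts()].
#' @param spec the [genome_spec()].
#' @return named list (one element per sample) of lists with read tables
#'   `polya` and `srna`; each read table has columns `id`, `seq`, `qual`.
#' @export
simulate_reads <- function(genome, annotation, truth, counts, spec) {
  stopifnot(inherits(spec, "genome_spec"))
  withr::with_seed(spec$seed + 2L,
                   .simulate_reads_impl(genome, truth, counts, spec))
}

.simulate_reads_impl <- function(genome, truth, counts, spec) {
  gchr <- as.character(genome[[1L]])
  glen <- nchar(gchr)
  rl <- spec$read_length_mrna
  samples <- colnames(counts$polya)
  feat <- rbind(
    data.frame(id = truth$genes$gene_id, start = truth$genes$start,
               end = truth$genes$end, strand = truth$genes$strand,
               tiled = FALSE, stringsAsFactors = FALSE),
    if (nrow(truth$clusters))
      data.frame(id = truth$clusters$cluster_id,
                 start = truth$clusters$start, end = truth$clusters$end,
                 strand = truth$clusters$strand, tiled = TRUE,
                 stringsAsFactors = FALSE))
  out <- vector("list", length(samples))
  names(out) <- samples

  lens <- as.integer(names(spec$srna_length_weights))

  for (s in samples) {
    ## poly-A+ library
    starts <- integer(); strands <- character()
    for (i in seq_len(nrow(feat))) {
      n <- counts$polya[feat$id[i], s]
      if (n == 0L) next
      last <- feat$end[i] - rl + 1L
      if (last < feat$start[i])
        stopf("feature %s shorter than the read length", feat$id[i])
      st <- if (feat$tiled[i])
        .tiling_starts(feat$start[i], feat$end[i], rl, n)
      else sample(feat$start[i]:last, n, replace = TRUE)
      starts <- c(starts, st)
      strands <- c(strands, rep(feat$strand[i], length(st)))
    }
    pseq <- substring(gchr, starts, starts + rl - 1L)
    neg <- strands == "-"
    pseq[neg] <- revcomp_chr(pseq[neg])
    bad <- runif(length(pseq)) < spec$frac_low_quality_reads
    polya <- data.frame(
      id = sprintf("%s_polyA_%06d", s, seq_along(pseq)),
      seq = pseq,
      qual = .make_quals(rep(rl, length(pseq)), bad, spec$q_high, spec$q_low),
      stringsAsFactors = FALSE)

    ## sRNA library: mature miRNA copies + bimodal background + junk
    ins <- character()
    if (nrow(truth$mirna)) {
      n_mir <- counts$srna[truth$mirna$name, s]
      ins <- rep(truth$mirna$mature_seq, n_mir)
    }
    n_bg <- spec$n_srna_background
    if (n_bg > 0L) {
      bg_len <- sample(lens, n_bg, replace = TRUE,
                       prob = spec$srna_length_weights)
      bg_start <- vapply(bg_len, function(l)
        sample.int(glen - l + 1L, 1L), integer(1))
      bg <- substring(gchr, bg_start, bg_start + bg_len - 1L)
      bg_neg <- runif(n_bg) < 0.5
      bg[bg_neg] <- revcomp_chr(bg[bg_neg])
      ins <- c(ins, bg)
    }
    n_junk <- round(spec$frac_junk_reads * length(ins))
    if (n_junk > 0L)
      ins <- c(ins, strrep("A", sample(lens, n_junk, replace = TRUE)))
    pad <- substring(spec$adaptor, 1L,
                     pmax(0L, spec$srna_cycle_length - nchar(ins)))
    sseq <- substr(paste0(ins, pad), 1L, spec$srna_cycle_length)
    bad_s <- runif(length(sseq)) < spec$frac_low_quality_reads
    srna <- data.frame(
      id = sprintf("%s_sRNA_%06d", s, seq_along(sseq)),
      seq = sseq,
      qual = .make_quals(nchar(sseq), bad_s, spec$q_high, spec$q_low),
      stringsAsFactors = FALSE)

    out[[s]] <- list(polya = polya, srna = srna)
  }
  out
}

#' Simulate a probe-level microarray expression table
#'
#' Emulates a normalized single-channel array hybridized with the same RNA
#' samples: a probe for a configurable fraction of genes, log2 signal
#' proportional to the true condition mean plus Gaussian noise, and a
#' present/absent call per sample driven by the true mean.
#'
#' @param truth a `truth_table`.
#' @param spec the [genome_spec()].
#' @param frac_with_probe fraction of genes represented on the array.
#' @param noise_sd standard deviation of log2 signal noise.
#' @param present_mean_min minimum true mean for a present call.
#' @return data frame with columns `probe`, `gene_id`, per-sample
#'   `signal_*` and `call_*` columns (samples KCl_1, KCl_2, KNO3_1,
#'   KNO3_2).
#' @export
simulate_array_table <- function(truth, spec, frac_with_probe = 0.85,
                                 noise_sd = 0.15, present_mean_min = 5) {
  stopifnot(inherits(truth, "truth_table"))
  withr::with_seed(spec$seed + 3L, {
    g <- truth$genes
    keep <- sort(sample(nrow(g), round(frac_with_probe * nrow(g))))
    g <- g[keep, ]
    samples <- c("KCl_1", "KCl_2", "KNO3_1", "KNO3_2")
    out <- data.frame(probe = paste0(g$gene_id, "_at"), gene_id = g$gene_id,
                      stringsAsFactors = FALSE)
    for (s in samples) {
      mu <- if (grepl("^KCl", s)) g$mean_KCl else g$mean_KNO3
      out[[paste0("signal_", s)]] <-
        round(log2(mu + 1) + rnorm(nrow(g), 0, noise_sd), 4)
      out[[paste0("call_", s)]] <- ifelse(mu >= present_mean_min, "P", "A")
    }
    out
  })
}

#' Write a read table to a FASTQ file (Sanger Phred+33)
#' @param reads data frame with columns `id`, `seq`, `qual`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(stats::setNames(reads$seq, reads$id)),
    Biostrings::PhredQuality(reads$qual))
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file into a read table
#' @param path FASTQ file (Sanger Phred+33 qualities).
#' @return data frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}
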