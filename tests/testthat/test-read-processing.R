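# Filtering rules at their stated thresholds, adaptor trimming at the
# overlap boundary, and accounting conservation.

mk_reads <- function(seqs, quals = NULL) {
  if (is.null(quals)) quals <- strrep("D", nchar(seqs))  # Q35
  data.frame(id = sprintf("r%d", seq_along(seqs)), seq = seqs,
             qual = quals, stringsAsFactors = FALSE)
}
q_chr <- function(scores) intToUtf8(scores + 33L)

test_that("quality filter applies the fraction-at-Q20 rule exactly", {
  cfg <- filter_config("sRNA")
  hi <- mk_reads(strrep("A", 10), q_chr(rep(35L, 10)))
  lo <- mk_reads(strrep("A", 10), q_chr(rep(10L, 10)))
  edge <- mk_reads(strrep("A", 10), q_chr(c(rep(30L, 9), 10L)))
  expect_equal(nrow(filter_quality(hi, cfg)), 1L)
  expect_equal(nrow(filter_quality(lo, cfg)), 0L)
  # 9/10 bases at Q30 >= 0.9 fraction: retained
  expect_equal(nrow(filter_quality(edge, cfg)), 1L)
  below <- mk_reads(strrep("A", 10), q_chr(c(rep(30L, 8), 10L, 10L)))
  expect_equal(nrow(filter_quality(below, cfg)), 0L)
})

test_that("N-containing reads are discarded as quality failures", {
  cfg <- filter_config("sRNA")
  r <- mk_reads("ACGTNACGTACGTACGTACGT")
  out <- filter_quality(r, cfg)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "n_fail"), 1L)
})

test_that("mismatched sequence/quality lengths name the offending record", {
  cfg <- filter_config("sRNA")
  bad <- data.frame(id = c("a", "b"), seq = c("ACGT", "ACGT"),
                    qual = c("DDDD", "DDD"))
  expect_error(filter_quality(bad, cfg), "record 2")
})

test_that("adaptor trimming truncates at the leftmost full occurrence", {
  cfg <- filter_config("sRNA")
  insert <- "ACGTACGTACGTACGTACGTA"
  r <- mk_reads(paste0(insert, cfg$adaptor))
  out <- trim_adaptor(r, cfg)
  expect_equal(out$seq, insert)
  expect_equal(nchar(out$qual), nchar(insert))
})

test_that("reads without the adaptor are unchanged and trimming is idempotent", {
  cfg <- filter_config("sRNA")
  r <- mk_reads("ACCCTTGGAACCTTGGAATT")
  expect_identical(trim_adaptor(r, cfg), r)
  once <- trim_adaptor(mk_reads(paste0("ACGTACGTACGTACGTACGTA",
                                       cfg$adaptor)), cfg)
  expect_identical(trim_adaptor(once, cfg), once)
})

test_that("a terminal adaptor prefix of the minimum overlap is removed", {
  cfg <- filter_config("sRNA")
  five <- substr(cfg$adaptor, 1, 5)
  r <- mk_reads(paste0("ACCCTTGGAACCGTGGAATT", five))
  out <- trim_adaptor(r, cfg)
  expect_equal(out$seq, "ACCCTTGGAACCGTGGAATT")
  # 4-base terminal prefix is below the overlap threshold: untouched
  r4 <- mk_reads(paste0("ACCCTTGGAACCGTGGAATT", substr(cfg$adaptor, 1, 4)))
  expect_identical(trim_adaptor(r4, cfg), r4)
})

test_that("size filter applies the closed 18-28 window for sRNA", {
  cfg <- filter_config("sRNA")
  lens <- c(17L, 18L, 28L, 29L)
  reads <- mk_reads(vapply(lens, function(l) strrep("ACGT", 8) |>
                             substr(1, l), character(1)))
  rs <- filter_size_and_composition(reads, cfg)
  kept <- nchar(rs$sequences$seq)
  expect_setequal(kept, c(18L, 28L))
  expect_equal(rs$stats[["size_fail"]], 2L)
})

test_that("polyA libraries have no upper size bound", {
  cfg <- filter_config("polyA")
  rs <- filter_size_and_composition(mk_reads(strrep("ACGT", 20)), cfg)
  expect_equal(rs$stats[["retained"]], 1L)
})

test_that("homopolymer reads are discarded by the composition rule", {
  cfg <- filter_config("sRNA")
  expect_warning(
    rs <- filter_size_and_composition(mk_reads(strrep("A", 20)), cfg),
    "no reads survive")
  expect_equal(rs$stats[["composition_fail"]], 1L)
  expect_equal(rs$stats[["retained"]], 0L)
  # 0.8 boundary: 16 of 20 A's is not > 0.8, retained
  mixed <- paste0(strrep("A", 16), "CGTC")
  rs2 <- filter_size_and_composition(mk_reads(mixed), cfg)
  expect_equal(rs2$stats[["retained"]], 1L)
})

test_that("identical reads collapse into one entry with multiplicity", {
  cfg <- filter_config("sRNA")
  rs <- filter_size_and_composition(
    mk_reads(rep("ACGTACGTACGTACGTACGT", 3L)), cfg)
  expect_equal(nrow(rs$sequences), 1L)
  expect_equal(rs$sequences$count, 3L)
})

test_that("accounting conserves reads and multiplicities ignore input order", {
  d <- tiny_dataset()
  cfg <- filter_config("sRNA", adaptor = d$spec$adaptor)
  raw <- d$reads$KNO3_2$srna
  rs <- process_reads(raw, cfg)
  st <- rs$stats
  expect_equal(st[["raw"]],
               st[["retained"]] + st[["quality_fail"]] +
                 st[["size_fail"]] + st[["composition_fail"]])
  expect_equal(sum(rs$sequences$count), st[["retained"]])
  shuffled <- raw[withr::with_seed(5L, sample(nrow(raw))), ]
  rs2 <- process_reads(shuffled, cfg)
  expect_identical(rs$sequences, rs2$sequences)
})

test_that("read_set construction rejects unbalanced accounting", {
  expect_error(read_set(data.frame(seq = "ACGT", count = 1L), "sRNA",
                        stats = c(raw = 5L, quality_fail = 1L,
                                  size_fail = 0L, composition_fail = 0L,
                                  retained = 1L)),
               "does not balance")
})

test_that("filter_stats mirrors the per-library accounting", {
  d <- tiny_dataset()
  cfg <- filter_config("polyA", adaptor = d$spec$adaptor)
  rs <- process_reads(d$reads$KCl_1$polya, cfg)
  tab <- filter_stats(list(KCl_1 = rs))
  expect_equal(tab$raw, unname(rs$stats[["raw"]]))
  expect_equal(tab$retained, unname(rs$stats[["retained"]]))
  expect_equal(tab$library, "polyA")
})
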