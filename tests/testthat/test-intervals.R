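# Interval algebra: BED parsing, direct-overlap merging, replicate
# consensus, Venn bookkeeping and promoter assignment.

test_that("parse_bed handles BED3..BED6, defaults and malformed input", {
  f <- bed_file("chr1\t100\t200\tp1\t5\t+")
  gr <- parse_bed(f)
  expect_equal(GenomicRanges::start(gr), 101)   # 0-based half-open input
  expect_equal(GenomicRanges::end(gr), 200)
  expect_equal(gr$name, "p1")
  expect_equal(gr$score, 5)
  expect_equal(as.character(GenomicRanges::strand(gr)), "+")

  g3 <- parse_bed(bed_file("chr1\t10\t20"))
  expect_equal(g3$score, 0)
  expect_equal(as.character(GenomicRanges::strand(g3)), "*")

  expect_error(parse_bed(bed_file("chr1\t200\t100")), "line 1")
  expect_error(parse_bed(bed_file(c("chr1\t1\t2", "chr1\tx\t5"))), "line 2")
  expect_error(parse_bed(bed_file("chr1\t5")), "line 1")
})

test_that("write_bed round-trips through parse_bed", {
  gr <- random_intervals(25)
  gr$summit <- GenomicRanges::start(gr) + 3
  f <- tempfile(fileext = ".bed")
  write_bed(gr, f)
  back <- parse_bed(f)
  expect_equal(GenomicRanges::start(back), sort(GenomicRanges::start(gr)))
  expect_equal(sum(back$score), sum(gr$score), tolerance = 1e-6)
  expect_equal(back$summit[order(back$name)][1],
               gr$summit[order(gr$name)][1])
})

test_that("merge_direct_overlap unions overlapping but not book-ended peaks", {
  # bed [100,200) + [150,250) -> [100,250)
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 151), c(200, 250)),
                               score = c(1, 2))
  m <- merge_direct_overlap(gr)
  expect_equal(length(m), 1L)
  expect_equal(GenomicRanges::start(m), 101)
  expect_equal(GenomicRanges::end(m), 250)
  expect_equal(m$score, 3)

  # bed [100,200) + [200,300): book-ended, zero shared bases -> two loci
  be <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 201), c(200, 300)))
  expect_equal(length(merge_direct_overlap(be)), 2L)
})

test_that("merge agrees with the quadratic closure oracle and is idempotent", {
  set.seed(11)
  for (trial in 1:25) {
    gr <- random_intervals(sample(2:200, 1))
    m <- merge_direct_overlap(gr)
    o <- oracle_merge(GenomicRanges::start(gr), GenomicRanges::end(gr))
    expect_equal(GenomicRanges::start(m), o$start)
    expect_equal(GenomicRanges::end(m), o$end)
    m2 <- merge_direct_overlap(m)
    expect_equal(GenomicRanges::ranges(m2), GenomicRanges::ranges(m))
    expect_equal(m2$score, m$score)
  }
})

test_that("consensus_common keeps loci supported by every replicate", {
  a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
  b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
  expect_equal(length(consensus_common(list(a, b))), 1L)

  d <- GenomicRanges::GRanges("chr1", IRanges::IRanges(501, 600))
  expect_equal(length(consensus_common(list(a, d))), 0L)

  expect_warning(out <- consensus_common(list(a, GenomicRanges::GRanges())),
                 "no peaks")
  expect_equal(length(out), 0L)
})

test_that("consensus over jittered replicates recovers the shared site count", {
  set.seed(21)
  n_shared <- 45
  centers <- sort(sample(seq(5000, 5e5, by = 4000), n_shared))
  reps <- lapply(1:4, function(r) {
    jit <- sample(-50:50, n_shared, replace = TRUE)
    shared <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(centers + jit - 150, centers + jit + 150))
    extra_c <- sample(seq(6e5, 8e5, by = 4000), 5) + r * 17
    extra <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(extra_c - 150, extra_c + 150))
    c(shared, extra)
  })
  cons <- consensus_common(reps)
  expect_true(abs(length(cons) - n_shared) / n_shared <= 0.05)
})

test_that("venn bookkeeping satisfies its margins and swap symmetry", {
  a <- merge_direct_overlap(random_intervals(80, span = 30000))
  b <- merge_direct_overlap(random_intervals(60, span = 30000))
  v <- venn_peaks(a, b)
  expect_equal(v$only_a + v$common_a, v$n_a)
  expect_equal(v$only_b + v$common_b, v$n_b)
  sw <- venn_peaks(b, a)
  expect_equal(sw$only_a, v$only_b)   # lost <-> gained under swap
  expect_equal(sw$only_b, v$only_a)
  expect_equal(sw$common_a, v$common_b)

  ident <- venn_peaks(a, a)
  expect_equal(ident$only_a, 0L)
  expect_equal(ident$only_b, 0L)
})

test_that("venn labels agree with the quadratic overlap oracle", {
  set.seed(31)
  for (trial in 1:10) {
    a <- merge_direct_overlap(random_intervals(sample(5:120, 1)))
    b <- merge_direct_overlap(random_intervals(sample(5:120, 1)))
    v <- venn_peaks(a, b)
    ol <- oracle_overlap_any(GenomicRanges::start(a), GenomicRanges::end(a),
                             GenomicRanges::start(b), GenomicRanges::end(b))
    expect_equal(sum(!ol), v$only_a)
    expect_equal(sum(ol), v$common_a)
  }
})

test_that("venn_complete reproduces the bookkeeping arithmetic", {
  out <- venn_complete(100, 60, 70)
  expect_equal(out$common, 30)
  expect_equal(out$gained, 30)
  expect_error(venn_complete(10, 2, 2), "common exceeds")
})

test_that("promoter assignment uses the half-open TSS window", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", tss = 10000,
                      strand = "+", stringsAsFactors = FALSE)
  # peak bed [9400,9600) overlaps window [9500,10500)
  pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9401, 9600),
                               name = "p1")
  expect_true(assign_to_promoters(pk, genes, window = 500)$bound[["g1"]])
  # peak bed [8000,9000) does not reach the window
  pk2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(8001, 9000))
  expect_false(assign_to_promoters(pk2, genes, window = 500)$bound[["g1"]])
  # exact boundary: peak ending at bed 9500 (end-exclusive) does not overlap
  pk3 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9401, 9500))
  expect_false(assign_to_promoters(pk3, genes, window = 500)$bound[["g1"]])

  genes2 <- rbind(genes, data.frame(gene_id = "g2", chrom = "chrUn",
                                    tss = 5000, strand = "-"))
  expect_warning(
    out <- assign_to_promoters(pk, genes2, window = 500,
                               chrom_lengths = c(chr1 = 2e4)),
    "unknown")
  expect_equal(names(out$bound), "g1")
})

test_that("planted promoter-bound genes are recovered from consensus peaks", {
  ds <- tiny_dataset()
  run <- tiny_run()
  bound <- assign_to_promoters(run$consensus$smad_wt, ds$genes,
                               window = 500,
                               chrom_lengths = ds$chrom_lengths)
  expect_equal(unname(bound$bound), ds$genes$bound)
})
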