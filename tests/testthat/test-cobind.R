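# Co-binding classification, dependence, flanking sites and differential
# binding with the moderated statistic.

mk_sites <- function(summits, cobound, chrom = "chr1") {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(summits - 100, summits + 100),
                               summit = summits,
                               site = paste0("s", seq_along(summits)))
  cof <- gr[cobound]
  classify_cobound(gr, cof)
}

test_that("co-binding requires at least one shared base", {
  smad <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200),
                                 summit = 150)
  cof_in <- GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 160))
  cof_out <- GenomicRanges::GRanges("chr1", IRanges::IRanges(201, 300))
  expect_true(classify_cobound(smad, cof_in)$cobound)
  expect_false(classify_cobound(smad, cof_out)$cobound)
  expect_equal(classify_cobound(smad, cof_in)$nearest_cobound_distance, 0)
})

test_that("classification flags equal the planted truth on synthetic loci", {
  ds <- tiny_dataset()
  run <- tiny_run()
  rec <- run$records
  truth <- ds$truth$sites
  truth_gr <- GenomicRanges::GRanges(truth$chrom,
                                     IRanges::IRanges(truth$start + 1, truth$end),
                                     class = truth$class)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(rec, truth_gr))
  matched <- rec[S4Vectors::queryHits(hits)]
  want_cobound <- truth_gr$class[S4Vectors::subjectHits(hits)] == "cobound"
  expect_equal(matched$cobound, want_cobound)
})

test_that("dependence test degenerates to p = 1 on identical conditions", {
  ds <- tiny_dataset()
  norm <- lapply(ds$tracks[c("smad_wt_rep1", "smad_wt_rep2")], normalize_rpm)
  rec <- mk_sites(c(5000, 9000, 13000, 17000), c(TRUE, TRUE, FALSE, FALSE))
  # reuse real coverage but identical track lists on both sides
  out <- dependence_test(rec, norm, norm)
  expect_equal(out$p, c(1, 1))
  expect_equal(out$mean_a, out$mean_b)
  expect_equal(out$mean_log2fc, c(0, 0))
})

test_that("dependence test equals a longhand paired t on site means", {
  ds <- tiny_dataset()
  run <- tiny_run()
  norm_wt <- lapply(ds$tracks[paste0("smad_wt_rep", 1:3)], normalize_rpm)
  norm_ko <- lapply(ds$tracks[paste0("smad_ko_rep", 1:3)], normalize_rpm)
  # wild-type site universe: loci gained in the null genotype belong to the
  # relocation analysis, not the dependence strata
  rec <- run$records[suppressWarnings(
    IRanges::overlapsAny(run$records, run$consensus$smad_wt))]
  out <- dependence_test(rec, norm_wt, norm_ko)
  a <- rowMeans(site_signal(norm_wt, rec))
  b <- rowMeans(site_signal(norm_ko, rec))
  sel <- rec$cobound
  tt <- t.test(b[sel], a[sel], paired = TRUE)
  expect_equal(out$p[out$stratum == "cobound"], tt$p.value)
  expect_equal(out$mean_a[out$stratum == "cobound"], mean(a[sel]))
  # planted dependence: strong at co-bound sites, absent at solo sites
  expect_lt(out$p[out$stratum == "cobound"], 0.01)
  expect_gt(out$p[out$stratum == "solo"], 0.05)
  expect_equal(out$mean_log2fc[out$stratum == "cobound"],
               -ds$config$dependence_effect_delta, tolerance = 0.15)
})

test_that("flanking_sites respects the summit distance boundary", {
  rec <- mk_sites(c(1000000, 1150000, 1200000 + 1000 + 1),
                  c(TRUE, FALSE, FALSE))
  fl <- flanking_sites(rec, window = 200000)
  expect_true("s2" %in% fl$site)          # 150 kb away: included
  expect_false("s3" %in% fl$site)         # 200 kb + 1 away: excluded
  rec2 <- mk_sites(c(1000000, 1200000), c(TRUE, FALSE))
  expect_true("s2" %in% flanking_sites(rec2, window = 200000)$site)
})

test_that("flanking set equals the quadratic all-pairs oracle", {
  set.seed(51)
  for (trial in 1:20) {
    n <- sample(10:80, 1)
    summits <- sort(sample(seq(1000, 5e6, by = 300), n))
    cobound <- runif(n) < 0.3
    rec <- mk_sites(summits, cobound)
    fl <- flanking_sites(rec, window = 200000)
    want <- oracle_flanking(summits, cobound, 200000)
    expect_setequal(as.integer(sub("^s", "", fl$site)), which(want))
  }
})

test_that("differential binding is null on identical conditions and
           antisymmetric under label swap", {
  ds <- tiny_dataset()
  run <- tiny_run()
  norm_wt <- lapply(ds$tracks[paste0("smad_wt_rep", 1:3)], normalize_rpm)
  norm_ko <- lapply(ds$tracks[paste0("smad_ko_rep", 1:3)], normalize_rpm)
  rec <- run$records

  same <- suppressWarnings(differential_binding(rec, norm_wt, norm_wt))
  expect_true(all(same$table$log2fc == 0))
  expect_false(any(same$table$significant))

  fwd <- differential_binding(rec, norm_wt, norm_ko)
  bwd <- differential_binding(rec, norm_ko, norm_wt)
  expect_equal(bwd$table$log2fc, -fwd$table$log2fc)
  expect_equal(bwd$table$p, fwd$table$p)
})

test_that("planted effects are recovered and q-values equal the BH oracle", {
  ds <- tiny_dataset()
  run <- tiny_run()
  db <- run$diff_binding
  summ <- db$summary
  expect_equal(summ$mean_log2fc[summ$class == "cobound"],
               -ds$config$dependence_effect_delta, tolerance = 0.15)
  expect_gt(summ$mean_log2fc[summ$class == "flanking"], 0)
  expect_equal(db$table$q, oracle_bh(db$table$p))

  # every planted ectopic locus that was tested is significantly up
  truth <- ds$truth$sites
  ect <- truth[truth$class == "ectopic", ]
  ect_gr <- GenomicRanges::GRanges(ect$chrom,
                                   IRanges::IRanges(ect$start + 1, ect$end))
  rec <- run$records
  tested_ect <- rec$site[suppressWarnings(IRanges::overlapsAny(rec, ect_gr))]
  tab <- db$table[db$table$site %in% tested_ect, ]
  expect_gte(mean(tab$significant & tab$log2fc > 0), 0.8)
})

test_that("moderated statistic matches the longhand formula", {
  set.seed(52)
  a <- matrix(rnorm(60, 5), 20, 3)
  b <- matrix(rnorm(60, 5.5), 20, 3)
  mt <- cswitch:::moderated_ttest(a, b, d0 = 4)
  s2_prior <- mean(mt$s2)
  for (i in c(1, 7, 20)) {
    o <- oracle_modt_row(a[i, ], b[i, ], s2_prior, d0 = 4)
    expect_equal(mt$t[i], o$t)
    expect_equal(mt$p[i], o$p)
  }
})
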