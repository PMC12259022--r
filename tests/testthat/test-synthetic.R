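# Synthetic data generator: determinism, mass bookkeeping, planted effects.

test_that("identical seed and config give byte-identical outputs", {
  cfg <- tiny_config(seed = 12, n_genes = 0, genome_length = 6e5,
                     n_chroms = 2, n_smad_sites = 20)
  d1 <- tempfile(); d2 <- tempfile()
  generate_dataset(cfg, out_dir = d1)
  generate_dataset(cfg, out_dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_equal(f1, list.files(d2, recursive = TRUE))
  md1 <- tools::md5sum(file.path(d1, f1))
  md2 <- tools::md5sum(file.path(d2, f1))
  expect_equal(unname(md1), unname(md2))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("null configuration plants no class differences", {
  cfg <- tiny_config(seed = 13, dependence_effect_delta = 0,
                     relocation_fraction_rho = 0, n_genes = 0,
                     genome_length = 6e5, n_chroms = 2, n_smad_sites = 30)
  ds <- generate_dataset(cfg)
  tr <- ds$truth$sites
  expect_false(any(tr$class == "ectopic"))
  expect_equal(tr$amplitude_wt, tr$amplitude_ko)
  # expected signal identical across genotypes, for both classes
  expect_identical(ds$expected$smad_wt$cov, ds$expected$smad_ko$cov)
})

test_that("per-replicate totals match library_size within Poisson error", {
  ds <- tiny_dataset()
  lib <- ds$config$library_size
  main <- grep("^(smad|cofactor_wt|activity)", names(ds$tracks), value = TRUE)
  for (nm in main) {
    expect_lt(abs(ds$tracks[[nm]]$library_size - lib) / lib, 0.01)
  }
  # expected totals are exact
  for (nm in grep("^(smad|cofactor_wt|activity)", names(ds$expected),
                  value = TRUE)) {
    expect_equal(ds$expected[[nm]]$library_size, lib, tolerance = 1e-8)
  }
})

test_that("ectopic sites exist only in the null genotype near a parent", {
  ds <- tiny_dataset()
  tr <- ds$truth$sites
  ect <- tr[tr$class == "ectopic", ]
  expect_equal(nrow(ect),
               round(ds$config$relocation_fraction_rho *
                     sum(tr$class == "cobound")))
  expect_true(all(ect$amplitude_wt == 0))
  expect_true(all(ect$amplitude_ko > 0))
  parents <- tr[match(ect$parent, tr$site_id), ]
  expect_true(all(ect$chrom == parents$chrom))
  expect_true(all(abs(ect$summit - parents$summit) <=
                  ds$config$relocation_distance))
  # wild-type expected coverage at ectopic summits is pure background
  win <- GenomicRanges::GRanges(ect$chrom,
                                IRanges::IRanges(ect$summit - 100 + 1,
                                                 ect$summit + 100))
  expect_true(all(region_means(ds$expected$smad_wt, win) <=
                  ds$config$background_rate + 1e-9))
  expect_true(all(region_means(ds$expected$smad_ko, win) >
                  50 * ds$config$background_rate))
})

test_that("observed co-bound log2FC matches the pre-sampling expectation", {
  ds <- tiny_dataset()
  cfg <- ds$config
  tr <- ds$truth$sites
  cob <- tr[tr$class == "cobound", ]
  win <- GenomicRanges::GRanges(cob$chrom,
                                IRanges::IRanges(cob$summit + 1 - 500,
                                                 cob$summit + 500))
  ps <- 0.5
  # oracle: expectation from the planted Poisson rates, before sampling
  f <- 1e6 / cfg$library_size
  e_wt <- region_means(ds$expected$smad_wt, win) * f
  e_ko <- region_means(ds$expected$smad_ko, win) * f
  want <- mean(log2((e_ko + ps) / (e_wt + ps)))

  norm_wt <- lapply(ds$tracks[paste0("smad_wt_rep", 1:3)], normalize_rpm)
  norm_ko <- lapply(ds$tracks[paste0("smad_ko_rep", 1:3)], normalize_rpm)
  o_wt <- rowMeans(vapply(norm_wt, region_means, numeric(nrow(cob)),
                          regions = win))
  o_ko <- rowMeans(vapply(norm_ko, region_means, numeric(nrow(cob)),
                          regions = win))
  got <- mean(log2((o_ko + ps) / (o_wt + ps)))
  expect_equal(got, want, tolerance = 0.05)
  expect_equal(want, -cfg$dependence_effect_delta, tolerance = 0.15)
})

test_that("planted gene sets have the configured sizes and effects", {
  ds <- tiny_dataset()
  g <- ds$genes
  rs <- ds$config$repressed_set_sizes
  expect_equal(sum(g$bmp_repressed), unname(rs[["bmp"]]))
  expect_equal(sum(g$cofactor_repressed), unname(rs[["cofactor"]]))
  expect_equal(sum(g$bmp_repressed & g$cofactor_repressed),
               unname(rs[["overlap"]]))
  # promoter signal drops by the planted effect in treated wild type
  win <- GenomicRanges::GRanges(g$chrom,
                                IRanges::IRanges(g$tss + 1 - 500, g$tss + 500))
  e_un <- region_means(ds$expected$activity_untreated, win)
  e_tr <- region_means(ds$expected$activity_treated, win)
  lfc <- log2(e_tr / e_un)
  expect_equal(mean(lfc[g$bmp_repressed]), -ds$config$promoter_effect,
               tolerance = 0.1)
  expect_equal(mean(abs(lfc[!g$bmp_repressed & !g$bmp_activated])), 0,
               tolerance = 0.05)
})

test_that("invalid configurations raise sizing errors naming the constraint", {
  expect_error(tiny_config(background_rate = 10), "background_rate")
  expect_error(tiny_config(repressed_set_sizes = c(bmp = 5, cofactor = 5,
                                                   overlap = 6)), "overlap")
  expect_error(generate_dataset(tiny_config(n_smad_sites = 5000)),
               "sizing error")
  expect_error(tiny_config(n_genes = 10), "exceed")
})
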