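# Promoter quantification, differential activity, set logic and Fisher.

test_that("promoter quantification is the mean over the TSS window", {
  flat <- make_track(list(chr1 = rep(2.5, 20000)), normalized = TRUE)
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      tss = c(5000, 9000), strand = c("+", "-"),
                      stringsAsFactors = FALSE)
  m <- quantify_promoters(genes, list(flat), window = 500)
  expect_equal(unname(m[, 1]), c(2.5, 2.5))

  set.seed(61)
  v <- runif(20000)
  tr <- make_track(list(chr1 = v), normalized = TRUE)
  m2 <- quantify_promoters(genes, list(tr), window = 500)
  # naive extraction: 0-based [tss-500, tss+500) -> 1-based tss-499 .. tss+500
  expect_equal(unname(m2["g1", 1]), mean(v[(5000 - 499):(5000 + 500)]))

  near_edge <- data.frame(gene_id = "e", chrom = "chr1", tss = 100,
                          strand = "+", stringsAsFactors = FALSE)
  expect_warning(me <- quantify_promoters(near_edge, list(tr), window = 500),
                 "truncated")
  expect_true(attr(me, "truncated")[["e"]])
})

test_that("differential activity is null on identical conditions and
           matches the moderated-statistic oracle", {
  set.seed(62)
  a <- matrix(rexp(300, 1), 100, 3,
              dimnames = list(sprintf("g%03d", 1:100), NULL))
  b <- matrix(rexp(300, 1), 100, 3, dimnames = dimnames(a))

  same <- differential_activity(a, a)
  expect_true(all(same$table$log2fc == 0))
  expect_equal(length(same$up) + length(same$down), 0L)

  da <- differential_activity(a, b, alpha = 0.01, pseudocount = 0.5, d0 = 4)
  la <- log2(a + 0.5); lb <- log2(b + 0.5)
  mt <- cswitch:::moderated_ttest(la, lb, d0 = 4)
  expect_equal(da$table$p, mt$p)
  i <- 17
  o <- oracle_modt_row(la[i, ], lb[i, ], mean(mt$s2), d0 = 4)
  expect_equal(da$table$p[i], o$p)
})

test_that("planted repressed and activated gene sets are recovered", {
  ds <- tiny_dataset()
  run <- tiny_run()
  genes <- ds$genes
  bmp <- run$activity$bmp
  # repressed by treatment = down in treated vs untreated
  planted_down <- genes$gene_id[genes$bmp_repressed]
  recall <- mean(planted_down %in% bmp$down)
  expect_gte(recall, 0.8)
  false_down <- setdiff(bmp$down, planted_down)
  expect_lte(length(false_down), max(2, 3 * 0.01 * (nrow(genes) -
                                                    length(planted_down))))
  # de-repressed on co-factor loss = up in ko_treated vs treated
  cof <- run$activity$cofactor
  planted_up <- genes$gene_id[genes$cofactor_repressed]
  expect_gte(mean(planted_up %in% cof$up), 0.8)
})

test_that("gene set logic intersects and filters over the universe", {
  universe <- paste0("g", 1:10)
  rep <- gene_set_logic(c("g1", "g2"), c("g2", "g3"), c("g2", "g5"), universe)
  expect_equal(rep$co_repressed, "g2")
  expect_equal(rep$only_a, "g1")
  expect_equal(rep$co_repressed_bound, "g2")
  expect_error(gene_set_logic(c("gX"), "g1", "g2", universe), "universe")

  disj <- gene_set_logic("g1", "g3", character(), universe)
  expect_equal(length(disj$co_repressed), 0L)

  # inclusion-exclusion on random sets
  set.seed(63)
  for (i in 1:10) {
    a <- sample(universe, sample(0:10, 1))
    b <- sample(universe, sample(0:10, 1))
    r <- gene_set_logic(a, b, character(), universe)
    expect_equal(length(a) + length(b) - length(union(a, b)),
                 length(r$co_repressed))
  }
})

test_that("the planted repressed-set overlap is recovered exactly", {
  ds <- tiny_dataset()
  genes <- ds$genes
  r <- gene_set_logic(genes$gene_id[genes$bmp_repressed],
                      genes$gene_id[genes$cofactor_repressed],
                      genes$gene_id[genes$bound],
                      genes$gene_id)
  expect_equal(length(r$co_repressed),
               unname(ds$config$repressed_set_sizes[["overlap"]]))
})

test_that("fisher enrichment handles identity, degeneracy and row/col swap", {
  ident <- binding_enrichment_fisher(10, 20, 10, 20)
  expect_equal(ident$p_two_sided, 1)
  expect_equal(ident$odds_ratio, 1)

  degen <- binding_enrichment_fisher(0, 0, 3, 10)
  expect_true(degen$degenerate)
  expect_equal(degen$p_two_sided, 1)

  f <- binding_enrichment_fisher(12, 20, 5, 18)
  # transposing the table leaves the exact test invariant
  tr <- fisher.test(t(f$table))$p.value
  expect_equal(f$p_two_sided, tr)
  expect_equal(f$odds_ratio, (12 * 13) / (8 * 5))
})

test_that("fisher p equals hypergeometric tail enumeration on random tables", {
  set.seed(64)
  for (i in 1:25) {
    t1 <- sample(2:30, 1); t2 <- sample(2:30, 1)
    b1 <- sample(0:t1, 1); b2 <- sample(0:t2, 1)
    f <- binding_enrichment_fisher(b1, t1, b2, t2)
    if (f$degenerate) next
    o <- oracle_fisher(b1, t1 - b1, b2, t2 - b2)
    expect_equal(f$p_one_sided, o$greater, tolerance = 1e-10)
    expect_equal(f$p_two_sided, o$two_sided, tolerance = 1e-10)
  }
})
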