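# Promoter-window activity: TSS +/- 500 bp quantification, two-condition
# differential calls at a p-value threshold, repressed-gene set logic, and
# the binding-enrichment Fisher test.

#' Quantify promoter-window signal per gene and replicate
#'
#' Mean RPM over `[TSS - window, TSS + window)` (0-based) for every gene and
#' every track.  Windows running off a chromosome edge are truncated and
#' flagged in the `truncated` attribute.
#'
#' @param genes A gene data.frame ([read_genes()] layout, `tss` 0-based).
#' @param tracks A list of RPM-normalized `coverage_track`s.
#' @param window Promoter half-width in bases (default 500).
#' @return A numeric matrix genes x tracks (rownames = gene ids) with
#'   attribute `truncated` (logical per gene).
#' @export
quantify_promoters <- function(genes, tracks, window = 500) {
  stopifnot(length(tracks) >= 1L)
  lens <- track_lengths(tracks[[1L]])
  missing <- setdiff(genes$chrom, names(lens))
  if (length(missing)) stop("gene chromosome missing from tracks: ", missing[1L])
  st1 <- genes$tss - window + 1          # 1-based window start
  en1 <- genes$tss + window
  truncated <- st1 < 1 | en1 > lens[genes$chrom]
  if (any(truncated)) {
    warning(sum(truncated), " promoter window(s) truncated at chromosome edges")
  }
  win <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1, st1), pmin(en1, lens[genes$chrom])))
  m <- vapply(tracks, function(t) region_means(t, win), numeric(nrow(genes)))
  if (nrow(genes) == 1L) m <- matrix(m, nrow = 1L)
  rownames(m) <- genes$gene_id
  attr(m, "truncated") <- setNames(truncated, genes$gene_id)
  m
}

#' Differential promoter activity between two conditions
#'
#' The same moderated statistic as [differential_binding()], applied to
#' per-gene promoter signal matrices on the log2(x + pseudocount) scale.
#' Calls use the raw p-value (`p < alpha`), matching promoter differential
#' analyses that report significance at p < 0.01; BH q-values are still
#' reported.
#'
#' @param signal_a,signal_b Gene x replicate matrices from
#'   [quantify_promoters()] (same gene order).
#' @param alpha Raw p-value threshold for calls (default 0.01).
#' @param pseudocount Pseudocount in RPM (default 0.5).
#' @param d0 Prior df for variance moderation; `NA` (default) estimates it
#'   by moment matching, a fixed value forces that prior weight.
#' @return A `cswitch_differential` with additional elements `up` and `down`
#'   (gene id sets: `up` = log2fc > 0 & p < alpha; `down` likewise negative).
#' @export
differential_activity <- function(signal_a, signal_b, alpha = 0.01,
                                  pseudocount = 0.5, d0 = NA) {
  stopifnot(nrow(signal_a) == nrow(signal_b),
            ncol(signal_a) >= 2L, ncol(signal_b) >= 2L)
  genes <- rownames(signal_a)
  nonzero <- rowSums(signal_a) + rowSums(signal_b) > 0
  if (any(!nonzero)) {
    warning("dropping ", sum(!nonzero),
            " gene(s) with zero signal in all replicates")
    signal_a <- signal_a[nonzero, , drop = FALSE]
    signal_b <- signal_b[nonzero, , drop = FALSE]
    genes <- genes[nonzero]
  }
  mt <- moderated_ttest(log2(signal_a + pseudocount),
                        log2(signal_b + pseudocount), d0 = d0)
  ma <- rowMeans(signal_a); mb <- rowMeans(signal_b)
  tab <- data.frame(
    gene = genes,
    mean_a = ma, mean_b = mb,
    log2fc = log2((mb + pseudocount) / (ma + pseudocount)),
    t = mt$t, p = mt$p, q = p.adjust(mt$p, method = "BH"),
    stringsAsFactors = FALSE)
  tab$significant <- tab$p < alpha
  up <- tab$gene[tab$significant & tab$log2fc > 0]
  down <- tab$gene[tab$significant & tab$log2fc < 0]
  summ <- data.frame(n = nrow(tab), n_up = length(up), n_down = length(down))
  structure(list(table = tab, summary = summ, alpha = alpha, up = up,
                 down = down, kind = "activity"),
            class = "cswitch_differential")
}

#' Repressed/activated gene-set logic
#'
#' Intersects the down-regulated sets of two comparisons and applies the
#' bound-gene filter, yielding the candidate direct-target subsets.
#'
#' @param down_a,down_b Gene id vectors (e.g. repressed by treatment;
#'   de-repressed on co-factor loss).
#' @param bound_genes Gene ids whose promoter carries a binding peak.
#' @param universe All quantifiable gene ids; members of the three sets must
#'   belong to it.
#' @return An object of class `gene_set_report`: list with `co_repressed`,
#'   `only_a`, `only_b`, bound-filtered variants, and a `counts` data.frame.
#' @export
gene_set_logic <- function(down_a, down_b, bound_genes, universe) {
  for (s in list(down_a, down_b, bound_genes)) {
    out <- setdiff(s, universe)
    if (length(out)) stop("gene outside universe: ", out[1L])
  }
  co <- intersect(down_a, down_b)
  rep <- list(
    co_repressed = co,
    only_a = setdiff(down_a, down_b),
    only_b = setdiff(down_b, down_a),
    co_repressed_bound = intersect(co, bound_genes),
    only_a_bound = intersect(setdiff(down_a, down_b), bound_genes),
    only_b_bound = intersect(setdiff(down_b, down_a), bound_genes))
  rep$counts <- data.frame(
    set = names(rep)[1:6],
    n = vapply(rep[1:6], length, 0L))
  class(rep) <- "gene_set_report"
  rep
}

#' @export
print.gene_set_report <- function(x, ...) {
  cat("Gene-set report:\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Fisher test for binding enrichment between two gene groups
#'
#' Exact hypergeometric test on the 2x2 table
#' `[(bound1, total1 - bound1), (bound2, total2 - bound2)]`.  Both the
#' one-sided (enrichment of group 1) and two-sided p are reported; the odds
#' ratio is the sample cross-product `(a*d)/(b*c)`.
#'
#' @param bound1,total1 Bound and total gene counts of group 1.
#' @param bound2,total2 Same for group 2.
#' @return A list of class `fisher_report`: `table`, `odds_ratio`,
#'   `p_one_sided`, `p_two_sided`, `degenerate` flag.
#' @export
binding_enrichment_fisher <- function(bound1, total1, bound2, total2) {
  stopifnot(bound1 <= total1, bound2 <= total2,
            bound1 >= 0, bound2 >= 0)
  m <- matrix(c(bound1, total1 - bound1, bound2, total2 - bound2),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("group1", "group2"), c("bound", "unbound")))
  degenerate <- any(rowSums(m) == 0) || any(colSums(m) == 0)
  if (degenerate) {
    out <- list(table = m, odds_ratio = NA_real_, p_one_sided = 1,
                p_two_sided = 1, degenerate = TRUE)
  } else {
    a <- m[1, 1]; b <- m[1, 2]; cc <- m[2, 1]; d <- m[2, 2]
    out <- list(
      table = m,
      odds_ratio = (a * d) / (b * cc),
      p_one_sided = fisher.test(m, alternative = "greater")$p.value,
      p_two_sided = fisher.test(m)$p.value,
      degenerate = FALSE)
  }
  class(out) <- "fisher_report"
  out
}

#' @export
print.fisher_report <- function(x, ...) {
  print(x$table)
  if (x$degenerate) {
    cat("degenerate margin: p = 1, odds ratio undefined\n")
  } else {
    cat(sprintf("odds ratio = %.3f; one-sided p = %.4g; two-sided p = %.4g\n",
                x$odds_ratio, x$p_one_sided, x$p_two_sided))
  }
  invisible(x)
}
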