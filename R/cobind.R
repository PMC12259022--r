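# Co-binding classification and relocation statistics — the package's core
# inference.  SMAD sites are classified by >= 1 bp overlap with co-factor
# peaks; occupancy dependence is tested per stratum with a paired-by-site t
# test; relocation is quantified over the non-co-bound sites whose summits
# lie within a fixed window (default 200 kb) of a co-bound summit, with a
# moderated two-sample statistic per site and joint BH adjustment.

#' Classify SMAD sites by co-factor co-binding
#'
#' A site is co-bound iff it shares at least one base with a co-factor peak.
#' Non-co-bound sites get the distance from their summit to the nearest
#' co-bound site summit on the same chromosome (`NA` if none); co-bound
#' sites get distance 0.
#'
#' @param smad_peaks A `GRanges` of (merged) SMAD peaks; a `summit` metadata
#'   column is used when present, otherwise the interval midpoint.
#' @param cofactor_peaks A `GRanges` of (merged) co-factor peaks.
#' @return `smad_peaks` with metadata columns `site`, `summit`, `cobound`,
#'   `nearest_cobound_distance`.
#' @export
classify_cobound <- function(smad_peaks, cofactor_peaks) {
  gr <- smad_peaks
  if (is.null(gr$summit) || all(is.na(gr$summit))) {
    gr$summit <- GenomicRanges::start(gr) +
      (GenomicRanges::end(gr) - GenomicRanges::start(gr)) %/% 2L
  }
  if (is.null(gr$site)) {
    gr$site <- if (!is.null(gr$name)) gr$name else
      paste0("site_", seq_along(gr))
  }
  gr$cobound <- suppressWarnings(IRanges::overlapsAny(
    gr, cofactor_peaks, minoverlap = 1L, ignore.strand = TRUE))
  gr$nearest_cobound_distance <- nearest_summit_distance(
    as.character(GenomicRanges::seqnames(gr)), gr$summit, gr$cobound)
  gr
}

# Distance from each summit to the nearest cobound summit (0 if cobound).
nearest_summit_distance <- function(chrom, summit, cobound) {
  d <- rep(NA_real_, length(summit))
  d[cobound] <- 0
  for (cc in unique(chrom)) {
    ref <- sort(summit[cobound & chrom == cc])
    idx <- which(!cobound & chrom == cc)
    if (length(ref) == 0L || length(idx) == 0L) next
    p <- summit[idx]
    k <- findInterval(p, ref)
    lo <- ifelse(k >= 1, abs(p - ref[pmax(k, 1)]), Inf)
    hi <- ifelse(k < length(ref), abs(ref[pmin(k + 1, length(ref))] - p), Inf)
    d[idx] <- pmin(lo, hi)
  }
  d
}

#' Per-site window mean signal across tracks
#'
#' Mean normalized coverage in a window of `2*halfwidth` bases centered on
#' each site summit, for every track in a list.
#'
#' @param tracks A list of RPM-normalized `coverage_track`s (replicates).
#' @param sites A classified `GRanges` (needs `summit`).
#' @param halfwidth Half-window in bases (default 500).
#' @return A numeric matrix, sites x tracks.
#' @export
site_signal <- function(tracks, sites, halfwidth = 500) {
  win <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(sites),
    IRanges::IRanges(start = pmax(1, sites$summit - halfwidth),
                     end = sites$summit + halfwidth - 1))
  m <- vapply(tracks, function(t) region_means(t, win),
              numeric(length(sites)))
  if (length(sites) == 1L) m <- matrix(m, nrow = 1L)
  rownames(m) <- sites$site
  m
}

#' Test co-factor dependence of SMAD occupancy per stratum
#'
#' Per stratum (co-bound / solo), each site contributes its across-replicate
#' mean window signal in each condition; the two-tailed test is paired by
#' site.  With identical conditions (all paired differences zero) the test
#' degenerates and p = 1 is reported; a single-site stratum reports `NA`.
#'
#' @param records Classified sites from [classify_cobound()].
#' @param tracks_a,tracks_b Lists of RPM-normalized replicate tracks for the
#'   two conditions.
#' @param halfwidth Half-window for per-site signal (default 500).
#' @param pseudocount Pseudocount (RPM) for the summary log2 fold change.
#' @return A data.frame, one row per stratum: `stratum`, `n_sites`,
#'   `mean_a`, `mean_b`, `mean_log2fc`, `p`.
#' @export
dependence_test <- function(records, tracks_a, tracks_b, halfwidth = 500,
                            pseudocount = 0.5) {
  a <- rowMeans(site_signal(tracks_a, records, halfwidth))
  b <- rowMeans(site_signal(tracks_b, records, halfwidth))
  strata <- list(cobound = records$cobound, solo = !records$cobound)
  rows <- lapply(names(strata), function(s) {
    sel <- strata[[s]]
    n <- sum(sel)
    p <- if (n < 2L) NA_real_
    else if (all(abs(a[sel] - b[sel]) < .Machine$double.eps^0.5)) 1
    else t.test(b[sel], a[sel], paired = TRUE)$p.value
    data.frame(stratum = s, n_sites = n,
               mean_a = mean(a[sel]), mean_b = mean(b[sel]),
               mean_log2fc = log2((mean(b[sel]) + pseudocount) /
                                  (mean(a[sel]) + pseudocount)),
               p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Non-co-bound sites flanking a co-bound site
#'
#' Returns the sites that are not co-bound but whose summit lies within
#' `window` bases (either side) of at least one co-bound site summit.  A
#' site near several co-bound sites counts once.
#'
#' @param records Classified sites from [classify_cobound()].
#' @param window Maximum summit-to-summit distance in bases (default 200000).
#' @return The flanking subset of `records`, with a `flanking` column added.
#' @export
flanking_sites <- function(records, window = 200000) {
  d <- records$nearest_cobound_distance
  keep <- !records$cobound & !is.na(d) & d <= window
  out <- records[keep]
  out$flanking <- rep(TRUE, length(out))
  out
}

# Newton inversion of trigamma on (0, inf); used for the prior-df moment
# estimate.
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  x <- 0.5 + 1 / y
  for (i in 1:30) {
    delta <- (trigamma(x) - y) / psigamma(x, 2)
    x <- max(x + delta, 1e-3)
    if (abs(delta) < 1e-10 * x) break
  }
  x
}

# Moderated two-sample statistic: per-row variances are shrunk toward a
# common prior variance with weight d0 prior degrees of freedom, and the t
# statistic is referenced to t(d0 + df).  With d0 = NA the prior df is
# estimated by moment-matching the spread of log sample variances: the
# excess of var(log s2) over trigamma(df/2) is attributed to genuine
# variance dispersion across rows (homogeneous rows then give a large d0
# and the statistic approaches an ordinary pooled-variance z test).
moderated_ttest <- function(mat_a, mat_b, d0 = NA) {
  ka <- ncol(mat_a); kb <- ncol(mat_b)
  stopifnot(ka >= 2L, kb >= 2L, nrow(mat_a) == nrow(mat_b))
  ma <- rowMeans(mat_a); mb <- rowMeans(mat_b)
  df <- ka + kb - 2
  ss <- rowSums((mat_a - ma)^2) + rowSums((mat_b - mb)^2)
  s2 <- ss / df
  if (is.na(d0)) {
    e <- log(pmax(s2, 1e-12))
    excess <- stats::var(e) - trigamma(df / 2)
    d0 <- if (!is.finite(excess) || excess <= 0) 1e6 else
      min(2 * trigamma_inverse(excess), 1e6)
  }
  s2_prior <- mean(s2)
  s2_mod <- (d0 * s2_prior + df * s2) / (d0 + df)
  se <- sqrt(s2_mod * (1 / ka + 1 / kb))
  t <- (mb - ma) / se
  t[se == 0 & mb == ma] <- 0
  p <- 2 * pt(-abs(t), df = df + d0)
  p[is.nan(p)] <- 1
  data.frame(mean_a = ma, mean_b = mb, t = t, p = p,
             df = df + d0, s2 = s2, s2_mod = s2_mod, d0 = d0)
}

#' Differential binding between conditions at classified sites
#'
#' Tests co-bound and flanking sites jointly: per-site window means are
#' log2-transformed with a pseudocount, a moderated two-sample statistic
#' (fixed prior df `d0`) is computed per site, and BH adjustment runs across
#' all tested sites.  Sites with zero signal in every replicate of both
#' conditions are dropped with a warning.
#'
#' @param records Classified sites from [classify_cobound()].
#' @param tracks_a,tracks_b Lists of RPM-normalized replicate tracks
#'   (condition A = reference, condition B = perturbed).
#' @param fdr Significance cutoff on BH-adjusted q (default 0.1).
#' @param pseudocount Pseudocount in RPM (default 0.5).
#' @param halfwidth Half-window for per-site signal (default 500).
#' @param d0 Prior degrees of freedom for variance moderation; `NA` (the
#'   default) estimates it from the spread of per-site log variances by
#'   moment matching, a fixed value (e.g. 4) forces that prior weight.
#' @param flank_window Distance defining flanking sites (default 200000).
#' @param include_solo Also test solo sites beyond the flanking window
#'   (default FALSE: the volcano covers co-bound + flanking sites).
#' @return An object of class `cswitch_differential` with elements `table`
#'   (site, class, mean_a, mean_b, log2fc, t, p, q, significant), `summary`
#'   (per-class n, mean log2fc, n significant) and `fdr`.
#' @export
differential_binding <- function(records, tracks_a, tracks_b, fdr = 0.1,
                                 pseudocount = 0.5, halfwidth = 500,
                                 d0 = NA, flank_window = 200000,
                                 include_solo = FALSE) {
  stopifnot(length(tracks_a) >= 2L, length(tracks_b) >= 2L)
  d <- records$nearest_cobound_distance
  cls <- ifelse(records$cobound, "cobound",
                ifelse(!is.na(d) & d <= flank_window, "flanking", "solo"))
  keep <- cls %in% c("cobound", "flanking") | include_solo
  sites <- records[keep]
  cls <- cls[keep]
  sa <- site_signal(tracks_a, sites, halfwidth)
  sb <- site_signal(tracks_b, sites, halfwidth)
  nonzero <- rowSums(sa) + rowSums(sb) > 0
  if (any(!nonzero)) {
    warning("dropping ", sum(!nonzero),
            " site(s) with zero signal in all replicates")
    sites <- sites[nonzero]; cls <- cls[nonzero]
    sa <- sa[nonzero, , drop = FALSE]; sb <- sb[nonzero, , drop = FALSE]
  }
  mt <- moderated_ttest(log2(sa + pseudocount), log2(sb + pseudocount),
                        d0 = d0)
  tab <- data.frame(
    site = sites$site, class = cls,
    mean_a = rowMeans(sa), mean_b = rowMeans(sb),
    log2fc = log2((rowMeans(sb) + pseudocount) /
                  (rowMeans(sa) + pseudocount)),
    t = mt$t, p = mt$p, q = p.adjust(mt$p, method = "BH"),
    stringsAsFactors = FALSE)
  tab$significant <- tab$q < fdr
  summ <- do.call(rbind, lapply(split(tab, tab$class), function(d) {
    data.frame(class = d$class[1L], n = nrow(d),
               mean_log2fc = mean(d$log2fc),
               n_significant = sum(d$significant))
  }))
  rownames(summ) <- NULL
  structure(list(table = tab, summary = summ, fdr = fdr,
                 kind = "binding"),
            class = "cswitch_differential")
}

#' @export
print.cswitch_differential <- function(x, ...) {
  cat("Differential", x$kind, "analysis:", nrow(x$table), "features,",
      sum(x$table$significant), "significant",
      if (x$kind == "binding") paste0("(q < ", x$fdr, ")")
      else paste0("(p < ", x$alpha, ")"), "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @export
summary.cswitch_differential <- function(object, ...) object$summary

#' Volcano plot of a differential analysis
#'
#' @param x A `cswitch_differential`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cswitch_differential <- function(x, ...) {
  cols <- c(cobound = "#3366cc", flanking = "#cc3333", solo = "grey50",
            up = "#cc3333", down = "#33691e", ns = "grey70")
  cl <- if ("class" %in% names(x$table)) x$table$class else "ns"
  graphics::plot(x$table$log2fc, -log10(pmax(x$table$p, 1e-300)),
                 col = ifelse(cl %in% names(cols), cols[cl], "grey50"),
                 pch = 20, xlab = "log2 fold change", ylab = "-log10 p", ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}
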