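# Sparse-signal peak calling with an empirical FDR threshold taken from a
# control track, in the spirit of callers designed for sparse tagmentation
# profiles.  Candidate peaks are maximal runs of nonzero signal; the block
# statistic is the total signal in the run.  The threshold is the smallest
# observed signal-block statistic t such that the fraction of *control*
# blocks with statistic >= t is at most `fdr` — i.e. the control track is
# treated as an empirical null sample for block totals.

# Candidate blocks: maximal nonzero runs of a track, optionally bridging
# internal gaps of up to max_gap zero bases (base-level sampling can drop
# isolated positions inside an otherwise contiguous enrichment).
signal_blocks <- function(track, max_gap = 0) {
  pieces <- lapply(names(track$cov), function(ch) {
    r <- track$cov[[ch]]
    sl <- IRanges::slice(r, lower = 0, includeLower = FALSE,
                         rangesOnly = TRUE)
    if (length(sl) == 0L) return(NULL)
    if (max_gap > 0) {
      sl <- IRanges::reduce(sl, min.gapwidth = max_gap + 1L)
    }
    v <- IRanges::Views(r, sl)
    data.frame(chrom = ch,
               start = IRanges::start(v), end = IRanges::end(v),
               total = IRanges::viewSums(v),
               max = IRanges::viewMaxs(v),
               summit = IRanges::viewWhichMaxs(v),  # leftmost max
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, pieces)
  if (is.null(df)) {
    df <- data.frame(chrom = character(), start = integer(), end = integer(),
                     total = numeric(), max = numeric(), summit = integer())
  }
  df
}

#' Call peaks against a control track
#'
#' Candidate blocks are maximal runs of nonzero signal.  Blocks are kept when
#' their total signal reaches the smallest threshold at which no more than an
#' `fdr` fraction of control blocks would survive.  If the control track has
#' no nonzero blocks, the `1 - fdr` quantile of the signal block totals is
#' used instead and the result is flagged (`attr(x, "fallback")`).
#'
#' Lowering `fdr` can only raise the threshold, so the number of called peaks
#' is monotone non-increasing in `fdr`; called peaks are disjoint by
#' construction.
#'
#' @param signal,control RPM-normalized `coverage_track`s.
#' @param fdr Target empirical FDR in (0, 1); default 0.1.
#' @param max_gap Zero-gap width (bases) tolerated inside a candidate block
#'   (default 0: blocks are strict maximal nonzero runs).
#' @return A `GRanges` of called peaks with metadata `name`, `score` (total
#'   signal), `max` (peak height) and `summit` (1-based position of the
#'   leftmost maximum).  Attribute `threshold` records the block-total cutoff.
#' @export
call_peaks <- function(signal, control, fdr = 0.1, max_gap = 0) {
  stopifnot(fdr > 0, fdr < 1)
  if (!signal$normalized || !control$normalized) {
    stop("signal and control tracks must be RPM-normalized")
  }
  sig <- signal_blocks(signal, max_gap = max_gap)
  ctl <- signal_blocks(control, max_gap = max_gap)
  fallback <- FALSE
  if (nrow(sig) == 0L) {
    out <- empty_peaks()
    attr(out, "threshold") <- Inf
    return(out)
  }
  if (nrow(ctl) == 0L) {
    thr <- as.numeric(quantile(sig$total, 1 - fdr, type = 1))
    fallback <- TRUE
    warning("control track has no signal blocks; ",
            "falling back to the global 1-fdr signal quantile")
  } else {
    cand <- sort(unique(sig$total))
    ctl_sorted <- sort(ctl$total)
    # number of control blocks with total >= t, for each candidate t
    n_lt <- findInterval(cand, ctl_sorted, left.open = TRUE)
    frac_ge <- (length(ctl_sorted) - n_lt) / length(ctl_sorted)
    ok <- which(frac_ge <= fdr)
    if (length(ok) == 0L) {
      out <- empty_peaks()
      attr(out, "threshold") <- Inf
      return(out)
    }
    thr <- cand[ok[1L]]
  }
  keep <- sig[sig$total >= thr, , drop = FALSE]
  out <- GenomicRanges::GRanges(
    keep$chrom, IRanges::IRanges(keep$start, keep$end),
    name = if (nrow(keep)) paste0("peak_", seq_len(nrow(keep))) else character(),
    score = keep$total, max = keep$max, summit = keep$summit)
  attr(out, "threshold") <- thr
  attr(out, "fallback") <- fallback
  out
}
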