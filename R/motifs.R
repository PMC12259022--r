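# IUPAC degenerate motif scanning and score-binned occurrence frequencies.
#
# The built-in motif set covers the two GTCT-based SMAD motifs (the
# palindrome GTCTAGAC and the GTCT direct repeat), two GC-rich SMAD-binding
# elements, and an AP1-like element.  Scanning runs on both strands; a match
# present at the same offset on both strands (a self-reverse-complement
# pattern landing on its own palindrome) is reported once with strand ".".

IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

#' Built-in SMAD/AP1 motif patterns
#'
#' @return A data.frame with columns `name`, `iupac`, `class`
#'   (`palindromic`, `direct_repeat`, `gc_rich`, `ap1`).
#' @export
motif_patterns <- function() {
  data.frame(
    name = c("SBE_palindrome", "SBE_GTCT_repeat", "SBE_GC_rich_1",
             "SBE_GC_rich_2", "AP1"),
    iupac = c("GTCTAGAC", "GTCTGTCTGTCT", "GGCGCCANNNNGNCV",
              "GRCGNCNNNNNGTCT", "TGASTCA"),
    class = c("palindromic", "direct_repeat", "gc_rich", "gc_rich", "ap1"),
    stringsAsFactors = FALSE)
}

check_pattern <- function(iupac) {
  letters <- strsplit(toupper(iupac), "")[[1L]]
  if (length(letters) < 4L) stop("motif pattern must be >= 4 letters: ", iupac)
  bad <- setdiff(letters, IUPAC_LETTERS)
  if (length(bad)) {
    stop("invalid IUPAC letter(s) in pattern '", iupac, "': ",
         paste(bad, collapse = ", "))
  }
  invisible(toupper(iupac))
}

#' Scan a sequence for an IUPAC pattern on both strands
#'
#' Degenerate letters in the pattern are wildcards; letters in the subject
#' are literal (an `N` in the subject is matched only by pattern `N`).  Minus
#' strand matches are matches of the reverse complement of the pattern,
#' reported at their forward-strand offset.  Overlapping matches are all
#' reported; a match at the same offset on both strands collapses to one row
#' with strand ".".
#'
#' @param pattern An IUPAC pattern string (or one row of [motif_patterns()]).
#' @param sequence A DNA string (character or `DNAString`) over `ACGTN`.
#' @return A data.frame with `offset` (0-based) and `strand` (`+`, `-`, `.`),
#'   sorted by offset.
#' @export
iupac_scan <- function(pattern, sequence) {
  if (is.data.frame(pattern)) pattern <- pattern$iupac[1L]
  pattern <- check_pattern(pattern)
  subj <- if (methods::is(sequence, "DNAString")) sequence else
    Biostrings::DNAString(toupper(as.character(sequence)))
  fwd <- BiocGenerics::start(
    Biostrings::matchPattern(pattern, subj, fixed = "subject"))
  rcp <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(pattern)))
  rev <- BiocGenerics::start(
    Biostrings::matchPattern(rcp, subj, fixed = "subject"))
  both <- intersect(fwd, rev)
  mk <- function(off, s) data.frame(offset = off,
                                    strand = rep(s, length(off)),
                                    stringsAsFactors = FALSE)
  df <- rbind(mk(setdiff(fwd, both) - 1, "+"),
              mk(setdiff(rev, both) - 1, "-"),
              mk(both - 1, "."))
  df <- df[order(df$offset), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Count motif matches inside peaks
#'
#' A match counts for a peak only when it lies fully inside the peak
#' interval.  Peaks extending beyond their chromosome end are an error.
#'
#' @param peaks A `GRanges`.
#' @param genome A `DNAStringSet` (or FASTA path) with one entry per
#'   chromosome.
#' @param patterns A pattern data.frame as from [motif_patterns()].
#' @return An integer matrix peaks x patterns, with an attribute `matches`: a
#'   `GRanges` of all matches genome-wide (metadata `motif`, match strand).
#' @export
peak_motif_counts <- function(peaks, genome, patterns = motif_patterns()) {
  if (is.character(genome) && length(genome) == 1L) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*", "", names(genome))
  }
  ch <- as.character(GenomicRanges::seqnames(peaks))
  missing <- setdiff(ch, names(genome))
  if (length(missing)) stop("peak chromosome not in genome: ", missing[1L])
  lens <- setNames(BiocGenerics::width(genome), names(genome))
  over <- GenomicRanges::end(peaks) > lens[ch]
  if (any(over)) {
    nm <- if (!is.null(peaks$name)) peaks$name[which(over)[1L]] else which(over)[1L]
    stop("peak beyond chromosome end: ", nm)
  }
  hits <- list()
  for (p in seq_len(nrow(patterns))) {
    for (cc in intersect(names(genome), unique(ch))) {
      m <- iupac_scan(patterns$iupac[p], genome[[cc]])
      if (nrow(m)) {
        hits[[length(hits) + 1L]] <- GenomicRanges::GRanges(
          cc, IRanges::IRanges(m$offset + 1,
                               m$offset + nchar(patterns$iupac[p])),
          match_strand = m$strand, motif = patterns$name[p])
      }
    }
  }
  matches <- if (length(hits)) suppressWarnings(do.call(c, hits)) else
    GenomicRanges::GRanges(match_strand = character(), motif = character())
  counts <- matrix(0L, nrow = length(peaks), ncol = nrow(patterns),
                   dimnames = list(
                     if (!is.null(peaks$name)) peaks$name else NULL,
                     patterns$name))
  if (length(matches) && length(peaks)) {
    ov <- suppressWarnings(GenomicRanges::findOverlaps(
      matches, peaks, type = "within", ignore.strand = TRUE))
    if (length(ov)) {
      tab <- table(factor(S4Vectors::subjectHits(ov), levels = seq_along(peaks)),
                   factor(matches$motif[S4Vectors::queryHits(ov)],
                          levels = patterns$name))
      counts <- counts + as.integer(tab)
      dim(counts) <- c(length(peaks), nrow(patterns))
      dimnames(counts) <- list(
        if (!is.null(peaks$name)) peaks$name else NULL, patterns$name)
    }
  }
  attr(counts, "matches") <- matches
  counts
}

#' Motif frequency across score-binned peaks, stratified by co-binding
#'
#' Within each stratum (co-bound / solo) peaks are ranked by score and cut
#' into `n_bins` equal-count bins (bin 1 = lowest scores; ties broken by rank
#' order).  The primary frequency is the fraction of a bin's peaks containing
#' at least one match; matches per kb is emitted alongside when peak widths
#' are supplied.
#'
#' @param scores Numeric peak scores.
#' @param cobound Logical co-binding flag per peak.
#' @param counts Matrix of per-peak per-motif match counts
#'   (from [peak_motif_counts()]).
#' @param n_bins Number of quantile bins (default 5).
#' @param widths Optional peak widths in bases for the density column.
#' @return A long data.frame: `bin`, `stratum`, `motif`, `n_peaks`,
#'   `n_with_match`, `frequency` and (if widths given) `matches_per_kb`.
#' @export
binned_frequency <- function(scores, cobound, counts, n_bins = 5,
                             widths = NULL) {
  stopifnot(length(scores) == length(cobound),
            length(scores) == nrow(counts))
  strata <- list(cobound = which(cobound), solo = which(!cobound))
  small <- vapply(strata, length, 0L) < n_bins
  if (any(small)) {
    stop("stratum '", names(strata)[small][1L], "' has fewer peaks than ",
         n_bins, " bins; use fewer bins")
  }
  rows <- list()
  for (s in names(strata)) {
    idx <- strata[[s]]
    r <- order(order(scores[idx], idx))       # rank, ties by original order
    bin <- floor((r - 1) * n_bins / length(idx)) + 1L
    for (m in colnames(counts)) {
      for (b in seq_len(n_bins)) {
        sel <- idx[bin == b]
        row <- data.frame(bin = b, stratum = s, motif = m,
                          n_peaks = length(sel),
                          n_with_match = sum(counts[sel, m] > 0),
                          frequency = mean(counts[sel, m] > 0))
        if (!is.null(widths)) {
          row$matches_per_kb <- sum(counts[sel, m]) / (sum(widths[sel]) / 1000)
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
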