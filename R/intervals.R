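# Interval algebra on peak calls.
#
# All user-facing files use the BED convention: 0-based, half-open [start,
# end).  Internally intervals are held as GRanges (1-based, closed); the
# conversion happens only in parse_bed()/write_bed() and the gene readers.
# "Direct overlap" means >= 1 shared base: book-ended intervals (end == next
# start) are NOT merged.

#' Read a BED file of peaks
#'
#' Parses a tab-separated BED3..BED6+ file into a `GRanges`.  Columns beyond
#' the third default to `name = "."`, `score = 0`, `strand = "."`.  A seventh
#' column, when present, is interpreted as the summit offset from the interval
#' start (as written by [call_peaks()]).  Malformed lines (non-integer
#' coordinates, `start >= end`) raise an error citing the line number.
#'
#' @param path Path to a BED file.
#' @return A `GRanges` sorted by (chrom, start, end, name), with metadata
#'   columns `name`, `score`, `summit` (1-based genomic position or `NA`).
#' @export
parse_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  keep <- !grepl("^(track|browser|#)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(empty_peaks())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("BED parse error: fewer than 3 columns at line ",
         lineno[which(nf < 3L)[1L]])
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start_chr <- vapply(fields, `[[`, "", 2L)
  end_chr <- vapply(fields, `[[`, "", 3L)
  bad <- !grepl("^[0-9]+$", start_chr) | !grepl("^[0-9]+$", end_chr)
  if (any(bad)) {
    stop("BED parse error: non-integer coordinates at line ",
         lineno[which(bad)[1L]])
  }
  start0 <- as.numeric(start_chr)
  end0 <- as.numeric(end_chr)
  bad <- start0 >= end0
  if (any(bad)) {
    stop("BED parse error: start >= end at line ", lineno[which(bad)[1L]])
  }
  getcol <- function(i, default) {
    ifelse(nf >= i, vapply(fields, function(f) if (length(f) >= i) f[[i]] else default, ""), default)
  }
  name <- getcol(4L, ".")
  score_chr <- getcol(5L, "0")
  score <- suppressWarnings(as.numeric(score_chr))
  score[is.na(score)] <- 0
  strand <- getcol(6L, ".")
  strand[!strand %in% c("+", "-", ".")] <- "."
  summit <- rep(NA_real_, length(start0))
  if (any(nf >= 7L)) {
    off <- suppressWarnings(as.numeric(getcol(7L, NA)))
    summit <- ifelse(is.na(off), NA_real_, start0 + off + 1)  # 1-based
  }
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start0 + 1, end0),
                               strand = strand,
                               name = name, score = score, summit = summit)
  sort_peaks(gr)
}

empty_peaks <- function() {
  GenomicRanges::GRanges(name = character(), score = numeric(),
                         summit = numeric())
}

sort_peaks <- function(gr) {
  o <- order(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr), GenomicRanges::end(gr),
             if (!is.null(gr$name)) gr$name else seq_along(gr))
  gr[o]
}

#' Write peaks to a BED6+ file
#'
#' Inverse of [parse_bed()]: emits 0-based half-open coordinates.  When the
#' `summit` metadata column is present and non-`NA`, a seventh column with the
#' summit offset from the interval start is written.
#'
#' @param gr A `GRanges` (metadata columns `name`, `score`, `summit` optional).
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  n <- length(gr)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else rep(".", n),
    score = if (!is.null(gr$score)) gr$score else rep(0, n),
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
    stringsAsFactors = FALSE)
  if (!is.null(gr$summit) && any(!is.na(gr$summit))) {
    df$summit_offset <- ifelse(is.na(gr$summit), -1,
                               gr$summit - 1 - df$start)
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

#' Merge directly overlapping intervals
#'
#' Collapses every maximal chain of intervals that share at least one base
#' into their union.  Book-ended intervals (zero-width gap) are kept apart:
#' direct overlap requires >= 1 shared base.  The merged `score` is the sum of
#' member scores.
#'
#' @param gr A `GRanges`.
#' @return A `GRanges` of pairwise non-overlapping merged loci with metadata
#'   columns `score` (sum over members) and `n_members`.
#' @export
merge_direct_overlap <- function(gr) {
  if (length(gr) == 0L) return(empty_merged())
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L, with.revmap = TRUE,
                               ignore.strand = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  scores <- if (!is.null(gr$score)) gr$score else rep(0, length(gr))
  S4Vectors::mcols(red) <- NULL
  red$score <- vapply(revmap, function(i) sum(scores[i]), 0)
  red$n_members <- lengths(revmap)
  red
}

empty_merged <- function() {
  GenomicRanges::GRanges(score = numeric(), n_members = integer())
}

#' Consensus peaks supported by every replicate
#'
#' Pools the replicate peak sets, merges directly overlapping peaks, and
#' keeps each merged locus only if at least one peak from *every* replicate
#' overlaps it (intersection-of-support; coordinates are the merged union of
#' the supporting peaks).
#'
#' @param peaksets A list of >= 2 `GRanges`, one per replicate.
#' @return A merged `GRanges` of consensus loci (may be empty).
#' @export
consensus_common <- function(peaksets) {
  stopifnot(is.list(peaksets), length(peaksets) >= 2L)
  if (any(lengths(peaksets) == 0L)) {
    warning("consensus_common: a replicate has no peaks; returning empty set")
    return(empty_merged())
  }
  pooled <- merge_direct_overlap(suppressWarnings(
    do.call(c, lapply(peaksets, function(g) {
      GenomicRanges::granges(g, use.mcols = FALSE)
    }))))
  support <- vapply(peaksets, function(rep_gr) {
    suppressWarnings(IRanges::overlapsAny(pooled, rep_gr, minoverlap = 1L,
                                          ignore.strand = TRUE))
  }, logical(length(pooled)))
  if (length(pooled) == 1L) support <- matrix(support, nrow = 1L)
  pooled[rowSums(support) == length(peaksets)]
}

#' Two-set peak Venn bookkeeping
#'
#' Labels each merged locus of set A as `common` (overlaps B) or `lost`
#' (A only), and each merged locus of B as `common` or `gained` (B only).
#' Because locus boundaries are merged within each set separately, the common
#' count is reported from both sides (`common_a`, `common_b`); on each side
#' `only + common = |set|` holds exactly.
#'
#' @param a,b `GRanges` peak sets (merged internally if not already).
#' @return An object of class `venn_counts`: a list with `only_a`, `only_b`,
#'   `common_a`, `common_b`, `n_a`, `n_b` and per-locus `labels_a`,
#'   `labels_b` factors (`lost`/`gained`/`common`).
#' @export
venn_peaks <- function(a, b) {
  ma <- merge_direct_overlap(a)
  mb <- merge_direct_overlap(b)
  in_b <- suppressWarnings(IRanges::overlapsAny(ma, mb, minoverlap = 1L,
                                                ignore.strand = TRUE))
  in_a <- suppressWarnings(IRanges::overlapsAny(mb, ma, minoverlap = 1L,
                                                ignore.strand = TRUE))
  out <- list(
    n_a = length(ma), n_b = length(mb),
    only_a = sum(!in_b), only_b = sum(!in_a),
    common_a = sum(in_b), common_b = sum(in_a),
    labels_a = factor(ifelse(in_b, "common", "lost"),
                      levels = c("lost", "common", "gained")),
    labels_b = factor(ifelse(in_a, "common", "gained"),
                      levels = c("lost", "common", "gained")),
    loci_a = ma, loci_b = mb)
  class(out) <- "venn_counts"
  out
}

#' @export
print.venn_counts <- function(x, ...) {
  cat("Peak Venn: |A| =", x$n_a, " |B| =", x$n_b, "\n")
  cat("  lost (A only)   :", x$only_a, "\n")
  cat("  gained (B only) :", x$only_b, "\n")
  cat("  common (A side) :", x$common_a, "  (B side:", x$common_b, ")\n")
  invisible(x)
}

#' Complete Venn counts from printed set sizes
#'
#' Given the total peak numbers of two conditions and the number of loci lost
#' from the first, completes the bookkeeping: `common = n_a - lost`,
#' `gained = n_b - common`.
#'
#' @param n_a,n_b Total merged-locus counts of sets A and B.
#' @param lost Number of A-only loci.
#' @return A list with `common` and `gained`.
#' @export
venn_complete <- function(n_a, n_b, lost) {
  stopifnot(lost <= n_a)
  common <- n_a - lost
  if (common > n_b) stop("inconsistent sizes: common exceeds |B|")
  list(common = common, gained = n_b - common)
}

#' Read a minimal gene table
#'
#' Tab-separated with header columns `gene_id`, `chrom`, `tss`, `strand`;
#' `tss` is a 0-based coordinate.
#'
#' @param path Path to the TSV.
#' @return A data.frame with those four columns.
#' @export
read_genes <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  req <- c("gene_id", "chrom", "tss", "strand")
  if (!all(req %in% names(df))) {
    stop("genes table must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in genes table")
  df
}

#' Assign peaks to gene promoters
#'
#' A peak maps to a gene iff it overlaps the promoter window
#' `[TSS - window, TSS + window)` (0-based half-open; the window is symmetric
#' and not shifted by strand).  A peak may map to several genes.
#'
#' @param peaks A `GRanges`.
#' @param genes A gene data.frame as from [read_genes()].
#' @param window Half-width of the promoter window in bases (default 500).
#' @param chrom_lengths Optional named vector of chromosome lengths; genes on
#'   chromosomes absent from it are skipped with a warning.
#' @return A list with `bound` (named logical per gene) and `map`
#'   (data.frame `gene_id`, `peak` name, peak index).
#' @export
assign_to_promoters <- function(peaks, genes, window = 500,
                                chrom_lengths = NULL) {
  if (!is.null(chrom_lengths)) {
    unknown <- !genes$chrom %in% names(chrom_lengths)
    if (any(unknown)) {
      warning("skipping ", sum(unknown), " gene(s) on unknown chromosomes: ",
              paste(utils::head(genes$gene_id[unknown], 5), collapse = ", "))
      genes <- genes[!unknown, , drop = FALSE]
    }
  }
  win <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = pmax(1, genes$tss - window + 1),
                     end = genes$tss + window))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(win, peaks, minoverlap = 1L,
                                                       ignore.strand = TRUE))
  bound <- setNames(rep(FALSE, nrow(genes)), genes$gene_id)
  bound[unique(S4Vectors::queryHits(hits))] <- TRUE
  pk_names <- if (!is.null(peaks$name)) peaks$name else as.character(seq_along(peaks))
  map <- data.frame(
    gene_id = genes$gene_id[S4Vectors::queryHits(hits)],
    peak = pk_names[S4Vectors::subjectHits(hits)],
    peak_index = S4Vectors::subjectHits(hits),
    stringsAsFactors = FALSE)
  list(bound = bound, map = map)
}
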