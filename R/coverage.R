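# Coverage tracks: per-base signal held as run-length lists, one Rle per
# chromosome.  Bases not covered by any bedGraph run read as 0.  The
# library_size slot carries the total read count used for RPM scaling.

#' Construct a coverage track
#'
#' @param cov A `SimpleRleList` (or coercible list of `Rle`) of per-base
#'   values, one element per chromosome.
#' @param library_size Total reads in the library.  Defaults to the sum of
#'   all values, which equals the read count for a raw coverage-level track.
#' @param normalized Whether values are already reads-per-million (RPM).
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(cov, library_size = NULL, normalized = FALSE) {
  if (is.list(cov)) cov <- methods::as(cov, "SimpleRleList")
  if (any(vapply(cov, function(r) any(S4Vectors::runValue(r) < 0), TRUE))) {
    stop("coverage values must be >= 0")
  }
  if (is.null(library_size)) {
    library_size <- sum(vapply(cov, function(r) sum(as.numeric(S4Vectors::runValue(r)) *
                                                    S4Vectors::runLength(r)), 0))
  }
  structure(list(cov = cov, library_size = library_size,
                 normalized = normalized),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", length(x$cov), "chromosome(s),",
      "library_size =", format(x$library_size, big.mark = ","),
      if (x$normalized) "(RPM normalized)" else "(raw)", "\n")
  invisible(x)
}

track_lengths <- function(track) {
  setNames(vapply(track$cov, length, 0L), names(track$cov))
}

#' Read a 4-column bedGraph into a coverage track
#'
#' Coordinates are 0-based half-open.  Bases missing from the file read as 0.
#'
#' @param path Path to the bedGraph file.
#' @param chrom_lengths Optional named vector of chromosome lengths used to
#'   pad the track; defaults to the maximum end seen per chromosome.
#' @param library_size,normalized See [coverage_track()].
#' @return A `coverage_track`.
#' @export
read_bedgraph <- function(path, chrom_lengths = NULL, library_size = NULL,
                          normalized = FALSE) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   col.names = c("chrom", "start", "end", "value"),
                   colClasses = c("character", "numeric", "numeric", "numeric"))
  if (any(df$start >= df$end)) stop("bedGraph: start >= end")
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1, df$end))
  if (!is.null(chrom_lengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(chrom_lengths)
    GenomeInfoDb::seqlengths(gr) <- chrom_lengths
  }
  cov <- GenomicRanges::coverage(gr, weight = df$value)
  coverage_track(cov, library_size = library_size, normalized = normalized)
}

#' Write a coverage track as bedGraph
#'
#' Zero-valued runs are omitted; coordinates are 0-based half-open.
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  pieces <- lapply(names(track$cov), function(ch) {
    r <- track$cov[[ch]]
    v <- as.numeric(S4Vectors::runValue(r))
    len <- S4Vectors::runLength(r)
    ends <- cumsum(as.numeric(len))
    starts <- ends - len
    keep <- v != 0
    if (!any(keep)) return(NULL)
    data.frame(chrom = ch, start = starts[keep], end = ends[keep],
               value = v[keep], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, pieces)
  if (is.null(df)) df <- data.frame(chrom = character(), start = numeric(),
                                    end = numeric(), value = numeric())
  write.table(format(df, scientific = FALSE, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
}

#' Normalize a track to reads per million (RPM)
#'
#' Multiplies every per-base value by `1e6 / library_size`.  Normalizing an
#' already-normalized track is an error.
#'
#' @param track A raw `coverage_track` with `library_size > 0`.
#' @return The RPM-normalized `coverage_track`.
#' @export
normalize_rpm <- function(track) {
  if (track$normalized) stop("track is already RPM-normalized")
  if (is.null(track$library_size) || track$library_size <= 0) {
    stop("library_size must be > 0 for RPM normalization")
  }
  f <- 1e6 / track$library_size
  cov <- methods::as(lapply(track$cov, function(r) r * f), "SimpleRleList")
  names(cov) <- names(track$cov)
  structure(list(cov = cov, library_size = track$library_size,
                 normalized = TRUE), class = "coverage_track")
}

#' Input-normalize a signal track against a control
#'
#' Per-base ratio `(chip + pseudocount) / (control + pseudocount)`; both
#' tracks must be RPM-normalized and on the same assembly (same chromosome
#' names and lengths).
#'
#' @param chip,control RPM-normalized `coverage_track`s.
#' @param pseudocount Stabilizing pseudocount in RPM units (default 0.5).
#' @return A `coverage_track` of ratios (`library_size = NA`).
#' @export
input_normalize <- function(chip, control, pseudocount = 0.5) {
  if (!chip$normalized || !control$normalized) {
    stop("both tracks must be RPM-normalized before input normalization")
  }
  lc <- track_lengths(chip); lk <- track_lengths(control)
  if (!identical(sort(names(lc)), sort(names(lk))) ||
      !all(lc[names(lk)] == lk)) {
    stop("assembly mismatch between chip and control tracks")
  }
  cov <- lapply(names(chip$cov), function(ch) {
    (chip$cov[[ch]] + pseudocount) / (control$cov[[ch]] + pseudocount)
  })
  names(cov) <- names(chip$cov)
  structure(list(cov = methods::as(cov, "SimpleRleList"),
                 library_size = NA_real_, normalized = TRUE),
            class = "coverage_track")
}

#' Find peak summits
#'
#' The summit is the position of the maximum track value inside each peak;
#' ties resolve to the leftmost maximum.  Peaks with all-zero signal get
#' their midpoint, flagged in the `flat` attribute.
#'
#' @param track A `coverage_track`.
#' @param peaks A `GRanges` within the track extent.
#' @return An integer vector of 1-based summit positions with attribute
#'   `flat` (logical: all-zero peaks).
#' @export
summit_of <- function(track, peaks) {
  ch <- as.character(GenomicRanges::seqnames(peaks))
  if (!all(ch %in% names(track$cov))) {
    stop("peak chromosome missing from track: ",
         setdiff(ch, names(track$cov))[1L])
  }
  n <- length(peaks)
  summit <- integer(n)
  flat <- logical(n)
  st <- GenomicRanges::start(peaks); en <- GenomicRanges::end(peaks)
  for (i in seq_len(n)) {
    if (en[i] > length(track$cov[[ch[i]]])) {
      stop("peak ", i, " extends beyond chromosome end on ", ch[i])
    }
    v <- as.numeric(S4Vectors::window(track$cov[[ch[i]]], st[i], en[i]))
    if (all(v == 0)) {
      summit[i] <- st[i] + (en[i] - st[i]) %/% 2L
      flat[i] <- TRUE
    } else {
      summit[i] <- st[i] + which.max(v) - 1L
    }
  }
  attr(summit, "flat") <- flat
  summit
}

#' Mean signal per region
#'
#' @param track A `coverage_track`.
#' @param regions A `GRanges`.
#' @return Numeric vector of per-region mean values (regions clipped to the
#'   chromosome extent).
#' @export
region_means <- function(track, regions) {
  ch <- as.character(GenomicRanges::seqnames(regions))
  out <- numeric(length(regions))
  for (cc in unique(ch)) {
    idx <- which(ch == cc)
    r <- track$cov[[cc]]
    if (is.null(r)) stop("region chromosome missing from track: ", cc)
    st <- pmax(1L, GenomicRanges::start(regions)[idx])
    en <- pmin(length(r), GenomicRanges::end(regions)[idx])
    v <- IRanges::Views(r, start = st, end = en)
    out[idx] <- IRanges::viewMeans(v)
  }
  out
}

#' Summit-centered signal matrix (metaplot)
#'
#' Extracts the window `[summit - flank, summit + flank)` around each summit,
#' averages within fixed-width bins, and stacks sites into a matrix.  Sites
#' closer than `flank` to a chromosome edge are dropped with a warning.
#'
#' @param track A `coverage_track`.
#' @param summits Either a `GRanges` with a `summit` metadata column or a
#'   data.frame with columns `chrom` and `summit` (1-based positions).
#' @param flank Half-window in bases (default 2000).
#' @param bin_width Bin width in bases (default 10); must divide `flank`.
#' @return An object of class `signal_matrix`: list with `matrix` (sites x
#'   bins), `positions` (bin start offsets relative to the summit),
#'   `col_mean` and `site_mean`.
#' @export
metaplot <- function(track, summits, flank = 2000, bin_width = 10) {
  if ((2 * flank) %% bin_width != 0) {
    stop("bin_width must divide the window width 2*flank")
  }
  if (methods::is(summits, "GRanges")) {
    pos <- summits$summit
    if (is.null(pos)) stop("summits GRanges needs a 'summit' metadata column")
    chrom <- as.character(GenomicRanges::seqnames(summits))
  } else {
    pos <- summits$summit
    chrom <- summits$chrom
  }
  nbin <- as.integer(2 * flank / bin_width)
  lens <- track_lengths(track)
  ok <- pos - flank >= 1 & pos + flank - 1 <= lens[chrom]
  if (any(!ok)) {
    warning("metaplot: dropped ", sum(!ok), " site(s) within ", flank,
            " bp of a chromosome edge")
  }
  pos <- pos[ok]; chrom <- chrom[ok]
  mat <- matrix(0, nrow = length(pos), ncol = nbin)
  for (i in seq_along(pos)) {
    v <- as.numeric(S4Vectors::window(track$cov[[chrom[i]]],
                                      pos[i] - flank, pos[i] + flank - 1))
    mat[i, ] <- colMeans(matrix(v, nrow = bin_width))
  }
  structure(list(matrix = mat,
                 positions = seq(-flank, flank - bin_width, by = bin_width),
                 col_mean = if (nrow(mat)) colMeans(mat) else numeric(nbin),
                 site_mean = rowMeans(mat)),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("signal_matrix:", nrow(x$matrix), "site(s) x", ncol(x$matrix),
      "bins; window", min(x$positions), "..",
      max(x$positions) + diff(x$positions[1:2]), "\n")
  invisible(x)
}

#' @export
plot.signal_matrix <- function(x, ...) {
  graphics::plot(x$positions, x$col_mean, type = "l",
                 xlab = "position relative to summit (bp)",
                 ylab = "mean signal", ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

# Mean of several tracks (all must share normalization state and assembly).
track_mean <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  cov <- tracks[[1L]]$cov
  if (length(tracks) > 1L) {
    for (t in tracks[-1L]) {
      cov <- methods::as(lapply(names(cov), function(ch) cov[[ch]] + t$cov[[ch]]),
                         "SimpleRleList")
      names(cov) <- names(tracks[[1L]]$cov)
    }
  }
  cov <- methods::as(lapply(cov, function(r) r / length(tracks)), "SimpleRleList")
  names(cov) <- names(tracks[[1L]]$cov)
  structure(list(cov = cov,
                 library_size = mean(vapply(tracks, `[[`, 0, "library_size")),
                 normalized = tracks[[1L]]$normalized),
            class = "coverage_track")
}
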