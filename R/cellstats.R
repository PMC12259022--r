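# Statistics on per-cell dot-count tables from multiplexed single-molecule
# in situ assays: one fluorescent dot ~ one mRNA molecule, so values are
# small nonnegative integers and ties are common.

#' Read a per-cell dot-count table
#'
#' Tab-separated with header: `cell_id`, `region` (CH/ChP), `genotype`
#' (wt/mut), `replicate`, then one integer column per gene.
#'
#' @param path Path to the TSV.
#' @return A data.frame; gene columns are returned in the `genes` attribute.
#' @export
read_cell_counts <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  meta <- c("cell_id", "region", "genotype", "replicate")
  if (!all(meta[1:3] %in% names(df))) {
    stop("counts table must have columns cell_id, region, genotype")
  }
  genes <- setdiff(names(df), meta)
  for (g in genes) {
    if (any(df[[g]] < 0) || any(df[[g]] != round(df[[g]]))) {
      stop("gene column '", g, "' must hold nonnegative integer counts")
    }
  }
  attr(df, "genes") <- genes
  df
}

#' ROC AUC comparison of two count distributions
#'
#' `AUC = P(x2 > x1) + 0.5 * P(x2 == x1)` over all cross pairs, computed via
#' the rank (Mann-Whitney) statistic; the p-value comes from the
#' corresponding two-sided rank-sum null (normal approximation under ties).
#'
#' @param x1,x2 Nonempty integer count vectors (group 1, group 2).
#' @return A list: `auc`, `p`, `n1`, `n2`.
#' @export
auc_compare <- function(x1, x2) {
  if (length(x1) == 0L || length(x2) == 0L) {
    stop("both groups must be nonempty")
  }
  r <- rank(c(x1, x2))
  r2 <- r[(length(x1) + 1):(length(x1) + length(x2))]
  u <- sum(r2) - length(x2) * (length(x2) + 1) / 2
  auc <- u / (length(x1) * length(x2))
  p <- if (length(unique(c(x1, x2))) == 1L) 1 else
    suppressWarnings(wilcox.test(x2, x1, exact = FALSE, correct = TRUE)$p.value)
  list(auc = auc, p = p, n1 = length(x1), n2 = length(x2))
}

#' Per-gene AUC comparison across a grouping of cells
#'
#' Pools cells across replicates for the primary statistic and emits a
#' per-replicate breakdown of group means alongside.
#'
#' @param counts A count data.frame from [read_cell_counts()].
#' @param genes Gene columns to compare (default: all).
#' @param group Column defining the two groups (default "genotype").
#' @param levels The two group labels, in (group1, group2) order; default the
#'   sorted unique values.
#' @param region Optional region filter (e.g. "ChP").
#' @return A data.frame: gene, auc, p, n1, n2; attribute `by_replicate`
#'   holds per-replicate group means when a `replicate` column exists.
#' @export
cell_auc_table <- function(counts, genes = NULL, group = "genotype",
                           levels = NULL, region = NULL) {
  if (!is.null(region)) counts <- counts[counts$region %in% region, ]
  genes <- genes %||% attr(counts, "genes") %||%
    setdiff(names(counts), c("cell_id", "region", "genotype", "replicate"))
  levels <- levels %||% sort(unique(counts[[group]]))
  stopifnot(length(levels) == 2L)
  g1 <- counts[counts[[group]] == levels[1L], , drop = FALSE]
  g2 <- counts[counts[[group]] == levels[2L], , drop = FALSE]
  out <- do.call(rbind, lapply(genes, function(g) {
    r <- auc_compare(g1[[g]], g2[[g]])
    data.frame(gene = g, auc = r$auc, p = r$p, n1 = r$n1, n2 = r$n2)
  }))
  if ("replicate" %in% names(counts)) {
    br <- do.call(rbind, lapply(genes, function(g) {
      agg <- stats::aggregate(counts[[g]],
                              by = list(replicate = counts$replicate,
                                        group = counts[[group]]),
                              FUN = mean)
      names(agg)[3] <- "mean_count"
      agg$gene <- g
      agg
    }))
    attr(out, "by_replicate") <- br
  }
  out
}

#' Pairwise gene-gene correlation across cells
#'
#' Product-moment correlation with two-sided p per gene pair.  Zero-variance
#' genes yield `NA` entries and a warning.
#'
#' @param counts A count data.frame (or numeric matrix cells x genes).
#' @param genes Gene columns to include.
#' @return A list: `r` and `p` (symmetric matrices), `n` cells.
#' @export
correlation_matrix <- function(counts, genes = NULL) {
  if (is.data.frame(counts)) {
    genes <- genes %||% attr(counts, "genes") %||%
      setdiff(names(counts), c("cell_id", "region", "genotype", "replicate"))
    m <- as.matrix(counts[, genes, drop = FALSE])
  } else {
    m <- counts
    genes <- colnames(m)
  }
  if (nrow(m) < 3L) stop("need >= 3 cells for correlation")
  k <- ncol(m)
  r <- matrix(NA_real_, k, k, dimnames = list(genes, genes))
  p <- r
  novar <- apply(m, 2, function(x) stats::var(x) == 0)
  if (any(novar)) {
    warning("zero-variance gene(s): ", paste(genes[novar], collapse = ", "),
            "; correlations undefined")
  }
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (novar[i] || novar[j]) next
    ct <- cor.test(m[, i], m[, j], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(r = r, p = p, n = nrow(m))
}

#' Multivariable linear fit of one gene on others
#'
#' Ordinary least squares of the response gene counts on the predictor gene
#' counts across cells.  Exactly collinear predictors are an error naming an
#' offending pair.
#'
#' @param counts A count data.frame or matrix.
#' @param response Response gene name.
#' @param predictors Predictor gene names.
#' @return A list: `coefficients` (incl. intercept), `r_squared`, `fit`
#'   (the underlying `lm`).
#' @export
multivar_fit <- function(counts, response, predictors) {
  if (is.data.frame(counts)) m <- counts else m <- as.data.frame(counts)
  stopifnot(response %in% names(m), all(predictors %in% names(m)))
  x <- as.matrix(m[, predictors, drop = FALSE])
  if (length(predictors) > 1L) {
    cc <- suppressWarnings(stats::cor(x))
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 0
    if (any(abs(cc) > 1 - 1e-12)) {
      idx <- sort(which(abs(cc) > 1 - 1e-12, arr.ind = TRUE)[1L, ])
      stop("collinear predictors: ", predictors[idx[1L]], " and ",
           predictors[idx[2L]])
    }
  }
  if (qr(cbind(1, x))$rank < ncol(x) + 1L) {
    stop("predictors are rank deficient (constant or collinear)")
  }
  fml <- stats::as.formula(paste(response, "~",
                                 paste(predictors, collapse = " + ")))
  fit <- lm(fml, data = m)
  list(coefficients = coef(fit),
       r_squared = summary(fit)$r.squared,
       fit = fit)
}
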