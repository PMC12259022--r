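# Independent brute-force oracles.  These re-derive every statistic from
# first principles (quadratic scans, closed-form algebra, tail enumeration)
# and must stay independent of the implementation paths they check.

# O(n^2) pairwise-union closure of intervals (matrix of 1-based start/end).
oracle_merge <- function(st, en) {
  changed <- TRUE
  while (changed && length(st) > 1L) {
    changed <- FALSE
    for (i in seq_along(st)) {
      for (j in seq_along(st)) {
        if (i >= j) next
        # >= 1 shared base (closed coordinates)
        if (st[i] <= en[j] && st[j] <= en[i]) {
          st[i] <- min(st[i], st[j]); en[i] <- max(en[i], en[j])
          st <- st[-j]; en <- en[-j]
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
  }
  o <- order(st)
  list(start = st[o], end = en[o])
}

# quadratic overlap labeling for two merged sets
oracle_overlap_any <- function(st1, en1, st2, en2) {
  vapply(seq_along(st1), function(i) {
    any(st1[i] <= en2 & st2 <= en1[i])
  }, logical(1))
}

# quadratic flanking-set: non-cobound summits within window of any cobound
oracle_flanking <- function(summit, cobound, window) {
  ref <- summit[cobound]
  vapply(seq_along(summit), function(i) {
    if (cobound[i]) return(FALSE)
    length(ref) > 0 && any(abs(summit[i] - ref) <= window)
  }, logical(1))
}

# IUPAC scan by regex expansion, both strands, overlapping matches
.iupac_sets <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                 B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGTN")
.revcomp_chr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", D = "H", H = "D", V = "B", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}
.iupac_regex <- function(pattern) {
  paste0("(?=", paste0("[", .iupac_sets[strsplit(pattern, "")[[1]]], "]",
                       collapse = ""), ")")
}
oracle_iupac_scan <- function(pattern, sequence) {
  scan1 <- function(pat) {
    m <- gregexpr(.iupac_regex(pat), sequence, perl = TRUE)[[1]]
    if (m[1] == -1) integer() else as.integer(m) - 1L
  }
  fwd <- scan1(pattern)
  rev <- scan1(.revcomp_chr(pattern))
  both <- intersect(fwd, rev)
  df <- rbind(
    data.frame(offset = setdiff(fwd, both), strand = rep("+", length(setdiff(fwd, both)))),
    data.frame(offset = setdiff(rev, both), strand = rep("-", length(setdiff(rev, both)))),
    data.frame(offset = both, strand = rep(".", length(both))))
  df <- df[order(df$offset), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Benjamini-Hochberg by the direct sort-and-cummin formula
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# moderated two-sample t re-derived longhand for one row
oracle_modt_row <- function(a, b, s2_prior, d0) {
  ka <- length(a); kb <- length(b)
  df <- ka + kb - 2
  s2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
  s2m <- (d0 * s2_prior + df * s2) / (d0 + df)
  t <- (mean(b) - mean(a)) / sqrt(s2m * (1 / ka + 1 / kb))
  p <- 2 * stats::pt(-abs(t), df + d0)
  list(t = t, p = p)
}

# Fisher exact p by full hypergeometric tail enumeration on the 2x2 table
# [[a, b], [c, d]]; margins fixed.
oracle_fisher <- function(a, b, c, d) {
  m <- a + c          # bound column total
  n <- b + d
  k <- a + b          # group1 row total
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  list(
    greater = sum(stats::dhyper(a:hi, m, n, k)),
    two_sided = sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# AUC by O(n^2) pair counting
oracle_auc <- function(x1, x2) {
  wins <- 0
  for (i in seq_along(x1)) for (j in seq_along(x2)) {
    wins <- wins + (x2[j] > x1[i]) + 0.5 * (x2[j] == x1[i])
  }
  wins / (length(x1) * length(x2))
}

# Pearson r longhand
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# least squares via explicitly solved normal equations
oracle_lm <- function(y, X) {
  Xd <- cbind(1, X)
  solve(t(Xd) %*% Xd, t(Xd) %*% y)[, 1]
}
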