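# Synthetic dataset generator with planted ground truth.
#
# The generator emulates, at the coverage level, a two-factor (a "SMAD" and a
# "co-factor") by two-genotype (co-factor present "wt" / absent "ko") design
# with replicates, plus promoter-activity tracks over three conditions
# (untreated, treated, ko_treated) and per-cell dot-count tables.  Reads are
# per-base expected counts (uniform background + triangular peaks) that are
# Poisson-sampled per base; there is no read-length or fragment model.
#
# Mass bookkeeping is exact: per condition the expected read total equals
# library_size.  In the co-factor-null genotype the reads lost from co-bound
# sites (factor 2^-delta) are redistributed to the planted ectopic sites
# (enhancer-switch redistribution); with no ectopic sites they fall back into
# the uniform background.  Planted promoter effects are balanced by an
# activated gene set and any residual is absorbed into the background rate.

#' Synthetic dataset configuration
#'
#' All downstream stages can be exercised against the truth tables this
#' configuration plants.  Identical seed + configuration give byte-identical
#' outputs.
#'
#' @param seed Master seed; per-stream seeds are derived from it by fixed
#'   labels so adding replicates never perturbs earlier streams.
#' @param genome_length Total genome size in bases, split equally across
#'   `n_chroms` chromosomes.  Genes live on the last chromosome; regulatory
#'   sites on the others.
#' @param n_chroms Number of chromosomes (>= 2 when `n_genes > 0`).
#' @param n_smad_sites Number of planted SMAD regulatory sites.
#' @param cobound_fraction Fraction of SMAD sites co-bound by the co-factor.
#' @param dependence_effect_delta log2 drop of SMAD signal at co-bound sites
#'   in the null genotype (>= 0).
#' @param relocation_fraction_rho Fraction of co-bound sites that acquire an
#'   ectopic flanking site in the null genotype.
#' @param relocation_distance Maximum summit offset of an ectopic site from
#'   its parent co-bound site (bases; default 200000).
#' @param n_replicates Replicates per factor and condition.
#' @param library_size Expected reads per replicate track.
#' @param peak_width Width of the triangular peak kernel (bases).
#' @param background_rate Uniform background, reads per base.
#' @param control_rate Reads per base of the flat nonspecific control (IgG)
#'   library and of the co-factor track in the null genotype (the antibody
#'   target is absent, so only sparse background is recovered).  Default
#'   `background_rate / 10`: a shallow control whose RPM-scaled single-read
#'   blocks set a stringent empirical peak-calling threshold.
#' @param amplitude_cv Coefficient of variation of per-site amplitudes
#'   (log-normal; 0 for equal amplitudes).
#' @param n_genes Number of genes (0 disables genes, activity tracks and the
#'   promoter analyses).
#' @param repressed_set_sizes Named integer vector `c(bmp=, cofactor=,
#'   overlap=)`: sizes of the treatment-repressed set, the co-factor-
#'   repressed set, and their planted overlap.
#' @param activated_set_size Genes up-regulated by treatment.  Default
#'   `NULL`: sized so the gained mass balances the repressed set's loss.
#' @param cofactor_activated_set_size Genes down-regulated on co-factor loss.
#'   Default `NULL`: sized to mass-balance the null-genotype condition.
#' @param promoter_effect Planted promoter effect in log2 units.
#' @param bound_rates Named rates `c(co_repressed=, bmp_only=, other=)` of
#'   genes carrying a planted SMAD peak at their TSS.
#' @param motif_rates Named rates `c(palindromic_cobound=, gc_rich_solo=,
#'   ap1_ectopic=)` of sites carrying the class-specific planted motif.
#' @param promoter_site_weight Amplitude of TSS SMAD sites relative to
#'   regulatory sites.
#' @param cell_table List: `n_cells_per_region` (per replicate and genotype),
#'   `n_replicates`, `correlation` (latent gene-gene correlation of the
#'   proliferation/Wnt marker pair), optional `panel` data.frame (see
#'   [default_cell_panel()]).
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1,
                             genome_length = 6e6,
                             n_chroms = 3,
                             n_smad_sites = 200,
                             cobound_fraction = 0.5,
                             dependence_effect_delta = 1,
                             relocation_fraction_rho = 0.5,
                             relocation_distance = 200000,
                             n_replicates = 3,
                             library_size = 1e6,
                             peak_width = 600,
                             background_rate = 0.01,
                             control_rate = NULL,
                             amplitude_cv = 0.2,
                             n_genes = 300,
                             repressed_set_sizes = c(bmp = 30, cofactor = 20,
                                                     overlap = 8),
                             activated_set_size = NULL,
                             cofactor_activated_set_size = NULL,
                             promoter_effect = 1,
                             bound_rates = c(co_repressed = 24 / 31,
                                             bmp_only = 84 / 153,
                                             other = 0.3),
                             motif_rates = c(palindromic_cobound = 0.8,
                                             gc_rich_solo = 0.6,
                                             ap1_ectopic = 0.8),
                             promoter_site_weight = 0.5,
                             cell_table = list(n_cells_per_region = 110,
                                               n_replicates = 3,
                                               correlation = 0.5)) {
  cfg <- as.list(environment())
  stopifnot(cobound_fraction >= 0, cobound_fraction <= 1,
            relocation_fraction_rho >= 0, relocation_fraction_rho <= 1,
            dependence_effect_delta >= 0,
            n_replicates >= 2, library_size > 0, peak_width >= 10,
            background_rate >= 0, n_chroms >= 1, amplitude_cv >= 0)
  rs <- repressed_set_sizes
  if (!all(c("bmp", "cofactor", "overlap") %in% names(rs))) {
    stop("repressed_set_sizes needs named entries bmp, cofactor, overlap")
  }
  if (rs[["overlap"]] > min(rs[["bmp"]], rs[["cofactor"]])) {
    stop("overlap set cannot exceed either repressed set")
  }
  if (n_genes > 0) {
    # default activated-set sizes mass-balance the planted repressed sets so
    # per-condition expected totals stay at library_size without large
    # background adjustments
    e <- promoter_effect
    up_gain <- 2^e - 1; down_loss <- 1 - 2^(-e)
    if (is.null(activated_set_size)) {
      activated_set_size <- max(0L, round(down_loss * rs[["bmp"]] / up_gain))
    }
    if (is.null(cofactor_activated_set_size)) {
      cofactor_activated_set_size <- max(0L, round(
        (up_gain * (rs[["cofactor"]] - rs[["overlap"]] + activated_set_size) -
           down_loss * (rs[["bmp"]] - rs[["overlap"]])) / down_loss))
    }
    cfg$activated_set_size <- activated_set_size
    cfg$cofactor_activated_set_size <- cofactor_activated_set_size
    need <- rs[["bmp"]] + rs[["cofactor"]] - rs[["overlap"]] +
      activated_set_size + cofactor_activated_set_size
    if (need > n_genes) stop("planted gene sets exceed n_genes")
    if (n_chroms < 2) stop("n_chroms must be >= 2 when genes are generated")
  }
  if (is.null(control_rate)) cfg$control_rate <- background_rate / 10
  if (background_rate * genome_length >= library_size) {
    stop("sizing error: background_rate * genome_length must be below ",
         "library_size (no mass left for peaks)")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("synthetic_config: genome", x$genome_length, "bp /", x$n_chroms,
      "chroms;", x$n_smad_sites, "SMAD sites (cobound fraction",
      x$cobound_fraction, ", delta", x$dependence_effect_delta, ", rho",
      x$relocation_fraction_rho, ");", x$n_genes, "genes;",
      x$n_replicates, "replicates x library", x$library_size, "\n")
  invisible(x)
}

#' Default dot-count gene panel
#'
#' Mean dot counts per cell by region for the wild type, planted mutant
#' log2 effects by region, and per-cell biological noise (sdlog of the
#' log-normal rate mixing).  The panel mirrors a dorsal-midline design:
#' proliferation (Mki67) and Wnt readouts (Axin2, Wnt7b) rise in the mutant
#' ChP while the secretory marker (Ttr) falls.
#'
#' @return A data.frame with columns `gene`, `mu_ch`, `mu_chp`, `eff_ch`,
#'   `eff_chp`, `sdlog`.
#' @export
default_cell_panel <- function() {
  data.frame(
    gene   = c("Mki67", "Axin2", "Ttr", "Wnt7b", "Wnt2b", "Bmp4"),
    mu_ch  = c(8,       6,       0.5,   7,       9,       1),
    mu_chp = c(2,       1.5,     12,    1,       0.8,     6),
    eff_ch = c(0.2,     0.2,     0,     0.2,     0,       0),
    eff_chp = c(1.5,    1.2,     -1,    1,       0,       0),
    sdlog  = rep(0.5, 6),
    stringsAsFactors = FALSE)
}

# Triangular peak kernel: per-base expected counts of total mass `amplitude`
# centered on `center` (1-based), width `width` bases.
triangle_kernel <- function(width) {
  h <- width %/% 2L
  d <- abs(seq.int(-h, h))
  w <- 1 - d / (h + 1)
  w / sum(w)
}

add_triangles <- function(rate, centers, amplitudes, width) {
  kern <- triangle_kernel(width)
  h <- width %/% 2L
  for (i in seq_along(centers)) {
    lo <- centers[i] - h
    hi <- centers[i] + h
    if (lo < 1 || hi > length(rate)) {
      stop("sizing error: planted site at position ", centers[i],
           " does not fit inside the chromosome; ",
           "increase genome_length or reduce peak_width")
    }
    rate[lo:hi] <- rate[lo:hi] + amplitudes[i] * kern
  }
  rate
}

# Evenly spaced positions with jitter, min distance to chromosome ends.
place_positions <- function(n, chrom_len, margin, min_spacing, what) {
  if (n == 0L) return(integer())
  spacing <- (chrom_len - 2 * margin) / n
  if (spacing < min_spacing) {
    stop("sizing error: cannot place ", n, " ", what,
         " on a chromosome of ", chrom_len, " bases (needs spacing >= ",
         min_spacing, "); increase genome_length or reduce counts")
  }
  jit <- runif(n, -spacing / 8, spacing / 8)
  as.integer(round(margin + (seq_len(n) - 0.5) * spacing + jit))
}

# Instantiate a degenerate IUPAC pattern as a concrete sequence.
instantiate_motif <- function(iupac) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  letters <- strsplit(iupac, "")[[1L]]
  paste0(vapply(letters, function(l) {
    s <- sets[[l]]
    if (length(s) == 1L) s else sample(s, 1L)
  }, ""), collapse = "")
}

# Exact-count random subset: round(rate * n) elements of idx.
planted_subset <- function(idx, rate) {
  k <- round(rate * length(idx))
  if (k == 0L) return(integer())
  sample(idx, k)
}

#' Generate a synthetic dataset with planted ground truth
#'
#' Builds the genome (with motifs written in at site centers), the gene
#' table, raw coverage tracks for every factor x condition x replicate,
#' per-condition expected-rate tracks (the Poisson means, for oracle
#' checks), the per-cell count table, and the truth tables.  When `out_dir`
#' is given everything is also written to disk as plain text (FASTA,
#' TSV, bedGraph).
#'
#' @param config A [synthetic_config()].
#' @param out_dir Optional output directory.
#' @return A list of class `synthetic_dataset`: `config`, `chrom_lengths`,
#'   `genome` (`DNAStringSet`), `genes`, `truth` (`$sites`, `$genes`,
#'   `$cells`), `tracks` (named list of raw `coverage_track`s),
#'   `expected` (named list, one per condition), `counts`.
#' @export
generate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  L <- as.integer(cfg$genome_length %/% cfg$n_chroms)
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  chrom_lengths <- setNames(rep(L, cfg$n_chroms), chroms)
  gene_chrom <- if (cfg$n_genes > 0) chroms[cfg$n_chroms] else NA
  reg_chroms <- if (cfg$n_genes > 0) chroms[-cfg$n_chroms] else chroms

  ## ---- regulatory sites -------------------------------------------------
  set.seed(stream_seed(cfg$seed, "sites"))
  margin <- 3000L + cfg$peak_width
  n_per <- diff(round(seq(0, cfg$n_smad_sites, length.out = length(reg_chroms) + 1)))
  sites <- do.call(rbind, lapply(seq_along(reg_chroms), function(i) {
    pos <- place_positions(n_per[i], L, margin, 4 * cfg$peak_width,
                           "SMAD sites")
    if (length(pos) == 0L) return(NULL)
    data.frame(chrom = reg_chroms[i], summit = pos, stringsAsFactors = FALSE)
  }))
  if (is.null(sites)) sites <- data.frame(chrom = character(), summit = integer())
  n_s <- nrow(sites)
  sites$class <- "solo"
  n_cob <- round(cfg$cobound_fraction * n_s)
  if (n_cob > 0) sites$class[sample(n_s, n_cob)] <- "cobound"

  # ectopic sites: planted near a parent co-bound site, null genotype only
  ect <- NULL
  delta <- cfg$dependence_effect_delta
  n_ect <- if (delta > 0) round(cfg$relocation_fraction_rho * n_cob) else 0L
  if (n_ect > 0) {
    if (cfg$relocation_distance < 2 * cfg$peak_width) {
      stop("sizing error: relocation_distance must be >= 2 * peak_width")
    }
    parents <- sample(which(sites$class == "cobound"), n_ect)
    epos <- integer(n_ect); echr <- character(n_ect)
    occupied <- split(sites$summit, sites$chrom)
    for (k in seq_len(n_ect)) {
      p <- parents[k]
      ok <- FALSE
      for (try in 1:200) {
        off <- sample(c(-1L, 1L), 1L) *
          as.integer(round(runif(1, 2 * cfg$peak_width,
                                 cfg$relocation_distance)))
        cand <- sites$summit[p] + off
        if (cand < margin || cand > L - margin) next
        if (min(abs(occupied[[sites$chrom[p]]] - cand)) < 2 * cfg$peak_width) next
        ok <- TRUE
        break
      }
      if (!ok) {
        stop("sizing error: could not place an ectopic site within ",
             cfg$relocation_distance, " bases of site ", p,
             "; genome too crowded")
      }
      epos[k] <- cand; echr[k] <- sites$chrom[p]
      occupied[[echr[k]]] <- c(occupied[[echr[k]]], cand)
    }
    ect <- data.frame(chrom = echr, summit = epos, class = "ectopic",
                      parent = paste0("site_", parents),
                      stringsAsFactors = FALSE)
  }
  sites$parent <- NA_character_
  sites$site_id <- paste0("site_", seq_len(n_s))
  if (!is.null(ect)) {
    ect$site_id <- paste0("ectopic_", seq_len(nrow(ect)))
    sites <- rbind(sites[, c("site_id", "chrom", "summit", "class", "parent")],
                   ect[, c("site_id", "chrom", "summit", "class", "parent")])
  } else {
    sites <- sites[, c("site_id", "chrom", "summit", "class", "parent")]
  }

  ## ---- genes ------------------------------------------------------------
  genes <- NULL
  if (cfg$n_genes > 0) {
    set.seed(stream_seed(cfg$seed, "genes"))
    tss <- place_positions(cfg$n_genes, L, 2000L, 1600, "genes")
    genes <- data.frame(
      gene_id = sprintf("gene_%04d", seq_len(cfg$n_genes)),
      chrom = gene_chrom, tss = tss - 1L,     # emitted 0-based
      strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
      stringsAsFactors = FALSE)
    rs <- cfg$repressed_set_sizes
    pool <- seq_len(cfg$n_genes)
    overlap_idx <- sample(pool, rs[["overlap"]])
    pool <- setdiff(pool, overlap_idx)
    bmp_only_idx <- sample(pool, rs[["bmp"]] - rs[["overlap"]])
    pool <- setdiff(pool, bmp_only_idx)
    cof_only_idx <- sample(pool, rs[["cofactor"]] - rs[["overlap"]])
    pool <- setdiff(pool, cof_only_idx)
    act_idx <- sample(pool, cfg$activated_set_size)
    pool <- setdiff(pool, act_idx)
    cact_idx <- sample(pool, cfg$cofactor_activated_set_size)
    genes$bmp_repressed <- seq_len(cfg$n_genes) %in% c(overlap_idx, bmp_only_idx)
    genes$cofactor_repressed <- seq_len(cfg$n_genes) %in% c(overlap_idx, cof_only_idx)
    genes$bmp_activated <- seq_len(cfg$n_genes) %in% act_idx
    genes$cofactor_activated <- seq_len(cfg$n_genes) %in% cact_idx
    # planted promoter binding, enriched in the co-repressed group
    other_idx <- setdiff(seq_len(cfg$n_genes),
                         c(overlap_idx, bmp_only_idx))
    bound_idx <- c(planted_subset(overlap_idx, cfg$bound_rates[["co_repressed"]]),
                   planted_subset(bmp_only_idx, cfg$bound_rates[["bmp_only"]]),
                   planted_subset(other_idx, cfg$bound_rates[["other"]]))
    genes$bound <- seq_len(cfg$n_genes) %in% bound_idx
  }

  ## ---- amplitudes -------------------------------------------------------
  set.seed(stream_seed(cfg$seed, "amplitudes"))
  sdlog <- sqrt(log(1 + cfg$amplitude_cv^2))
  lnorm1 <- function(n) if (n == 0L) numeric() else
    exp(rnorm(n, -sdlog^2 / 2, sdlog))
  bg_total <- cfg$background_rate * L * cfg$n_chroms
  site_mass <- cfg$library_size - bg_total
  is_ect <- sites$class == "ectopic"
  n_prom <- if (!is.null(genes)) sum(genes$bound) else 0L
  w <- c(rep(1, sum(!is_ect)), rep(cfg$promoter_site_weight, n_prom))
  f <- lnorm1(length(w))
  amp_all <- site_mass * (w * f) / sum(w * f)
  amp <- numeric(nrow(sites))
  amp[!is_ect] <- amp_all[seq_len(sum(!is_ect))]
  prom_amp <- if (n_prom > 0) amp_all[(sum(!is_ect) + 1):length(amp_all)] else numeric()

  # null genotype: co-bound mass drops by 2^-delta; the lost mass moves to
  # the ectopic sites (or the background when there are none)
  amp_ko <- amp
  cob <- sites$class == "cobound"
  amp_ko[cob] <- amp[cob] * 2^(-delta)
  lost <- sum(amp[cob]) - sum(amp_ko[cob])
  bg_extra_ko <- 0
  if (any(is_ect)) {
    amp_ko[is_ect] <- lost / sum(is_ect)
  } else if (lost > 0) {
    bg_extra_ko <- lost / (L * cfg$n_chroms)
  }
  amp[is_ect] <- 0

  # co-factor track: binds the co-bound sites in wt, nothing in ko
  cof_f <- lnorm1(sum(cob))
  cof_amp <- if (sum(cob) > 0) site_mass * cof_f / sum(cof_f) else numeric()

  # activity (promoter mark): per-gene triangular promoter signal
  act <- NULL
  if (!is.null(genes)) {
    gf <- lnorm1(cfg$n_genes)
    g_amp <- site_mass * gf / sum(gf)
    e <- cfg$promoter_effect
    mult <- list(
      untreated  = rep(1, cfg$n_genes),
      treated    = ifelse(genes$bmp_repressed, 2^(-e),
                          ifelse(genes$bmp_activated, 2^e, 1)),
      ko_treated = ifelse(genes$bmp_repressed & !genes$cofactor_repressed, 2^(-e),
                          ifelse(genes$cofactor_repressed & !genes$bmp_repressed, 2^e,
                                 ifelse(genes$bmp_activated, 2^e,
                                        ifelse(genes$cofactor_activated, 2^(-e), 1)))))
    act <- list(g_amp = g_amp, mult = mult)
    for (cond in names(mult)) {
      resid <- site_mass - sum(g_amp * mult[[cond]])
      if (bg_total + resid < 0) {
        stop("sizing error: planted activity effects exceed the background ",
             "mass in condition ", cond,
             "; increase background_rate or shrink the planted sets")
      }
    }
  }

  ## ---- genome sequence with planted motifs ------------------------------
  set.seed(stream_seed(cfg$seed, "genome"))
  base_chars <- c("A", "C", "G", "T")
  seqs <- lapply(chroms, function(ch) sample(base_chars, L, replace = TRUE))
  names(seqs) <- chroms

  set.seed(stream_seed(cfg$seed, "motifs"))
  pats <- motif_patterns()
  pat_of <- function(nm) pats$iupac[pats$name == nm]
  sites$motif <- NA_character_
  sites$motif_start <- NA_integer_     # 0-based
  plant <- function(rows, motif_names) {
    for (i in seq_along(rows)) {
      r <- rows[i]
      nm <- motif_names[(i - 1L) %% length(motif_names) + 1L]
      inst <- instantiate_motif(pat_of(nm))
      len <- nchar(inst)
      start1 <- sites$summit[r] - len %/% 2L
      seqs[[sites$chrom[r]]][start1:(start1 + len - 1L)] <<-
        strsplit(inst, "")[[1L]]
      sites$motif[r] <<- nm
      sites$motif_start[r] <<- start1 - 1L
    }
  }
  mr <- cfg$motif_rates
  plant(planted_subset(which(sites$class == "cobound"),
                       mr[["palindromic_cobound"]]), "SBE_palindrome")
  plant(planted_subset(which(sites$class == "solo"),
                       mr[["gc_rich_solo"]]),
        c("SBE_GC_rich_1", "SBE_GC_rich_2"))
  plant(planted_subset(which(sites$class == "ectopic"),
                       mr[["ap1_ectopic"]]), "AP1")
  genome <- Biostrings::DNAStringSet(vapply(seqs, paste0, "", collapse = ""))
  names(genome) <- chroms

  ## ---- expected rate tracks per condition -------------------------------
  w2 <- cfg$peak_width
  rate_track <- function(fill_rate, centers_by_chrom, amps_by_chrom,
                         width = w2) {
    cov <- lapply(chroms, function(ch) {
      r <- rep(fill_rate, L)
      ce <- centers_by_chrom[[ch]]
      if (!is.null(ce) && length(ce)) {
        r <- add_triangles(r, ce, amps_by_chrom[[ch]], width)
      }
      S4Vectors::Rle(r)
    })
    names(cov) <- chroms
    coverage_track(cov, normalized = FALSE)
  }
  by_chrom <- function(sel, amps) {
    list(centers = split(sites$summit[sel], sites$chrom[sel]),
         amps = split(amps[sel], sites$chrom[sel]))
  }
  add_prom_sites <- function(bc) {
    if (is.null(genes) || n_prom == 0L) return(bc)
    bsel <- genes$bound
    bc$centers[[gene_chrom]] <- c(bc$centers[[gene_chrom]],
                                  genes$tss[bsel] + 1L)
    bc$amps[[gene_chrom]] <- c(bc$amps[[gene_chrom]], prom_amp)
    bc
  }
  expected <- list()
  wt_sel <- !is_ect
  bc <- add_prom_sites(by_chrom(wt_sel, amp))
  expected$smad_wt <- rate_track(cfg$background_rate, bc$centers, bc$amps)
  ko_sel <- amp_ko > 0
  bc <- add_prom_sites(by_chrom(ko_sel, amp_ko))
  expected$smad_ko <- rate_track(cfg$background_rate + bg_extra_ko,
                                 bc$centers, bc$amps)
  bc <- by_chrom(cob, replace(numeric(nrow(sites)), which(cob), cof_amp))
  expected$cofactor_wt <- rate_track(cfg$background_rate, bc$centers, bc$amps)
  expected$cofactor_ko <- rate_track(cfg$control_rate, list(), list())
  expected$igg_ctrl <- rate_track(cfg$control_rate, list(), list())
  if (!is.null(genes)) {
    for (cond in names(act$mult)) {
      a <- act$g_amp * act$mult[[cond]]
      resid_rate <- (site_mass - sum(a)) / (L * cfg$n_chroms)
      cen <- list(); cen[[gene_chrom]] <- genes$tss + 1L
      am <- list(); am[[gene_chrom]] <- a
      expected[[paste0("activity_", cond)]] <-
        rate_track(cfg$background_rate + resid_rate, cen, am,
                   width = min(w2, 999L))
    }
  }

  ## ---- Poisson-sampled replicate tracks ---------------------------------
  tracks <- list()
  for (cond in names(expected)) {
    for (r in seq_len(cfg$n_replicates)) {
      set.seed(stream_seed(cfg$seed, paste0("track:", cond, ":rep", r)))
      cov <- lapply(chroms, function(ch) {
        lam <- as.numeric(expected[[cond]]$cov[[ch]])
        S4Vectors::Rle(rpois(length(lam), lam))
      })
      names(cov) <- chroms
      tracks[[paste0(cond, "_rep", r)]] <- coverage_track(cov,
                                                          normalized = FALSE)
    }
  }

  ## ---- cell count table -------------------------------------------------
  panel <- cfg$cell_table$panel %||% default_cell_panel()
  counts <- simulate_cell_counts(
    panel,
    n_cells_per_region = cfg$cell_table$n_cells_per_region %||% 110,
    n_replicates = cfg$cell_table$n_replicates %||% 3,
    correlation = cfg$cell_table$correlation %||% 0.5,
    seed = stream_seed(cfg$seed, "cells"))

  ## ---- truth tables ------------------------------------------------------
  truth_sites <- data.frame(
    site_id = sites$site_id, chrom = sites$chrom,
    summit = sites$summit - 1L,                     # 0-based
    start = sites$summit - 1L - w2 %/% 2L,
    end = sites$summit - 1L + w2 %/% 2L + 1L,
    class = sites$class, parent = sites$parent,
    amplitude_wt = amp, amplitude_ko = amp_ko,
    planted_log2fc = ifelse(sites$class == "cobound", -delta,
                            ifelse(sites$class == "ectopic", NA, 0)),
    motif = sites$motif, motif_start = sites$motif_start,
    stringsAsFactors = FALSE)
  truth <- list(sites = truth_sites, genes = genes,
                cells = attr(counts, "planted"))

  out <- structure(list(config = cfg, chrom_lengths = chrom_lengths,
                        genome = genome, genes = genes, truth = truth,
                        tracks = tracks, expected = expected,
                        counts = counts),
                   class = "synthetic_dataset")
  if (!is.null(out_dir)) write_dataset(out, out_dir)
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", length(x$tracks), "tracks,",
      nrow(x$truth$sites), "planted sites,",
      if (is.null(x$genes)) 0 else nrow(x$genes), "genes,",
      nrow(x$counts), "cells\n")
  invisible(x)
}

#' Simulate a per-cell dot-count table
#'
#' Counts are Poisson draws around per-cell log-normal rates; the planted
#' genotype effect shifts the rate of affected genes by `eff` log2 units in
#' the mutant, and the first two panel genes share a latent Gaussian factor
#' with the given correlation.
#'
#' @param panel A panel data.frame ([default_cell_panel()] layout).
#' @param n_cells_per_region Cells per region, replicate and genotype.
#' @param n_replicates Biological replicates.
#' @param correlation Latent correlation between the first two panel genes.
#' @param seed Seed for this stream.
#' @return A data.frame `cell_id`, `region`, `genotype`, `replicate` plus one
#'   column per panel gene; attribute `planted` stores the effect table.
#' @export
simulate_cell_counts <- function(panel = default_cell_panel(),
                                 n_cells_per_region = 110,
                                 n_replicates = 3,
                                 correlation = 0.5,
                                 seed = 1) {
  set.seed(seed)
  stopifnot(abs(correlation) < 1)
  rows <- list()
  k <- nrow(panel)
  for (gt in c("wt", "mut")) for (rep_i in seq_len(n_replicates)) {
    for (reg in c("CH", "ChP")) {
      n <- n_cells_per_region
      z <- matrix(rnorm(n * k), n, k)
      # first two genes share a latent factor at the requested correlation
      if (k >= 2) {
        shared <- rnorm(n)
        z[, 1] <- sqrt(correlation) * shared + sqrt(1 - correlation) * z[, 1]
        z[, 2] <- sqrt(correlation) * shared + sqrt(1 - correlation) * z[, 2]
      }
      mu <- if (reg == "CH") panel$mu_ch else panel$mu_chp
      eff <- if (reg == "CH") panel$eff_ch else panel$eff_chp
      if (gt == "mut") mu <- mu * 2^eff
      lam <- sweep(exp(sweep(z, 2, panel$sdlog, `*`) -
                         matrix(panel$sdlog^2 / 2, n, k, byrow = TRUE)),
                   2, mu, `*`)
      cnt <- matrix(rpois(n * k, lam), n, k)
      colnames(cnt) <- panel$gene
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = sprintf("%s_%s_rep%d_c%03d", gt, reg, rep_i, seq_len(n)),
        region = reg, genotype = gt, replicate = rep_i,
        cnt, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "planted") <- panel
  attr(out, "genes") <- panel$gene
  out
}

#' Write a synthetic dataset to disk as plain text
#'
#' Emits `genome.fa` (60-column FASTA), `genes.tsv`, `truth_sites.tsv`,
#' `truth_genes.tsv`, `counts.tsv` and one bedGraph per track under
#' `tracks/`.
#'
#' @param ds A `synthetic_dataset`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(ds, out_dir) {
  dir.create(file.path(out_dir, "tracks"), recursive = TRUE,
             showWarnings = FALSE)
  Biostrings::writeXStringSet(ds$genome, file.path(out_dir, "genome.fa"),
                              width = 60)
  wt <- function(df, f) write.table(df, file.path(out_dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  if (!is.null(ds$genes)) wt(ds$genes, "genes.tsv")
  wt(ds$truth$sites, "truth_sites.tsv")
  if (!is.null(ds$truth$genes)) wt(ds$truth$genes, "truth_genes.tsv")
  wt(ds$counts, "counts.tsv")
  for (nm in names(ds$tracks)) {
    write_bedgraph(ds$tracks[[nm]],
                   file.path(out_dir, "tracks", paste0(nm, ".bedgraph")))
  }
  invisible(out_dir)
}

# Truth peaks as a GRanges (internal convenience for tests/pipeline).
truth_site_granges <- function(ds, classes = c("cobound", "solo")) {
  tr <- ds$truth$sites
  tr <- tr[tr$class %in% classes, , drop = FALSE]
  GenomicRanges::GRanges(tr$chrom,
                         IRanges::IRanges(tr$start + 1L, tr$end),
                         site = tr$site_id, summit = tr$summit + 1L,
                         class = tr$class)
}
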