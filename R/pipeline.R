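# End-to-end pipeline: simulate -> call peaks -> consensus -> venn ->
# co-binding classification -> dependence / relocation -> motif binning ->
# promoter differential -> set logic -> Fisher -> cell statistics, with a
# reproducibility manifest.  Every stage is also callable on its own.

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the [synthetic_config()] fields at the top level, with
#' an optional `pipeline:` block for stage parameters (`fdr`, `alpha`,
#' `flank_window`, `halfwidth`, `promoter_window`, `n_bins`).
#'
#' @param path Path to the YAML file.
#' @return A list with elements `synthetic` (a `synthetic_config`) and
#'   `pipeline` (stage overrides).
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  pl <- y$pipeline %||% list()
  y$pipeline <- NULL
  for (nm in c("repressed_set_sizes", "bound_rates", "motif_rates")) {
    if (!is.null(y[[nm]])) y[[nm]] <- unlist(y[[nm]])
  }
  cfg <- do.call(synthetic_config, y)
  list(synthetic = cfg, pipeline = pl)
}

default_stage_params <- function() {
  list(fdr = 0.1, alpha = 0.01, flank_window = 200000, halfwidth = 500,
       promoter_window = 500, n_bins = 5, pseudocount = 0.5, d0 = NA,
       max_gap = 50)
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Generates (or reuses) a synthetic dataset, then chains every analysis
#' stage.  With `out_dir`, all tables are written as TSV and a manifest of
#' file digests is emitted; rerunning with the same configuration and seed
#' reproduces identical digests.
#'
#' @param config A `synthetic_config`, a list as returned by
#'   [read_config()], or a path to a YAML config.
#' @param out_dir Optional output directory.
#' @param seed Optional seed overriding the configuration seed.
#' @param dataset Optional pre-built `synthetic_dataset` (skips simulation).
#' @return An object of class `cswitch_run`: a list with the dataset and the
#'   results of every stage (`peaks`, `consensus`, `venn`, `records`,
#'   `dependence`, `diff_binding`, `motif_bins`, `activity_*`, `set_logic`,
#'   `fisher`, `cells`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL,
                         dataset = NULL) {
  if (is.character(config)) config <- read_config(config)
  if (inherits(config, "synthetic_config")) {
    config <- list(synthetic = config, pipeline = list())
  }
  sp <- utils::modifyList(default_stage_params(), config$pipeline)
  cfg <- config$synthetic
  if (!is.null(seed)) cfg$seed <- seed

  stage <- function(name) message("[cswitch] ", name)
  stage("simulate")
  ds <- dataset %||% generate_dataset(cfg)

  stage("normalize")
  norm <- lapply(ds$tracks, normalize_rpm)
  grp <- function(cond) norm[grep(paste0("^", cond, "_rep"), names(norm))]

  stage("callpeaks")
  igg <- grp("igg_ctrl")
  call_all <- function(cond) {
    lapply(seq_along(grp(cond)), function(r) {
      call_peaks(grp(cond)[[r]], igg[[min(r, length(igg))]], fdr = sp$fdr,
                 max_gap = sp$max_gap)
    })
  }
  peaks <- list(smad_wt = call_all("smad_wt"), smad_ko = call_all("smad_ko"),
                cofactor_wt = call_all("cofactor_wt"))

  stage("consensus")
  consensus <- lapply(peaks, consensus_common)

  stage("venn")
  venn <- venn_peaks(consensus$smad_wt, consensus$smad_ko)

  stage("classify")
  # site universe for the relocation analysis: union of both genotypes'
  # consensus loci, so sites gained in the null genotype are testable
  smad_mean <- track_mean(c(grp("smad_wt"), grp("smad_ko")))
  cons <- merge_direct_overlap(suppressWarnings(c(
    GenomicRanges::granges(consensus$smad_wt, use.mcols = FALSE),
    GenomicRanges::granges(consensus$smad_ko, use.mcols = FALSE))))
  cons$summit <- summit_of(smad_mean, cons)
  cons$name <- paste0("locus_", seq_along(cons))
  cons$score <- region_means(smad_mean, cons) * BiocGenerics::width(cons)
  records <- classify_cobound(cons, consensus$cofactor_wt)

  stage("dependence")
  # dependence is assessed on the wild-type site universe (co-bound vs solo);
  # loci only present in the null genotype belong to the relocation analysis
  records_wt <- records[suppressWarnings(
    IRanges::overlapsAny(records, consensus$smad_wt))]
  dependence <- dependence_test(records_wt, grp("smad_wt"), grp("smad_ko"),
                                halfwidth = sp$halfwidth,
                                pseudocount = sp$pseudocount)

  stage("relocate")
  diff_binding <- differential_binding(records, grp("smad_wt"),
                                       grp("smad_ko"), fdr = sp$fdr,
                                       pseudocount = sp$pseudocount,
                                       halfwidth = sp$halfwidth, d0 = sp$d0,
                                       flank_window = sp$flank_window)

  stage("motifbin")
  motif_bins <- NULL
  if (sum(records$cobound) >= sp$n_bins &&
      sum(!records$cobound) >= sp$n_bins) {
    counts <- peak_motif_counts(records, ds$genome)
    motif_bins <- binned_frequency(records$score, records$cobound, counts,
                                   n_bins = sp$n_bins,
                                   widths = BiocGenerics::width(records))
  }

  activity <- list(); set_logic <- NULL; fisher <- NULL
  if (!is.null(ds$genes)) {
    stage("promdiff")
    gsig <- function(cond) quantify_promoters(ds$genes, grp(cond),
                                              window = sp$promoter_window)
    untreated <- gsig("activity_untreated")
    treated <- gsig("activity_treated")
    ko_treated <- gsig("activity_ko_treated")
    activity$bmp <- differential_activity(untreated, treated,
                                          alpha = sp$alpha,
                                          pseudocount = sp$pseudocount,
                                          d0 = sp$d0)
    activity$cofactor <- differential_activity(treated, ko_treated,
                                               alpha = sp$alpha,
                                               pseudocount = sp$pseudocount,
                                               d0 = sp$d0)
    stage("setlogic")
    bound <- assign_to_promoters(consensus$smad_wt, ds$genes,
                                 window = sp$promoter_window,
                                 chrom_lengths = ds$chrom_lengths)
    universe <- ds$genes$gene_id
    # repressed by treatment = down in treated; repressed by the co-factor =
    # de-repressed (up) on co-factor loss
    set_logic <- gene_set_logic(activity$bmp$down, activity$cofactor$up,
                                names(bound$bound)[bound$bound], universe)
    stage("fisher")
    co <- set_logic$co_repressed
    only_a <- set_logic$only_a
    fisher <- binding_enrichment_fisher(
      length(set_logic$co_repressed_bound), length(co),
      length(set_logic$only_a_bound), length(only_a))
  }

  stage("cellstats")
  cells <- list(
    auc = cell_auc_table(ds$counts, region = "ChP", group = "genotype",
                         levels = c("wt", "mut")),
    correlation = correlation_matrix(ds$counts),
    fit = multivar_fit(ds$counts, "Mki67", c("Axin2", "Ttr")))

  run <- structure(list(config = cfg, params = sp, dataset = ds,
                        peaks = peaks, consensus = consensus, venn = venn,
                        records = records, dependence = dependence,
                        diff_binding = diff_binding,
                        motif_bins = motif_bins, activity = activity,
                        set_logic = set_logic, fisher = fisher,
                        cells = cells, manifest = NULL),
                   class = "cswitch_run")
  if (!is.null(out_dir)) run$manifest <- write_run(run, out_dir)
  run
}

#' @export
print.cswitch_run <- function(x, ...) {
  cat("cswitch pipeline run (seed ", x$config$seed, ")\n", sep = "")
  cat(" consensus peaks: wt =", length(x$consensus$smad_wt),
      "ko =", length(x$consensus$smad_ko),
      "cofactor =", length(x$consensus$cofactor_wt), "\n")
  cat(" venn: lost =", x$venn$only_a, "gained =", x$venn$only_b,
      "common =", x$venn$common_a, "\n")
  cat(" co-bound sites:", sum(x$records$cobound), "of",
      length(x$records), "\n")
  print(x$diff_binding)
  if (!is.null(x$fisher)) print(x$fisher)
  invisible(x)
}

# Write all result tables + manifest; returns the manifest data.frame.
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, f) {
    write.table(df, file.path(out_dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
    f
  }
  files <- c(
    wt(as.data.frame(run$consensus$smad_wt), "consensus_smad_wt.tsv"),
    wt(as.data.frame(run$consensus$smad_ko), "consensus_smad_ko.tsv"),
    wt(data.frame(set = c("only_a", "only_b", "common_a", "common_b"),
                  n = c(run$venn$only_a, run$venn$only_b,
                        run$venn$common_a, run$venn$common_b)), "venn.tsv"),
    wt(run$dependence, "dependence.tsv"),
    wt(run$diff_binding$table, "differential_binding.tsv"),
    wt(run$diff_binding$summary, "differential_binding_summary.tsv"))
  if (!is.null(run$motif_bins)) {
    files <- c(files, wt(run$motif_bins, "motif_bins.tsv"))
  }
  if (length(run$activity)) {
    files <- c(files,
               wt(run$activity$bmp$table, "activity_treated_vs_untreated.tsv"),
               wt(run$activity$cofactor$table, "activity_ko_vs_treated.tsv"),
               wt(run$set_logic$counts, "gene_sets.tsv"))
  }
  files <- c(files, wt(run$cells$auc, "cell_auc.tsv"))
  digests <- tools::md5sum(file.path(out_dir, files))
  manifest <- data.frame(file = files, md5 = unname(digests),
                         stringsAsFactors = FALSE)
  manifest <- rbind(manifest,
                    data.frame(file = "__seed__", md5 = as.character(run$config$seed)),
                    data.frame(file = "__version__",
                               md5 = as.character(utils::packageVersion("cswitch"))))
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest
}
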