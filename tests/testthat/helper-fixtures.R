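# Shared fixtures: small synthetic configurations and hand-built tracks.

tiny_config <- function(seed = 3, ...) {
  args <- utils::modifyList(list(
    seed = seed, genome_length = 9e5, n_chroms = 3, n_smad_sites = 40,
    library_size = 2e5, n_genes = 60,
    repressed_set_sizes = c(bmp = 8, cofactor = 6, overlap = 3),
    cell_table = list(n_cells_per_region = 30, n_replicates = 2,
                      correlation = 0.5)), list(...))
  do.call(synthetic_config, args)
}

# One shared small dataset (and pipeline run), built once per test session.
.fixture_env <- new.env(parent = emptyenv())

tiny_dataset <- function() {
  if (is.null(.fixture_env$ds)) {
    .fixture_env$ds <- generate_dataset(tiny_config())
  }
  .fixture_env$ds
}

tiny_run <- function() {
  if (is.null(.fixture_env$run)) {
    .fixture_env$run <- suppressMessages(suppressWarnings(
      run_pipeline(tiny_config(), dataset = tiny_dataset())))
  }
  .fixture_env$run
}

# coverage_track from a list of per-chromosome numeric vectors
make_track <- function(values, library_size = NULL, normalized = FALSE) {
  if (is.numeric(values)) values <- list(chr1 = values)
  cov <- lapply(values, S4Vectors::Rle)
  coverage_track(cov, library_size = library_size, normalized = normalized)
}

# random interval set on one chromosome (1-based closed GRanges)
random_intervals <- function(n, span = 10000, max_width = 300) {
  st <- sample.int(span, n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  GenomicRanges::GRanges("chr1", IRanges::IRanges(st, st + w - 1),
                         name = paste0("iv", seq_len(n)),
                         score = stats::runif(n))
}

bed_file <- function(lines) {
  f <- tempfile(fileext = ".bed")
  writeLines(lines, f)
  f
}
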