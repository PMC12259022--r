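Package: cswitch
Title: Co-Factor Dependent Transcription-Factor Binding Relocation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for studying how a chromatin co-factor redirects
    a signaling transcription-factor complex across the genome, using sparse
    coverage profiles (CUT&TAG/ChIP-seq style). Provides BED interval algebra
    (direct-overlap merging, replicate consensus, condition Venn bookkeeping,
    peak-to-promoter assignment), RPM coverage normalization with
    summit-centered metaplots, an empirical-FDR sparse peak caller, IUPAC
    degenerate motif scanning with score-binned frequency curves, co-binding
    classification with dependence and 200-kb relocation statistics using a
    moderated two-sample test, promoter-window differential activity with
    gene-set logic and Fisher enrichment, per-cell dot-count statistics
    (ROC AUC, correlation, multivariable regression), and a fully
    parameterized synthetic-data generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    graphics,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    IRanges,
    GenomicRanges,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
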