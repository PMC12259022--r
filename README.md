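# cswitch

Analysis toolkit for **co-factor dependent relocation of a signaling
transcription-factor complex** — the "enhancer switching" phenomenon in
which a chromatin co-factor (e.g. PRDM16) anchors SMAD4/pSMAD1/5/8 at
repressive elements, and loss of the co-factor both weakens SMAD binding
at those sites and redirects it to ectopic sites within ~200 kb.

The package is aimed at regulatory-genomics analysts working with sparse
coverage profiles (CUT&TAG / ChIP-seq at the coverage level). It provides:

* **Interval algebra** on peak calls: BED I/O, direct-overlap merging
  (book-ended peaks are *not* merged), replicate consensus
  (intersection-of-support), condition Venn bookkeeping with lost / gained
  / common labels, and peak-to-promoter assignment over TSS ± 500 bp
  windows.
* **Coverage tools**: reads-per-million normalization
  (`value × 1e6 / library`), input ratios, summit finding
  (leftmost maximum), and summit-centered metaplot matrices.
* **Peak calling** against a control track with an empirical FDR
  threshold on block total signal, for self-contained synthetic runs.
* **IUPAC motif scanning** on both strands, with the SMAD-binding element
  set built in (palindromic `GTCTAGAC`, `GTCT` direct repeat, two GC-rich
  SBEs, AP1), and motif occurrence frequencies across score-binned peaks
  stratified by co-binding.
* **The core inference**: classification of SMAD sites by co-factor
  co-binding, a paired-by-site dependence test per stratum, flanking-site
  selection within 200 kb of co-bound summits, and per-site differential
  binding with a variance-moderated statistic
  (`s²_mod = (d0·s²_prior + df·s²)/(d0+df)`, prior df estimated by
  moment-matching by default) and Benjamini–Hochberg control at q < 0.1.
* **Promoter activity**: TSS-window quantification, differential calls at
  p < 0.01, repressed/activated gene-set logic, and the exact Fisher test
  for binding enrichment.
* **Per-cell dot-count statistics**: ROC AUC with half-credit ties,
  correlation matrices, multivariable least squares.
* **A synthetic-data generator** that plants all of the above — site
  classes, effect sizes, motifs, gene sets, cell-level shifts — with exact
  mass bookkeeping and byte-level reproducibility, so every stage is
  testable against known truth.

## Worked example

Simulate a small study (40 SMAD sites, half co-bound; a twofold planted
dependence effect, `delta = 1`; half of the co-bound sites acquiring an
ectopic neighbor in the co-factor-null genotype, `rho = 0.5`; 60 genes
with planted repressed sets) and run the full pipeline:

```r
library(cswitch)

cfg <- synthetic_config(seed = 1, genome_length = 9e5, n_chroms = 3,
                        n_smad_sites = 40, library_size = 2e5, n_genes = 60,
                        repressed_set_sizes = c(bmp = 8, cofactor = 6,
                                                overlap = 3))
run <- run_pipeline(cfg)
run
```

```
cswitch pipeline run (seed 1)
 consensus peaks: wt = 61 ko = 71 cofactor = 20
 venn: lost = 0 gained = 10 common = 61
 co-bound sites: 20 of 71
Differential binding analysis: 50 features, 31 significant (q < 0.1)
    class  n mean_log2fc n_significant
  cobound 20  -0.9566709            20
 flanking 30   1.7265874            11
```

Reading the output: the wild-type consensus recovers the 40 planted
regulatory sites plus the planted promoter-bound genes; the null genotype
gains 10 loci — exactly the planted ectopic sites. All 20 co-bound loci
lose signal (mean log2 fold change −0.96 for a planted effect of −1),
while the flanking class (solo sites within 200 kb of a co-bound summit,
including the ectopic ones) shows a net gain: the enhancer-switch
signature. The per-stratum dependence test makes the same point:

```r
run$dependence
```

```
  stratum n_sites   mean_a   mean_b   mean_log2fc            p
1 cobound      20 19.21418  9.64702 -0.9581777361 3.070531e-15
2    solo      41 14.00200 14.00723  0.0005196601 8.900185e-01
```

Co-bound occupancy halves (p ≈ 3e-15, paired two-tailed t across sites)
while solo sites are untouched. The gene-level worked example needs no
simulation at all — given that 24 of 31 co-repressed genes versus 84 of
153 singly-repressed genes carry a promoter peak:

```r
binding_enrichment_fisher(24, 31, 84, 153)
```

```
       bound unbound
group1    24       7
group2    84      69
odds ratio = 2.816; one-sided p = 0.01511; two-sided p = 0.02689
```

## Documentation

The methods vignette (`vignettes/cswitch-methods.Rmd`) describes the
models and conventions in detail: interval and coordinate rules, the
coverage and pseudocount model, the empirical-FDR caller, the moderated
statistic and its prior-df estimate, motif encodings, the synthetic
generator's mass bookkeeping, and what passing tests do and do not show
about real data.
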