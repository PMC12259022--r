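---
title: "Models and methods behind cswitch"
author: "cswitch authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cswitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cswitch)
```

# The scientific question

BMP signaling activates receptor SMADs (pSMAD1/5/8) which, together with
the co-SMAD SMAD4, bind genomic regulatory elements. On its own this
complex tends to act as an activator; in some cell states it represses
proliferation genes instead. A chromatin co-factor (in the motivating
system, PRDM16 in neural stem cells and choroid plexus epithelium) can
anchor the SMAD complex at a distinct set of repressive elements. When the
co-factor is removed, two things happen at once:

1. SMAD occupancy drops at the formerly co-bound sites (a *dependence*
   effect), and
2. SMAD signal appears at *ectopic* sites in the neighborhood — within a
   few hundred kilobases — of the co-bound sites (a *relocation* or
   "enhancer switching" effect), where different sequence elements
   (AP1-like motifs) and co-activators take over.

`cswitch` implements the computational side of this analysis as a
reusable, fully testable pipeline operating on coverage-level signal
tracks (bedGraph), peak calls (BED), a genome (FASTA), a minimal gene
table, and per-cell dot-count tables. Because the real datasets require
raw sequencing data, every stage can instead be exercised on a synthetic
dataset with *planted* ground truth, so that the whole chain — from peak
calling to the relocation volcano — is verifiable end to end.

# Interval conventions

All files use BED conventions: 0-based, half-open `[start, end)`.
Internally intervals are `GRanges`. Two rules deserve emphasis:

* **Direct overlap.** Peaks are merged only when they share at least one
  base. Book-ended intervals (`end == next start`) are *not* merged. This
  mirrors merge tools run in their "as-given" mode, which preserve peak
  boundaries rather than chaining nearby peaks.
* **Promoter windows.** A gene's promoter is `[TSS - w, TSS + w)` with
  `w = 500` bp by default, symmetric and not shifted by strand.

Replicate consensus (`consensus_common()`) pools all replicate peaks,
merges direct overlaps, and keeps a merged locus only when every
replicate contributes at least one overlapping peak. The condition Venn
(`venn_peaks()`) counts merged loci per set; because locus boundaries are
merged within each set separately, a single A-locus spanning two B-loci is
counted once on the A side and twice on the B side. Both sides are
reported (`common_a`, `common_b`); each satisfies its own margin identity
`only + common = |set|`. The completion helper `venn_complete()` performs
the same arithmetic from printed set sizes.

# Coverage model and normalization

A `coverage_track` is a per-chromosome run-length vector of per-base
values with a library size. RPM normalization multiplies every value by
`1e6 / library_size`; bases absent from a bedGraph read as zero, and
input normalization is the per-base pseudocounted ratio
`(chip + c) / (control + c)`.

The pseudocount `c = 0.5` RPM is shared by all log-ratio computations in
the package. It stabilizes empty windows but biases measured log2 fold
changes toward zero when window means are within an order of magnitude of
`c`; with the default synthetic configuration, a planted twofold drop is
measured as roughly −0.87 rather than −1.0. This is a property of
pseudocounted fold changes generally, not of the simulation, and it is why
recovery checks compare observed effects against expectations computed
from the planted rates *through the same estimator*.

Summits are the leftmost position of the maximum value inside a peak
(midpoint, flagged, when a peak is all zero — the tie-break and the summit
definition itself are not standardized in the literature, so both are
explicit here). Metaplots extract `[summit - flank, summit + flank)`
windows (default ±2000 bp, 10 bp bins) and report the site × bin matrix,
per-bin means and per-site means.

# Peak calling

`call_peaks()` is a deliberately small re-implementation of sparse-signal
peak calling in the spirit of empirical-FDR callers for tagmentation data:
candidate blocks are maximal runs of nonzero signal; the block statistic is
its total signal; the threshold is the smallest observed signal-block
statistic `t` such that at most a fraction `fdr` of *control* blocks reach
`t`. The control track is treated as an empirical null sample of block
totals. Two consequences are tested as invariants: lowering `fdr` never
increases the number of calls, and calls are disjoint sub-intervals of
candidate blocks. When the control has no signal the caller falls back to
the `1 - fdr` quantile of the signal blocks and flags the result. Exact
equivalence with any published caller is a non-goal; downstream stages
only require consistent calls.

One practical wrinkle comes from simulating at coverage level: per-base
Poisson sampling drops isolated bases inside an otherwise contiguous
enrichment, splitting one peak into a dense core plus shoulder fragments.
Real fragment pileups do not do this (each sequenced fragment covers tens
of bases). `call_peaks(max_gap =)` therefore allows small internal zero
gaps when forming candidate blocks; the pipeline uses 50 bp, while the
default (0) preserves the strict maximal-run definition.

# Co-binding, dependence and relocation

`classify_cobound()` labels a SMAD site co-bound iff it shares ≥ 1 bp with
a co-factor peak, and records the distance from each solo summit to the
nearest co-bound summit. Per-site signal is the mean RPM in a ±500 bp
window around the summit — a width-independent quantity comparable across
sites.

* **Dependence** (`dependence_test()`): per stratum (co-bound / solo),
  per-site condition means are compared with a two-tailed *paired-by-site*
  t test. Pairing is a choice — the sites are the experimental units and
  are identical across conditions — and the unpaired alternative differs
  only in power. Identical inputs make every paired difference exactly
  zero; the test degenerates and p = 1 is reported.
* **Flanking sites** (`flanking_sites()`): non-co-bound sites whose summit
  lies within 200 kb (configurable) of at least one co-bound summit. A
  site near several co-bound sites counts once.
* **Differential binding** (`differential_binding()`): co-bound and
  flanking sites are tested jointly. Per-site replicate window means are
  log2-transformed with the pseudocount, a moderated two-sample statistic
  is computed per site, and Benjamini–Hochberg adjustment runs across all
  tested sites; significance is `q < 0.1` by default. The summary reports
  the mean log2 fold change per class — the quantity plotted beside a
  relocation volcano.

## The moderated statistic

Per-site variances from 2–4 replicates are unstable, so each pooled
variance is shrunk toward a common prior:
`s²_mod = (d0 · s²_prior + df · s²) / (d0 + df)`, with the t statistic
referenced to `t(d0 + df)`. The prior weight `d0` is, by default,
estimated from the data by moment-matching the spread of `log s²`: the
excess of `var(log s²)` over `trigamma(df/2)` (the spread expected from
sampling alone) is attributed to genuine variance dispersion and inverted
through the trigamma function. When site variances are homogeneous this
estimate grows large and the statistic approaches a pooled-variance z
test, keeping the null p-value distribution close to uniform; a fixed
`d0` (for example 4) can be supplied instead, but referencing a fixed-
prior statistic to `t(d0+df)` is conservative precisely in the
homogeneous case, which is why estimation is the default. Promoter
differential activity uses the same statistic but calls significance on
the raw p-value (`p < 0.01` by default), matching the promoter analyses
this pipeline emulates; q-values are still reported.

# Motif analysis

The built-in motif set transcribes the field's SMAD-binding elements:
the palindrome `GTCTAGAC`; the GTCT direct repeat `GTCTGTCTGTCT`; two
GC-rich SBEs, `GGCGCCANNNNGNCV` and `GRCGNCNNNNNGTCT`; and an AP1-like
element `TGASTCA`. The first GC-rich element is one reading of the
shorthand "GGCGCC-AN4-GNCV" (A followed by four Ns); the alternative
reading, (AN)×4, is not used but any pattern string can be supplied.

Scanning treats pattern letters as IUPAC wildcards and subject letters as
literal; both strands are scanned by matching the reverse complement of
the pattern, and a match present at the same offset on both strands (a
self-reverse-complement pattern on its own palindrome) is reported once
with strand ".". For binned frequencies, peaks are stratified by
co-binding, ranked by score within stratum and cut into five equal-count
bins; the reported frequency is the fraction of a bin's peaks with at
least one fully contained match. Presence/absence is robust to peak-width
differences; matches per kb is emitted as a secondary column. Equal-count
(rank) binning makes the curves invariant to monotone score rescaling.

# Promoter activity and gene-set logic

Promoter signal is the mean RPM over TSS ± 500 bp per gene and replicate.
Two pairwise comparisons mirror the experimental design: treated vs untreated
(genes down = repressed by the treatment) and co-factor-null-treated vs
treated (genes up = de-repressed, i.e. repressed by the co-factor).
`gene_set_logic()` intersects the two repressed sets and applies the
bound-promoter filter; `binding_enrichment_fisher()` tests whether the
co-repressed set is enriched for bound promoters with an exact
hypergeometric test. Both one- and two-sided p are reported. The odds
ratio is the sample cross-product `(a·d)/(b·c)`, not the conditional MLE.

# Per-cell dot counts

Dot-count tables (one row per cell; region, genotype and replicate
labels; integer counts per gene) are compared per gene with the ROC AUC,
`P(x₂ > x₁) + ½ P(x₂ = x₁)`, computed from the rank statistic; ties are
common in small counts, hence the half-credit convention, and the p-value
comes from the corresponding two-sided rank-sum null. Cells are pooled
across replicates for the primary statistic with a per-replicate
breakdown emitted alongside. Gene–gene structure uses the product-moment
correlation with two-sided p, and `multivar_fit()` is ordinary least
squares of one gene on others with exact-collinearity detection. Region
labels are inputs: image segmentation is out of scope.

# The synthetic-data generator

`generate_dataset()` builds a self-contained toy study:

* **Genome.** `n_chroms` equal chromosomes of random sequence (default
  3 × 2 Mb); genes live on the last chromosome, regulatory sites on the
  others. Concrete instances of the class-specific motifs are written
  into the sequence at site centers (palindrome at 80% of co-bound sites,
  GC-rich SBEs at 60% of solo sites, AP1 at 80% of ectopic sites, by
  default), so the motif module can be validated against exact planted
  coordinates.
* **Tracks.** Reads are per-base expected counts — a uniform background
  plus triangular peaks of width 600 bp — Poisson-sampled per base, with
  no read-length model. Per-site amplitudes are log-normal with CV 0.2
  around the equal-share amplitude `(library − background) / n_sites`.
* **Mass bookkeeping.** Expected totals equal `library_size` exactly in
  every main condition. In the co-factor-null genotype, co-bound sites are
  attenuated by `2^-delta` and the lost mass is redistributed equally over
  the ectopic sites (the enhancer-switch reading of relocation); with no
  ectopic sites it returns to the background. This conservation is what
  keeps RPM normalization by observed totals unbiased, so the planted
  `delta` is recoverable.
* **Controls.** The IgG-like control and the co-factor track in the null
  genotype are shallow flat background libraries (`control_rate`, default
  one tenth of the background rate). After RPM scaling each control read
  is worth a large value, so the empirical threshold sits above the
  shoulder fragments of genuine peaks — the same reason real sparse
  controls give clean thresholds.
* **Promoter activity.** Three conditions (untreated, treated,
  co-factor-null treated) with planted repressed sets: the
  treatment-repressed set (down in treated), the co-factor-repressed set
  (up in null; overlap planted explicitly), plus activated counterweight
  sets sized automatically so each condition's expected total stays at
  `library_size` without distorting unaffected genes. Promoter binding is
  planted at higher rates in the co-repressed group, emulating the
  enrichment the Fisher test measures.
* **Cells.** Dot counts are Poisson draws around per-cell log-normal
  rates; the proliferation and Wnt-readout genes share a latent factor
  with correlation 0.5, and the mutant genotype shifts selected genes in
  the ChP region (up for Mki67/Axin2/Wnt7b, down for Ttr).

Identical seed and configuration give byte-identical outputs; every
stochastic stream derives its own seed from the master seed and a fixed
label, so adding replicates never perturbs earlier streams.

What the simulation does *not* emulate: fragment-length structure,
GC/mappability bias, irreproducible-discovery structure between
replicates (replicates share identical expected tracks), chromatin
domains, and any read-level error. Passing tests on synthetic data
therefore demonstrate the correctness and calibration of the *computations*
under the stated generative model — not robustness to every artifact of
real chromatin profiling.

# Problem sizes and reproducibility checks

The packaged checks run at deliberately moderate scale, chosen so the
full suite completes in a few minutes on one CPU while keeping the
statistical criteria meaningful:

* parameter recovery: 200 SMAD sites (100 co-bound, 50 ectopic), 2 × 2 Mb
  genome, 3 replicates of 1e6 reads — the planted `delta = 1` is
  recovered as a mean co-bound log2 fold change within ±0.15 of −1, at
  least 80% of planted ectopic sites reach `q < 0.1`, and the co-bound
  palindrome frequency falls inside the exact binomial 95% CI of the
  planted rate in every score bin;
* null calibration: 500 sites with `delta = 0, rho = 0` (the fraction of
  sites at `p < 0.05` must stay within 0.05 ± 0.02) and 1000 genes with no
  planted sets (false-call rate at `alpha = 0.01` at most twice nominal);
* oracle equivalence: interval merging, Venn labels and flanking sets
  against quadratic brute-force scans; IUPAC scanning against regex
  expansion; BH, moderated-t, AUC, correlation, least-squares and Fisher
  p-values against longhand formulas and hypergeometric tail enumeration.

Two worked examples use printed study quantities as inputs: the peak-set
bookkeeping (7639 and 3337 consensus peaks with 5936 lost gives 1634
gained) and the binding-enrichment Fisher test (24/31 vs 84/153 gives a
one-sided p of 0.015). `scripts/acceptance.R` recomputes all of the above
from scratch.

# Known limitations

* The caller is a minimal thresholding scheme; model-based callers,
  duplicate handling and fragment-length estimation are out of scope.
* The Venn common count is side-dependent by construction; consumers who
  need a single number should state which side they count (the completion
  arithmetic uses the A side).
* Pseudocounted fold changes are biased toward zero for weak sites; the
  bias is shared by estimator and expectation in all recovery checks.
* The moderated statistic assumes exchangeable per-site variances around
  a single prior; strong mean–variance trends would call for a trended
  prior, which is not implemented.
* AUC p-values use the rank-sum correspondence with a normal
  approximation under ties; exact small-sample nulls are not implemented.
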