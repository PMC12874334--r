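---
title: "Models, parameters and design choices in hdmomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in hdmomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

hdmomics implements the downstream analysis of a chronic-allergen-exposure
lung-tumor study design — somatic-mutation consolidation, mutational
spectra, bulk expression, DNA methylation, and promoter
methylation–expression integration — together with a synthetic-data
generator that plants a known truth. This vignette documents the models,
the tunable parameters with their defaults and units, the numerical
choices, and what the synthetic world does and does not establish.

## Study design assumed throughout

Two treatments (HDM allergen vs VEH vehicle) × two tissues (normal lung vs
tumor), n = 3 biological replicates per cell. All planted effects sit in
the normal-tissue contrast; the tumor contrast is null, mirroring the
biological picture of a tumor compartment that is already reprogrammed and
comparatively unresponsive.

## Somatic-mutation consolidation

Candidate variants from four callers are keyed by
(chromosome, position, ref, alt) per sample and pass four filters in fixed
order:

1. **Consensus**: support by ≥ 2 of 4 callers (`min_callers = 2`).
2. **Known sites**: exact-key match against a sites-only VCF of known
   germline variants. Allele identity is required, not just position —
   a stricter reading that avoids discarding true somatic alleles at
   polymorphic positions.
3. **Shared**: any variant passing in ≥ 2 samples is removed from all
   samples (`min_samples = 2`; the source description says "multiple",
   which we parameterize).
4. **Clustered**: any variant belonging to a group of > 3 variants whose
   positions span ≤ 10 bp is removed. The span is inclusive
   (`max(pos) − min(pos) + 1 ≤ window`), scanned per chromosome with a
   two-pointer sweep; this is order-free, idempotent, and provably equal to
   brute-force subset enumeration (the test suite checks all position
   multisets of size ≤ 6 exhaustively). A tiny floating-point slack
   (1e−12) keeps group means landing exactly on a threshold from being
   lost to representation error; the same slack idea is used for the
   methylation Δβ boundary.

The filter order (consensus → known → shared → clustered) is logged in the
audit attribute; rerunning the chain on its own output is a no-op.
Mutational burden is pass-count / callable Mb; `callable_mb` is a required
user input (default 30 in the toy config) because a real callable-genome
denominator is not derivable from variant lists alone.

## Mutational spectra

SBS96 uses the pyrimidine-centric convention: purine-reference SNVs are
reverse-complemented with their flanking context before labelling;
category order is substitution class (C>A … T>G), then 5′ base, then 3′
base. DBS78 maps doublets to the canonical orientation table
(reverse-complementing both alleles when needed); doublets whose alternate
shares a base with the reference have no category and are excluded. ID83
follows the COSMIC v3 conventions: 1-bp events subtyped by the pyrimidine
of the affected base with homopolymer bins 0–5 ("5" = 5 or more additional
identical bases); longer events binned by length (2, 3, 4, 5+) and
repeat-unit count; deletions with no additional repeat copy are classified
by microhomology length (maximum of left/right partial match after left
alignment). Indels are normalized (shared VCF anchor stripped) and
left-aligned before classification; mutations whose needed context
contains N are excluded and counted, never guessed.

The GSEA-style running sum (below) and the spectrum code share one
numerical convention worth stating: when an extremum is an exact ±tie
(possible with symmetric step weights), the earliest rank position within
1e−10 of the maximum wins, so results do not depend on last-bit rounding.

## Expression

* **Filtering**: genes with row sum < 10 are removed.
* **Normalization**: median-of-ratios size factors (the DESeq definition:
  per-sample median of count / per-gene geometric mean over all-positive
  genes); TMM factors (weighted trimmed mean of M-values, 30% M-trim, 5%
  A-trim, inverse-variance weights, geometric mean 1) for the integration
  stage's expression matrix. Our TMM agrees with edgeR to 1e−6 in the test
  suite.
* **Differential expression** is a deliberate simplification of the cited
  pipeline: per-gene two-group negative-binomial model with size-factor
  offsets, method-of-moments dispersion pooled across the two groups
  (floor 1e−8), **no shrinkage, no outlier replacement, no independent
  filtering**. The Wald statistic log2FC/SE is referenced to a *t*
  distribution with nA + nB − 2 degrees of freedom rather than N(0, 1):
  with n = 3 per group and unshrunk dispersions the normal reference is
  empirically anticonservative (type-I ≈ 0.12 at nominal 0.05), while the
  t reference is calibrated (≈ 0.03–0.05 across our null simulations,
  slightly conservative at low dispersion). DEG calls: FDR < 0.05
  (Benjamini–Hochberg) and |log2FC| ≥ 1.
* **Module scores**: per-gene z-score across the samples in scope, then
  the mean over present members. Scoring is done within tissue (normal and
  tumor scored separately), since the two tissues are reported in separate
  panels; this is exposed via the `samples` argument. Constant genes
  contribute z = 0. The curated IL-1/inflammasome (17 genes) and IL-17
  target (12 genes) modules ship in `extdata/gene_sets/il_modules.gmt`.
* **Preranked GSEA**: weighted Kolmogorov–Smirnov running sum with weight
  |stat|; the ranking metric is the DE Wald statistic (the source does not
  state its ranking metric; this is our documented substitute). NES is ES
  divided by the mean |ES| of same-sign gene-label permutations
  (seed-controlled; 10,000 by default, 1,000 in the pipeline stage for
  runtime), p is the permutation tail with add-one smoothing, FDR is BH
  across sets.
* **Deconvolution**: population score = mean log2(TPM+1) over marker
  genes; group differences by Welch + BH across populations. This is a
  generic marker-set scorer; the published murine marker lists are not
  redistributed.

## Methylation

β-values are clamped to [1e−6, 1−1e−6] on load. Significance is tested on
M-values (logit2) with a vectorized Welch test, while effect sizes are
reported on the β scale (Δβ = group A − group B) plus the
`mean.quot.log2` effect log2((mA + ε)/(mB + ε)) with ε = 0.01 (the
stabilizing offset of the cited array pipeline; configurable). A feature
is hyper/hypo iff |Δβ| ≥ 0.2 (inclusive) and p < 0.05. The exact site-level
test of the cited array pipeline is not restated in its methods; Welch-on-M
is our documented substitute. Regions (promoters, gene bodies, CpG
islands, 5,000-bp tiles) aggregate member sites by unweighted mean
(no coverage weights exist in a β matrix); intervals are 0-based
half-open.

## Integration

Promoter windows are −1,500/+500 bp around the TSS in transcription
orientation: plus strand [t−1500, t+500), minus strand [t−499, t+1501) —
always width 2,000 unclipped. Significant CpGs (p < 0.05) inside a
promoter are assigned to that promoter's gene; a CpG overlapping two
promoters is assigned to both (no information loss; the source does not
resolve overlaps). The per-gene methylation effect is the mean of member
CpGs' mean.quot.log2 ("most significant CpG" is available via
`aggregate = "top"`). Quadrants (hyper-up, hyper-down, hypo-up, hypo-down,
low-effect) use |RNA log2FC| ≥ 1 and |methylation log2FC| ≥ 0.1. The
inverse-correlation screen computes Pearson r between promoter β and log2
TMM expression across the three exposed normal samples; genes are retained
iff r ≤ −0.6 (boundary passes) and p < 0.1 (boundary fails), restricted to
the DMG ∩ DEG intersection; retained hyper-down genes are "repressed",
hypo-up genes "activated". At n = 3 the p < 0.1 condition implies
|r| ≳ 0.987, so effect size dominates — matching the source's stated
emphasis on effect size over FDR at this sample size; BH-adjusted
correlation p-values are still reported. Whether the original correlation
used β or M methylation and log or raw TMM expression is not fully
specified; β vs log2-TMM is our documented default and both inputs are
caller-supplied matrices, so other scales are a one-line change.

## The synthetic world

The generator's defaults are a stated world, fixed once:

* 2 Mb toy genome over two chromosomes (desk-scale; not a real assembly),
  2,000 non-overlapping genes on an even grid (~50% per strand, TSS ≥ 1.5
  kb from chromosome ends), one CpG island per fifth promoter, 5,000-bp
  tiles.
* ~1,000 true somatic SNVs per tumor sample drawn so their trinucleotide
  spectrum matches a fixed planted SBS96 signature (CpG-context C>T
  enriched plus a C>A component over a flat background), with small indel
  (4%) and doublet (2%) fractions; decoy single-caller calls, germline
  sites present in all samples and the known-sites VCF, clustered
  artifacts (4 variants within 10 bp), and cross-sample shared artifacts.
  Every variant occupies its own 10-bp genomic bin, so planted true
  variants can never accidentally trip the shared or clustered filters —
  which is what makes exact consensus recovery a meaningful test.
* Counts are negative-binomial with lognormal baselines (log-mean
  log 200, log-sd 1.2), per-sample library factors in [0.7, 1.3], and
  dispersion 0.02 — the low-dispersion regime of genetically identical
  inbred mice, and the regime in which an unshrunk n = 3 test has power.
  Planted DEGs (5% of genes; |log2FC| ≥ 3) are drawn from genes with
  baseline mean count ≥ 50: planting effects below the detection floor of
  an n = 3 unshrunk design would make recovery metrics measure the
  generator, not the method. The 12 + 8 epigenetically controlled genes
  are subsets of the up/down DEGs.
* β-values are beta-distributed around per-site baselines
  (mean/precision parameterisation, precision 2,000 ≈ site-level sd 0.01,
  realistic for array replicates; support strictly inside (0,1)).
  Promoters of epi genes carry ±0.4 Δβ and contain exactly their six
  coupled CpGs (filler/background sites avoid these windows — at toy gene
  density, neighboring windows would otherwise dilute the promoter mean).
  The methylation–expression coupling is applied on the M-value scale
  (0.45 M-units per expression z-score unit), z-scored within each
  treatment group, and wired to the *realized* TMM log-expression of the
  gene — the same quantity the screen later correlates — so the planted
  anti-correlation is limited only by β noise, as the r ≤ −0.6 & p < 0.1
  bar at n = 3 demands. Coupling on the M scale keeps the
  coupling-induced variance uniform on the scale the Welch test uses;
  z-scoring within groups leaves the planted group Δβ intact.

What a green test establishes: filter/classifier correctness against
enumeration oracles, calibration of the test statistics under the model's
own null, and that the pipeline recovers a planted signal of the stated
size at the study's n. What it does not establish: behavior under real
biological confounding (batch effects, cell-type composition, coverage
heterogeneity, array probe artifacts), or the original study's specific
gene lists and counts, which depend on the deposited data.

## Known limitations

* The DE stage is intentionally simpler than the cited tool (no dispersion
  shrinkage or outlier handling); at the boundary of detectability its
  calibration is slightly conservative.
* The NES permutation scheme is gene-label permutation only; sample
  permutation is out of scope at n = 3.
* The clustered-filter exhaustive proof covers multisets of ≤ 6 positions;
  beyond that the two-pointer argument is relied upon.
* The run configuration's on-disk form is JSON (no YAML parser in the
  supported dependency set).
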