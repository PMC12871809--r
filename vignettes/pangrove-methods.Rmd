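---
title: "Methods: organism-centric pangenome metatranscriptomics and 16S community analysis"
author: "pangrove"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organism-centric pangenome metatranscriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific setting

Gut microbial communities degrade dietary fiber cooperatively: primary
degraders cleave polysaccharide backbones (for xylan, endo-xylanases and
side-chain hydrolases), while secondary fermenters live off the released
oligo- and monosaccharides (xylosidases, xylose isomerase, xylulokinase).
`pangrove` implements the computational side of an experiment that probes
this division of labor by feeding a model omnivore chemically defined diets
whose only carbohydrate is xylan, microcrystalline cellulose (MCC), or a
w:w mixture of the two, and then profiling the hindgut community with 16S
rRNA amplicons and metatranscriptomics.

The central modelling idea is *organism-centric pangenome mapping*:
instead of mapping transcripts to individual (often incomplete) genomes,
translated reads are aligned against protein databases and the hits are
matched to gene clusters of genus-level pangenomes built from reference
and single-cell genomes. Each pangenome's cluster-level count table is a
per-organism "transcriptome" that can be interrogated for CAZyme and
pathway expression along the diet gradient.

## Weighted top-hit resolution

Translated reads are aligned against two databases (a large reference
protein database and a custom gut-derived single-cell-genome database) and
the two runs are combined per read, keeping every hit whose bitscore
equals the maximum across both runs (`combine_runs()`). Ties are common
and are treated as genuine ambiguity rather than broken arbitrarily:

* **Taxonomic counting** (`weighted_taxon_counts()`): for each read, the
  set $T$ of *distinct* taxa among its tied top hits each receive $1/|T|$.
  Distinctness matters — several accessions of the same organism do not
  dilute that organism's weight. Column sums therefore equal the number of
  reads with hits, a conservation law asserted throughout the tests.
* **Cluster assignment** (`assign_reads()`): identically, over distinct
  (pangenome, gene cluster) targets. A read whose tie set spans catalogs
  splits across pangenomes; this mirrors the taxon rule, which we chose
  for internal consistency since either convention is defensible.
* **Tie definition**: exact bitscore equality after parsing, no epsilon.
  Bitscores are already coarse-grained; any epsilon would be arbitrary.

Weighted (fractional) counts have no direct urn model, so rarefaction of
weighted tables (`rarefy_weighted()`) subsamples *reads* without
replacement and rebuilds the weights, rather than resampling fractional
counts. This is the faithful generative interpretation; it can differ
numerically from rarefying the fractional table directly.

## Functional rollups

* **CAZymes** (`aggregate_cazyme()`): a family's count is the summed
  weight of clusters carrying it. A cluster annotated with two families is
  deliberately *overcounted* — full weight to each family — so family
  totals can exceed the CAZyme-annotated cluster total (never undercount a
  documented activity). Class tallies sum families by prefix (GH, GT, PL,
  CE, AA, CBM, SLH).
* **Fiber panel** (`fiber_panel()`): diet-level shares of
  cellulose/xylan-active GH families. The default pools counts across a
  diet's samples before normalising by the diet's total transcripts; a
  per-sample-mean variant is available (`per_sample_mean = TRUE`) because
  either reading of "share within the diet" is plausible. Pooling is the
  default because it is invariant to splitting a sample into half-weight
  replicates.
* **Pathways** (`aggregate_pathways()`): gene clusters roll up to KEGG
  level-3 pathways through their KOs; a KO in $k$ pathways contributes to
  all $k$ (multi-membership is intentional). Two normalisations are kept:
  share of the whole sample's transcripts and share of the pangenome's
  transcripts.
* **Enzymatic steps** (`step_contributions()`): curated KO lists for the
  steps of xylan and cellulose degradation and pentose entry into central
  carbon metabolism. Per-diet step abundance averages per-sample shares
  (a per-sample quantity), while the phylum pie fractions pool weights
  across the diet's samples (a pooled quantity) — two deliberately
  different conventions matching the two quantities' meanings. The shipped
  step spec (`default_step_spec()`, `inst/extdata/step_spec.tsv`) is
  provisional and editable: the full curated KO membership of each step is
  an input, not something this package can derive.

## 16S community workflow

From an ASV count table onward: contaminant filtering (case-insensitive
substring blocklist over the full lineage — chloroplast, mitochondria,
endosymbiont), hypergeometric rarefaction, Shannon diversity (natural
log), richness, Pielou's evenness $J = H/\ln S$ (undefined at $S \le 1$),
Bray-Curtis and Sørensen dissimilarity (Sørensen computed as binary
Bray-Curtis), NMDS, PERMANOVA, vector fitting of a gradient variable onto
ordination scores, Kruskal-Wallis and pairwise Wilcoxon tests (Holm
adjustment by default; the adjustment is configurable because published
analyses often leave it unstated), and taxonomic rollups.

Standard steps delegate to the field's standard implementations (vegan's
`vegdist`, `metaMDS`, `rrarefy`, `diversity`; base R's rank tests).
PERMANOVA and the envfit-style vector fit are implemented directly from
their definitions — the squared-dissimilarity partition with a seeded
label-permutation pseudo-F, and the $r=\sqrt{R^2}$ of regressing the
centred variable on the scores — because the tests require full control of
the permutation set (including exhaustive enumeration at small $n$);
vegan's `adonis2` and `envfit` serve as independent cross-checks in the
test suite. All permutation p-values use the add-one estimator
$p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})$, which never returns zero.

NMDS defaults: $k = 2$, 20 random restarts, 200 iterations; scores are
reported from the best restart without Procrustes alignment.

## Differential abundance

`nb_wald_test()` is a transparent approximation of the standard
negative-binomial differential-abundance workflow, not a port of any
implementation: median-of-ratios size factors; per-feature
method-of-moments dispersion estimated *within* groups (so real group
differences do not inflate it), floored at $10^{-8}$; an NB log-link GLM
with size-factor offsets fitted by IRLS; a Wald test on the group
coefficient; Benjamini-Hochberg adjustment. There is no empirical-Bayes
dispersion shrinkage, no fold-change shrinkage and no independent
filtering. One consequence of estimating the dispersion from the same few
samples is that the usual normal reference for the Wald statistic is
anticonservative at $n = 6$ per group (measured type-I error ~0.08-0.10
at nominal 0.05); the test therefore uses a $t$ reference with residual
degrees of freedom, the standard small-sample correction, which restores
the nominal level (~0.05-0.06) without touching power (power ~1 for
4-fold changes at mean 200, dispersion 0.1, $n = 6/6$).

Enrichment designation follows the study's rule: a feature is enriched in
diet D if some pairwise contrast involving D has adjusted $p < 0.05$,
baseMean $> 100$, and a fold change favoring D; features enriched in any
ratio (mixed-fiber) diet are designated mixed-fiber, giving the
xylan/cellulose/mixed partition. "Enriched by D" is interpreted as *any*
pairwise contrast favoring D (all pairwise tables are computed); an
alternative reading — only the contrast against the opposite pure fiber —
can be obtained by passing a subset of tables.

The variance-stabilising transform is the log surrogate
$\log_2(\text{count}/s_j + 1)$. The exact dispersion-trend-based
transform requires a fitted mean-dispersion relationship that is not part
of this package's scope; the surrogate is monotone, maps zeros to zero,
and removes library-size differences to within ~0.1 log2 units for counts
above ~50, which is what the downstream ordinations need.

## Constrained ordination

`rda_counts()` regresses the centred sample × feature matrix on the
centred model matrix; the constrained fraction is
$\|\hat Y\|_F^2 / \|Y\|_F^2$, axes are the PCA of $\hat Y$, and model
significance is a permutation pseudo-F (rows of the model matrix
permuted). `rda_diet_models()` runs the four diet models — Diet (factor),
percent xylan (numeric), contains-xylan, contains-cellulose — plus the
unconstrained PC1. Because percent xylan is constant within a diet, its
column lies in the Diet factor's span, so the Diet fraction is always at
least the percent-xylan fraction; this nesting inequality is asserted on
every dataset in the tests. Reported fractions are raw (unadjusted)
constrained fractions.

`kendall_grouping()` clusters genera by Kendall $\tau_b$ over samples
(single linkage, joined at $\tau \ge 0.5$ by default, after a >1% mean
relative-abundance filter). Threshold and filter are configurable because
the original grouping rule for co-occurring genera is typically
reported only qualitatively.

## The synthetic-data generator

Raw sequencing data is neither required nor emulated at the sequence
level: `simulate_*()` generates the *statistical* structure the analysis
consumes, plus ground truth for recovery tests.

* **Designs**: 16S — 6 diets × 10 insects, xylan percentages
  {0, 14, 25, 75, 86, 100}; metatranscriptome — 5 diets × 6 insects,
  {0, 14, 50, 86, 100} (the ratio-diet percentages of a 6:1 / 3:1 / 1:1
  mixing design).
* **Taxa**: the 17 shipped pangenome taxa with their phylum groupings.
  Log abundance of taxon $t$ in sample $s$ is
  $b_t + \beta_t f_t(x_s) + \mathcal N(0, 0.3)$, softmax-normalised;
  $x_s$ is the xylan fraction. $f$ is linear for most phyla and
  saturating ($1 - e^{-x/0.2}$, normalised) for Bacillota, whose response
  to xylan is present already at the lowest inclusion level. Baseline
  abundances and slopes are fixed at values that reproduce the qualitative
  activity ranking (Bacteroides dominant; Fibrobacterota rare and
  cellulose-responsive).
* **Expression**: each catalog cluster has a functional role
  (endo-xylanase, xylosidase, cellulase, side-chain removal, xylose
  utilisation, glycosyl modification, housekeeping, unannotated) with a
  log-normal base rate and a role slope on the xylan fraction
  (endo +1.5, side-chain +1.2, xylose utilisation +1.5, cellulase −2.0).
  Fiber-responsive rates use a 70% linear + 30% saturating gradient: on a
  diet design symmetric in xylan percent, a purely linear response would
  make the contains-xylan and contains-cellulose splits statistically
  exchangeable, contradicting the asymmetry the generator must emulate.
* **Cross-feeding** is rate coupling, not a mechanistic metabolite pool:
  the xylosidase rate of Bacillota clusters is multiplied by the realised
  endo-xylanase output of the source organism (Bacteroides), normalised
  to mean one across samples. This is sufficient to test the detection
  logic (secondary xylosidase output tracking primary endo output along
  the gradient) without claiming kinetic realism.
* **Hits**: each read draws a (taxon, cluster) source proportional to
  abundance × rate, or an off-catalog origin at rate 0.2 (placing the
  assigned fraction inside the empirically plausible 66-95% band); it
  emits a top hit to a random accession of its cluster, a tied-bitscore
  second hit with probability 0.3, and with probability 0.3 its best hit
  sits in the custom database at a strictly higher bitscore than its
  primary-database decoy. Read depths are log-normal (16S: meanlog
  log(40000), sdlog 0.5, mean ≈ 45k; metatranscriptome desk scale:
  meanlog log(20000), sdlog 0.4).
* **Contaminants**: 12 ASVs from chloroplast/mitochondria/endosymbiont
  lineages at an expected 5% read share, for filter testing.

What the generator does *not* emulate: sequence-level error, rRNA
carry-over, compositional coupling beyond the softmax, genuinely shared
accessions between catalogs, and the full annotation sparsity of real
pangenomes. Passing recovery tests therefore demonstrate that the
pipeline's logic is correct under its own assumptions, not that the
original study's numbers are reproduced.

## Numerical choices and problem sizes

Ties in bitscores are exact equalities; weighted counts stay fractional
(no rounding before statistics); all simulation and permutation code takes
explicit integer seeds and is deterministic given them; degenerate inputs
(all-zero samples, empty pangenomes, constant envfit variables, groups of
size one) return flagged missing values or warnings rather than errors
where the quantity is merely undefined.

The test suite exercises the pipeline at two scales: small configurations
(3-4 replicates, ~1,500 reads/sample, 12-cluster catalogs) for unit and
oracle tests, and one study-shaped run (5 diets × 6 samples, 17 catalogs
of 40 clusters, ~20,000 reads/sample) for structure recovery — sizes
chosen so the full suite and the acceptance script each complete in a few
minutes on a single CPU while keeping every conservation and recovery
property measurable.

## Known limitations

* The NB test approximates but does not numerically match
  shrinkage-based differential-abundance tools; its acceptance surface is
  calibration and recovery on synthetic data.
* The VST surrogate diverges from dispersion-trend transforms for
  low-count features.
* The shipped KO→pathway map and step spec are curated subsets meant to
  be replaced by full tables where available.
* Per-read tie structure must be retained to rarefy weighted counts; the
  weighted table alone is not sufficient.
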