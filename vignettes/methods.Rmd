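---
title: "Differential TF activity from ATAC-seq: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential TF activity from ATAC-seq: models, simulation design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfatac)
```

## Scope

`tfatac` infers which transcription-factor motifs change in chromatin
accessibility between two groups of bulk ATAC-seq samples, and provides a
semi-simulation engine plus fully synthetic fixtures to measure how well
such inferences work under controlled perturbations and technical biases.
This vignette is the package's account of the underlying models, the
parameters that matter, and the choices made where the design was open.

## Coordinates and fragment handling

All user-facing intervals are BED-style: 0-based, half-open. A fragment
`[start, end)` represents two Tn5 transposition events; the insertion
points are `start` and `end - 1`. Fragment files are assumed pre-shifted
(10x convention). For unshifted input, `tn5_insertions()` accepts explicit
`shift_plus`/`shift_minus` offsets (the +4/−5 convention); the default is
no shift, because whether a given fragment file was shifted upstream is
generally not recorded in the file itself.

Fragment length classes use fixed cutpoints — nucleosome-free (NF)
≤ 120 bp, mono-nucleosome (120, 300], di-nucleosome (300, 500],
multi-nucleosome > 500 bp — and the NF filter keeps fragments of
30–120 bp. Consensus peaks are built by union-merging peak calls and
resizing each merged interval to a fixed width (default 300 bp) about its
midpoint; resized peaks that newly overlap are deliberately not re-merged,
and clipping happens only at contig boundaries. A fragment overlapping
*k* peaks counts once in each, keeping counts integral.

## Motif deviation z-scores

For motif $m$ and sample $j$, let $Y_{mj} = \sum_{i \in m} X_{ij}$ be the
fragment counts summed over matched peaks and
$E_{ij} = \frac{(\sum_j X_{ij})(\sum_i X_{ij})}{\sum_{ij} X_{ij}}$ the
library-size expectation. The raw deviation $(Y - E)/E$ confounds motif
signal with covariate-linked technical signal (GC content,
accessibility), so it is compared to the same quantity computed on random
background peak sets: each matched peak is replaced by a draw from its
pool of nearest neighbors in standardized (GC, $\log1p$ mean count)
space. Subtracting the background mean gives the bias-corrected
deviation; dividing by the background SD gives the z-score.

Two tunables matter:

* **`niter`** (background iterations, default 2000): the background mean
  and SD are Monte-Carlo estimates, so differential results are only
  reproducible across seeds when `niter` is large. The package's tests
  verify that the across-seed variance of the true motif's z-score
  decreases over `niter` ∈ {50, 250, 1000}; simulations in the test suite
  use 250–500 as a compromise between this reproducibility and runtime,
  and 2000 remains the recommended analysis default.
* **`k_neighbors`** (pool size, default 25): the pool must be wide enough
  that background sets differ across iterations but tight enough that the
  sampled background truly matches the foreground covariates. We chose 25
  after observing that wider pools (50) let a sample-wise GC bias leak
  into a handful of significant motifs in the strength-0 robustness
  suite, while 25 removed those false positives without affecting null
  calibration (z-score SD stays within [0.7, 1.3]) or recovery of planted
  perturbations. Much tighter pools (10) further increase robustness but
  shrink background diversity; 25 is the default, and both knobs are
  exposed.

Per-sample z-score distributions can shift or stretch for technical
reasons; `normalize_activity()` therefore offers median-centering,
MAD-scaling and full quantile normalization across samples (robust
statistics, because the distributions are heavy-tailed in practice).
Quantile normalization is the default and the recommended preprocessing
before the moderated test. Degenerate cases are explicit: a motif with no
matched peaks gets `NaN` scores and a flag; a zero background SD yields
z = 0 with a flag rather than NaN propagation.

The library-size expectation is the only size-factor model implemented:
trimmed-mean (TMM-style) factors are a natural alternative but did not
change distributional artifacts in our experience, and the downstream
normalization addresses them more directly.

## GC smooth quantile normalization and the multivariate model

Sample-specific GC bias is a dominant technical axis in ATAC-seq. Before
computing per-peak log fold-changes or per-sample regressions, counts are
log-CPM transformed (`log2(count/colsum * 1e6 + 0.5)`) and normalized by
smooth quantile normalization within equal-occupancy GC bins: at each
quantile rank $k$ inside a bin, the normalized value is
$w_k q_k + (1 - w_k) q_{gk}$, where $q_k$ is the overall mean order
statistic, $q_{gk}$ the group-specific one, and
$w_k = 1 - \mathrm{SSB}_k/\mathrm{SST}_k$ is clipped to $[0, 1]$ and
smoothed by a running median (window = max(3, 5% of ranks), forced odd).
With one group (or exchangeable groups) $w \to 1$ and the procedure is
exact within-bin quantile normalization; where the groups differ globally
at a quantile, $w \to 0$ and the group difference is preserved rather
than normalized away. Ties map to the average of the implicated reference
values. Bins with fewer than two peaks are merged into a neighbor. The
default of 10 GC bins balances bin occupancy against resolution of the
GC–count relationship at the fixture scale (a few hundred peaks per bin).

The multivariate model then regresses each sample's normalized
accessibility on *all* motif indicator columns at once (column-centered
response, column-standardized predictors, intercept included), so similar
motifs compete for credit. Activity scores are the per-motif t-values
(coefficient over standard error), which are comparable across samples
and feed the moderated test. All-zero, duplicated, and rank-deficient
columns are dropped with a message — with highly redundant motif
collections, this multivariate route is exactly where motif archetypes
(below) become useful.

## Binned enrichment and p-value aggregation

Peaks are sorted by log fold-change into an odd number of equal-count
bins (default 9); the bin whose range covers zero is the reference.
Motif over-representation in each non-zero bin is tested with a one-sided
Fisher exact test (hypergeometric upper tail) against either the zero bin
or all other bins, with log2 enrichments computed on rates with +0.5
pseudocounts. Because fold-changes are estimated, exact ties can break
equal-count binning; `peak_logfc()` optionally jitters the vector with
amplitude 0.001 × max|logFC| under a fixed seed. Bin-level p-values for
one motif are dependent, so they are aggregated with Simes' method
(`min_i n p_(i)/i`), which stays valid under positive dependence; the
aggregated p-value is what enters ranking. Changing the bin count mostly
trades resolution against per-bin power and is exposed as a parameter.

## Footprint scores

`motif_insertion_profiles()` accumulates insertion events in ±200 bp
windows around motif matches (strand-flipped for minus-strand sites).
Two scores are derived:

* the **insertion model** weights each position by the motif's global
  (across-sample) profile — smoothed by an 11-bp running mean, mirrored
  about the center, normalized to sum one — and sums weighted insertions
  per sample. Weighting by the global profile means each sample is scored
  on where *this motif's* insertions concentrate, not on a fixed shape.
* the **two-part footprint test** summarizes each motif/sample as
  footprint depth `log2((F20/40 + c)/(M/L + c))` (near-flank rate over
  in-motif rate, pseudocount c = 0.5 per bp) and flanking accessibility
  `log2(F200/400 + c)`, tests both matrices with the moderated test and
  combines the two p-values by Fisher's method (chi-square, 4 df). The
  ratio-of-rates definition makes depth scale-invariant (uniform
  insertion gives exactly 0) and the pseudocount keeps it finite at empty
  windows. No sequence-bias correction is applied: the Tn5 preference is
  shared across samples and cancels in group comparisons.

## Moderated group comparison

All activity matrices go through the same inferential machinery: a
per-motif two-group pooled-variance model, with residual variances shrunk
toward a prior fitted to all motifs by the moment method on log variances
(scaled-F model). The moderated t has $d_0 + d_g$ degrees of freedom. The
implementation keeps the shrinkage arithmetic explicit so that the prior
df can be forced to 0 (ordinary t, used as an internal consistency check)
or ∞ (fully pooled variance). Only the two-group design is implemented —
the benchmark setting — and BH is the multiplicity adjustment throughout.
Results are ranked by p-value, then |effect| (important for methods that
produce tied p-values), then motif id, with NA p-values last.

## The semi-simulation

The engine plants a perturbation of a single TF into baseline fragment
data in three steps:

1. **Fold-change assignment.** The enrichment scores of the TF's ChIP
   peaks are quantile-mapped (type-7 interpolation between order
   statistics) onto the enrichment distribution of a reference scenario,
   and each peak inherits the log2 fold-change of the nearest reference
   peak (ties to the lower index). Two synthetic scenario tables ship
   with the package: an *activation* shape (high-occupancy peaks most
   affected, magnitudes up to ~3 log2 units) and a *haploinsufficiency*
   shape (low-occupancy peaks most affected, magnitudes capped near 1, as
   halving the TF dosage implies). They are labelled synthetic in their
   filenames; real reference ChIP tables can be supplied as TSVs.
2. **Downsampling.** At strength $p$, the downsampled group retains each
   peak's overlapping fragments at rate $2^{-p |log2FC_i|}$, i.e.
   $n_s = \min\{\lceil n_0 2^{-p|log2FC_i|}\rceil, n_0\}$, sampled
   uniformly without replacement. This is the log-scale reading of
   "fold-changes multiplied by a factor p": it is the only reading under
   which $p = 0$ reproduces the original dataset exactly, which is the
   stated boundary behavior. Negative fold-changes downsample group B,
   positive group A, so the realized B-vs-A sign matches the planted
   sign. A fragment overlapping two perturbed peaks is assigned to the
   peak with the larger overlap (ties to the lower index) so it is
   downsampled at most once. Downsampling is independent per peak and
   sample, as the formula's indices suggest.
3. **Technical biases.** Optionally, each sample's fragments are
   resampled toward a target GC density (binned over [0, 1]) or a target
   fragment-length class mixture, with acceptance probability
   proportional to target/empirical density, normalized so the maximum
   acceptance is 1. Target mass on empirically empty bins is unreachable
   and triggers a warning rather than an error.

All stochastic steps require an explicit seed and are reproducible; seeds
are consumed through a scoped RNG so library calls never disturb the
caller's random state.

## The synthetic fixture generator

`generate_fixture()` builds a complete dataset with the structure the
methods assume. Defaults define the study conditions used by the test
suite and were chosen once, as plausible for bulk ATAC-seq at desk scale:

* 2000 peaks of 300 bp on one contig with 600 bp gaps; 100 motifs; two
  groups of 3 samples (the common minimal replicated design).
* Per-peak GC ~ Beta(9, 11) (mean 0.45, typical for peak sets); motif
  matches ~ Bernoulli with a logit linear in standardized GC (per-motif
  slopes ~ N(0, 1), so some motifs are GC-entangled and exercise the
  background correction) plus sparse pairwise co-occurrence boosts
  (~n/10 motif pairs, +1.5 logits).
* Counts ~ NB with peak-specific log-normal means (median 20 fragments
  per peak per sample, sdlog 0.6) and size 5 — overdispersion in the
  range seen in replicated bulk ATAC — times log-normal library factors
  (sdlog 0.15).
* Each counted fragment is realized with a length from the four-class
  mixture (weights 0.55/0.30/0.10/0.05; multi-nucleosome lengths capped
  at 800 bp) and a midpoint uniform in the peak, plus a per-fragment GC
  annotation (peak GC + N(0, 0.04)); GC is an annotation, not derived
  from sequence, because no in-scope method consumes sequence beyond GC
  and matches.
* The ChIP set of the perturbed motif covers 70% of its matched peaks
  plus 10% off-motif peaks, reproducing the imperfect motif–binding
  overlap that makes real TFs differ in difficulty; enrichment scores are
  log-normal.

What the generator does *not* emulate — peak-calling artifacts, sequence
content, mappability, chromatin domains, correlated biological
variability between peaks of a pathway — bounds what passing tests mean:
they demonstrate correctness and calibration of the algorithms under the
stated statistical model, not performance on any particular real dataset.

## Benchmark metrics

The rank of the true motif is the best rank of any motif in the truth
set. The network/archetype score is the mean over k = 1..100 of the
proportion of top-k motifs in a member set, divided by its maximum
attainable value (rectangle-rule AUC; the quadrature is a choice, made
here for its simplicity and exact brute-force checkability). Precision
counts motifs clustering with network members as positives (cluster
expansion is the default; a raw-members-only flag exists), recall counts
only true motifs. Motif similarity is the IC-weighted Pearson correlation
over all ungapped offsets (overlap ≥ 5) and both orientations, with the
weight of an aligned column pair the mean of the two columns' information
content; complete-linkage clustering of 1 − similarity cut at 0.45
(human) / 0.35 (mouse) defines archetypes. For ranking methods across
datasets, true-motif ranks are mapped through $2/(e^{\sqrt{r}} + 1)$ — a
bounded, strictly decreasing benefit score that stops discriminating
among very poor ranks — and missing cells are imputed per dataset with
the worse of the column median and mean, so absence is never rewarded;
since all metrics are benefit scores after the transform, "worse" is
always the smaller of the two. Rank-sum aggregation across methods uses
the exact convolution of discrete uniform ranks when the state space is
small (n·methods ≤ 1e4) and seeded Monte-Carlo otherwise.

## Numerical and degenerate-input policy

Explicit behavior, rather than NaN propagation, everywhere a contract
exists: empty fragment files parse to empty sets; records with
start ≥ end are rejected and counted; zero-count PPM columns become
uniform with a warning; constant predictors yield flagged NA results;
a single motif falls back to the ordinary t-test with a warning; Simes
drops NA inputs with a warning; Fisher's method clamps zero p-values to
the smallest positive double. Problem sizes in the test suite (2000
simulated null motif-sets, 20 seeds × 5 strengths for recovery, 1e4
draws for super-uniformity) were chosen to give the property tests
meaningful power at desk scale; the acceptance script records the n
behind every number it reports.

## Known limitations

* Only two-group designs; no covariates or contrast matrices.
* The GC bias model treats GC as an annotation; sequence-level
  corrections (and sequence-composition-matched enrichment backgrounds)
  are out of scope, though a GC-stratified comparison is available for
  the binned enrichment.
* Motif archetype construction clusters motifs but does not merge PPMs
  into consensus models.
* The semi-simulation assumes binding changes translate into
  accessibility changes at ChIP peaks; factors for which this fails are
  invisible to it by construction.
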