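---
title: "Methods: copy-number calling and subtype classification for two-color aCGH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number calling and subtype classification for two-color aCGH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oacgh)
```

## The problem

Oligonucleotide array CGH (oaCGH) measures DNA copy number as the ratio of
two fluorescent signals per probe: a test sample (e.g. a canine
leukemia/lymphoma cell line) in one channel and a pooled normal reference
in the other, on arrays of ~180,000 probes spaced ~13 kb across the
genome. `oacgh` turns the raw per-probe signal pairs into: a normalized
log2-ratio profile; constant-mean segments; gain/loss calls under two
complementary rules; genome-imbalance summaries; a subtype assignment by
co-clustering against labeled reference tumor cohorts; and concordance
scores against locus-level FISH enumeration. A companion module covers the
expression-side computations (variance filtering, baseline fold changes,
comparative-Ct qPCR quantification) used to corroborate copy-number
findings.

Because no public signal-level dataset accompanies this design, every
input has a synthetic generator with planted, machine-readable truth
(`sim_*()` functions); the test suite and the acceptance script score the
pipeline exclusively against that planted truth.

## Normalization model

For probe $p$ with red (test) and green (reference) processed signals,

$$a_p = \log_2\!\left(\frac{r_p}{g_p}\right), \qquad
z_p = \frac{a_p - \operatorname{mode}(a)}{\operatorname{MAD}(a)}.$$

Mode-centering anchors the copy-neutral state at 0 even in aneuploid
genomes, where the *median* can sit inside an aberration but the dominant
density mode is still the neutral mass. Two conventions deserve emphasis:

* **MAD is the mean absolute deviation about the median**, not the
  conventional median absolute deviation. This matches the
  median-anchored dichotomization rule below; the conventional statistic
  is available everywhere via `scale_stat = "median_abs"` for
  sensitivity checks.
* **The mode of a continuous sample is estimated by Gaussian KDE** with
  Silverman's rule-of-thumb bandwidth on a 512-point grid
  (`stats::density`), taking the first (smallest) grid argmax on ties.
  The estimate is therefore only grid/bandwidth-accurate; tests assert
  the re-estimated mode of the normalized output lies within half a
  bandwidth of 0, not exactly at 0.

By construction the normalized output has mean absolute deviation about
its median exactly 1 (an affine identity, asserted to 1e-9 in the tests).

Quality control (`qc_filter()`) excludes probes with either channel at or
above the saturation cap (default $2^{16}-1$, the 16-bit scanner ceiling)
or at or below `min_signal` (default 0, which also removes signals for
which the log ratio is undefined). Excluded probes take no part in any
downstream statistic.

## Segmentation

`segment_cbs()` implements circular binary segmentation: per chromosome,
the maximal two-sample statistic over all circular arcs

$$T(i,j) = \frac{|\bar{x}_{\text{arc}} - \bar{x}_{\text{compl}}|}
{\sqrt{1/\ell + 1/(n-\ell)}}$$

is referred to a permutation null (`n_perm = 1000` permutations at
`alpha = 0.01` by default), splitting recursively until no significant
arc remains. Numerical choices:

* The constant overall-variance factor is dropped from $T$: permutations
  preserve the value multiset, so it cannot change either the argmax or
  the permutation decision.
* Arc lengths are restricted to `[min_width, n - min_width]`
  (`min_width = 3`, echoing the three-consecutive-probe calling
  convention); chromosomes with fewer than `2 * min_width` retained
  probes remain single segments.
* The permutation loop stops early once the exceedance count proves
  $p > \alpha$, and the arc scan inside permutations stops at the first
  statistic reaching the observed one — both pure speedups with no effect
  on the accept/reject decision.
* The permutation stream is seeded (`seed` argument, fanned out from the
  pipeline's global seed), so segmentation is bit-reproducible.
* Adjacent segments whose means agree within `merge_tol = 1e-10` are
  merged.
* An arc and its complement induce the same split of the circle; the
  engine reports whichever representation attains the floating-point
  maximum first, and correctness tests compare induced breakpoint sets.

The scan is $O(n^2)$ per tested split and is written in C++ (Rcpp), the
usual practice for segmentation kernels. Defaults are tuned for
chromosome-scale series of up to a few thousand probes; for full
180k-probe arrays, lower `n_perm` (the decision needs only
`alpha * n_perm` exceedances) or segment per chromosome in parallel.

## Calling rules

Two independent reductions of segments to states in $\{-1, 0, +1\}$:

* `call_threshold()`: gain if the segment mean is $\geq$ `gain_thr`
  (default +0.2) over at least `min_probes` (default 3) probes; loss
  symmetrically at `loss_thr` (default −0.2). The thresholds are applied
  to the *normalized* ratio — whether the original convention applied
  them to raw or recentred log2 ratios is not recoverable from the
  method's description, and this package documents its choice rather
  than asserting it. The rule is applied to the same CBS segments as the
  robust rule below, one segmentation backing both.
* `call_mad()`: gain/loss where the segment mean lies more than `k = 3`
  mean absolute deviations from the median of the sample's response
  across all chromosomes. The statistic is computed on probe-level
  normalized ratios (`basis = "probe"`), since the rule references the
  sample's genome-wide response; a segment-mean basis is available.

Both rules are antisymmetric (negating the profile swaps gains and
losses), property-tested over random segment tables.

## Imbalance metrics

An *aberration* is a maximal run of adjacent same-state non-neutral
segments. Its extent is the union of the probe tiles it covers (first
probe start to last probe end, with probes modelled as half-open tiles of
width = spacing); numerically identical to extending the first-to-last
probe midpoints by half a spacing on each side, and accurate to within
one spacing per aberration against planted truth. Percent genome
gained/lost/changed uses the total length of non-excluded chromosomes as
denominator. The X chromosome is excluded by default: with a pooled
female reference, male test samples carry a constitutive X imbalance that
is not somatic.

## Subtype classification by co-clustering

Queries are placed on a fixed 1 Mb marker grid (`make_marker_grid()`,
length-weighted projection of segment means per bin, empty bins set to
copy-neutral 0 — how independently segmented samples were originally
placed on common markers is unstated, so the binning is this package's
decision). Cohort and queries are stacked, scaled per sample
(median/mean-absolute-deviation, consistent with the probe
normalization; per-marker z-scoring is the alternative), and clustered
with Ward's method on Euclidean distances. "Ward" here is the
minimum-variance criterion on squared Euclidean distances with
`hclust`-style square-rooted heights (`ward.D2`); the test suite verifies
it against a brute-force Lance–Williams agglomeration oracle on all
matrices up to 12 rows. The tree is cut into `k` flat clusters (default:
the number of distinct cohort subtypes — the original analysis reads
clusters visually, so `k` is exposed); each query takes the majority
subtype among labeled members of its cluster, falling back to the
nearest labeled neighbour (flagged) on empty or tied votes.

`cluster_cell_lines()` covers the sample-only dendrogram on dichotomized
tracks: states projected to the grid (state at bin midpoint), Ward over
the resulting $\{-1,0,1\}$ vectors.

## FISH concordance

Per-locus cell counts over copy categories $\{0,1,2,3,4,>4\}$ reduce to
the modal category (ties toward the category nearest 2, then lower — a
single-state convention this package defines, since heterogeneous
multi-modal distributions have no canonical reduction), rejected below 50
scored cells. The modal copy maps to a state against a baseline ploidy of
2 (configurable, because hypodiploid lines shift the natural reference),
with ">4" compared as 5, and is matched to the state of the array segment
containing the locus midpoint. The packaged `fish_loci()` table carries
the CanFam2 intervals of the 20 cancer-gene BAC probes.

## Expression companion

`median_center()` (per-array median 0), `sd_filter()` (drop rows with SD
< threshold, default 2, n−1 denominator, boundary retained — the filter
removes strictly "< 2"), `fold_change()` (log2 difference to the mean
baseline, reported as signed folds: $2^d$ up, $-2^{-d}$ down, matching
"downregulated k-fold" phrasing; the >5-fold gene lists use
|signed fold| > 5, a reading this package adopts and flags), and
`ddct()` (replicates averaged per sample and gene first, then
$\Delta Ct = Ct_{target} - Ct_{ref}$,
$\Delta\Delta Ct = \Delta Ct_{case} - \overline{\Delta Ct}_{baseline}$,
fold $= 2^{-\Delta\Delta Ct}$; invariant to per-sample plate shifts).
Expression input is an already-normalized log2 matrix — array
preprocessing (GC-RMA and kin) is upstream of this package's contract.

## What the generators emulate — and what they do not

* `sim_genome("canine")`: 38 autosomes with lengths decaying
  geometrically 122→24 Mb plus X, ~2.4 Gb, CanFam2-like scale. The
  `"toy"` preset (3 autosomes + X, ~1000 probes at 13 kb) keeps test and
  example runtimes in seconds; all documented test scales (toy genome,
  20-seed cohorts, 1000 FISH loci, 5000-gene matrices) were chosen as
  the smallest sizes at which the binomial/CLT bounds in the tests are
  meaningful.
* `sim_signal()`: green channel lognormal around `baseline_signal`, red
  = green × $2^{\text{shift} + \varepsilon}$, $\varepsilon \sim N(0,
  \sigma^2)$. This makes the log-ratio construction exactly invertible
  (at $\sigma = 0$ the planted shifts are recovered bit-exactly), which
  is what the round-trip tests need. It does **not** model dye bias,
  spatial artifacts, GC waves, probe-response heterogeneity, or
  saturation tails — so passing tests certify the algorithmic chain, not
  robustness to scanner physics.
* `sim_cohort()`: per-sample Bernoulli carriage of subtype signature
  templates plus marker-level Gaussian noise. Default signatures encode
  the recurrent aberrations reported for canine cohorts at their
  published frequencies (CDKN2A-region loss in >55% of T-cell lymphoma,
  proximal CFA 22 loss in 20%, CFA 29 gain in 40%; CFA 13 gain in 25% of
  B-cell lymphoma; recurrent multi-chromosome losses with CFA 13 gain in
  histiocytic malignancy; CFA 1-distal loss and CFA 12/25 gains in acute
  leukemia). Those scattered marginal rates alone do not define seven
  separable classes — real subtype clusters cohere through many
  co-occurring aberrations that no published table enumerates — so each
  subtype additionally carries two hallmark whole-chromosome templates
  at 0.9 frequency as a stand-in for that aggregate structure, and the
  three subtypes with no published copy-number profile (AML, T-CLL,
  B-CLL) are hallmark-only. The defaults are thus illustrative of
  separable subtype structure, not a canonical disease model; the
  ~94% recovery the acceptance run reports measures the pipeline's
  ability to exploit such structure, not clinical accuracy.
* `sim_fish_counts()`: multinomial per locus — truth category with
  probability `p`, remainder split evenly between the two adjacent
  categories (whole remainder to the single neighbour at the 0 and >4
  ends). No cell-to-cell correlation or sectioning artifacts.
* `sim_expression()`: planted differential block (± `effect_log2` in
  cases, alternating sign) over a near-constant background; with equal
  group sizes a planted row's SD is ≈ |effect|/2, which is what makes
  the SD-filter recovery test exact at the default effect of 5.

One global seed fans out to deterministic per-component substreams
(`substream_seed()`), so any stage can be regenerated independently and
the end-to-end run is byte-reproducible.

## Known limitations

* Single-sample segmentation only; no joint multi-sample segmentation,
  no allele-specific copy number, no LOH.
* The permutation CBS is a surrogate for the proprietary segmentation
  used with commercial scanner software; segment boundaries are not
  expected to replicate any particular vendor's output.
* No recurrence/significance analysis across samples (GISTIC-like), no
  enrichment analysis, no probe-to-gene annotation: those depend on
  external services or databases.
* Whether published megabase totals count probe-grid extent or segment
  boundaries is unstated; this package documents its probe-tile
  convention rather than claiming equivalence.
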