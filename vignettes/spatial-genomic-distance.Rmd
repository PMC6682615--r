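---
title: "Methods: spatial-genomic distance analysis for multiregion biopsies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial-genomic distance analysis for multiregion biopsies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(spatgeno)
```

## The question the package addresses

Diffuse gliomas are spatially heterogeneous: two biopsies from one tumor can
differ in their somatic mutations, copy-number profile and methylation state.
`spatgeno` quantifies how that molecular divergence scales with the physical
separation of stereotactic biopsy sites. For every intra-patient pair of
samples it computes the Euclidean distance between the recorded 3D biopsy
coordinates (mm) and three genomic distances, then summarizes each modality's
spatial-genomic relationship by a pooled Pearson correlation and an ordinary
least-squares line

\[ d_\mathrm{genomic} = a + b \cdot d_\mathrm{euclid}, \]

from which two interpretable constants follow: the expected genomic
divergence added per 10 mm of physical separation (`10 b`) and the physical
separation equivalent to one genomic-distance unit (`1 / b`).

All distances are strictly intra-patient; samples are never compared across
tumors.

## The three genomic distances

**Mutation count distance.** Annotated somatic calls are first filtered by
five retention criteria (exonic location; protein-altering function class,
i.e. frameshift insertion/deletion, nonsynonymous SNV, stopgain, stoploss;
reference reads >= 10; alternate reads >= 8; alternate allele frequency >=
0.1). Per patient, the filtered calls form a mutation-by-sample matrix of
alternate allele frequencies (0 where absent). Two pairwise summaries are
computed:

* the continuous Jaccard (Tanimoto) distance
  \(\sum_i (P_i-Q_i)^2 / (\sum_i P_i^2 + \sum_i Q_i^2 - \sum_i P_i Q_i)\),
  which is 0 for identical profiles and 1 for disjoint mutation sets, and
  reduces to the set Jaccard distance on presence/absence vectors;
* the *mutation count distance*, the number of mutations private to one of
  the two samples (union minus shared).

The association stage uses the count distance by default: it is the measure
on which the per-mm regression constants are expressed (tens of mutations
over a few cm), whereas the Tanimoto distance is bounded in [0, 1] and
saturates. `mutation_measure = "jaccard"` switches the association to the
bounded measure. When both allele frequencies and read counts are supplied
and disagree beyond 1e-6, the supplied frequency wins with a warning.

Mutation burdens far above the expected exome-wide background (about 1
mutation/Mb, i.e. about 30 over a 30 Mb exome) indicate hypermutation.
`flag_hypermutation()` flags samples whose filtered count exceeds
`max(absolute_threshold = 300, fold_threshold = 10 x cohort median)`; the
`max()` form requires a sample to be an outlier both absolutely and
relative to its cohort before it is flagged. Flags are advisory only --
exclusion requires an explicit switch -- because hypermutation is a
biological finding, not an artifact, and its handling is an analyst's call.

**CNV distance.** Per patient, segment boundaries from all samples are
unified: per chromosome, the sorted union of segment start/end positions
defines maximal intervals, and every interval covered by at least one
sample's segmentation becomes an event. Events therefore never straddle an
input breakpoint, and each (event, sample) cell inherits the log2 copy ratio
of its unique covering segment. The pairwise distance is the Canberra form

\[ \sum_i \frac{|P_i - Q_i|}{|P_i| + |Q_i|}, \]

over events present in both samples, with a 0/0 term defined as 0. Note the
magnitude denominators: log2 ratios are signed, and \(P_i + Q_i\) can be zero
or negative for informative events (e.g. a gain in one sample mirrored by a
loss in the other), which would make the naive form undefined or negative.
With magnitudes, every term lies in [0, 1], the total is bounded by the
number of shared events, self-distance is exactly 0, and on non-negative
input the value coincides with the classical Canberra distance. Events
missing from a sample's segmentation are excluded pairwise rather than
imputed (`impute_neutral = TRUE` restores a log2 = 0 imputation for
whole-genome tilings). Coordinates are 0-based half-open. Breakpoint union
is per patient, because distances never cross patients; a cohort-wide union
only inflates every patient's event list with breakpoints irrelevant to it.

**Methylation distance.** Beta values (methylated / total signal, in [0, 1])
are quality-filtered in a fixed order: first samples with more than 10% of
values missing, then probes with more than 3 missing values among the
remaining samples (both strict inequalities; re-running the filter is a
no-op). Cohort-level probe ranking by median absolute deviation
(`select_top_mad_probes()`, unscaled MAD) serves clustering-style outputs;
the pairwise distance itself uses the top 500 probes by *within-patient*
variance (unbiased, n-1 denominator -- with 2-6 samples per patient the
denominator choice is material, and the n-1 form is the default estimator
of the population quantity; `unbiased = FALSE` gives the n denominator).
Probes with any missing value within a patient are ineligible for that
patient's selection, which makes the selection deterministic; ties break
lexicographically by probe id. The distance is the L1 total variation
\(\sum_i |P_i - Q_i|\), bounded by the probe count k. Because probes are
selected per patient, absolute distances are comparable across patients only
through the common k.

## Pairing conventions

Needle cores long enough to split are divided into a shallow and a deep
sub-sample; the two halves are assigned a fixed separation of 5 mm, derived
from the biopsy needle geometry (0.9 mm bore with a 10 mm side port). The
constant is configurable (`shallow_deep_mm`) precisely because it encodes
one instrument's geometry. A shallow/deep pair taken by forceps at a single
spatial location has no principled nonzero separation; it is assigned 0 mm
(`same_site_forceps_mm`, configurable) and can be excluded from association
entirely (`exclude_same_site_forceps = TRUE`), which preserves the
ambiguity rather than guessing. Samples lacking a complete coordinate
triple are flagged and excluded from coordinate-based pairs, never repaired.
Coordinate units are fixed to mm; no unit auto-detection is attempted. The
(<2 mm) localization uncertainty of image-guided coordinates is not modeled
in the distance computation; it informs the synthetic generator's scale
choices only.

## Association

Pairs are pooled across patients per modality; `pearson_correlation()`
reports the product-moment r with the two-sided p from the t transform
\(t = r\sqrt{n-2}/\sqrt{1-r^2}\), and `ols_fit()` the least-squares line.
Pairs sharing a sample within a patient are *not* independent, so the pooled
p-value is anti-conservative; this mirrors the standard pooled analysis in
the field and is documented rather than corrected. As a robustness
extension, `associate(permutation = TRUE)` reports a permutation p-value
obtained by shuffling genomic distances within patients, which respects the
cluster structure. No multiple-testing correction is applied across the
three modalities. Reported equivalence constants are rounded to one decimal
(two where the constant is below one); raw values are always retained in the
machine-readable output.

## The synthetic cohort generator

The study data this design targets are individual-level patient genomics and
are not redistributable, so the package ships a generator whose outputs
exercise every pipeline stage with known ground truth.

Geometry: each patient contributes 2-4 biopsy tracks uniform within a
30 mm-radius sphere; 80% of tracks are needle tracks, half of which split
into shallow/deep sub-samples placed genuinely 5 mm apart along a random
axis (so the assigned convention and the true geometry agree); 10% of
forceps tracks yield a same-location pair. Defaults give roughly 4-5 samples
per patient, and 25 patients, matching the scale of a multiregion biopsy
trial cohort.

Spatial signal enters all three modalities through one mechanism:
**subclonal alterations with planar fronts**. An alteration with unit normal
u and offset t affects exactly the samples on one side of the plane
u.x = t. With u uniform on the sphere and t uniform on [-T, T] (T = tumor
radius + half the split offset, so every site lies inside the slab), the
probability that an alteration separates two sites a distance d apart is
exactly E|u.(a-b)|/(2T) = d/(4T), *linear in d with no small-perturbation
approximation*. Budgeting per-alteration distance weights w so that
\(\sum w = 4\,T\,b\) therefore gives an expected genomic distance of
exactly `b` per mm:

* mutations: `round(4 T b)` subclonal mutations of weight 1 each (default
  b = 1.7/mm), on top of 10 truncal mutations present everywhere; truncal
  allele frequencies are drawn around 0.40, subclonal around 0.20, so shared
  mutations show systematically higher AFs, as branched evolution predicts;
* CNV: segments receive switch magnitudes |delta| ~ U(1.5, 2.5) on top of
  baseline log2 ~ N(0, 0.4); each switched segment's Canberra term weight
  w = |delta|/(|b| + |b+delta|) is known at generation, and fronts are
  assigned greedily until the weight budget 4 T b (default b = 6.9/mm) is
  met -- 1200 segments provide both the budget and the dynamic range (the
  Canberra total cannot exceed the shared event count);
* methylation: 500 designated mid-range probes (baseline beta 0.3-0.6 within
  a bimodal background of 10,000 probes) carry beta-scale switches scaled to
  the budget for b = 0.18/mm. Two analytic corrections keep the realized
  slope on target: a switch displaces the probe's measurement-noise baseline
  E|e_a - e_b| = 2 sd/sqrt(pi), and probes with a missing value within a
  patient drop out of the variance selection (expected retention
  (1 - missing_rate)^E[samples/patient]); both enter the weight budget in
  closed form.

Read counts for intended-pass calls are drawn to satisfy all five retention
criteria at depth 100, and a 20% admixture of labelled decoy calls violates
exactly one criterion each, so the filter's behavior is testable against
construction labels rather than a reimplementation.

Reproducibility: every patient draws from a child seed derived from (master
seed, patient index, modality), so cohorts are bit-for-bit reproducible and
extensible -- adding patients never perturbs existing ones.

What the generator does *not* emulate: clonal selection and growth dynamics
(fronts are static planes, not expanding lesions), array chemistry and probe
annotation, read-level sequencing noise, purity/ploidy confounding, and the
irregular, imaging-driven placement of real biopsy targets. Passing the
recovery tests therefore shows that the pipeline measures what the model
puts in -- linear spatial-genomic scaling at configured slopes -- not that
real tumors behave this way.

`simulate_distance_pairs()` bypasses the mechanistic model entirely and
draws (distance, genomic distance) pairs from an explicit line plus Gaussian
noise truncated at zero, for direct slope/intercept recovery checks. Its
default distance range, 7-25 mm, spans the separations at which multi-site
biopsy pairs are typically observed and keeps the published negative
intercepts from activating the truncation.

## Numerical conventions and degenerate inputs

* Continuous Jaccard with both profiles all-zero (0/0): defined as 0 with a
  warning -- two samples with no retained mutations have identical profiles.
* Canberra 0/0 terms contribute 0 (required for self-distance zero).
* Zero-slope fits: `mm_per_unit` is reported as undefined (NA) rather than
  infinite.
* Association requires n >= 3 pairs, non-constant x and y; otherwise the
  modality is reported with `insufficient_n = TRUE` and null statistics
  instead of an error, so partial cohorts still produce reports.
* Pattern trees (`mutation_sharing_tree()`): mutations are partitioned by
  their presence pattern across samples; the all-sample pattern forms the
  trunk from the zero-mutation root "N", remaining patterns attach greedily
  beneath the deepest strict superset, every sample ends in a leaf (with a
  zero-length private branch if needed), and branch lengths are mutation
  counts. Patterns that overlap a placed sibling without nesting -- which
  cannot arise under a strict branching process but can in data -- are
  attached to the deepest compatible ancestor and reported in
  `incompatible`, not silently resolved. With more than three samples several
  greedy orders are defensible; this one (decreasing pattern size,
  lexicographic tie-break) was chosen for determinism.
* VCF ingestion accepts only pre-split, single-ALT records; positions are
  1-based (VCF convention), CNV coordinates 0-based half-open (BED/CNVkit
  convention).

## Problem sizes

The test suite and the acceptance script run the full mechanistic generator
at 25 patients (about 110 samples, roughly 200 pairs), 1200 CNV segments and
10,000 probes -- large enough that pooled OLS recovers each target slope
within its standard error scale, small enough to run in well under a minute
per modality on one core. Property suites use 200-1000 randomized cases per
invariant with fixed seeds.

## Known limitations

* Pooled inference ignores within-patient clustering (see above); the
  permutation extension is the provided mitigation.
* The naive OLS standard error understates the sampling variability of the
  recovered slope when pairs share samples; recovery checks at a fixed seed
  should be read with that in mind.
* Per-patient probe selection makes methylation distances relative; only
  their spatial scaling, not their absolute values, is comparable across
  patients.
* The greedy pattern tree is a summary of sharing structure, not a fitted
  phylogeny.
* Whether "exonic" should include splicing annotations is data-dictionary
  dependent; the default is strict `exonic`, configurable via
  `allowed_regions`.
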