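---
title: "Methylation-array profiling, DMR detection and intensity-based CNV calling: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation-array profiling, DMR detection and intensity-based CNV calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(metharray)
```

# Scope

`metharray` implements an end-to-end analysis of 450k-style DNA methylation
microarrays for germ-cell biology cohorts: probe filtering and quantile
normalization, β/M-value computation with probe-type bias correction,
genomic-class methylation profiling, pairwise differentially methylated
region (DMR) detection, copy-number inference from total probe fluorescence
against a copy-stable control cohort, and window-of-linearity qPCR
quantification. Because raw array cohorts are bulky and access-controlled,
the package ships a synthetic cohort generator with planted ground truth so
every stage is exercised and validated without downloads. This vignette
records the models, the tunable parameters and the design decisions, in the
spirit of the methods sections of the established expression/methylation
packages.

# The synthetic cohort generator

The generator emulates the observables the pipeline consumes, not chip
chemistry.

**Genome and probes.** 23 chromosomes (autosomes plus X) at 1/100 of the
human lengths, with ~20,000 probes by default so the full pipeline runs in
seconds. Half of the probes (configurable `cluster_fraction`) are placed in
CGI-like clusters of 4–8 probes spaced 30–120 bp — these create the
CpG-dense regions that DMR chaining tests — and the rest are uniform
singletons. Cluster probes are mostly annotated `CGI` (80%) and often `TSS`
(40%); background probes carry repeat-class labels (`LINE`, `SINE`, `LTR`)
at genome-like rates. Probes are design type I with probability 0.28.

**Methylation.** Per probe, a methylated/unmethylated mode is drawn with a
CGI-dependent probability (`meth_mode_prob`, defaults 0.2 for CGI probes and
0.8 otherwise: islands mostly unmethylated, bulk genome mostly methylated),
then a true β from `Beta(5, 95)` (mean 0.05) or `Beta(95, 5)` (mean 0.95).
These shapes put ~97% of each mode's mass inside the corresponding extreme
decile, matching the sharp bimodal peaks real arrays show. Tumor (`SE`)
samples re-draw a fraction (`tumor_hypometh_fraction`, default 0.5) of their
methylated-mode probes from the unmethylated mode — *except* probes
annotated `CGI` or `TSS` (`hypometh_exclude_classes`), reproducing the
promoter/CGI-spared global hypomethylation of seminoma-like tumors. Planted
DMRs override β deterministically: non-target groups sit at β = 0.2
(M = −2) and the target group at M = −2 + `delta_m`.

**Intensity.** Total probe fluorescence is
`affinity(probe) × noise(probe, sample) × copy/2`, with per-probe affinity
lognormal(log 2000, sd 0.5) — probe affinities genuinely span orders of
magnitude on arrays — and per-cell lognormal noise sd 0.1 (~10% CV).
Channels are `meth = β·T`, `unmeth = (1−β)·T`; β-scale Gaussian noise
(`noise_sd`, default 0.02) is applied and channels recomposed at fixed
total, so copy number (total) and methylation (split) are orthogonal by
construction — the same arrays feed both analyses, as in the modelled
workflow. Totals are floored at 1 a.u. before any log2 so homozygous
deletions stay finite. Planted CNVs accept a `mosaic_fraction`; the
effective scale is `(2(1−f) + copy·f)/2`. The `control` group (10 female
blood-like samples by default) is validated copy-2 everywhere.

**What it does not emulate:** dye chemistry, bead replicates, batch
effects, and lymphocyte-infiltration purity gradients (a two-component
mixture would emulate the reported link between infiltration and apparent
hypomethylation depth, but no quantitative model is available to calibrate
it, so tumor purity is fixed at 1). Passing tests therefore demonstrate
algorithmic correctness on an idealized cohort, not robustness to every
artifact of scanner data.

# Preprocessing

**Detection p-values.** Arrays carry negative-control probes;
`detection_pvalues()` scores probe n in sample s as
`1 − ecdf_neg(meth + unmeth)` over that sample's negative-control totals.
A pass-through mode uses an externally supplied detection matrix instead.

**Filtering** is sequential so per-criterion counts are well defined:
(1) non-CpG probes, (2) probes without detectable signal (p ≤ 0.01 in at
least 95% of samples; missing cells drop out of the denominator and are
never imputed), (3) multi-target probes, (4) probes with a SNP at/within
10 bp of the target CpG (MAF ≥ 0.05). Filtering is idempotent, and the
report satisfies `n_input − Σremoved = n_retained`.

**Quantile normalization** pools the two channels per sample and maps each
sample's pooled intensity distribution onto the across-sample mean quantile
function (ties share their mean target). Pooling is deliberate: each probe
contributes one high and one low intensity whichever way it is methylated,
so the pooled distribution is comparable across samples even under global
hypomethylation. Normalizing the channels separately instead forces a
hypomethylated sample's methylated-channel distribution onto the normals'
and leaks the global shift into every β — measurably moving the medians of
methylation-spared probe classes.

**β and M.** `β = meth/(meth + unmeth)` (missing when both channels are
zero); `M = log2(β/(1−β))` with β clamped to `[ε, 1−ε]`, ε = 10⁻³, bounding
|M| at log2(999) ≈ 9.97 so region medians can never go infinite.

**Type-bias correction.** Type II probes read compressed β relative to
type I. The correction maps type II β onto the sample's type I distribution
*stratified by methylation state*: values below 1/3 are quantile-mapped
(101 percentile anchors, linear interpolation) onto the type I
sub-distribution below 1/3, values above 2/3 likewise onto the high
stratum, and the sparse middle is carried by an affine bridge between the
stratum boundary images. A single whole-distribution quantile or rank map
is unstable exactly where it matters: between the β modes the empirical CDF
is nearly flat, so a sub-percent difference in the two types' mode
proportions throws intermediate β values across the methylation gap
(planted effects of ΔM = 3 can collapse to noise). Conditioning on the
stratum removes the dependence on mode proportions — the same insight that
motivates three-state beta-mixture corrections, realized here without an EM
fit. The mode is recorded in `meta$type_bias` so outputs are never
mistaken for a mixture-model correction. Samples with fewer than 50 probes
of either type are left uncorrected with a warning.

The pipeline order is fixed and logged in the output metadata:
filter → quantile normalize → β → type-bias correct → M. Whether detection
filtering preceded normalization in the modelled workflow is not
recoverable; this order is a package choice.

# Genomic-class profiles

β values are pooled per group and binned into ten width-0.1 bins,
`[0, 0.1), …, [0.9, 1.0]`. Per-class profiles count a probe in every class
it belongs to (multi-membership), over the nine coarse classes (TSS —
optionally folding TSS1500/TSS200 — 5'UTR, gene body, 3'UTR, LINE, SINE,
LTR, CGI, enhancer). Both the coarse and the finer promoter vocabularies
are supported since the source material uses both granularities.

# DMR detection

**Candidate regions** are maximal chains: per chromosome, a probe extends
the chain iff its gap to the previous probe is ≤ 200 bp (inclusive); chains
of ≥ 4 probes become candidates. Chaining is order-invariant and never
crosses chromosomes.

**Testing.** The two test populations are the pooled per-probe-per-sample
M-values of the region in each group (M is preferred over β for testing
because of its better variance behaviour). The Mann-Whitney p-value is
exact two-sided when the combined count is ≤ 30 and tie-free, otherwise the
normal approximation with tie and continuity correction; an all-constant
region returns p = 1 with U = n·m/2 rather than dividing by a zero
variance. U and effect signs are oriented group_a − group_b. Group-level
pooling follows the region-level testing construction of pairwise DMR
tools; the group construct (rather than single-sample pairs) is required to
reproduce cohort-level DMR counts.

**Calling.** Benjamini-Hochberg adjustment runs over all testable regions
(untestable ones are excluded from the family). Two published
parameterizations are preserved as explicit modes, not reconciled:
`methods` (BH p ≤ 0.05 and |Δmedian M| ≥ 1.4) and `results` (BH p ≤ 0.01
and |Δmedian β| ≥ 0.25; the 25% difference is taken on the β scale, the
natural reading, and the assumption is recorded here). Records sort by
adjusted p, then |effect|.

# Copy-number inference

Copy number scales total fluorescence, so the CNV track works on raw
`meth + unmeth` totals (floored at 1 a.u.), *not* on quantile-normalized
data — normalization would equalize exactly the signal being measured.

**Bins.** Equal-probe-count bins (default 50 probes) per chromosome, with
the remainder merged into the last bin; equal probe support equalizes
median stability across bins. On a real-sized manifest this yields ~8.9k
bins genome-wide. Whether the published binning was equal-width or
equal-count is not recoverable; equal-count is the package's choice.

**Baseline.** Per sample, log2 totals are median-centred (library-size
scaling); then every probe is centred on its median across the control
cohort. The probe-centring step matters: a bin *median* — unlike a mean —
does not cancel per-probe affinity between a sample and the controls, and
with affinities spanning orders of magnitude the residual leakage (~0.06
log2 units per bin) would swamp the 10%-mosaic detection limit. Centring
residuals against a control reference is standard practice in
intensity-based CNV callers for methylation arrays. The baseline is the
per-bin median and MAD, across control samples, of the per-sample bin
medians of centred values; at least 3 controls are required or dispersion
is undefined.

**Calling.** `log2_ratio` = sample bin median − baseline median. A bin is
significant when |ratio| > k·max(MAD, mad_floor) with k = 3 and
mad_floor = 0.05 (a robust z against control dispersion; small control
cohorts make parametric tests fragile). States follow the published
five-state cutoffs — homozygous deletion ≤ −0.96, hemizygous/mosaic
deletion ≤ −0.24, neutral in (−0.24, 0.12), duplication ≥ 0.12, high-copy
gain ≥ 0.72 — applied as a total function with the quoted boundary
inclusions. The known coarseness of these cutoffs is preserved, not fixed:
a 100% single-copy loss (expected ratio −1 < −0.96) classifies as
homozygous deletion. `gain_loss` is ±1 only for significant bins. A 10%
mosaic single-copy gain (expected ratio log2(1.05) ≈ 0.07 < 0.12) is by
design below the duplication cutoff — the documented ~10% cell-fraction
detection limit. For male samples chrX ratios are shifted +1 before
thresholding since the all-female baseline carries two X copies; with sex
unknown, chrX calls are suppressed.

# qPCR quantification

`fit_efficiency()` selects, among contiguous windows of 4–6 cycles inside
the exponential phase (above the noise floor, below half the observed
plateau), the window maximizing r² of log2(fluorescence) vs cycle;
efficiency = 2^slope (flagged when r² < 0.99 or efficiency leaves
(1, 2.1]). The noise floor is mean + 3·sd of cycles 1–5 — a baseline
estimate that needs no no-template model; on short fixtures whose
exponential phase starts at cycle 1 this floor can exceed every usable
cycle, in which case all positive cycles below half-plateau are used.
`estimate_n0()` inverts the exponential at a threshold inside the fitted
window (default: geometric mean of the window endpoints):
Cq is the log-linearly interpolated crossing cycle and `n0 =
threshold / efficiency^Cq`; within the window the estimate is
threshold-invariant. Curves never reaching the threshold report n0 = 0
with an `undetected` flag. Replicate (triplicate) N0 values are averaged
per reaction set, and target expression is normalized to the geometric
mean of two reference genes (arithmetic mean available); an undetected
reference flags the result rather than dividing by zero.

# Sample-level summaries

Hierarchical clustering runs on the top-variance β probes (default 5000)
with euclidean distance and average linkage — the distance/linkage were not
specified in the modelled workflow, so standard deterministic choices are
exposed as arguments. PCA runs on centred M-values by default (β optional).
Gene-set enrichment is a one-sided hypergeometric tail with BH across sets
— generic over-representation plumbing, explicitly not a replica of any
annotation web service. All summaries are deterministic with no hidden
seeds.

# Numerical choices and degenerate inputs

* β clamp ε = 10⁻³ (M bounded at ±9.97); both-channels-zero cells are
  missing and propagate.
* All-tied Mann-Whitney input: p = 1, no division by zero.
* Quantile normalization of a single sample: identity with a warning.
* Zero-intensity floor 1 a.u. before log2 (configurable).
* Degenerate control baselines (MAD 0) are flagged and the `mad_floor`
  applies.
* Chromosome Y is rejected by default (the CNV scheme spans autosomes + X)
  but loadable with `allow_chrY = TRUE`.
* Coordinates are 1-based inclusive internally; BED export converts to
  0-based half-open; SEG stays 1-based inclusive.

# Problem sizes

The test-suite and acceptance computations use cohorts of 3,000–20,000
probes with 4 samples per biological group and 10 controls, 30 planted DMRs
of 6 probes at |ΔM| = 3 under β noise 0.02, arm-scale planted CNVs at 50
probes per bin, and qPCR curves over 45 cycles at 1% proportional noise
spanning four logs of N0 — sizes chosen so each property is measured with
comfortable margins while the whole suite runs in well under a minute.

# Known limitations

* The type-bias correction is a stratified quantile map, not a fitted
  mixture; probes genuinely at intermediate methylation are bridged
  linearly rather than modelled.
* Fixed-bin CNV calling does no segmentation (no CBS/HMM), no
  allele-specific copy number, and no purity/ploidy estimation.
* The DMR effect-size gates are the published constants; they are
  parameters, not estimates.
* The generator's idealizations listed above bound what green tests imply
  about scanner data.
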