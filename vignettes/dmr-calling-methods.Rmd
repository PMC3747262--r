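---
title: "Region-level DMR calling for MeDIP tiling arrays: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-level DMR calling for MeDIP tiling arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tilemeth` calls ~1 kb differentially methylated regions (DMRs) from
two-channel MeDIP tiling-microarray data and correlates region
methylation with continuous plasma phenotypes. This vignette documents
the statistical model, the tunable parameters, the synthetic-data
generator used for calibration, and the design choices made where more
than one reasonable convention exists.

## The measurement model

Each array yields, per probe, a bound (methylation-enriched, Cy5) and an
input (Cy3) intensity; the per-probe signal is `log2(bound/input)`.
Non-positive channel intensities are a hard error rather than being
offset by a pseudo-count: in practice they indicate a broken upstream
conversion, and silently patching them would bias the quantile step.

Arrays of one cell type are quantile-normalized jointly, under the
assumption that all samples share the same overall methylation level;
cell types are analyzed independently throughout, because the cellular
methylation landscapes differ and normalizing them together would remove
genuine cell-type signal. Tied values within an array receive the mean
of the reference quantiles they span, which makes the result independent
of tie ordering. Two consequences worth knowing: with ties present,
(i) the tied column's sorted vector is no longer *exactly* the reference
vector, and (ii) quantile normalization is no longer exactly idempotent.
Both properties hold to machine precision for tie-free data, which is
the relevant regime for continuous fluorescence ratios.

Technical replicates (three arrays per sample in the motivating design)
are reduced to one column per subject by the arithmetic mean
(`method = "median"` is available). Inference then treats subjects, not
arrays, as the unit of analysis: triplicate arrays are technical, and
using them as independent columns would pseudo-replicate.

## Probe-level inference

For the two-group contrast we use an empirical-Bayes moderated
t-statistic. Per probe, `lfc = mean(A) - mean(B)` and the pooled
within-group variance `s^2` on `d = nA + nB - 2` degrees of freedom; a
prior variance `s0^2` with `d0` prior degrees of freedom is fit across
all probes of the array by matching the mean and variance of `log(s^2)`
to their digamma/trigamma expressions under the scaled-F sampling model
(the trigamma equation is inverted by Newton iteration). The posterior
variance `(d0*s0^2 + d*s^2)/(d0 + d)` replaces `s^2` in the t-statistic,
and p-values use `d0 + d` degrees of freedom. When the observed
dispersion of `log(s^2)` does not exceed what `d` alone explains, there
is no finite `d0`: we set `d0 = Inf` and take `s0^2` as the geometric
mean of the `s^2`, so that posterior variances equal `s0^2` exactly (in
particular, equal input variances are returned unchanged). The test
suite cross-checks the whole fit against `limma::eBayes` and the `d0 = 0`
limit against the textbook pooled t.

For the phenotype arm, each probe's methylation is correlated
(Pearson) with the per-subject analyte level, subjects with missing
phenotype excluded pairwise, and two-sided p-values come from the exact
t transform on `n - 2` degrees of freedom. A constant phenotype is an
error, not an `NA`: every downstream quantity would be undefined.

## Region-level inference

Each locus is partitioned into non-overlapping windows of exactly
`region_width` bp (default 1000) anchored at the locus start, the final
window truncated at the locus end; probes are assigned by start
coordinate. Windows with fewer than `min_probes_per_region` probes
(default 3 — the rank-sum test is powerless below that) are marked
untestable and excluded from the FDR family rather than assigned p = 1,
which would distort the BH step.

A testable region is scored by Wilcoxon rank-sum enrichment of its
probe scores (moderated t or Pearson r) against a background of all
other probes **on the same locus**. Two one-sided tests are combined as
`p = min(1, 2*min(p_up, p_down))`, and the smaller side defines the
region's direction; this preserves the directional "large positive or
negative" logic and yields a per-region direction, unlike a single
two-sided test on absolute scores. Midranks handle ties. For 25 or
fewer total probes the null distribution is enumerated exactly by
subset-sum counting over the (doubled) midranks; beyond that, the
normal approximation with tie correction and a 0.5 continuity
correction is used — the tests verify the two agree to within 0.05 near
the boundary and that the exact path matches brute-force enumeration of
all rank assignments.

Benjamini–Hochberg adjustment runs once per statistic kind over all
testable regions of a cell type, across loci: nothing in the procedure
is locus-specific, and per-locus families would trade FDR control for
unstable small families. A region is **called** when `q <= 0.2` and it
contains at least one probe with `p <= 0.05` and `|lfc| >= 0.25` (or
`|r| >= 0.5`) whose sign matches the region direction; the sign
concordance prevents a region from being called "higher in A" on the
strength of an opposite-direction probe. All five thresholds are
exposed in `calling_thresholds()`. The region's mean probe `lfc` is
reported so users preferring a stricter region-level effect filter
(e.g. mean |lfc| > 0.5) can apply it downstream.

Two background choices are defensible: locus-restricted (default) and
array-wide (`background = "array"`). Locus restriction protects against
cross-locus distribution shifts (different loci genuinely differ in
methylation level and variance), at a cost documented under
*Limitations*.

## Annotation

Distances are measured from the region midpoint to the TSS, signed in
the gene's orientation (negative = upstream); the nearest gene
minimizes absolute distance, ties broken by lexicographic gene id for
determinism. Promoter membership is decided by the *midpoint* falling
within TSS −2000 to +1000 bp: a point anchor is what makes a region
reported at −2042 bp "just outside" a promoter whose window ends at
−2000, whereas an overlap rule would swallow any 1-kb region centred
there. The overlap rule is still available
(`promoter_rule = "overlap"`). Regulatory-element overlap is binary at
≥ 1 bp of half-open intersection, with no reciprocal-fraction
requirement, and is computed with `IRanges::findOverlaps`; tests check
it against brute-force all-pairs intersection.

All coordinates are 0-based half-open everywhere internally and in BED
output; conversion to 1-based conventions happens only in reporting.

## The synthetic-data generator

The generator exists so the whole pipeline can be exercised and
calibrated without any external data. Its defaults are the motivating
study's design: 8 group-A vs 12 group-B subjects, 3 replicate arrays
per sample, two cell types, probes at 100-bp spacing, eight loci of
100–180 kb. Per probe and array,

```
log2(bound/input) = baseline + affinity + effect*[group A, in DMR]
                    + subject_noise + replicate_noise
```

with three variance components, additive and Gaussian on the log2
scale:

* `probe_noise_sd` (0.3): a per-probe *affinity* effect, drawn once per
  cell type and shared across arrays — probe-to-probe differences in
  hybridization/enrichment efficiency. It cancels exactly in group
  contrasts and correlations, as such systematic effects do after
  within-probe comparisons.
* `subject_sd` (0.3): biological noise per (subject, probe).
* `replicate_sd` (0.2): technical measurement noise per (array, probe),
  the component that replicate averaging suppresses.

The magnitudes are engineering choices (no noise levels are published
for this assay at this granularity); they were chosen once to give
per-probe moderated t values around 6 for a 1.0-log2 planted effect —
comfortably detectable, as the validated regions in this kind of study
are — and are exposed in `simulation_spec()`. The baseline is a smooth
two-component sinusoid per locus (periods 20 kb and 57 kb), mimicking
slowly varying average methylation without affecting group differences.
The input channel is log-normal around a fixed brightness and
`bound = input * 2^(log-ratio)`, so channels are positive by
construction and planted log-ratios are exact. Phenotypes are
`intercept + slope * (subject mean true methylation over a linked
region) + Gaussian noise`; annotation tracks are Poisson-placed
intervals with exponential widths.

Determinism: every draw uses a sub-stream seed derived by hashing the
master seed with a purpose string (`"subj/T_cell/A01"`,
`"array/A01_T_cell_r2"`, ...), so regeneration with the same seed is
bit-identical and partial regeneration (e.g. phenotypes only) is
stable.

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: CpG-density bias of MeDIP
enrichment, dye bias, spatial array artifacts, correlated probe noise
along the genome, cell-composition heterogeneity, and non-Gaussian
outliers. The calibration results say the *statistics* behave as
designed under the assumed noise model, not that the model captures
every failure mode of a real hybridization.

## Calibration results and problem sizes

The Monte-Carlo suites (`null_calibration()`, `recovery_sensitivity()`)
run the full pipeline — simulation, normalization, probe statistics,
region calls — on 50 independent studies each. They use `mc_spec()`:
the full default design in subjects, replicates, spacing and noise, but
two loci of 30 kb rather than eight of 100–180 kb; region-level
calibration is driven by the number of regions per family and probes
per region, both of which are preserved, and this size keeps 100
whole-pipeline simulations within seconds. Under the null the mean
false-discovery proportion at nominal FDR 0.2 is well below 0.25; with
planted 1000-bp DMRs of |log2 effect| 1.0 the sensitivity (correct
direction required) is at or near 1. `scripts/acceptance.R` recomputes
both from scratch, plus correlation-arm recovery and a full
default-scale study.

## Limitations

* **Locus-restricted background with a strong DMR.** A large planted
  (or real) DMR inflates the locus background, so *other* regions of
  the same locus rank slightly low against it and occasionally produce
  an opposite-direction call nearby. The probe-concordance requirement
  suppresses most of these; users worried about the remainder can
  switch to `background = "array"` or apply the region-level mean-lfc
  filter.
* The BH guarantee assumes the usual positive-dependence conditions;
  region p-values within a locus share a background and are mildly
  dependent. The null calibration suite is the empirical check.
* Quantile normalization enforces identical marginal distributions; a
  global methylation shift between groups is removed by design.
* The moderated-t model assumes a single variance prior across probes;
  no intensity-dependent variance trend is fit.
* The pipeline functions and `run_pipeline()` (config in, TSV/BED out)
  are the interface; there is no shell executable — users of an
  analysis package of this kind drive it from R.
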