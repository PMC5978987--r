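---
title: "Population-based CNV detection from read depth: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-based CNV detection from read depth: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(popcnv)
```

## The problem

A deletion halves the read coverage of the affected region; a
duplication raises it by half. Detecting this from binned read counts
would be easy if coverage were uniform, but whole-genome sequencing
coverage carries technical structure that survives standard per-sample
corrections: the mean coverage of a bin differs between genomic regions
beyond counting noise, some samples run consistently high or low across
large portions of the genome, and libraries respond differently to
sequence context (GC, mappability, chemistry). Methods that normalize
each sample in isolation therefore confuse technical structure with copy
number, especially for small or rare variants.

`popcnv` treats the cohort itself as the control: every bin of every
sample is compared with the same bin in a panel of reference samples,
after a normalization step that is local to the bin.

## Model and pipeline

### Counting and GC correction

The genome is tiled into non-overlapping bins of `bin_size` bp (default
5,000 — small enough to resolve variants of a few kilobases, large
enough that a diploid bin at 40x coverage holds ~1,600 read starts). A
read is assigned to the single bin containing its leftmost aligned base
and counts only if it is a primary, non-duplicate alignment with the
proper-pair flag and MAPQ at or above `min_mapq` (default 30; the flag
set operationalizes "properly mapped", which aligners do not define
uniformly). GC bias is corrected per sample by a loess trend (span 0.3)
fitted to mean counts over 100 GC-quantile knots; each count is divided
by the trend at its bin's GC and the sample's genome-wide median is
restored exactly. Bins whose fitted trend falls below 1% of the sample
median cannot be corrected reliably and are zeroed and flagged.

Bins are then filtered on cross-sample behaviour: a bin is dropped when
its cross-sample median is below `low_frac` (0.1) times or above
`high_mult` (3) times the genome-wide median, or when more than
`max_zero_frac` (0.1) of samples have a zero count. Comparisons are
strict, so a bin exactly on a threshold survives.

### Targeted normalization

For each usable bin, its coverage vector across the reference panel is
scaled to mean 1 and compared (Euclidean distance) with a seeded random
candidate pool of `C` = 5,000 usable bins shared by all target bins; the
`K` = 100 nearest candidates plus the bin itself form its *support set*.
Two bins whose scaled reference vectors agree respond the same way to
whatever technical structure the cohort carries, whichever its cause.
The normalization factor for sample *s* at bin *b* is the median over
supporting bins *j* of `ref_median(j) / count(s, j)` (zero-count
supports skipped; more than half zero marks the value missing). The
median over 100 supports makes the factor robust to a CNV inside the
support set, and because the factor is a ratio it absorbs any global
per-sample scaling exactly. `K` and `C` trade cost against support
quality; with `K` = 100 the bin's own anomaly cannot dominate its
factor.

### Per-bin statistics and moderation

Reference location and scale per bin are the median and 1.4826 × MAD of
the normalized panel (SD where the MAD is zero), computed on the
analysis scale below. A panel of a few dozen samples estimates a MAD
with roughly 13% relative error, so across thousands of bins some
scales are badly underestimated, and those bins fire as recurrent
single-bin false positives in every sample. The per-bin variance is
therefore moderated (`limma::squeezeVar`): shrunk toward a robust trend
in log location, with residual degrees of freedom scaled by the MAD's
37% Gaussian efficiency. This is the same empirical-Bayes argument used
for small-replicate expression data, applied to a coverage panel.

### Analysis scale

Z-scores are computed on square-root-transformed normalized coverage.
Counting noise on the raw scale is right-skewed; even with exactly known
parameters the upper tail at 4 standard deviations is several-fold
heavier than normal, which surfaces as duplication-biased false calls.
The square-root transform stabilizes the variance and removes nearly all
of the skew at realistic dispersions. `build_reference(transform =
"identity")` restores the raw-coverage scale.

### FDR estimation

The null for a sample's Z-scores is estimated from the centre of its own
distribution, so true CNVs in the tails do not inflate it: the scale
`sigma0` matches the median of |z| to the half-normal median, and the
tail weight matches the 95%/50% |z| quantile ratio to a scaled t
(degrees of freedom on a grid; normal Z-scores return the normal). The
t family is needed because panel-size-limited scale estimates leave
residual per-bin variance heterogeneity, which makes the marginal null
mildly but consequentially heavier-tailed than normal. Two-sided
p-values are Benjamini–Hochberg adjusted across the sample's tested
bins; a bin is abnormal when its q-value is below `fdr_threshold`
(default 0.05).

### Merging and copy number

Runs of same-direction abnormal bins become one call, tolerating
`stitch` (default 0) non-abnormal tested bins inside a run. A circular
binary segmentation mode is available: recursive two-cut change-point
search on the z track with a permutation stopping rule (alpha = 0.01).
Region significance is recomputed by Stouffer combination
(`mean(z) * sqrt(nbins)`) through the sample's fitted null, and
BH-adjusted against the number of *tested bins* rather than the number
of calls — candidate regions were nominated from that many hypotheses,
and per-call multiplicity alone lets marginal single-bin noise calls
through. `call_cnvs()` keeps regions with region-level q below the
threshold. Copy number is `2 × mean(normalized coverage) /
mean(reference coverage)` over the call's bins; deletions and
duplications are assigned by the sign of z, and the copy-number value is
reported, not thresholded.

## Cohort statistics

Same-type calls cluster into catalog regions by single linkage at
reciprocal overlap ≥ 0.5 (the field-standard criterion for "the same"
CNV); a region spans the union of its cluster and carries the union of
samples. Database frequency takes, within each database, the largest
carrier count among variants covering at least half of the region (any
variant type, because database entries may be large multi-allelic
regions), and the maximum across databases; *rare* means strictly below
1%. Deletion/duplication balance between cohorts is a 1-df Pearson
chi-squared on rare regions, with seeded control downsampling.

Burden analyses compare a catalog's overlap with an annotation track
against size- and gap-matched random control regions (constructive
matching: the number of gap-hitting controls is fixed at the rounded
target and placements are rejection-sampled). The case/control burden
statistic is the median fold-enrichment difference over paired
subsampled catalogs, with the control-region seed shared within a pair
so placement noise cancels. Its null permutes cohort labels at the
*sample* level: each replicate relabels the pooled samples and takes the
paired fold difference of one disjoint subsample split. Label
permutation at the catalog level is not used because the realized
between-cohort difference is a fixed offset that catalog relabeling
never resamples, which makes that null anticonservative on exchangeable
cohorts; the single-split replicate carries at least the observed
statistic's noise, so the test errs on the conservative side. All
empirical p-values use the (1 + hits)/(1 + draws) convention.

Known-gene enrichment controls for gene length with 20 length-quantile
strata: null gene sets preserve the stratum composition of the CNV-hit
set. Proximity analysis measures each qualifying call's distance to the
nearest known-gene exon (zero when overlapping), counts exposed
individuals per distance threshold, forms odds ratios (Haldane 0.5
correction for empty cells), and compares distance distributions with a
two-sample KS test (per-call by default; per-individual minima by flag —
the choice changes the test's unit of evidence and both are defensible).

## The simulator

`simulate_coverage()` draws counts with mean

```
depth_mean * mu_b * L_s * g_s(gc_b) * A_{s, r(b)} * cn_{s,b} / 2
```

- `mu_b ~ lognormal(0, 0.3)`: region effects — the bin-to-bin mean
  structure observed in real cohorts.
- `L_s ~ lognormal(0, 0.05)`: per-sample rank bias (samples consistently
  high or low genome-wide).
- `g_s`: a per-sample Gaussian-bump GC response (optimum ~N(0.45,
  0.02), width 0.15, mean-normalized), removable in principle by
  per-sample GC correction.
- `A`: latent region-class batch structure — each bin belongs to one of
  3 response classes and every sample has a lognormal(0, 0.03)
  multiplier per class. This emulates sample-by-region technical
  response (mappability, library chemistry) that no smooth per-sample
  correction can remove, and is precisely the structure targeted
  normalization exploits; without it a global quantile normalization
  would look artificially optimal.
- Noise: negative binomial with size 800 at the default depth of 1,600
  reads/bin (40x, 125 bp reads, 5 kbp bins), i.e. residual variance
  about 3 x Poisson. The *structured* overdispersion of real data lives
  in the bias terms above; the residual bin-by-sample dispersion after
  such structure in high-coverage WGS is a few-fold Poisson. Poisson
  and Gaussian noise arms exist for null comparisons.
- Spikes: non-overlapping events (1-bin buffer) of given length, copy
  number and Bernoulli carrier frequency; twin mode assigns carriers at
  the pair level so monozygotic twins share all events.

What the simulator does *not* model: mappability and reference-genome
artifacts, read-level sequence errors, sex chromosomes, correlated
breakpoint placement, multi-allelic loci, and real inter-cohort batch
confounding. Passing the benchmark therefore shows that the statistical
machinery is calibrated and sensitive under the documented bias
structure, not that any real cohort is free of artifacts the simulator
omits.

## Benchmark sizes and numerical choices

The bundled benchmark (tests and `scripts/acceptance.R`) uses 45 samples
by 2,000 bins — a panel size at the recommended minimum range (20+
reference samples) and enough bins for stable trend and null fits while
keeping a full pipeline run under ten seconds. Spike-in experiments use
100 events of 4 bins (and a 1-bin variant) at 2% carrier frequency;
permutation calibrations use 50 seeds at 500 replicates.

Degenerate inputs: all-zero reference bins are flagged unusable; bins
with zero scale or missing values are excluded from testing and logged;
`sigma0` falls back to 1 when fewer than 500 bins are tested (with a
warning); fold-enrichment of 0/0 is an error at the user surface and a
missing value inside the permutation machinery. Ties in quantile
normalization take average ranks; nearest-neighbour ties in support
selection break deterministically by bin index; the candidate pool,
control-region placement, permutations and the simulator are all seeded,
and the pipeline is byte-deterministic end to end for fixed seeds
(the CBS stopping rule consumes the R RNG stream; seed before calling if
byte-stable CBS output matters).

## Limitations

Sensitivity at 50% carrier frequency is limited by construction (the
panel median absorbs the variant); use control-only panels in
case/control designs where that matters. Single-bin events are detected
at high rates in the benchmark's clean-signal regime but degrade first
as depth falls or dispersion rises. The catalog's union-span regions can
overstate breakpoint extent for ragged clusters. Copy-number estimates
are continuous and unphased; integer genotyping (e.g. an HMM over
samples) is out of scope.
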