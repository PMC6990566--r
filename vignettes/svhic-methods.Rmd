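---
title: "Testing the effects of common structural variants on Hi-C chromatin contacts"
author: "svhic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing the effects of common structural variants on Hi-C chromatin contacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svhic)
```

## The problem

Topologically associating domains (TADs) are self-interacting genomic
regions of roughly 0.1–1 Mb that organize regulatory contacts. Common
structural variants (SVs) — deletions and inversions segregating in the
population — can remove or rearrange the sequence that shapes these
contacts. `svhic` implements a cohort-scale analysis that asks, locus by
locus, whether the number of Hi-C contacts near an SV varies with the
number of SV alleles a sample carries (its *dosage*, 0/1/2).

The pipeline starts from binned per-sample contact matrices (40 kb bins
by default) and SV genotypes in VCF, and produces per-deletion
association statistics, inflation-calibrated significance summaries,
TAD-boundary annotations, group comparisons, and per-bin-pair effect
maps. A synthetic-data module generates full cohorts with known ground
truth so every stage can be validated end to end.

## Data model and normalization

A `ContactMatrix` is a symmetric non-negative matrix for one chromosome
of one sample with a per-bin missingness mask; bins with zero marginal
coverage cannot be normalized and are excluded from every downstream
average (they render as gray in the heatmaps). Bins are 0-based and
half-open: bin *b* covers `[b*binsize, (b+1)*binsize)`. A `HiCCohort`
holds one matrix per sample on a shared grid, with batch labels.

Two normalization stages precede association testing:

1. **Per-bin bias removal** (`hicnormNormalize`): cis counts are
   regressed on the log pairwise products of per-bin effective length,
   GC content and mappability (Poisson GLM, log link), and each count is
   divided by its fitted bias, rescaled to preserve the overall mean.
   When bin covariates are not available the stage is skipped with a
   notice.
2. **Band-wise cross-sample normalization** (`bandQuantileNormalize`,
   `batchCorrectBands`): for each genomic distance *d*, the entries at
   `|i − j| = d` form one vector per sample; these are
   quantile-normalized to the mean quantile profile, making each
   sample's distribution at each distance identical, then per-batch
   location/scale shifts of each band are removed toward the pooled band
   mean and standard deviation. Bands where any sample has fewer than
   `minBandEntries = 10` usable entries are left unchanged. Ties are
   broken by genomic position so the post-normalization multiset is
   exactly equal across samples; the batch step can in principle produce
   small negative values, which are clamped at zero to preserve the
   non-negativity invariant.

## TAD boundary calling

The directionality index (DI) of bin *i* contrasts its upstream and
downstream contact sums `A` and `B` over a `windowBins = 50` window
(2 Mb at 40 kb): with `E = (A+B)/2`,

\[ \mathrm{DI}_i = \mathrm{sign}(B - A)\left(\frac{(A-E)^2}{E} +
   \frac{(B-E)^2}{E}\right), \]

zero when `A = B` or `E = 0`. A three-state Gaussian-emission hidden
Markov model (upstream bias / no bias / downstream bias) is fit to the
DI profile by expectation–maximization. Initialization is deterministic
(state means from DI tertiles, sticky transitions), so fits are
reproducible without random restarts; emissions are single Gaussians
with a floor on the standard deviation; missing DI values are
marginalized. Decoding is per-bin posterior maximum by default, with
Viterbi available — on clean profiles the two agree, and posterior
decoding degrades more gracefully when states are uncertain. A boundary
is called wherever the decoded path switches from upstream bias (end of
a domain) to downstream bias (start of the next); the boundary interval
runs from the end of the last upstream-biased bin through the first
downstream-biased bin, and domains shorter than `minDomainBins = 3`
(120 kb — below the usual TAD scale) are merged into their predecessor.

## Span/flank association testing

For each common deletion (carried by at least 3 samples by default,
matching a 19-sample cohort at ≥ 3/19), the bins it overlaps are masked
and two pair sets are built from the `nFlank = 6` nearest unmasked bins
on each side (240 kb at 40 kb bins; flanks skip masked bins, e.g.
segmental duplications, rather than shrinking):

* the **span** set — all left × right pairs, i.e. contacts that cross
  the deletion; and
* the **flank** set — all same-side pairs excluding the diagonal, i.e.
  contacts that do not cross it.

Per sample, contacts are averaged over each set (a median variant is
available; some published summary tables use the median) and the
statistic is tested against dosage by ordinary least squares with two
ancestry PCs and sex as covariates. The default `"dosageOnStat"`
orientation regresses *dosage on the contact statistic* plus
covariates and reports the statistic term; the conventional
`"standard"` orientation (statistic on dosage) is available. The two
orientations give
numerically identical p-values — the t statistic of either coefficient
is the partial-correlation t — and differ only in the coefficient's
scale, so the choice matters for effect-size interpretation, not for
significance. Covariates were chosen (and can be re-chosen via
`selectCovariates`) as the combination minimizing the genomic inflation
factor

\[ \lambda = \mathrm{median}\{\chi^2_1(1 - p)\} / 0.4549364, \]

with nested candidate models added one block at a time and saturated
models (parameters approaching the sample count) excluded; at n = 19,
two PCs plus sex is the largest sensible model. Empirical null
distributions come from re-running the full regression on
seeded permutations of each dosage vector (`nPerm = 100` by default),
giving QQ reference quantiles, pooled null coefficient sets for the
TAD-boundary group comparisons (Wilcoxon rank-sum, exhaustively
enumerated when both groups have ≤ 8 values, normal approximation with
tie correction otherwise), and Kolmogorov–Smirnov comparisons of
p-value strata (large > 10 kb versus small deletions).

Per-bin-pair coefficient maps (`perBinCoefficients`) apply the same
regression independently to every unmasked pair in a window around the
SV, for the blue-red effect heatmaps; maps from multiple loci are
aligned on the left/right deletion boundaries and aggregated by the
cellwise median (`aggregateCoefficientMaps`), which resists single-locus
outliers.

## Inversions

For a polymorphic inversion, the analysis window is its bins plus
62 bins (~2.5 Mb) per side. `genotypeCorrelationMap` computes, per bin
pair, the Pearson correlation of contact values with inversion dosage
across genotyped samples (pairwise deletion of missing contacts;
zero-variance cells flagged). `mirrorInversionContacts` reverses the bin
order inside the inversion — an exact involution — so carrier matrices
can be compared bin-for-bin with reference-orientation matrices.
Correlation maps default to the normalized cohort; whether the original
analysis used normalized or raw counts is not recorded, and the choice
only rescales, not reorders, per-pair correlations.

## The synthetic cohort generator

`simConfig`/`simulateDataset` generate cohorts with the statistical
structure the analysis assumes. Expected contacts follow a power-law
distance decay `depth · max(|i−j|, 1)^{−α}` with `α = 1`, multiplied by
`betaTad = 3` when both bins share a TAD; `depth` defaults to
`100 / betaTad` so the main diagonal band averages ~100 counts. Counts
are Poisson (or negative binomial with selectable dispersion) around the
expectation; effects are injected **in expectation**, so noise-model
calibration stays valid. Samples get Hardy–Weinberg SV genotypes,
Bernoulli(0.5) sex, two-population background SNPs (for ancestry PCs;
frequency separation 0.3), and round-robin batches with a multiplicative
factor of 1.25 on later batches — a modest processing-date effect.
Heterozygous effects are linear midpoints (`dosage/2` blending), the
simplest model consistent with additive 0/1/2 coding.

Deletions support two effect modes. **Direct**: bins inside the deletion
lose coverage in proportion to dosage, and pairs spanning it behave as
if the deleted bins were excised — their effective distance shrinks by
`effectSize · dosage/2 · length`, floored at one bin — reproducing the
gain of deletion-spanning contacts. **Fusion**: for carriers the
inter-TAD factor across the deleted boundary interpolates toward
`betaTad` in proportion to `dosage/2 · effectSize`, modelling insulation
loss. Inversions blend the reference-orientation expectation with the
coordinate-reversed one by `dosage/2`. The default demo design (19
samples, 400 bins, four TADs, one 3-bin direct deletion, one
boundary-straddling fusion deletion, one 30-bin inversion) scales with
the configured geometry.

What the generator does **not** emulate: restriction-fragment structure,
mappability and GC bias (bin covariates are a separate input),
copy-number-variable coverage outside the focal SV, linkage between SVs
and background SNPs, and realistic genome coordinates. Passing tests
therefore demonstrate that the statistics behave as designed under the
assumed generative model, not that real Hi-C data meet those
assumptions.

## Validation studies and their problem sizes

The packaged studies re-run the full pipeline at fixed, documented
scales, chosen so each completes in minutes on one CPU while keeping
Monte-Carlo noise small relative to what it measures:

* `calibrationStudy` — 18 independent effect-free cohorts of 19 samples
  × 250 bins with 90 random deletion loci each (~1600 tested loci) plus
  a 2-permutation pooled null. Many small cohorts are used instead of
  one large one because association p-values share each cohort's
  sample-level quirks (depth draws, covariate configurations), making λ
  cluster by cohort; pooling across cohorts averages this out. A
  calibrated pipeline gives λ near 1 for span and flank and uniform
  null p-values.
* `powerStudy` — 50 cohorts, one 3-bin direct deletion each, on 200-bin
  chromosomes. The 200-bin size keeps a single locus from dominating its
  distance bands: on very short chromosomes the band-wise quantile step
  redistributes a localized true gain across the band's few other
  entries and leaks signal into the flanks, an artifact real
  chromosomes (thousands of bins per band) do not have. The injected
  effect is ~6 residual standard deviations per dosage copy — well above
  the 0.5 sd regime where ≥ 80% power is expected.
* `fusionWedgeStudy` — 8 cohorts with a boundary-straddling fusion
  deletion; the aggregated coefficient map's inter-TAD cells should show
  a positive median wedge.
* `inversionEnrichmentStudy` — 5 cohorts of 9 genotyped samples with a
  30-bin inversion; measures the fold enrichment of breakpoint-spanning
  pairs (one bin inside, one outside) in the top decile of |r|. At this
  sample size the null |r| spread (7 degrees of freedom) is wide and
  distal pairs carry around one expected count, so only the most
  breakpoint-proximal pairs rise above the noise: the concentration is
  real (the strongest cells are overwhelmingly breakpoint-spanning) but
  the *decile-level* fold enrichment saturates near 1.3–1.6 against a
  geometric ceiling of ~3.2. Deeper matrices or larger genotyped cohorts
  would be needed for decile-level separation.
* `boundaryRecoveryStudy` — 20 cohorts × 100 bins with boundaries at
  fixed positions; recovery is a true boundary having a called-boundary
  midpoint within ±1 bin.

## Numerical choices and degenerate inputs

* Quantile normalization with unequal per-sample counts interpolates
  each sample's quantile function on a common grid; with equal counts it
  reduces to classical mean-quantile normalization.
* The HMM guards: all-zero or constant DI profiles decode directly to a
  single no-bias state; emission standard deviations are floored at
  10⁻³ of the profile's spread; EM stops when the relative
  log-likelihood change falls below `tol = 10⁻⁶` (the likelihood trace
  is non-decreasing and checked in tests).
* Regressions refuse monomorphic dosages, constant statistics, and
  rank-deficient designs by name; per-cell failures in coefficient maps
  flag the cell rather than aborting the map.
* Untestable loci (no unmasked flank bins on either side) error with a
  recorded reason; one-sided loci keep their flank but have an empty
  span set.
* `p = 0` never occurs in λ computations (two-sided t-tests on finite
  designs), and `genomicInflation` rejects p-values outside (0, 1].

## Known limitations

* With 19 samples the regression supports at most ~3 covariates; the
  surrogate-variable block exists but saturates the model and is off by
  default.
* Band-wise quantile normalization assumes most entries of a band are
  unaffected by any single locus; it slightly shrinks genuine localized
  effects (rank competition), which is visible on very short synthetic
  chromosomes.
* The boundary caller emits non-nested, non-overlapping domains only; no
  loop calling or hierarchical TADs.
* Group Wilcoxon tests treat permutation-null coefficients pooled across
  loci as exchangeable with observed ones; loci with very different
  contact scales weaken this.
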