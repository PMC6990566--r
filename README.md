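# svhic

Cohort-scale analysis of how common structural variants — deletions and
inversions segregating in a population — affect 3D chromatin structure
measured by Hi-C.

Given per-sample binned contact matrices, SV genotypes (VCF) and sample
metadata, `svhic`:

* normalizes contact matrices across samples band by band (per genomic
  distance) with quantile normalization and batch correction, after an
  optional per-bin Poisson-GLM bias-removal step;
* calls TAD boundaries from the directionality index with a
  three-state Gaussian-emission HMM;
* tests each common deletion for association between its dosage
  (0/1/2 copies) and the average contacts that **span** the deletion
  versus those in the same-side **flank** windows, by OLS with ancestry
  PCs and sex as covariates;
* calibrates significance with seeded genotype-permutation nulls, the
  genomic inflation factor `lambda = median(chisq_1(1-p)) / 0.4549`,
  QQ tables, Kolmogorov–Smirnov size-stratum comparisons, and Wilcoxon
  group tests of TAD-boundary versus non-boundary deletions;
* maps per-bin-pair regression coefficients around a locus (blue-red
  effect heatmaps) and aggregates them across loci;
* correlates contacts with inversion genotype around large inversions
  and mirrors carrier matrices for visual comparison; and
* simulates complete cohorts (distance-decay + TAD block structure,
  Hardy–Weinberg genotypes, dosage-linked deletion/inversion effects,
  batch effects, count noise) with ground truth for validation.

The model at the core: for deletion *v* with per-sample dosage
`d ∈ {0,1,2}` and per-sample region statistic `x` (mean contacts over
the span or flank pair set within 6 bins of the deletion),

```
d ~ x + PC1 + PC2 + sex        (default orientation)
```

and the statistic term's two-sided t-test provides the per-locus
p-value; permuted-dosage refits provide the empirical null.

## Worked example

Simulate the demo cohort — 19 samples, one chromosome, four TADs, a
3-bin mid-TAD deletion with a direct (breakpoint-spanning) effect, a
2-bin deletion straddling a TAD boundary with a fusion effect, and a
polymorphic inversion — then run the pipeline:

```r
library(svhic)

cfg  <- simConfig(nBinsTotal = 200L, tadBoundaryBins = c(50L, 100L, 150L))
sim  <- simulateDataset(cfg, seed = 7)
pcs  <- ancestryPCs(sim$snpGenotypes, k = 2)
covs <- covariateSet(pcs = pcs$scores, sex = sim$samples$sex)

res <- runPipeline(sim$cohort, sim$svs, covariates = covs,
                   minCarriers = 3L, nPerm = 50L, seed = 8)
res$results[, c("svId", "region", "beta", "p", "tbClass", "svLen")]
#>             svId region        beta            p tbClass  svLen
#>  demo_del_direct   span 0.286293093 1.413617e-10   NonTB 120000
#>  demo_del_direct  flank 0.005237744 9.579612e-01   NonTB 120000
#>  demo_del_fusion   span 0.214246731 1.353710e-11      TB  80000
#>  demo_del_fusion  flank 0.197174211 9.710044e-02      TB  80000

res$boundaries$boundaryBins
#>      start end
#> [1,]    50  51
#> [2,]   100 101
#> [3,]   150 151
```

Reading the output: both injected deletions show a strong positive span
association (contacts crossing the deletion increase with dosage,
p ≈ 1e-10) while their flank contacts stay null — the direct-deletion
signature. The fusion deletion is classified `TB` because it overlaps a
called TAD boundary; the called boundary intervals land exactly on the
simulated boundaries at bins 50/100/150. With real data, start from
`readContactMatrix()` (triplet or dense TSV) and `readSVGenotypes()`
(VCF with `SVTYPE`/`END`), and pass bin covariates to add the
bias-removal stage.

`plotContactHeatmap()`, `plotCoefficientHeatmap()` and `plotQQ()` render
the red count maps, blue-red coefficient maps (gray = masked/missing)
and QQ curves; `flankSweep()` re-derives regions across flank widths;
`genotypeCorrelationMap()` and `mirrorInversionContacts()` cover the
inversion analysis.

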