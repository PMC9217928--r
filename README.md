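# loscreen

In-utero screening for large offspring syndrome (LOS) in cattle. Bovine
fetuses produced by in vitro embryo production (IVP) are at risk of an
overgrowth syndrome; `loscreen` implements the statistical machinery needed
to detect it during gestation and to analyze the accompanying maternal blood
transcriptome:

- **Phenotyping** — classify fetuses as overgrown using sex-specific weight
  thresholds set at the 97th percentile (Hyndman–Fan type 7, inclusive `>=`)
  of artificial-insemination (AI) control weights, estimated per collection
  day and never pooled across sexes; exact one-sided binomial tests for
  female-biased pregnancy loss; umbilicus-to-crown-rump calibration from
  ultrasound pixel measurements.
- **Fetometry** — a day-55 ultrasound product index
  `P = AD x AH x CRL x HL x TH x TD` (six of the seven standard
  measurements; biparietal diameter is excluded), screened against the
  maximum product observed among controls, plus Pearson correlations of
  measurements with fetal weight.
- **Leukocyte transcriptomics** — three size-factor methods
  (median-of-ratios, TMM, upper-quartile) written from their definitions,
  average-linkage (UPGMA) hierarchical clustering with Newick export, and a
  negative-binomial GLM likelihood-ratio differential-expression engine run
  in two backend configurations whose significant gene sets are
  intersected. Stable reference genes for qPCR are selected by joint
  null-ness in both backends plus a coefficient-of-variation ceiling.
- **qPCR** — comparative-CT (delta-delta-CT) fold differences against the
  geometric mean of reference-gene CTs, centred so the geometric mean of
  baseline folds is exactly 1.
- **Synthetic cohorts** — seeded generators for fetus tables, ultrasound
  exams, count matrices with planted differential genes and per-dam
  expression profiles, and CT tables, plus deterministic packaged fixtures
  that reproduce the published cohort composition.
- **Pipeline** — validated CSV/TSV readers, a configuration object, and
  `run_pipeline()`, which strings the stages together and writes a
  deterministic report directory (CSV/TSV tables, a Newick dendrogram, and
  a JSON summary).

## Worked example

Classify the packaged day-105 fixture and screen its ultrasound products:

```r
library(loscreen)

fx <- study_fixture(105)
labs <- classify_los(fx$fetuses, thresholds = fx$thresholds)
labs
#> LOS classification
#>   thresholds (g): F = 463.14, M = 548.92
#>   labels: Control-AI = 12, IVP-LOS = 17, IVP-Normal = 29

los_prevalence(labs)
#> [1] 0.3695652   # 17 of 46 IVP fetuses

p <- product_index(fx$exams)
thr <- control_threshold(p, labs)
thr
#> [1] 79.92
names(which(screen_products(p, thr)))
#> [1] "664"  "604B"

sex_ratio_test(13, 46)
#> Exact binomial sex-ratio test: 13 females of 46 (p = 0.002267, one-sided vs 1:1)
```

The two flagged fetuses are exactly the two extreme overgrowth cases in the
fixture, and the day-105 IVP sex ratio is significantly female-depleted.

For the transcriptome stages, simulate a cohort and run everything at once:

```r
cfg <- sim_config(seed = 7, n_genes = 500, n_de_genes = 20)
coh <- simulate_cohort(cfg, day = 105)
meta <- sample_meta_from_cohort(coh$fetuses, n_dams = 23)
counts <- simulate_counts(cfg, meta)$counts
report <- run_pipeline(coh$fetuses, exams = coh$exams, counts = counts,
                       meta = meta, config = pipeline_config(seed = 7),
                       out_dir = "results/run1")
```

`results/run1` then contains `labels.csv`, `screening.csv`,
`size_factors.csv`, per-backend differential-expression tables,
`dendrogram.newick` and `report.json`; regenerating with the same seed is
byte-identical.

## Testing

```sh
Rscript -e 'devtools::test()'
```

The suite checks every component against independent oracles (hand
formulas, exhaustive enumeration, brute-force clustering) and, when the
packages are installed, cross-checks the size-factor implementations
against `edgeR` and `DESeq2`.

## Methods

See the vignette (`vignettes/los-screening-methods.Rmd`) for the generator
model, the numerical conventions of the NB-LRT engine, and known
limitations.
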