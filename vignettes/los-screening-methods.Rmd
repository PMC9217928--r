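---
title: "Screening for fetal overgrowth: models, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for fetal overgrowth: models, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind the synthetic-cohort
generator, the numerical conventions of each analysis engine, and what the
package deliberately does not attempt. It is the reference for every choice
that is not obvious from the function documentation.

## 1. The screening problem

In vitro embryo production (IVP) in cattle elevates the risk of large
offspring syndrome (LOS), a fetal overgrowth condition. The screening
design implemented here has three layers:

1. **Weight phenotyping.** A fetus is called overgrown when its weight is
   at or above the 97th percentile of sex-matched artificial-insemination
   (AI) control weights collected on the same gestation day.
2. **Ultrasonographic fetometry.** At day 55 of gestation six standard
   measurements — abdominal diameter (AD), abdominal height (AH),
   crown-rump length (CRL), head length (HL), thorax height (TH), thorax
   diameter (TD) — are multiplied into a product index and screened against
   the maximum product observed among controls.
3. **Maternal leukocyte transcriptomes.** Blood drawn from dams carrying
   extreme-overgrowth fetuses versus the rest is profiled by RNA-seq;
   differential expression is assessed with two analysis configurations
   and only the intersection of their significant sets is reported, and
   stable genes are selected as qPCR references.

## 2. Phenotyping conventions

- The percentile is Hyndman–Fan **type 7** (the R default): for sorted
  controls $x_{(1)} \le \dots \le x_{(n)}$, $h = (n-1)q + 1$ and
  $Q = x_{(\lfloor h \rfloor)} + (h - \lfloor h \rfloor)
  (x_{(\lceil h \rceil)} - x_{(\lfloor h \rfloor)})$. No claim is made
  that this matches the convention of any other statistics package; the
  choice is recorded here and tested against the hand formula.
- Classification is **inclusive** (`weight >= threshold` is overgrown),
  thresholds are estimated per sex and per day and never pooled, and AI
  controls are never labelled overgrown regardless of weight.
- The sex-ratio test is the exact one-sided binomial tail
  $P(X \le k \mid n, 1/2) = 2^{-n} \sum_{i=0}^{k} \binom{n}{i}$, computed
  via `pbinom` and verified against term-wise enumeration.

## 3. Fetometry

The product index $P = AD \cdot AH \cdot CRL \cdot HL \cdot TH \cdot TD$
deliberately excludes the biparietal diameter. Two threshold modes exist:
`"control-max"` (the largest product among AI controls; flagging is
strictly `>`) and `"fixed"` (default 100, a round reference line for
plots). Correlations are Pearson with the usual $t$-based two-sided
p-value.

## 4. The synthetic cohort generator

All generators draw from substreams derived by hashing a stream name with
the user seed, so enlarging one stream (say, the gene panel) never
perturbs another (the cohort), and the caller's RNG state is saved and
restored.

### 4.1 Weights

Control weights are lognormal, moment-matched to the published
control means and SDs per sex and day. IVP fetuses receive, with
probability `pi_los` (default 0.3), a lognormal overgrowth multiplier
(`meanlog = log(1.4)`, `sdlog = 0.25`). At day 55 the multiplier is
attenuated by `growth_divergence_d55 = 0.25` — overgrowth has only begun
to diverge at the time of the ultrasound exam — while at later days it
applies in full.

### 4.2 Cohort structure

| parameter | default | rationale |
|---|---|---|
| `n_ai_dams` | 12 | published control herd size |
| `n_ivp_dams` | 48 | yields IVP cohorts near the published sizes |
| `embryos_per_ivp_transfer` | 2 | two embryos per recipient |
| `implantation_prob` | 0.56 | chosen so the expected twin fraction among pregnancies, $p/(2-p)$, matches the observed twin fraction; a binomial implantation model cannot match the pregnancy rate and the twin fraction simultaneously, and the twin fraction is what downstream analyses consume |
| `female_loss_d105` | 0.6 | fraction of IVP female conceptuses lost by day 105, reproducing the female-depleted late sex ratio while day-56 ratios stay near 1:1 |
| `pi_los` | 0.3 | overgrowth mixture weight |

### 4.3 Biometry

Measurements follow cube-root allometry: each measurement equals a fixed
base shape times $(w_{55}/w_{\mathrm{ref}})^{1/3}$ times lognormal
measurement noise (`measurement_cv = 0.05`), where $w_{55}$ is the day-55
weight implied by the fetus's growth track. With noise and overgrowth
disabled this is exact, which the tests exploit.

### 4.4 Counts

Counts are negative binomial with gene-wise dispersions drawn from a
Gamma(2, rate 20) prior, library sizes uniform on `libsize_range`, and a
planted block of `n_de_genes` differential genes (log2 fold change
`de_log2fc` between extreme-dam samples and the rest). Two structural
features matter:

- **Dam expression profiles.** Each dam receives a per-gene normal effect
  with SD `dam_effect_sd`, shared by both of her samples. A scalar per-dam
  effect would be removed by size-factor normalization; a per-gene profile
  is what makes samples cluster by animal, as required of the generator.
- **Stable genes.** `n_stable_genes` (default 20) housekeeping-like genes
  are highly expressed, nearly dispersion-free and excluded from the dam
  profiles, so the reference-gene screen has a real target population.

### 4.5 What the generator does not emulate

No read-level simulation (no GC or length bias, no multimapping), no
batch/lane effects, no unwanted-variation structure beyond the dam
profiles, and no attempt to reproduce any real count matrix. The
generator exists to give the engines data with known truth, not to mimic
a particular experiment.

## 5. Normalization and clustering

- **Median-of-ratios**: the per-sample median, over genes positive in all
  samples, of count over gene geometric mean. Scaling a library by $c$
  scales its factor by exactly $c$.
- **TMM**: gene-wise log2 ratios against a reference sample (the one whose
  upper quartile of library-scaled positive counts is closest to the mean
  upper quartile), doubly trimmed (30% of M-values, 5% of A-values per
  tail, rank-window convention `floor(n*trim)+1 … n-floor(n*trim)`), then
  combined by a precision-weighted mean with inverse asymptotic binomial
  variances; factors are rescaled to geometric mean 1 and are depth-free.
  The test suite cross-checks against `edgeR::calcNormFactors` to ~1e-3.
- **Upper-quartile**: type-7 75th percentile of positive counts, rescaled
  to geometric mean 1.
- **UPGMA clustering** of sample columns under euclidean distance, with
  the Lance–Williams average-linkage update. Distance ties are broken by
  the lexicographically smallest pair of minimum original column indices,
  making the tree fully deterministic; the result is a genuine `hclust`
  object and can be exported as Newick with branch lengths equal to
  height differences.

## 6. The NB-LRT engine

One negative-binomial GLM likelihood-ratio engine is run in two
configurations, and the significant sets are intersected:

| | backend A | backend B |
|---|---|---|
| offsets | `log(colSums(counts) * TMM factor)` | `log(median-of-ratios factor)` |
| dispersion | Cox–Reid adjusted profile likelihood, shrunk toward the common value with `prior_df = 10` | gene-wise Cox–Reid, `prior_df = 0` |

Numerical conventions, all tested:

- IRLS with weights $\mu/(1+\phi\mu)$; log-likelihood via
  `dnbinom(size = 1/phi)` with a Poisson limit for tiny $\phi$.
- Dispersion maximized over $\log\phi \in [\log 10^{-6}, \log 20]$ with
  `optimize` tolerance 0.01; shrinkage on the log scale weighted by
  `prior_df` against the residual degrees of freedom.
- The LRT statistic $2(\ell_{\mathrm{full}} - \ell_{\mathrm{reduced}})$
  is clamped at 0; the reduced design must be nested in the full design
  (checked by rank), and the chi-square degrees of freedom equal the
  column-count difference.
- All-zero genes get $p = 1$, log2 fold change 0, and status
  `"untestable"`; `log2FC` is the first coefficient dropped from the full
  design, divided by $\log 2$.
- Multiplicity correction is Benjamini–Hochberg.

Calibration on 2000 simulated null genes keeps the empirical type-I error
at $\alpha = 0.05$ inside the 95% Monte-Carlo band; this is asserted in
the acceptance tests rather than assumed.

Reference genes for qPCR must look null in **both** backends (backend A
adjusted p at the top of the scale, `>= 0.99`, operationalizing
"FDR = 1"; backend B adjusted p `> 0.8`) and have a coefficient of
variation of normalized counts `<= 0.10`. On small synthetic panels this
triple criterion may select few or no genes; that is by design, not a
failure.

## 7. qPCR

$\Delta CT$ is the target CT minus the geometric mean of the reference
CTs; $\Delta\Delta CT$ centres on the arithmetic mean baseline
$\Delta CT$, and the fold is $2^{-\Delta\Delta CT}$. Centring on the mean
makes the geometric mean of baseline folds exactly 1. Technical
replicates, when present, are averaged arithmetically first and the fact
recorded in the result. An alternative `ref_mode = "linear"` aggregates
linearized quantities $2^{-CT}$ instead, which reduces to the arithmetic
mean of reference CTs; both phrasings circulate in protocols and they
differ by a small fraction of a cycle.

## 8. Problem sizes and limitations

The engines are written for panel-scale problems (hundreds to a few
thousand genes, tens of samples); the UPGMA implementation is the
straightforward $O(n^3)$ scan, fine for sample counts in the dozens. No
plotting, no database, no web service, no amplification-efficiency
correction for qPCR, and the percentile convention is documented but not
claimed to match any particular external software.
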