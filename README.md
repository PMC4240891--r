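# immunemeta

Immune metagene scoring and neoadjuvant chemotherapy response modelling for
breast tumor expression cohorts.

## The problem

Tumor-infiltrating immune cells leave coordinated transcriptional footprints
in bulk expression profiles. Three such footprints — a B-cell/plasma-cell
signature (**B/P**), a T-cell/natural-killer signature (**T/NK**) and a
monocyte/dendritic-cell signature (**M/D**) — together with a proliferation
signature (**P**) can be summarized per tumor as *metagene scores*: the mean
log2 intensity over the signature's member genes, with multi-probe genes
averaged to gene level first. This package provides everything needed to ask
whether those scores predict **pathologic response** to neoadjuvant
chemotherapy (pCR or residual cancer burden class 0–1) in pooled microarray
cohorts:

* **Scoring** — signature loading with overlap-probe exclusion, probe→gene
  collapsing, two-stage averaging, mean-centering, tertile stratification.
* **Preprocessing** — duplicate-profile removal by pairwise correlation,
  low-signal outlier-array exclusion, common-probe restriction across
  platforms, quantile normalization, and empirical-Bayes (ComBat) batch
  adjustment across datasets.
* **Subtyping** — nearest-centroid intrinsic subtype assignment (Basal,
  LumA, LumB, HER2-E, Claudin-low, Normal-like) by Spearman correlation.
* **Modelling** — logistic regression with Wald CIs and likelihood-ratio
  tests: univariate models, immune models adjusted for proliferation and
  subtype, analyses stratified by proliferation tertile or subtype,
  LRT-based stepwise selection, treatment-by-response chi-square, and
  inter-metagene Spearman correlations.
* **Simulation** — a synthetic-cohort generator whose defaults emulate the
  pooled study population (six subtypes at their observed frequencies, a
  Gaussian-copula latent structure with Spearman(M/D, T/NK) = 0.80, a
  calibrated ≈27% response rate, probe multiplicity, batch shifts), so the
  entire pipeline runs and is tested offline.

The central model is ordinary binomial logistic regression. For a metagene
score *m* entered as a continuous covariate,

    logit P(response = 1) = β0 + β1 m (+ γ·P + δ·subtype)

and results are reported as odds ratios exp(β1) per unit of raw mean log2
intensity with 95% Wald intervals; p-values are likelihood-ratio tests
against the model without the term.

## Worked example

```r
library(immunemeta)

cfg    <- sim_config(seed = 20140101)      # default synthetic cohort, n = 680
cohort <- simulate_cohort(cfg)
x      <- combat_adjust(cohort$expr, cohort$batch)
scores <- score_metagenes(x, cohort$signatures)
d      <- prepare_model_data(scores, code_response(cohort$clinical))

univariate_response_table(d)
```

```
              variable odds_ratio ci_low ci_high  p_value   n converged
1                  B/P      2.007 1.6672   2.417 4.40e-15 680      TRUE
2                 T/NK      2.492 2.0311   3.058 1.81e-22 680      TRUE
3                  M/D      2.729 2.2074   3.373 6.24e-26 680      TRUE
4                    P      1.974 1.6686   2.335 9.78e-18 680      TRUE
5              subtype         NA     NA      NA 4.79e-16 680      TRUE
...
```

Each row is one simple logistic model: e.g. a one-unit increase in the M/D
score multiplies the odds of pathologic response by 2.73 (95% CI 2.21–3.37),
and the subtype factor as a whole is strongly associated with response
(LRT p ≈ 5e-16). Note these ORs are *marginal* fits to a cohort generated
with all four latent effects active simultaneously on correlated factors, so
they sit above the per-factor conditional effects used to generate the data.
The inter-metagene correlation structure the simulator is calibrated to:

```r
round(spearman_matrix(d[, c("BP", "TNK", "MD", "P")]), 2)
#>        BP  TNK   MD     P
#> BP   1.00 0.58 0.60 -0.01
#> TNK  0.58 1.00 0.80  0.02
#> MD   0.60 0.80 1.00  0.04
#> P   -0.01 0.02 0.04  1.00
```

A stepwise model (LRT entry/stay at 0.05/0.05) over ER status, the four
metagenes and subtype:

```r
stepwise_select(d, c("er_neg", "P", "BP", "TNK", "MD", "subtype"))
#> stepwise_result: selected MD + P + subtype + TNK + BP [n = 680]
```

`run_analysis(out_dir, config)` composes all of the above — simulate,
deduplicate, outlier-filter, normalize, batch-adjust, score, classify, code
response, fit every table — and writes the report CSVs plus a JSON run
manifest with the sample-count filtering chain.

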