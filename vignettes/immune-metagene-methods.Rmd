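---
title: "Immune metagenes and chemotherapy response: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune metagenes and chemotherapy response: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunemeta)
```

## Overview

`immunemeta` quantifies four transcriptional programs in bulk breast-tumor
expression profiles — B-cell/plasma-cell (B/P), T-cell/NK (T/NK),
monocyte/dendritic (M/D) and proliferation (P) metagenes — and models their
association with pathologic response to neoadjuvant chemotherapy. This
vignette documents the statistical machinery, the tunable parameters, the
synthetic-cohort generator, and the design choices made where several
defensible options existed.

## Metagene scoring

A metagene is a fixed list of (probe set, gene symbol) pairs. Scoring is a
two-stage mean on the log2 intensity scale:

1. probe sets interrogating the same gene are averaged to one gene-level
   value per sample (`collapse_probes()`);
2. the metagene score is the mean over member genes (`score_metagene()`).

Because both stages are plain arithmetic means, scoring is invariant to
probe and sample order and *affine-equivariant*: adding a constant to all
intensities shifts every score by that constant. Three probe sets shared
between the T/NK and M/D lists are removed from both metagenes at load time
(`DEFAULT_EXCLUSION_PROBES`) so the two scores measure distinct infiltrates;
after exclusion the loader enforces that no probe maps to two metagenes.
Published probe counts for such signatures are sometimes quoted before and
sometimes after overlap removal, so `print.signature_set()` reports both
counts rather than asserting either.

Missing probes are skipped with a message when at least half of a
metagene's probes are present; below that the call fails with a coverage
error, because cohorts restricted to a common probe panel should essentially
never lose half a signature — partial coverage signals an upstream join
problem, not normal variation.

**Tertiles.** `assign_tertiles()` thresholds at the empirical 33.33rd and
66.67th percentiles (type-7 linear interpolation), with scores at or below
a threshold going to the lower group. This is deterministic, yields
near-equal thirds for continuous scores, and — being rank-based — gives
labels invariant under any strictly monotone transform of the scores.

**Centering.** `mean_center()` exists for cross-cohort distribution
comparisons only. All model fits use the raw, uncentered averages, so odds
ratios are per unit of raw mean log2 intensity; this unit convention is
recorded in the function documentation because "per unit of score" is
meaningless without it.

## Preprocessing

The intended stage order is: duplicate removal → outlier exclusion →
common-probe restriction → quantile normalization → batch adjustment. Each
stage is a pure function returning the transformed matrix plus a
machine-readable report.

* `dedup_profiles()` removes the later-ordered member of any sample pair
  with Pearson correlation above 0.99 (first occurrence kept — a stable,
  documented rule). The 0.99 default reflects that technical replicates on
  these array platforms correlate above 0.99 while biological replicates do
  not.
* `filter_outliers()` drops samples whose median intensity falls more than
  3 MADs below the cohort median of medians. This is a declared surrogate
  for manual inspection of signal-intensity distributions, not a
  reconstruction of any particular study's criterion.
* `quantile_normalize()` (via limma) forces every sample onto the mean
  of sorted vectors; it requires a complete matrix and is idempotent.
  Missing values are never imputed anywhere in the package — ingest fails
  loudly instead.
* `combat_adjust()` (via sva) performs parametric empirical-Bayes
  location/scale batch correction with an intercept-only model, matching
  the method's default use when adjustment precedes all modelling. A
  single-batch input is returned unchanged; a batch with fewer than two
  samples is an error naming the batch.

## Subtype assignment

`classify_subtype()` assigns each sample the intrinsic subtype whose
centroid has the highest Spearman correlation over shared panel genes,
requiring at least 50% panel coverage. Rank correlation makes calls
invariant to monotone per-sample transforms; ties break by centroid column
order with a warning. Claudin-low is treated as a sixth centroid in the
same pass — a deliberate simplification of the published two-stage
predictor, adequate here because subtype enters the analysis only as a
covariate and stratification variable, and the simulator generates
claudin-low tumors from their own centroid anyway. Centroids are data, not
code: they load from a TSV (`load_centroids()`), and tests use synthetic
centroids so no external file is needed.

## Response coding

`code_response()` derives the binary outcome: residual cancer burden (RCB)
class 0 or 1 codes 1; RCB 2 or 3 codes 0; when RCB is absent a pCR flag of
yes/no codes 1/0; with neither, the response is missing and the sample is
censored from the models (complete-case analysis throughout). When RCB and
the pCR flag contradict (RCB 0 with "no pCR", or RCB ≥ 1 with "pCR"), RCB
wins with a warning — it is the finer-grained pathology measure. The coding
is idempotent and row-order independent.

## The regression layer

All fits are maximum-likelihood binomial logistic regressions (IRLS, score
tolerance 1e-10, ≤100 iterations). `fit_logistic()` reports per-term odds
ratios with 95% Wald intervals; `lrt_pvalue()` compares nested fits on the
same samples via twice the log-likelihood difference against a chi-square.
Perfect or quasi-separation (boundary fitted probabilities together with
diverging coefficients or exploding standard errors, as happens when a
subtype level has zero responders) is flagged `converged = FALSE` rather
than hidden; singular designs raise an error naming the collinear terms.

Table builders mirror the analysis plan:

* `univariate_response_table()` — one simple model per metagene plus one
  model with subtype categorical (reference level: Normal-like, so subtype
  odds ratios read "versus normal-like"). ER status, where used, is coded
  negative-versus-positive.
* `adjusted_response_table()` — each immune metagene adjusted for P and
  subtype; the p-value is the LRT for the immune term.
* `stratified_analysis()` — tertile labels are computed on the *full*
  scored cohort (including response-missing samples) and models fit within
  the annotated subset of each stratum; this mirrors how stratum sizes in
  such analyses sum to the annotated total while being unequal. Strata with
  fewer than 10 annotated cases are reported with their headers
  (n, responders, nonresponders) but skipped for fitting.
* `stepwise_select()` — forward selection with backward removal using LRT
  p-values at entry/stay thresholds 0.05/0.05. Published stepwise analyses
  of this kind often leave the software's test choice (score, Wald or LRT)
  unstated; the LRT was chosen here for consistency with every other
  p-value in the package, and the thresholds match the convention that
  retained terms be significant at 0.05. Candidates are scanned in
  lexicographic order, which doubles as the tie-break, making selection
  fully deterministic. Factors enter and leave as whole
  (multi-degree-of-freedom) terms; candidates that are constant or
  collinear given the current model are passed over — this is what allows
  six mutually exclusive subtype indicators to be offered simultaneously,
  as in the 11-variable specification, without the design ever becoming
  singular.
* `chisq_independence()` — Pearson chi-square without continuity
  correction; `treatment_class()` collapses the eight regimen labels to
  four classes (anthracycline only, anthracycline+paclitaxel,
  anthracycline+docetaxel, taxane only; unspecified excluded) for the 4×2
  treatment-by-response test. The exact 4-level grouping used in prior
  analyses of pooled regimens is not standardized; this one groups by the
  pharmacologically distinct combinations.

Complete-case handling is per-model: each table uses the maximal annotated
subset for its own variables, so the effective n legitimately differs
between the univariate tables and the stepwise models.

## The synthetic cohort

`simulate_cohort()` generates data with the statistical structure the
analysis assumes — not a transcriptome emulator. Its defaults *are* the
study conditions; they were fixed once, from the cohort structure the
analysis targets, and are not tuning knobs.

* **n = 680** samples, the response-annotated panel size. Missingness rates
  for ER/HER2/response default to zero: the simulator models the analysis
  subset, and missingness plumbing is exercised separately (a configurable
  fraction of samples, 10% by default, carries only the pCR flag so the
  RCB-missing coding path runs on every cohort).
* **Subtype frequencies** Basal .30, LumA .31, LumB .19, HER2-E .11,
  Claudin-low .07, Normal-like .02.
* **Latent structure**: four factors (B/P, T/NK, M/D, P), unit variance,
  drawn from a Gaussian copula. Spearman targets are converted to Pearson
  via 2·sin(πρ/6). The M/D–T/NK entry is 0.80 (the one observed value);
  the remaining immune–immune entries default to 0.60 and immune–P to 0 —
  explicitly assumptions, chosen so the immune block is substantially but
  not degenerately collinear while proliferation stays orthogonal to it.
* **Subtype shifts**: the proliferation latent is shifted per subtype
  (Basal +0.8, HER2-E +0.6, LumB +0.5, Claudin-low 0, LumA −0.5,
  Normal-like −0.8), making proliferative subtypes proliferative and
  creating the subtype–P confounding the adjusted models exist to handle.
  Immune latents carry no subtype shift (an assumption; it keeps the
  M/D–T/NK calibration independent of subtype mixing).
* **Response model**: Bernoulli with
  logit p = β0 + Σ β·latent + subtype terms, with per-unit log odds ratios
  log(1.60), log(1.59), log(1.69), log(2.54) for B/P, T/NK, M/D, P and
  subtype terms log(1.33), log(1.12), log(1.08), log(0.18), log(0.55)
  versus Normal-like. `calibrate_intercept()` root-finds β0 so the marginal
  response rate equals 0.27 over a 1e5-draw Monte-Carlo population (with
  all effects zero this reduces to logit(0.27) ≈ −0.9946 exactly).
* **Measurement layer**: each signature gene is its latent plus a fixed
  N(8,1) baseline and N(0, 0.5) gene noise; each gene has 2 probe sets with
  fixed N(0, 0.3) affinities and N(0, 0.5) probe noise — typical residual
  log2-scale noise for these arrays. Fifty marker genes with
  subtype-specific N(8,1) means drive the centroid classifier; the
  generative means are returned as the centroid set. Five batches receive
  independent per-probe N(0, 0.3) additive shifts.
* **Determinism**: one seed threads through intercept calibration and
  cohort generation; the same seed reproduces every output byte for byte.

Because effect sizes act on the noise-free latents, measurement noise
attenuates fitted odds ratios slightly (by ≈ 1–2% here, the noise variance
of a score being the per-gene noise divided by the gene count). Parameter-
recovery tests therefore check 95% CI coverage against *pseudo-true*
coefficients obtained by fitting the same model to one very large simulated
cohort (n = 40,000) under the identical measurement protocol — the
attenuated large-sample limit — rather than against the noise-free inputs.

**What the simulator does not emulate**, and hence what green tests do not
establish about real data: full-transcriptome covariance, probe-level
chemistry and saturation, platform differences beyond a shared panel,
non-additive batch effects, informative missingness, and any coupling
between treatment and response (treatment is drawn independently, matching
the null association the chi-square test probes). Passing tests show the
*machinery* is correct under the declared generative model, not that the
biological effect sizes transfer.

## Numerical choices and degenerate inputs

* Quantile thresholds: type-7 (linear interpolation) empirical quantiles.
* All-equal scores: tertile assignment puts every sample in the low group
  under the ≤ rule and warns.
* Constant score vectors: their Spearman rows/columns are `NA` with a
  warning rather than an arbitrary number.
* LRT statistics are floored at 0 (they can go microscopically negative
  through floating-point); identical models give p = 1.
* Stepwise termination: the loop stops when no entry or removal occurs, or
  when a previously visited model recurs (enter/remove cycles are possible
  with correlated candidates at equal thresholds).
* Problem sizes in the test suite (cohorts of 150–680, 200 recovery
  replicates, 100 selection replicates, 40,000-sample pseudo-truth fit)
  were chosen to keep Monte-Carlo error well inside the asserted bounds
  while the whole suite completes in a couple of minutes.

## Known limitations

* The claudin-low single-pass centroid treatment is an approximation; a
  faithful two-stage predictor would need the published cell-line centroids.
* The shipped M/D signature fixture is synthetic in its probe identifiers
  and in the gene symbols that are not part of the MHC-class-II annotation;
  real signature lists load through the same TSV interface.
* Stepwise selection inherits the instability of all threshold-based
  selection: terms near p = 0.05 can flip with the test variant (LRT vs
  score vs Wald), so borderline selections should be read as such.
* RMA summarization from raw CEL files is out of scope; the package accepts
  normalized log2 matrices and offers quantile normalization as the
  in-package stand-in.
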