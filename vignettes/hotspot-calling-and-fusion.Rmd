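---
title: "Hotspot ctDNA calling, score fusion, and the synthetic cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hotspot ctDNA calling, score fusion, and the synthetic cohort model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcedfusion)
```

## The detection problem

Circulating tumor DNA (ctDNA) is a minor fraction of plasma cell-free DNA
(cfDNA). A deep amplicon panel targets a few hundred recurrent ("hotspot")
somatic mutations; at ~100,000x coverage, a mutation present at a variant
allele fraction (VAF) of a few parts in ten thousand still yields tens of
supporting reads. The difficulty is that PCR and sequencing error produce
alternate reads at comparable rates, and clonal hematopoiesis (CHIP)
contributes genuine somatic mutations of blood-cell origin that are not
tumor-derived. `mcedfusion` implements the resulting decision pipeline:

1. **Coverage QC** — an amplicon observed below a minimum depth
   (default 10,000 reads, strict `<`) is failed and excluded from calling.
2. **Limit of detection (LOD)** — estimated from a titration series of
   reference standards (expected VAFs 3%, 0.5%, 0.1%, 0.05%, 0%): the LOD
   is the smallest level whose detection fraction reaches 0.95 with the
   median observed VAF within 2-fold of expected. Without titration data
   the model defaults to `5e-4`, the lowest non-zero level of this design.
3. **Per-site baseline cutoffs** — background error differs between sites,
   so a single global threshold either loses sensitivity or floods the
   panel with false positives. From a cohort of negative-control plasmas
   the model learns, per site, `mean + k * SD` of the observed VAFs
   (default `k = 3`; an empirical-quantile alternative, `q = 0.999`, is
   provided). A site never observed above zero keeps cutoff 0. The
   effective threshold at a site is always `max(lod, cutoff)`.
4. **Calling** — an observation is a PASS mutation iff its depth passes QC
   and its VAF is at or above the effective threshold (inclusive `>=`).
5. **CHIP filtering** — for candidate-positive samples, any PASS call whose
   matched white-blood-cell (WBC) VAF also reaches the same effective
   threshold is re-flagged `CHIP` and removed. Symmetric thresholds are the
   minimal reading of "same protocol on WBC gDNA"; WBC evidence is modeled
   as available conditionally on candidate positivity, and a
   candidate-positive sample without WBC data follows a configurable
   policy (`flag`, the default, or `drop_sample`).
6. **Sample verdict** — ctDNA-positive iff at least one PASS mutation
   remains; the sample mean VAF is the arithmetic mean over PASS calls
   only.

Every rejected candidate keeps exactly one filter label (`LOW_COVERAGE`,
`BELOW_LOD`, `BELOW_BASELINE`, `CHIP`), so call sets are auditable.

## Fusion with the SPOT-MAS score and evaluation

Each sample may carry a SPOT-MAS score, the cancer-probability output of a
multimodal methylation/fragmentomics classifier, consumed here purely as a
number in [0, 1]. The score arm is positive when the score **strictly
exceeds** 0.60; the hotspot arm uses the calibrated positivity flag (or, in
concordance mode, a mean-VAF cutoff); the combined call is the OR of the
two arms. The mixed boundary semantics are deliberate: the score rule is
"exceeds", the VAF rules are inclusive (`>=`).

`evaluate_performance()` reports sensitivity per stratum (overall, per
cancer type, per stage I / II / IIIA / unknown — unknown-stage patients
form their own stratum and remain in the overall figure) and specificity
on controls (never stage-stratified), each with a Wilson score interval.
The Wilson interval inverts the score test; we use
`z = qnorm(0.975) = 1.959964` for 95% intervals. By construction the OR
rule dominates: combined sensitivity is at least each arm's, combined
specificity at most each arm's. Samples without a score are `unevaluable`:
excluded from score-arm and concordance metrics, retained for hotspot-only
evaluation. Gene-level summaries count each patient at most once per gene;
recurrent sites are those with PASS calls in at least two patients. Cohort
demographics are compared with the Mann-Whitney U test (ages; normal
approximation with tie correction) and the Yates-corrected Chi-squared
test (sex).

## What the synthetic cohorts emulate

No patient data ships with the package. `generate_cohort()` produces
cohorts with the statistical structure the pipeline assumes, plus a ground
truth channel for testing:

* **Design**: 570 calibration plasmas, 304 evaluation controls, and 255
  patients across five cancer types (breast 64, colorectal 59, gastric 62,
  liver 29, lung 41), with per-type stage composition; a 700-site panel
  over 23 cancer genes.
* **Shedding**: each patient is a ctDNA shedder with a type-specific
  probability (defaults: liver 0.965, colorectal 0.593, lung 0.537,
  gastric 0.419, breast 0.313). Shedders carry `1 + Poisson(0.7)` planted
  mutations with VAFs log-uniform on `[5e-4, 0.2]`. The published
  prevalences fix only the shedder probabilities; the VAF law and mutation
  multiplicity are modeling choices (log-uniform spreads mass evenly
  across the detectable decades, which is the stressful case for
  threshold calibration).
* **Noise**: per-site error rates are drawn once per panel from
  `Beta(4, 39996)` (mean 1e-4) and alternate counts are binomial. The
  shape is chosen so the assay operates in its published regime: most
  sites sit far below the LOD while an occasional site approaches it, and
  baseline calibration then holds control-level positivity well under 2%
  (empirically ~0.5%). A heavier tail (e.g. `Beta(2, .)`) puts a dozen
  sites right at the LOD and corresponds to an assay that would have
  blacklisted those amplicons.
* **Depth**: negative binomial, mean 100,000, size 20; amplicons fail with
  probability 0.01 (Poisson mean 4,000 reads). A real consequence: a
  shedder whose only planted mutation lies on a failed amplicon is
  undetectable, which bounds attainable sensitivity ~0.5% below the
  shedding probability.
* **CHIP**: 5% of cancer and control samples carry one CHIP mutation,
  cfDNA VAF log-uniform on [0.002, 0.05], mirrored in the matched WBC
  table at a ratio drawn in [0.5, 2]. Calibration plasmas are generated
  CHIP-free: they stand for vetted negative reference material, and
  contaminating them would conflate two failure modes in tests.
* **Scores**: class-conditional `Beta` distributions with concentration 6,
  solved numerically (monotone root finding on the mean) so that
  `P(score > 0.60)` equals each class's configured rate (controls 0.016;
  breast 0.516, colorectal 0.576, gastric 0.629, liver 0.966, lung 0.80 —
  the last three derived from the published concordance quadrants).
  Scores and shedding are independent given the class; stage is
  independent of shedding by default.

What passing tests on this generator do **not** show about real data:
error rates here are binomial and site-independent, with no strand bias,
UMI structure, batch effects, or sample-quality covariates; CHIP has a
single-site signature rather than a gene spectrum (DNMT3A/TET2/ASXL1);
scores are exchangeable within class rather than correlated with tumor
burden. The pipeline's thresholds transfer to real data only after
recalibration on real negative controls and titrations.

## Validation design and numerical choices

The test suite validates the two stochastic layers separately, which is
more powerful than any single end-to-end comparison:

* the generator's shedding channel is compared to its configured
  probabilities over 200 cohorts (shedding depends only on cohort
  composition, so a minimal panel isolates it cheaply);
* the pipeline is then required to recover the *realized* truth on 20
  full-size default cohorts with bounded slack: at most 2% of true
  shedders missed and at most 2% of non-shedding patients falsely
  positive (observed: well under 1% each — the dominant miss channel is
  the amplicon-failure mechanism above).

Calling is additionally checked for exact agreement with a brute-force
nested-loop re-implementation on small cohorts, and the Wilson interval
against direct root-finding inversion of the score test to 1e-9.

Numerical conventions: VAFs are fractions in [0, 1] everywhere internally
and percentages only in reports (rounded half away from zero to 1
decimal); coordinates are 1-based VCF convention; depth QC is strict `<`,
VAF thresholds inclusive `>=`, the score threshold strict `>`. Degenerate
inputs are handled explicitly: zero-depth observations travel the
LOW_COVERAGE path rather than producing NaN VAFs; a site with fewer than
two usable negatives falls back to the LOD with a warning; an empty
stratum reports `n = 0` with no interval rather than erroring; a
titration whose 0% blank reaches the detection criterion aborts LOD
estimation (the noise floor exceeds the assay's resolution).

Problem sizes in the shipped tests (full-size cohorts for 20 seeds,
reduced panels for high-replication property loops) were chosen to give
each check 3-sigma resolution at interactive runtimes; all are
regenerated in code at test time.

## Known limitations

* The baseline rule assumes the negative-cohort VAF distribution at a site
  is stable; `mean + 3 SD` under-covers when depth varies strongly between
  samples, which is why the LOD floor matters at quiet sites.
* LOD estimation scores a detection as "any alternate read at passing
  depth", which is only meaningful on clean reference material; it will
  (by design) refuse to estimate an LOD from noisy input.
* CHIP filtering requires the variant to be visible in WBC at the same
  threshold; CHIP clones below the WBC detection limit pass through.
* Fusion consumes the SPOT-MAS score as given; no attempt is made to model
  or retrain the underlying classifier, and samples without a score are
  simply not fusion-evaluable.

## A worked run

```{r, eval = FALSE}
cfg <- sim_config(seed = 1)
cohort <- generate_cohort(cfg)

neg <- subset(cohort$cfdna,
              sample_id %in% subset(cohort$samples,
                                    group == "calibration_negative")$sample_id)
model <- hotspot_calibration(neg, cohort$panel)

eval_counts <- subset(cohort$cfdna, !sample_id %in% neg$sample_id)
calls <- predict(model, eval_counts, wbc = cohort$wbc)

combined <- classify_combined(calls, cohort$samples)
evaluate_performance(combined, cohort$samples, arm = "combined")
```
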