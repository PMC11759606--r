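---
title: "Weakly supervised pathomics: from tiles to metastasis and survival models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised pathomics: from tiles to metastasis and survival models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the modelling idea

Routine H&E sections of breast-cancer resection specimens carry prognostic
information that is expensive to extract by immunohistochemistry. `pathomil`
implements a whole-slide pipeline that uses only *slide-level* labels — the
patient's estrogen-receptor (ER) status — to train a *patch-level*
classifier, and then aggregates the patch outputs into a fixed-length slide
representation used for two downstream tasks: metastasis classification and
overall-survival modelling.

The weak-supervision step is the crux: every 512 × 512 tile of a slide
inherits that slide's ER label. Individual tiles are therefore noisily
labelled, but a classifier trained over many tiles still learns
tissue patterns associated with ER status, and the *distribution* of its
per-tile likelihoods is a stable slide-level signature even when individual
tile predictions are unreliable. This is a form of multiple-instance
learning with distribution-based (rather than attention-based) pooling.

The pipeline stages, each its own module with a stable interface:

1. **Tiling** — non-overlapping 512 × 512 tiles anchored at the image
   origin; partial edge tiles are discarded rather than padded so every
   tile honours the fixed-size contract. A tile is excluded as background
   iff the fraction of pixels with all RGB channels ≥ 220 strictly exceeds
   0.8; both constants are package choices (the underlying rule is
   "exclusively white background") and are arguments.
2. **Reinhard colour normalization** — per-channel mean/SD matching in
   Ruderman's lαβ space (log-LMS decorrelated axes), the space of the
   original colour-transfer method, rather than CIELAB. Each channel is
   mapped through `(x − μ_tile)·(σ_ref/σ_tile) + μ_ref`; a near-constant
   channel (σ < 1e-8) is shifted without scaling. Background exclusion runs
   *before* normalization (cheaper, and white tiles would otherwise distort
   nothing but their own statistics); the order is configurable. Unless a
   reference is supplied, the statistics of the first non-background tile
   of the cohort serve as the reference and are written to
   `reinhard_ref.json`.
3. **Patch model** — per-tile Z-score normalization of the RGB channels
   (population SD, ε-guarded; per-tile rather than dataset-wide, which is
   the configurable default), optional random-crop/flip augmentation at
   train time, and a classifier trained with plain SGD on softmax
   cross-entropy under the cosine-decay schedule
   η(t) = η_min + ½(η_max − η_min)(1 + cos(π·t/T_i)) with defaults
   η_max = 0.01, η_min = 0, T_i = 50.
4. **Fusion** — two independent slide encodings of the patch likelihoods,
   concatenated with deterministic names into exactly
   206 = 2 × (101 + 2) features per slide:
   * *PLH*: a histogram over 101 equal-width bins on [0, 1] (edges k/101,
     last bin closed), count-normalized to sum to 1 so slides with
     different tile counts are comparable;
   * *BoW TF-IDF*: each patch quantized to one of the same 101 "words";
     tf(w) = count(w)/bag size, idf(w) = ln((1+N)/(1+df(w))) + 1 fitted on
     the N training slides and frozen for test slides (the smoothed "+1"
     convention);
   * per pipeline, two predictive label features: the majority-vote
     predicted label (ties resolve to 1) and the indicator that the mean
     likelihood is ≥ 0.5. The exact construction of these two features and
     the BoW codebook are under-determined design points; using the
     histogram bins as the vocabulary keeps the two pipelines comparable
     and forces exactly 101 probability features each.
5. **Selection** — a greedy Pearson-redundancy filter in canonical column
   order: a column is dropped iff its *absolute* correlation with any
   already-kept column strictly exceeds 0.9 (anti-correlated duplicates
   are as redundant as correlated ones). Constant columns are dropped with
   a log entry. The filter is fitted on training rows only, to avoid
   test-set leakage, and is idempotent, threshold-monotone and row-order
   independent (all property-tested).
6. **Metastasis models** — random forest, XGBoost, and an L2-regularised
   logistic model on the selected features. The metric panel reports
   accuracy, rank-statistic AUC with a DeLong 95% CI (chosen over the
   bootstrap for determinism; 0/0 threshold metrics report 0 and are
   flagged), sensitivity, specificity, PPV and NPV at a Youden-optimal
   threshold determined on the training cohort and frozen for test.
7. **Survival** — an L2-penalized Cox model. The penalty constant
   `c = 0.3` is interpreted as the weight of `c/2·‖β‖²` added to the
   negative Breslow partial log-likelihood (the parameterization is
   otherwise under-determined; this reading is implemented via
   `survival::coxph` with a `ridge(theta = c)` term, Breslow ties by
   default, Efron by flag). The selected slide features are first
   collapsed into a scalar *pathomics signature* (the Cox linear
   predictor); the final model combines signature + age + Ki-67 +
   metastasis, matching the axes of the clinical nomogram. Kaplan–Meier
   stratification searches percentile thresholds 20–80 in steps of 5 on
   the training risk scores, picks the threshold minimizing the log-rank
   p-value, and freezes that *absolute* threshold for the test cohort.
   Because the threshold is chosen to minimize p, the training p-value is
   optimized (exploratory) — only the frozen-threshold test-cohort p is
   confirmatory. The nomogram maps each covariate affinely to points, the
   covariate with the largest |coef|·range spanning 0–100, with each
   covariate's zero-point end at its lowest-hazard extreme; total points
   convert back to the linear predictor and to survival probabilities at
   36 and 60 months through the Breslow baseline hazard.

## The synthetic-data generator

No slide images ship with the package; every stage is exercised against a
generator (`cohort_config()` / `generate_cohort()`) that plants the
statistical structure the pipeline assumes:

* slide ER labels ~ Bernoulli(prevalence 0.5);
* each tissue tile carries a latent likelihood drawn from Beta(8, 2) for
  ER+ slides and Beta(2, 8) for ER− slides (class means 0.8 vs 0.2 — a
  strong, nearly separable plant; equal shapes give an exact null);
* tiles are painted so the latent likelihood is recoverable through two
  channels: the eosin-like hue shifts with it, and the count of dark
  nucleus-like blobs (Poisson with mean 3 + 27·likelihood) grows with it.
  The hue channel is recoverable by a trivial intensity feature; the blob
  channel survives per-tile Z-scoring, so the patch network has signal to
  learn even after its own input normalization;
* about 10% of tiles are near-white background, exercising the exclusion
  rule (every slide keeps at least one tissue tile);
* the metastasis label follows a logistic model on the slide's mean latent
  likelihood with intercept −5 and slope 10, giving roughly balanced
  classes and a strong but imperfect association; 25% of metastasis labels
  are missing, mirroring unreachable follow-up;
* survival times are exponential (Weibull shape configurable; the
  event-time family is a generator choice, not an estimand) with log-hazard
  1.0·risk + 0.3·age(SD) + 0.5·Ki-67(SD), where the planted risk score is
  the centred slide mean likelihood; age ~ N(52.6, 10.4²) and Ki-67 a
  scaled Beta on [0.01, 0.90] loosely match a routine breast-cancer cohort
  and exist for realism only;
* censoring is controlled directly: a Bernoulli(rate) subset is censored
  at a uniform fraction of its event time, so the realized censoring
  fraction concentrates tightly around the configured rate.

All randomness flows from the config seed; identical `(config, seed)`
pairs are bit-identical, and the pipeline fans one root seed out to fixed
per-stage seeds so stages can be re-run in isolation.

What the generator does *not* emulate: realistic histology texture, stain
physics, scanner artefacts, intra-slide heterogeneity of the latent
signal, spatial correlation between neighbouring tiles, or tumor-ROI
annotation (synthetic slides are all-ROI). Passing the test suite
therefore demonstrates that the machinery is correct and recovers planted
structure at realistic sample sizes — not that the pipeline attains any
particular accuracy on real slides.

## The patch backbone

The packaged backbone (`backbone = "tiny"`) is a single-hidden-layer ReLU
network (16 units) over a fixed per-tile representation of the Z-scored
image: an 8 × 8 grid of block means per channel, an 8 × 8 grid of block
standard deviations of luminance, and nine global luminance summaries
(lower-tail fractions at −2…−0.5 and low quantiles), 265 inputs in total.
It trains in seconds on a CPU with the exact optimizer, loss and schedule
described above, which is what the package's guarantees are about; the
large ImageNet backbones (DenseNet121, ResNet50, Inception_v3) are
recognised configuration values but require an external deep-learning
runtime and are deliberately not bundled — transfer-learning initialization
is likewise out of scope. Nothing downstream depends on the backbone
choice: any model producing per-tile likelihoods can feed the fusion stage
through `predict_patches()`'s output schema.

## Numerical choices and degenerate inputs

* Z-scoring and Reinhard statistics use the population (divide-by-n) SD,
  so the checkerboard tile maps to exactly ±1 and reference matching is
  exact at any tile size.
* Likelihood binning: index = min(⌊x·101⌋, 100), i.e. edges k/101 with the
  last bin closed so likelihood 1.0 is counted.
* Logistic/softmax probabilities are clipped at 1e-12 inside the
  cross-entropy; a non-finite loss aborts training with diagnostics.
* `concordance_index` counts a pair comparable iff the earlier time is an
  event and times differ; risk ties score ½; no comparable pairs yields a
  flagged `NA`.
* The log-rank statistic falls back to a direct observed-minus-expected
  tally when the variance matrix is singular (e.g. all subjects share one
  event time), reporting statistic 0 when O = E in every group.
* Ties in the KM percentile search resolve to the lowest percentile;
  candidates leaving fewer than 2 subjects in a group are skipped.
* `pearson_filter` requires ≥ 2 rows; single-class cohorts get flagged-NA
  AUCs; empty contingency denominators report 0 with a `degenerate` flag.

## Problem sizes and defaults

Tile side length is a generator parameter (default 64 px). Clinical
slides at 0.5 μm/pixel use 512 px tiles and the tiling functions keep 512
as their default; the generator's 64 px default is the package's
desk-scale choice — the painted statistics, not the absolute tile size,
carry the signal, and nothing downstream depends on tile size. The
end-to-end checks run 120 slides × 100 tiles (strong plant) and
200 slides × 49 tiles (null), training 12 epochs without augmentation on
cached features; module-level tests use smaller cohorts and 2–30 epochs.
These sizes are stated here as the package's reference conditions so
results are interpretable and reproducible.

## Known limitations

* The tiny backbone sees block statistics, not raw pixels; texture signal
  finer than the 8 × 8 grid that also vanishes from the global summaries
  is invisible to it.
* TF-IDF's idf is degenerate on very small fitting cohorts (df(w) ∈ {0, N}
  for all words when N is tiny), making BoW features nearly proportional
  to PLH features there; the redundancy filter then keeps only one copy.
* With strong plants and small test cohorts, threshold metrics
  (sensitivity/specificity at the Youden point) saturate at 0 or 1; the
  AUC columns are the stable quantities.
* The minimum-p percentile search inflates the training log-rank p-value
  by construction; it is reported for transparency, never as evidence.
* `fit_cox` on many near-collinear features relies on the ridge penalty
  for identifiability; with `c` near 0 and p comparable to n it can be
  ill-conditioned.
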