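# pathomil

Weakly supervised pathomics for metastasis and survival prediction from
H&E whole-slide images.

## What this is for

Digitized H&E sections of breast-cancer resection specimens carry
prognostic signal, but per-region annotation is expensive. `pathomil`
implements the whole-slide pipeline in which only *slide-level* labels —
the patient's estrogen-receptor (ER) status, i.e. luminal vs non-luminal
subtype — supervise a *patch-level* classifier, and the distribution of
its per-tile outputs becomes the slide representation used to predict
metastasis and overall survival. It is written for methodologists and
computational-pathology practitioners who want every stage of such a
pipeline as tested, reusable functions, exercisable end to end without any
external image data (a synthetic-slide generator with planted signal is a
first-class module).

## The model in brief

1. **Tiling & normalization.** Slides are cut into non-overlapping
   512 × 512 tiles (0-based row-major grid); tiles that are "exclusively
   white" (fraction of pixels with all RGB channels ≥ 220 exceeding 0.8)
   are excluded; kept tiles are Reinhard-normalized: per-channel
   mean/SD matching in Ruderman lαβ space,
   `x ↦ (x − μ_tile)·σ_ref/σ_tile + μ_ref`.
2. **Weakly supervised patch model.** Every tile inherits its slide's ER
   label. Inputs are per-tile Z-scored; training uses SGD on softmax
   cross-entropy under the cosine-decay schedule
   `η(t) = η_min + ½(η_max − η_min)(1 + cos(πt/T_i))` with
   η_max = 0.01, η_min = 0, T_i = 50.
3. **Slide fusion (MIL pooling).** Two encodings of each slide's patch
   likelihoods — a 101-bin patch-likelihood histogram (PLH) and a
   bag-of-words TF-IDF vector over the same 101 likelihood "words"
   (idf = ln((1+N)/(1+df)) + 1, fitted on training slides and frozen) —
   each extended by two predictive label features:
   **206 = 2 × (101 + 2)** named features per slide.
4. **Selection & metastasis models.** A greedy Pearson filter drops any
   feature whose |r| with an already-kept feature exceeds 0.9; random
   forest, XGBoost and an L2-logistic model are evaluated with accuracy,
   AUC (DeLong 95% CI), sensitivity, specificity, PPV and NPV at a
   Youden threshold frozen from the training cohort.
5. **Survival.** An L2-penalized Cox model (penalty `c/2·‖β‖²` with
   c = 0.3, Breslow ties) collapses the slide features into a pathomics
   signature; the final Cox model combines signature, age, Ki-67 and
   metastasis, is evaluated by C-index, stratified by the
   log-rank-optimal percentile threshold (grid 20–80 by 5, frozen for the
   test cohort), and rendered as a nomogram (affine 0–100 point scales,
   survival probabilities at 36/60 months via the Breslow baseline).

See `vignettes/weakly-supervised-pathomics.Rmd` for the full methods
account, including what the synthetic generator does and does not
emulate.

## Worked example

```r
library(pathomil)

# simulate a 30-slide cohort (49 tiles of 64 px per slide)
cohort <- generate_cohort(cohort_config(n_patients = 30, tiles_per_slide = 49,
                                        tile_size = 64, seed = 1))
cohort
#> synthetic_cohort: 30 slides x 49 tiles of 64 px
#>   ER+ slides: 14  metastasis labelled: 24
#>   events: 22 / 30

run <- run_pipeline(
  pipeline_config(
    cohort = cohort_config(n_patients = 30, tiles_per_slide = 49,
                           tile_size = 64),
    train  = train_config(epochs = 12, augment = FALSE, batch_size = 64),
    seed   = 1),
  out_dir = tempfile("demo_run"))

run$n_features
#> [1] 206
run$n_features_selected
#> [1] 88
subset(run$metastasis, cohort == "test", select = c(model_name, auc, accuracy))
#>       model_name auc  accuracy
#> 2  random_forest 0.8 0.5714286
#> 4        xgboost 0.9 0.8571429
#> 6 ridge_logistic 0.8 0.5714286
unlist(run$survival[c("cindex_train", "cindex_test", "km_percentile")])
#>  cindex_train   cindex_test km_percentile
#>     0.7475728     0.6000000    25.0000000
```

Reading the output: the fusion stage produced the full 206-feature slide
representation, of which 88 survived the redundancy filter on this small
cohort. On the held-out third of the slides the three learners rank
metastasis cases with AUC 0.8–0.9 (the plant is strong but the labelled
test cohort here is only 8 slides, so threshold metrics are coarse), and
the combined survival model orders test-cohort event times with C-index
0.60 after a training C-index of 0.75 — the expected train/test gap at
n = 30. The run directory contains every intermediate artefact
(`tiles.csv`, `patch_preds.csv`, `features.csv`, `metastasis_metrics.csv`,
`survival_metrics.json`, `summary.json`), and re-running with the same
seed reproduces them bit-identically.

The `analysis/` directory holds the same workflow as numbered stage
scripts (`01_simulate.R` … `06_survival.R`) at a 60-slide scale, writing
tables under `results/tables/` and figures (probability maps, ROC, KM
curves) under `results/figures/`.

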