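#' Pipeline run configuration
#'
#' Bundles the per-stage configurations and fans one root seed out to the
#' stages (via a fixed per-stage derivation), so any stage can be re-run in
#' isolation and a whole run is reproducible from a single integer.
#'
#' @param cohort a [cohort_config()]; its seed is overridden by the derived
#'   synth-stage seed.
#' @param train a [train_config()]; its seed is overridden likewise.
#' @param pearson_threshold redundancy-filter cut (default 0.9).
#' @param classifier_algos metastasis learners, see [train_classifiers()].
#' @param l2_c Cox L2 penalty constant (default 0.3).
#' @param survival_covariates covariates of the final survival model:
#'   `"signature"` (the pathomics Cox linear predictor) plus any of
#'   `"age"`, `"ki67"`, `"metastasis"`.
#' @param horizons nomogram survival horizons in months.
#' @param seed root seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            train = train_config(epochs = 12, augment = FALSE),
                            pearson_threshold = 0.9,
                            classifier_algos = c("random_forest", "xgboost",
                                                 "ridge_logistic"),
                            l2_c = 0.3,
                            survival_covariates = c("signature", "age", "ki67",
                                                    "metastasis"),
                            horizons = c(36, 60),
                            seed = 1L) {
  cohort$seed <- stage_seed(seed, "synth")
  train$seed <- stage_seed(seed, "train")
  cfg <- list(cohort = cohort, train = train,
              pearson_threshold = pearson_threshold,
              classifier_algos = classifier_algos,
              l2_c = l2_c,
              survival_covariates = survival_covariates,
              horizons = horizons,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full weakly supervised pathomics pipeline
#'
#' Executes simulate -> tile/normalize -> train patch model -> infer ->
#' fuse -> select -> metastasis models -> survival model as a DAG over a
#' run directory. Each stage writes its outputs under `out_dir` and, with
#' `resume = TRUE`, stages whose outputs already exist are skipped, so a
#' partial run continues where it stopped. The summary contains every
#' reported number together with the seeds and a hash of the stored config,
#' and is itself reproducible bit-for-bit from `(config, seed)`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created if missing).
#' @param resume skip stages whose outputs already exist (default TRUE).
#' @return the run summary (list), invisibly; also written as
#'   `summary.json`.
#' @export
run_pipeline <- function(config, out_dir, resume = TRUE) {
  assert_that(inherits(config, "pipeline_config"),
              "config must come from pipeline_config()")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass_deep(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  done <- function(...) all(file.exists(file.path(out_dir, c(...))))
  stage <- function(name, outputs, expr) {
    if (resume && done(outputs)) {
      message("[", name, "] outputs present; skipping (resume)")
    } else {
      message("[", name, "] running")
      ok <- tryCatch({ expr; TRUE }, error = function(e) {
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             " (outputs under ", out_dir, ")", call. = FALSE)
      })
    }
    invisible(NULL)
  }

  # -- simulate ----------------------------------------------------------
  cohort_dir <- file.path(out_dir, "cohort")
  stage("simulate", file.path("cohort", "manifest.csv"), {
    cohort <- generate_cohort(config$cohort)
    write_cohort(cohort, cohort_dir, overwrite = TRUE)
  })
  manifest <- read_manifest(file.path(cohort_dir, "manifest.csv"))

  # -- tile + normalize --------------------------------------------------
  proc_dir <- file.path(out_dir, "proc")
  stage("tile", file.path("proc", "tiles.csv"), {
    tile_slide_set(manifest, proc_dir,
                   tile_size = config$cohort$tile_size)
  })
  tiles_index <- read.csv(file.path(proc_dir, "tiles.csv"),
                          stringsAsFactors = FALSE)

  read_tiles <- function(index_rows) read_indexed_tiles(proc_dir, index_rows)
  kept <- tiles_index[!tiles_index$failed & !is.na(tiles_index$background) &
                        !tiles_index$background, ]
  slide_er <- stats::setNames(manifest$er_label, manifest$slide_id)
  slide_split <- stats::setNames(manifest$split, manifest$slide_id)

  # -- patch model (weak labels: each tile inherits its slide's ER) ------
  model_path <- file.path(out_dir, "patch_model.rds")
  stage("train_patch", "patch_model.rds", {
    train_rows <- kept[slide_split[kept$slide_id] == "train", ]
    tiles <- read_tiles(train_rows)
    labels <- as.integer(slide_er[train_rows$slide_id])
    stopifnot(all(labels == slide_er[train_rows$slide_id]))  # weak-label bookkeeping
    model <- train_patch_model(tiles, labels, config$train)
    saveRDS(model, model_path)
  })
  model <- readRDS(model_path)

  # -- inference over every kept tile ------------------------------------
  preds_path <- file.path(out_dir, "patch_preds.csv")
  stage("infer", "patch_preds.csv", {
    preds <- predict_patches(model, read_tiles(kept))
    write.csv(preds, preds_path, row.names = FALSE)
  })
  preds <- read.csv(preds_path, stringsAsFactors = FALSE)

  # -- fusion: PLH + BoW TF-IDF, idf frozen on training slides -----------
  stage("fuse", c("features.csv", "idf.json"), {
    fused <- fuse_slides(preds,
                         train_slide_ids = manifest$slide_id[manifest$split == "train"])
    write.csv(fused$features, file.path(out_dir, "features.csv"),
              row.names = FALSE)
    jsonlite::write_json(list(idf = fused$idf$idf,
                              n_slides = fused$idf$n_slides,
                              bins = 101),
                         file.path(out_dir, "idf.json"),
                         auto_unbox = TRUE, digits = NA)
  })
  features <- read.csv(file.path(out_dir, "features.csv"),
                       stringsAsFactors = FALSE, check.names = FALSE)

  # -- redundancy filter (fit on training rows only) ---------------------
  stage("select", c("features_selected.csv", "kept_features.json"), {
    fmat <- as.matrix(features[, -1])
    train_rows <- slide_split[features$slide_id] == "train"
    kept_cols <- suppressMessages(
      pearson_filter(fmat[train_rows, , drop = FALSE],
                     threshold = config$pearson_threshold))
    sel <- features[, c("slide_id", kept_cols)]
    write.csv(sel, file.path(out_dir, "features_selected.csv"),
              row.names = FALSE)
    jsonlite::write_json(kept_cols, file.path(out_dir, "kept_features.json"))
  })
  selected <- read.csv(file.path(out_dir, "features_selected.csv"),
                       stringsAsFactors = FALSE, check.names = FALSE)

  # -- metastasis models -------------------------------------------------
  stage("fit_metastasis", "metastasis_metrics.csv", {
    lab <- manifest[match(selected$slide_id, manifest$slide_id), ]
    use <- !is.na(lab$metastasis_label)
    X <- as.matrix(selected[use, -1, drop = FALSE])
    y <- lab$metastasis_label[use]
    split <- lab$split[use]
    fits <- train_classifiers(X[split == "train", , drop = FALSE],
                              y[split == "train"],
                              algos = config$classifier_algos,
                              seed = stage_seed(config$seed, "metastasis"))
    metrics <- list()
    scores_all <- data.frame(slide_id = lab$slide_id[use], split = split,
                             metastasis = y)
    for (algo in names(fits)) {
      sc <- predict_classifier(fits[[algo]], X)
      thr <- youden_threshold(sc[split == "train"], y[split == "train"])
      metrics[[paste0(algo, "_train")]] <-
        evaluate_classifier(sc[split == "train"], y[split == "train"],
                            threshold = thr, model_name = algo,
                            cohort = "train")
      metrics[[paste0(algo, "_test")]] <-
        evaluate_classifier(sc[split == "test"], y[split == "test"],
                            threshold = thr, model_name = algo,
                            cohort = "test")
      scores_all[[paste0("score_", algo)]] <- sc
    }
    write.csv(do.call(rbind, metrics),
              file.path(out_dir, "metastasis_metrics.csv"), row.names = FALSE)
    write.csv(scores_all, file.path(out_dir, "metastasis_scores.csv"),
              row.names = FALSE)
  })
  met_metrics <- read.csv(file.path(out_dir, "metastasis_metrics.csv"),
                          stringsAsFactors = FALSE)

  # -- survival model ----------------------------------------------------
  stage("fit_survival", c("survival_metrics.json", "cox_fit.json"), {
    surv_path <- file.path(cohort_dir, "survival.csv")
    if (!file.exists(surv_path)) {
      stop("survival table not found: ", surv_path)
    }
    survival_tab <- read.csv(surv_path, stringsAsFactors = FALSE)
    sdat <- merge(
      merge(selected, manifest[, c("slide_id", "patient_id", "split",
                                   "metastasis_label")], by = "slide_id"),
      survival_tab, by = "patient_id"
    )
    sdat <- sdat[order(sdat$slide_id), ]
    feat_cols <- setdiff(names(selected), "slide_id")
    train <- sdat$split == "train"

    # pathomics signature: L2-Cox on the selected slide features,
    # collapsed to its linear predictor
    sig_fit <- fit_cox(sdat[train, ], covariates = feat_cols,
                       l2_c = config$l2_c)
    sdat$signature <- as.numeric(
      as.matrix(sdat[, feat_cols]) %*% sig_fit$coefficients)

    covs <- config$survival_covariates
    sdat$metastasis <- sdat$metastasis_label
    model_dat <- sdat[, c("patient_id", "slide_id", "split", "time_months",
                          "event", covs)]
    cc <- stats::complete.cases(model_dat)
    model_dat <- model_dat[cc, ]
    mtrain <- model_dat$split == "train"
    full_fit <- fit_cox(model_dat[mtrain, ], covariates = covs,
                        l2_c = config$l2_c)
    lp <- as.numeric(as.matrix(model_dat[, covs]) %*% full_fit$coefficients)

    cindex_train <- concordance_index(lp[mtrain],
                                      model_dat$time_months[mtrain],
                                      model_dat$event[mtrain])
    cindex_test <- concordance_index(lp[!mtrain],
                                     model_dat$time_months[!mtrain],
                                     model_dat$event[!mtrain])
    strat <- km_stratify(lp[mtrain], model_dat$time_months[mtrain],
                         model_dat$event[mtrain])
    test_groups <- stratify_risk(lp[!mtrain], strat$threshold)
    logrank_test_p <- if (nlevels(droplevels(test_groups)) == 2) {
      logrank_test(test_groups, model_dat$time_months[!mtrain],
                   model_dat$event[!mtrain])$p_value
    } else {
      NA_real_
    }
    ranges <- lapply(covs, function(v) range(model_dat[[v]][mtrain]))
    names(ranges) <- covs
    nomo <- build_nomogram(full_fit, ranges, horizons = config$horizons)

    jsonlite::write_json(
      list(signature = as.list(sig_fit$coefficients),
           survival_model = as.list(full_fit$coefficients),
           l2_c = config$l2_c),
      file.path(out_dir, "cox_fit.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(cindex_train = as.numeric(cindex_train),
           cindex_test = as.numeric(cindex_test),
           km_percentile = strat$percentile,
           km_threshold = strat$threshold,
           km_logrank_p_train = strat$logrank_p,
           km_logrank_p_test = logrank_test_p,
           n_train = sum(mtrain), n_test = sum(!mtrain)),
      file.path(out_dir, "survival_metrics.json"), auto_unbox = TRUE,
      digits = NA)
    jsonlite::write_json(
      list(covariates = nomo$covariates,
           coefficients = as.list(nomo$coefficients),
           points_per_unit = lapply(nomo$scales, `[[`, "points_per_unit"),
           reference = lapply(nomo$scales, `[[`, "ref"),
           horizons = nomo$horizons),
      file.path(out_dir, "nomogram.json"), auto_unbox = TRUE, digits = NA)
  })
  surv_metrics <- jsonlite::read_json(file.path(out_dir, "survival_metrics.json"),
                                      simplifyVector = TRUE)

  summary <- list(
    seed = config$seed,
    stage_seeds = list(synth = config$cohort$seed, train = config$train$seed,
                       metastasis = stage_seed(config$seed, "metastasis")),
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_slides = nrow(manifest),
    n_tiles_kept = nrow(kept),
    n_features = ncol(features) - 1,
    n_features_selected = ncol(selected) - 1,
    metastasis = met_metrics,
    survival = surv_metrics
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), unclass_deep)
  } else {
    x
  }
}

#' Validate a slide manifest
#'
#' Checks the header schema, the `{0, 1}` / `{0, 1, NA}` label codings
#' (label 1 = ER-positive resp. metastasis), split values and uniqueness of
#' slide ids.
#'
#' @param manifest a manifest data frame or path to `manifest.csv`.
#' @return character vector of itemized problems (empty when well-formed).
#' @export
validate_manifest <- function(manifest) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) return(paste("file not found:", manifest))
    manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  }
  errors <- character(0)
  required <- c("slide_id", "patient_id", "er_label", "metastasis_label", "split")
  missing <- setdiff(required, names(manifest))
  if (length(missing) > 0) {
    return(paste("missing column(s):", paste(missing, collapse = ", ")))
  }
  dup <- unique(manifest$slide_id[duplicated(manifest$slide_id)])
  for (d in dup) errors <- c(errors, paste("duplicated slide_id:", d))
  bad_er <- !manifest$er_label %in% c(0, 1)
  if (any(bad_er)) {
    errors <- c(errors, paste0("er_label must be coded 0/1; offending rows: ",
                               paste(which(bad_er), collapse = ", ")))
  }
  bad_met <- !(manifest$metastasis_label %in% c(0, 1) |
                 is.na(manifest$metastasis_label))
  if (any(bad_met)) {
    errors <- c(errors, paste0("metastasis_label must be coded 0/1/NA; ",
                               "offending rows: ",
                               paste(which(bad_met), collapse = ", ")))
  }
  bad_split <- !manifest$split %in% c("train", "test")
  if (any(bad_split)) {
    errors <- c(errors, paste0("split must be train/test; offending rows: ",
                               paste(which(bad_split), collapse = ", ")))
  }
  errors
}

#' Count labelled cases in a per-patient label table
#'
#' Counts the rows whose label column is non-missing -- the accounting used
#' when only a subset of a cohort has known metastasis or survival status.
#'
#' @param table a data frame or CSV path.
#' @param label_col the label column (default `"metastasis_label"`).
#' @return integer count of non-missing labels.
#' @export
count_labelled_cases <- function(table, label_col = "metastasis_label") {
  if (is.character(table)) table <- read.csv(table, stringsAsFactors = FALSE)
  assert_that(label_col %in% names(table), "no column named ", label_col)
  sum(!is.na(table[[label_col]]))
}
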