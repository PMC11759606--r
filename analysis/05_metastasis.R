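# Metastasis prediction from the selected slide features: random forest,
# XGBoost and an L2-logistic baseline, with the full metric panel on the
# frozen train/test split and a ROC figure.

source("analysis/00_config.R")

manifest <- read_manifest(file.path(pm_workdir, "cohort", "manifest.csv"))
selected <- read.csv(file.path(pm_workdir, "features_selected.csv"),
                     stringsAsFactors = FALSE, check.names = FALSE)

lab <- manifest[match(selected$slide_id, manifest$slide_id), ]
use <- !is.na(lab$metastasis_label)
X <- as.matrix(selected[use, -1])
y <- lab$metastasis_label[use]
split <- lab$split[use]
message(sprintf("%d labelled slides (%d train / %d test), %d with metastasis",
                sum(use), sum(split == "train"), sum(split == "test"), sum(y)))

fits <- train_classifiers(X[split == "train", ], y[split == "train"],
                          algos = pm_config$classifier_algos,
                          seed = pathomil:::stage_seed(pm_seed, "metastasis"))

metrics <- list()
test_scores <- list()
for (algo in names(fits)) {
  sc <- predict_classifier(fits[[algo]], X)
  thr <- youden_threshold(sc[split == "train"], y[split == "train"])
  metrics[[paste0(algo, "_train")]] <-
    evaluate_classifier(sc[split == "train"], y[split == "train"],
                        threshold = thr, model_name = algo, cohort = "train")
  metrics[[paste0(algo, "_test")]] <-
    evaluate_classifier(sc[split == "test"], y[split == "test"],
                        threshold = thr, model_name = algo, cohort = "test")
  test_scores[[algo]] <- sc[split == "test"]
}
metrics <- do.call(rbind, metrics)
rownames(metrics) <- NULL
write.csv(metrics, file.path(pm_tabdir, "metastasis_metrics.csv"),
          row.names = FALSE)
print(metrics[, c("model_name", "cohort", "accuracy", "auc", "sensitivity",
                  "specificity")], digits = 3)

plot_roc(test_scores, y[split == "test"],
         file.path(pm_figdir, "metastasis_roc_test.png"),
         main = "Metastasis prediction, test cohort")
message("ROC figure: ", file.path(pm_figdir, "metastasis_roc_test.png"))
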