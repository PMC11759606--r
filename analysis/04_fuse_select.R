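# Fuse patch likelihoods into the 206-dimensional slide representation
# (PLH histogram + BoW TF-IDF, each with two label features), then drop
# Pearson-redundant columns using the training slides only.

source("analysis/00_config.R")

manifest <- read_manifest(file.path(pm_workdir, "cohort", "manifest.csv"))
preds <- read.csv(file.path(pm_workdir, "patch_preds.csv"),
                  stringsAsFactors = FALSE)

fused <- fuse_slides(preds,
                     train_slide_ids = manifest$slide_id[manifest$split == "train"])
write.csv(fused$features, file.path(pm_workdir, "features.csv"),
          row.names = FALSE)
message(sprintf("fused %d slides into %d features each",
                nrow(fused$features), ncol(fused$features) - 1))

fmat <- as.matrix(fused$features[, -1])
train <- manifest$split[match(fused$features$slide_id,
                              manifest$slide_id)] == "train"
kept_cols <- pearson_filter(fmat[train, ],
                            threshold = pm_config$pearson_threshold)
message(sprintf("Pearson filter (|r| > %.1f dropped): %d of %d features kept",
                pm_config$pearson_threshold, length(kept_cols), ncol(fmat)))

selected <- fused$features[, c("slide_id", kept_cols)]
write.csv(selected, file.path(pm_workdir, "features_selected.csv"),
          row.names = FALSE)
jsonlite::write_json(kept_cols, file.path(pm_workdir, "kept_features.json"))
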