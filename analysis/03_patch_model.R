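# Train the patch-level classifier under weak (slide-inherited) ER labels,
# predict a likelihood for every kept tile, and render per-slide
# probability maps.

source("analysis/00_config.R")

proc_dir <- file.path(pm_workdir, "proc")
manifest <- read_manifest(file.path(pm_workdir, "cohort", "manifest.csv"))
index <- read.csv(file.path(proc_dir, "tiles.csv"), stringsAsFactors = FALSE)
kept <- index[!index$failed & !is.na(index$background) & !index$background, ]

slide_er <- setNames(manifest$er_label, manifest$slide_id)
slide_split <- setNames(manifest$split, manifest$slide_id)

train_rows <- kept[slide_split[kept$slide_id] == "train", ]
tiles_train <- read_indexed_tiles(proc_dir, train_rows)
labels <- as.integer(slide_er[train_rows$slide_id])

model <- train_patch_model(tiles_train, labels, pm_config$train)
print(model)
saveRDS(model, file.path(pm_workdir, "patch_model.rds"))
write.csv(model$history, file.path(pm_tabdir, "patch_training_history.csv"),
          row.names = FALSE)

preds <- predict_patches(model, read_indexed_tiles(proc_dir, kept))
write.csv(preds, file.path(pm_workdir, "patch_preds.csv"), row.names = FALSE)

# held-out patch-level discrimination under the weak labels
test_rows <- slide_split[preds$slide_id] == "test"
panel <- evaluate_classifier(preds$likelihood[test_rows],
                             as.integer(slide_er[preds$slide_id[test_rows]]),
                             model_name = pm_config$train$backbone,
                             cohort = "test")
write.csv(panel, file.path(pm_tabdir, "patch_level_metrics.csv"),
          row.names = FALSE)
message(sprintf("held-out patch AUC %.3f (accuracy %.3f) over %d tiles",
                panel$auc, panel$accuracy, sum(test_rows)))

# probability maps of the first two test slides (blue = ER-, red = ER+)
for (sid in head(manifest$slide_id[manifest$split == "test"], 2)) {
  grid <- probability_map(preds, sid)
  render_probability_map(grid,
                         file.path(pm_figdir, paste0("probmap_", sid, ".png")))
  message("probability map: ", file.path(pm_figdir, paste0("probmap_", sid, ".png")),
          sprintf("  (mean likelihood %.2f, ER label %d)",
                  mean(grid, na.rm = TRUE), slide_er[[sid]]))
}
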