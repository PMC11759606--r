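# Shared configuration for the analysis scripts. Source this first (all
# scripts do). The scripts are run from the repository root, in order:
#   Rscript analysis/01_simulate.R
#   Rscript analysis/02_tile_normalize.R
#   ...
# Every script is a thin driver over the pathomil package; all outputs land
# under results/.

library(pathomil)

pm_seed <- 20260923L
pm_workdir <- "results/pipeline"
pm_figdir <- "results/figures"
pm_tabdir <- "results/tables"

for (d in c(pm_workdir, pm_figdir, pm_tabdir)) {
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
}

# Desk-scale study conditions: 60 slides of 49 tiles (64 px) with the
# strong ER plant; training uses the tiny backbone without augmentation.
pm_config <- pipeline_config(
  cohort = cohort_config(n_patients = 60, tiles_per_slide = 49,
                         tile_size = 64),
  train = train_config(epochs = 12, augment = FALSE, batch_size = 64),
  seed = pm_seed
)
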