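# Cut every slide into non-overlapping tiles, drop white-background tiles,
# and Reinhard-normalize the kept ones against the cohort reference.

source("analysis/00_config.R")

manifest <- read_manifest(file.path(pm_workdir, "cohort", "manifest.csv"))
proc_dir <- file.path(pm_workdir, "proc")

index <- tile_slide_set(manifest, proc_dir,
                        tile_size = pm_config$cohort$tile_size)

kept <- sum(!index$background, na.rm = TRUE)
message(sprintf("%d tiles indexed; %d kept after background exclusion (%.0f%%)",
                nrow(index), kept, 100 * kept / nrow(index)))
message("tile index: ", file.path(proc_dir, "tiles.csv"))
message("Reinhard reference: ", file.path(proc_dir, "reinhard_ref.json"))
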