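# Simulate the synthetic slide cohort: ER-labelled slides whose tiles are
# painted from a latent per-tile likelihood, a metastasis label driven by
# the slide's mean likelihood, and right-censored survival times.

source("analysis/00_config.R")

cohort <- generate_cohort(pm_config$cohort)
print(cohort)

cohort_dir <- file.path(pm_workdir, "cohort")
manifest_path <- write_cohort(cohort, cohort_dir, overwrite = TRUE)
message("cohort written under ", cohort_dir)

problems <- validate_manifest(manifest_path)
stopifnot(length(problems) == 0)

m <- cohort$manifest
message(sprintf("ER+ slides: %d/%d; metastasis labelled: %d; events: %d/%d",
                sum(m$er_label), nrow(m), sum(!is.na(m$metastasis_label)),
                sum(cohort$survival$event), nrow(cohort$survival)))
message(sprintf("realized censoring: %.2f (configured %.2f)",
                1 - mean(cohort$survival$event),
                pm_config$cohort$censoring_rate))
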