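# Survival modelling: collapse the selected slide features into a
# pathomics signature with an L2-Cox fit, combine it with age, Ki-67 and
# metastasis in the final Cox model, evaluate C-indices, stratify by the
# log-rank-optimal percentile threshold, and build the nomogram.

source("analysis/00_config.R")

manifest <- read_manifest(file.path(pm_workdir, "cohort", "manifest.csv"))
selected <- read.csv(file.path(pm_workdir, "features_selected.csv"),
                     stringsAsFactors = FALSE, check.names = FALSE)
survival_tab <- read.csv(file.path(pm_workdir, "cohort", "survival.csv"),
                         stringsAsFactors = FALSE)

sdat <- merge(
  merge(selected, manifest[, c("slide_id", "patient_id", "split",
                               "metastasis_label")], by = "slide_id"),
  survival_tab, by = "patient_id"
)
sdat <- sdat[order(sdat$slide_id), ]
feat_cols <- setdiff(names(selected), "slide_id")
train <- sdat$split == "train"

sig_fit <- fit_cox(sdat[train, ], covariates = feat_cols,
                   l2_c = pm_config$l2_c)
sdat$signature <- as.numeric(as.matrix(sdat[, feat_cols]) %*%
                               sig_fit$coefficients)
message(sprintf("pathomics signature: %d features, train C-index %.3f",
                length(feat_cols), sig_fit$cindex_train))

covs <- pm_config$survival_covariates
sdat$metastasis <- sdat$metastasis_label
mdat <- sdat[stats::complete.cases(sdat[, c("time_months", "event", covs)]),
             c("patient_id", "split", "time_months", "event", covs)]
mtrain <- mdat$split == "train"
full_fit <- fit_cox(mdat[mtrain, ], covariates = covs, l2_c = pm_config$l2_c)
print(full_fit)

lp <- as.numeric(as.matrix(mdat[, covs]) %*% full_fit$coefficients)
ci_train <- concordance_index(lp[mtrain], mdat$time_months[mtrain],
                              mdat$event[mtrain])
ci_test <- concordance_index(lp[!mtrain], mdat$time_months[!mtrain],
                             mdat$event[!mtrain])
message(sprintf("C-index: %.3f (train, n=%d) / %.3f (test, n=%d)",
                ci_train, sum(mtrain), ci_test, sum(!mtrain)))

strat <- km_stratify(lp[mtrain], mdat$time_months[mtrain], mdat$event[mtrain])
message(sprintf("risk threshold at the %dth percentile (log-rank p = %.3g, train)",
                strat$percentile, strat$logrank_p))
plot_km(strat$groups, mdat$time_months[mtrain], mdat$event[mtrain],
        file.path(pm_figdir, "km_train.png"),
        main = "Training cohort, risk strata")
test_groups <- stratify_risk(lp[!mtrain], strat$threshold)
if (nlevels(droplevels(test_groups)) == 2) {
  plot_km(test_groups, mdat$time_months[!mtrain], mdat$event[!mtrain],
          file.path(pm_figdir, "km_test.png"),
          main = "Test cohort, frozen threshold")
}

ranges <- lapply(covs, function(v) range(mdat[[v]][mtrain]))
names(ranges) <- covs
nomo <- build_nomogram(full_fit, ranges, horizons = pm_config$horizons)
at_median <- predict_nomogram(
  nomo, as.data.frame(lapply(mdat[mtrain, covs, drop = FALSE], stats::median)))
message(sprintf("nomogram: median training patient scores %.0f points; S(36m) = %.2f, S(60m) = %.2f",
                at_median$total_points, at_median$surv_prob_36m,
                at_median$surv_prob_60m))

jsonlite::write_json(
  list(cindex_train = as.numeric(ci_train), cindex_test = as.numeric(ci_test),
       km_percentile = strat$percentile, km_threshold = strat$threshold,
       km_logrank_p_train = strat$logrank_p,
       nomogram = list(covariates = nomo$covariates,
                       coefficients = as.list(nomo$coefficients))),
  file.path(pm_tabdir, "survival_summary.json"), auto_unbox = TRUE,
  digits = NA, pretty = TRUE)
message("survival summary: ", file.path(pm_tabdir, "survival_summary.json"))
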