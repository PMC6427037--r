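# 03 - Assemble the model table: drop incomplete records, prune
# collinear covariates at |r| > 0.65, standardize the survivors, and
# join the standardized ecoregion diversity covariate.

source("analysis/00_config.R")

ds <- analysis_dataset()
tab <- ds$table

jsonlite::write_json(list(
  retained = tab$covariate_names,
  dropped_covariates = tab$dropped_covariates,
  dropped_fraction = tab$dropped_fraction,
  standardization = tab$standardization
), file.path(RESULTS_DIR, "preprocess.json"), auto_unbox = TRUE,
  digits = NA, pretty = TRUE)

print(tab)
cat("dropped covariates (with trigger partner and correlation):\n")
print(tab$dropped_covariates, digits = 3)
cat("row drop fraction:", tab$dropped_fraction, "\n")
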