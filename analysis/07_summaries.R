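# 07 - Descriptive layers: ecoregion z-scores of the significant
# covariates (>= 10 surveys per ecoregion), bleaching prevalence by
# 5-degree absolute-latitude band with the Spearman effort check, and
# the annual bleaching-probability trend with Wilson 95% intervals.
# Run 04 first (reads its effects.csv for the significance flags).

source("analysis/00_config.R")

ds <- analysis_dataset()
tab <- ds$table
eff <- read.csv(file.path(RESULTS_DIR, "effects.csv"))

zs <- tryCatch(ecoregion_zscores(tab$data, eff, min_surveys = 10),
               error = function(e) { message(conditionMessage(e)); NULL })
if (!is.null(zs)) {
  write.csv(round_df(zs), file.path(RESULTS_DIR, "ecoregion_zscores.csv"),
            row.names = FALSE)
  cat("ecoregion z-scores for ", nrow(zs), " ecoregions (",
      nrow(attr(zs, "excluded")), " excluded under the 10-survey rule)\n",
      sep = "")
}

prof <- latitude_profile(tab$data, band_width = 5)
write.csv(round_df(prof), file.path(RESULTS_DIR, "latitude_profile.csv"),
          row.names = FALSE)
cat("\nbleaching prevalence by |latitude| band:\n")
print(prof, digits = 3)

ec <- effort_correlation(prof)
cat(sprintf("\nprevalence vs effort: Spearman rho = %.3f, p = %.3f over %d bands\n",
            ec$rho, ec$p_value, ec$n_bands))

tr <- annual_trend(tab$data)
write.csv(round_df(tr), file.path(RESULTS_DIR, "annual_trend.csv"),
          row.names = FALSE)
slope <- coef(lm(probability ~ year, tr))[2]
cat(sprintf("annual bleaching probability: %.3f (%d) -> %.3f (%d), OLS slope %+.4f/yr\n",
            tr$probability[1], tr$year[1],
            tr$probability[nrow(tr)], tr$year[nrow(tr)], slope))

jsonlite::write_json(list(
  effort = ec,
  latitude_bands = prof,
  annual_probability = tr[c("year", "probability", "ci_lower", "ci_upper")],
  trend_slope_per_year = unname(slope)
), file.path(RESULTS_DIR, "report.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
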