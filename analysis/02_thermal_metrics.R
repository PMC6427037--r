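# 02 - Thermal-stress covariates per survey.
#
# For every survey: survey-week SST, climatology (52-week means, MMM),
# SSTA/TSA anomalies with their dispersions and >=1 C exceedance
# frequencies, Degree Heating Weeks over the trailing 12-week window,
# and the long-run warming rate at the site. The full covariate table
# is bulky and fully regenerable, so it goes to scratch/; results/
# keeps a per-covariate summary.

source("analysis/00_config.R")

ds <- analysis_dataset()
cov <- ds$covariates
write.csv(round_df(cov), file.path(SCRATCH_DIR, "covariates_full.csv"),
          row.names = FALSE)

num <- names(cov)[vapply(cov, is.numeric, logical(1))]
summ <- do.call(rbind, lapply(num, function(v) data.frame(
  covariate = v, mean = mean(cov[[v]]), sd = sd(cov[[v]]),
  min = min(cov[[v]]), max = max(cov[[v]]))))
write.csv(round_df(summ), file.path(RESULTS_DIR, "covariate_summary.csv"),
          row.names = FALSE)

cat("covariate table: ", nrow(cov), " surveys x ", ncol(cov),
    " columns (full table in scratch/)\n", sep = "")
cat("DHW:  mean ", round(mean(cov$dhw), 2), " C-weeks, ",
    round(100 * mean(cov$dhw >= 8), 1),
    "% of surveys at/above the 8 DHW severe-bleaching level\n", sep = "")
cat("rate of SST change: mean ",
    round(mean(cov$rate_of_sst_change), 4), " C/yr\n", sep = "")
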