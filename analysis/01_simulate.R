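# 01 - Build the synthetic world and draw the bleaching surveys.
#
# Generates the weekly SST grid (seasonal cycle, 0.02 C/yr warming,
# sparse marine heatwave blocks), the ecoregion/site layout with its
# equatorial diversity gradient, the survey schedule (right-skewed
# revisit counts, mean 2.75 per site), and percent-bleaching counts
# from the hierarchical negative-binomial model.

source("analysis/00_config.R")

ds <- analysis_dataset()
sv <- ds$surveys

write.csv(round_df(sv), file.path(RESULTS_DIR, "surveys.csv"),
          row.names = FALSE)
write.csv(round_df(ds$world$sites[c("site_id", "ecoregion_id",
                                    "latitude", "longitude", "depth")]),
          file.path(RESULTS_DIR, "sites.csv"), row.names = FALSE)
write.csv(ds$world$diversity, file.path(RESULTS_DIR, "diversity.csv"),
          row.names = FALSE)

cat("sites:        ", nrow(ds$world$sites), "\n")
cat("surveys:      ", nrow(sv), " (",
    format(min(sv$date)), " .. ", format(max(sv$date)), ")\n", sep = "")
cat("zero fraction:", round(mean(sv$bleaching_pct == 0), 3), "\n")
cat("mean bleached:", round(mean(sv$bleaching_pct), 2), "%\n")
cat("cap rate:     ", attr(sv, "cap_rate"),
    "(fraction of raw draws above 100)\n")
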