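# 04 - Fit the hierarchical Bayesian negative-binomial model by MCMC
# and classify covariate effects by their 95% credible intervals
# (positive / negative / null), forest-plot style.
#
# Note: the intercept b0 and the ecoregion grand mean mu enter the
# model only through their sum, so their individual chains wander
# along a flat ridge and are flagged by the convergence check; the
# covariate coefficients, diversity effect, dispersion and variance
# components are identified and mix well.

source("analysis/00_config.R")

ds <- analysis_dataset()
fit <- fit_bleaching_model(ds$table, analysis_model_spec())
eff <- summarize_effects(fit)

write.csv(round_df(eff, 5), file.path(RESULTS_DIR, "effects.csv"),
          row.names = FALSE)
write.csv(round_df(fit$convergence, 5),
          file.path(RESULTS_DIR, "convergence.csv"), row.names = FALSE)
top <- coralbleach:::draws_matrix(fit,
                                  coralbleach:::top_level_parameters(fit))
write.csv(round_df(as.data.frame(top), 5),
          file.path(SCRATCH_DIR, "draws_top_level.csv"),
          row.names = FALSE)

cat("effect classification (95% CrI rule):\n")
print(eff[c("parameter", "covariate", "mean", "l95", "u95",
            "classification")], digits = 3)
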