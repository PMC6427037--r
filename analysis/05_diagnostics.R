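# 05 - Posterior-predictive checks for the zero-inflated fit.
#
# Two complementary checks: the Bayesian P-value for the mean of the
# non-zero bleaching values (a plain mean-based check is swamped by the
# zeros), and the zero-pattern comparison - how often replicates
# reproduce an observed zero, and how much bleaching they predict when
# they overestimate one.

source("analysis/00_config.R")

ds <- analysis_dataset()
fit <- fit_bleaching_model(ds$table, analysis_model_spec())

ppc <- posterior_predictive_check(fit, n_rep = 500,
                                  seed = ANALYSIS_SEED + 1L)
jsonlite::write_json(unclass(ppc),
                     file.path(RESULTS_DIR, "ppc.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
print(ppc)
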