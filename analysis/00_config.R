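# Shared configuration for the analysis scripts: one synthetic world
# standing in for the global survey compilation (weekly SST 1982-2017,
# sites nested in latitudinal ecoregions, surveys 1998-2017), one seed.
# Every script sources this file and regenerates what it needs
# deterministically, so the scripts can be run independently and in any
# order. Small summary tables go to results/; bulky regenerable
# intermediates (full covariate table, posterior draws) go to scratch/.

library(coralbleach)

ANALYSIS_SEED <- 20170131L
RESULTS_DIR <- "results"
SCRATCH_DIR <- "scratch"
dir.create(RESULTS_DIR, showWarnings = FALSE)
dir.create(SCRATCH_DIR, showWarnings = FALSE)

analysis_sim_config <- function() {
  sim_config(seed = ANALYSIS_SEED)   # package defaults are the study conditions
}

analysis_model_spec <- function() {
  # The full-scale fit uses 3 chains with a 4000-iteration burn-in and
  # 5000 retained iterations; here the chains are shortened so the
  # whole pipeline stays a coffee-break run at this problem size
  # (~800 surveys, 300 sites).
  model_spec(n_chains = 3, n_adapt = 500, n_burnin = 1000,
             n_iterations = 1500, seed = ANALYSIS_SEED)
}

# Deterministic rebuild of the shared dataset: world, survey schedule,
# thermal covariates, bleaching draws, and the preprocessed model table.
analysis_dataset <- function() {
  cfg <- analysis_sim_config()
  w <- gen_world(cfg)
  sched <- coralbleach:::gen_survey_schedule(w, cfg)
  cov <- covariate_table(w, sched)
  sv <- gen_bleaching(w, cfg, surveys = sched, covariates = cov)
  cov$bleaching_pct <- sv$bleaching_pct
  tab <- build_analysis_table(cov, w$diversity, prune_threshold = 0.65)
  list(config = cfg, world = w, schedule = sched, covariates = cov,
       surveys = sv, table = tab)
}

round_df <- function(df, digits = 4) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  df
}
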