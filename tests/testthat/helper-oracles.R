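# Shared fixtures: brute-force oracles for the thermal metrics, a tiny
# synthetic world, and hand-built posterior-draw objects so diagnostics
# can be tested without running MCMC.

# Independent brute-force implementation of the thermal metrics using
# plain loops; deliberately naive so it cannot share bugs with the
# vectorised implementation under test.
brute_metrics <- function(dates, temps, survey_date, baseline_years = NULL) {
  yr <- as.integer(format(dates, "%Y"))
  if (is.null(baseline_years)) baseline_years <- range(yr)
  wk <- integer(length(dates))
  for (i in seq_along(dates)) {
    yday <- as.integer(format(dates[i], "%j")) - 1L
    wk[i] <- min(52L, yday %/% 7L + 1L)
  }
  base <- which(yr >= baseline_years[1] & yr <= baseline_years[2])
  weekly <- numeric(52)
  for (w in 1:52) {
    acc <- c()
    for (i in base) if (wk[i] == w) acc <- c(acc, temps[i])
    weekly[w] <- mean(acc)
  }
  mo <- as.integer(format(dates, "%m"))
  mmm <- -Inf
  for (m in 1:12) {
    acc <- c()
    for (i in base) if (mo[i] == m) acc <- c(acc, temps[i])
    if (length(acc)) mmm <- max(mmm, mean(acc))
  }
  idx <- max(which(dates <= survey_date))
  ssta <- tsa <- numeric(idx)
  for (i in seq_len(idx)) {
    ssta[i] <- temps[i] - weekly[wk[i]]
    tsa[i] <- temps[i] - mmm
  }
  dhw <- 0
  for (i in (idx - 11L):idx) if (temps[i] - mmm >= 1)
    dhw <- dhw + (temps[i] - mmm)
  yrs <- unique(yr[seq_len(idx)])
  ycnt_ssta <- ycnt_tsa <- numeric(length(yrs))
  for (j in seq_along(yrs)) for (i in seq_len(idx)) if (yr[i] == yrs[j]) {
    if (ssta[i] >= 1) ycnt_ssta[j] <- ycnt_ssta[j] + 1
    if (tsa[i] >= 1) ycnt_tsa[j] <- ycnt_tsa[j] + 1
  }
  t <- numeric(idx); y <- numeric(idx)
  for (i in seq_len(idx)) {
    t[i] <- 1900 + as.POSIXlt(dates[i])$year + as.POSIXlt(dates[i])$yday / 365.25
    y[i] <- temps[i]
  }
  slope <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
  list(weekly = weekly, mmm = mmm,
       sst_at_survey = temps[idx], sst_min = min(temps[seq_len(idx)]),
       sst_max = max(temps[seq_len(idx)]), sst_stdev = sd(temps[seq_len(idx)]),
       ssta = ssta[idx], ssta_stdev = sd(ssta),
       ssta_freq = sum(ssta >= 1),
       ssta_freq_stdev = if (length(yrs) > 1) sd(ycnt_ssta) else 0,
       tsa = tsa[idx], tsa_stdev = sd(tsa), tsa_freq = sum(tsa >= 1),
       tsa_freq_stdev = if (length(yrs) > 1) sd(ycnt_tsa) else 0,
       dhw = dhw, rate_of_sst_change = slope)
}

weekly_dates <- function(n, start = "2000-01-04") as.Date(start) + 7 * (0:(n - 1))

tiny_config <- function(...) {
  sim_config(n_ecoregions = 4, sites_per_ecoregion = 4, weeks = 520,
             start_year = 2000, seed = 42, ...)
}

# Build a posterior_draws object from fixed parameter values (optionally
# jittered) without any MCMC, for testing summaries and PPCs.
make_fake_draws <- function(o, Z, site, region, z_div,
                            b0 = 0, gamma = rep(0, ncol(Z)), k = 1,
                            a = rep(0, max(site)),
                            R = rep(0, max(region)),
                            mu = 0, b_div = 0, sd_site = 0.5,
                            sd_eco = 0.5,
                            n_iter = 100, n_chains = 2, jitter = 0,
                            seed = 1) {
  S <- max(site); E <- max(region); J <- ncol(Z)
  nm <- c("b0", paste0("gamma[", seq_len(J), "]"), "mu", "b_div", "k",
          "sd_site", "sd_eco", paste0("a[", seq_len(S), "]"),
          paste0("R[", seq_len(E), "]"))
  base <- c(b0, gamma, mu, b_div, k, sd_site, sd_eco, a, R)
  set.seed(seed)
  chains <- lapply(seq_len(n_chains), function(ch) {
    m <- matrix(rep(base, each = n_iter), nrow = n_iter,
                dimnames = list(NULL, nm))
    if (jitter > 0) m <- m + matrix(rnorm(length(m), 0, jitter), nrow = n_iter)
    coda::mcmc(m)
  })
  structure(list(samples = coda::mcmc.list(chains),
                 covariate_names = colnames(Z) %||%
                   paste0("x", seq_len(J)),
                 sites = paste0("S", seq_len(S)),
                 ecoregions = paste0("E", seq_len(E)),
                 data = list(o = o, Z = Z, site = site, region = region,
                             d = z_div, N = length(o), S = S, E = E,
                             J = J),
                 spec = NULL, convergence = NULL),
            class = "posterior_draws")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal hand-built analysis_table for model-level tests.
make_table <- function(o, Z, site_ids, eco_ids, z_div) {
  eco <- sort(unique(eco_ids))
  structure(list(
    data = data.frame(site_id = site_ids, ecoregion_id = eco_ids,
                      bleaching_pct = o),
    z = Z, o = as.integer(o), covariate_names = colnames(Z),
    standardization = NULL, dropped_covariates = NULL,
    dropped_rows = NULL, dropped_fraction = 0,
    site_ids = site_ids, ecoregion_ids = eco_ids, ecoregions = eco,
    z_diversity = stats::setNames(z_div, eco)
  ), class = "analysis_table")
}

# Simulate an iid-design dataset straight from the generative equations
# (no SST machinery), returning a ready analysis_table plus the truth.
sim_iid_dataset <- function(n, J = 3, S = max(2L, n %/% 5L), E = 4,
                            b0 = log(5), gamma = rep(0, J), k = 0.6,
                            site_sd = 0, eco_sd = 0, mu = 0, b_div = 0,
                            seed = 1) {
  set.seed(seed)
  site <- rep(seq_len(S), length.out = n)
  region <- rep(seq_len(E), length.out = S)
  z_div <- if (E > 1) as.numeric(scale(seq_len(E))) else 0
  Z <- matrix(rnorm(n * J), n, J,
              dimnames = list(NULL, paste0("x", seq_len(J))))
  R <- rnorm(E, mu + b_div * z_div, eco_sd)
  a <- rnorm(S, R[region], site_sd)
  lp <- b0 + drop(Z %*% gamma) + a[site]
  o <- rnbinom(n, mu = exp(lp), size = k)
  site_ids <- sprintf("S%04d", site)
  eco_ids <- sprintf("E%02d", region[site])
  tab <- make_table(o, Z, site_ids, eco_ids,
                    stats::setNames(z_div, sprintf("E%02d", seq_len(E))))
  list(table = tab,
       truth = list(b0 = b0, gamma = gamma, k = k, a = a, R = R,
                    mu = mu, b_div = b_div, site = site,
                    region = region, z_div = z_div))
}
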