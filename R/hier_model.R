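# Hierarchical Bayesian negative-binomial bleaching model.
#
# Observation level:   o_i ~ NB(mean p_i, dispersion k)
#                      log p_i = b0 + sum_j gamma_j z_ij + a_{s(i)}
# Site level:          a_s ~ Normal(R_{r(s)}, tau)
# Ecoregion level:     R_r ~ Normal(g_r, T),  g_r = mu + b_div * d_r
#
# tau and T are standard deviations in the public interface; the
# sampler works with precisions internally. The posterior is sampled
# with JAGS via rjags; the joint log density is also implemented
# directly in R (log_likelihood) for diagnostics and oracle testing.

#' MCMC specification for the bleaching model
#'
#' @param prior_sd_coefficients sd of the vague normal priors on the
#'   intercept, covariate coefficients, grand mean and diversity effect.
#' @param k_prior shape/rate of the vague gamma prior on the dispersion.
#' @param sd_prior_scale scale of the half-Cauchy priors on the site and
#'   ecoregion standard deviations.
#' @param n_chains number of chains (>= 2).
#' @param n_adapt JAGS adaptation steps.
#' @param n_burnin burn-in iterations discarded after adaptation.
#' @param n_iterations retained iterations per chain.
#' @param seed integer; chain RNGs derive from it, so runs are exactly
#'   reproducible.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(prior_sd_coefficients = 100,
                       k_prior = c(shape = 0.01, rate = 0.01),
                       sd_prior_scale = 2.5,
                       n_chains = 3,
                       n_adapt = 1000,
                       n_burnin = 4000,
                       n_iterations = 5000,
                       seed = 1L) {
  if (n_chains < 2) stop("n_chains must be >= 2")
  if (n_iterations <= 0) stop("n_iterations must be positive")
  structure(list(prior_sd_coefficients = prior_sd_coefficients,
                 k_prior = k_prior, sd_prior_scale = sd_prior_scale,
                 n_chains = as.integer(n_chains),
                 n_adapt = as.integer(n_adapt),
                 n_burnin = as.integer(n_burnin),
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed)),
            class = "model_spec")
}

bugs_model_code <- function() {
  "model {
    for (i in 1:N) {
      o[i] ~ dnegbin(prob[i], k)
      prob[i] <- k / (k + p[i])
      log(p[i]) <- b0 + inprod(Z[i, ], gamma[]) + a[site[i]]
    }
    for (s in 1:S) { a[s] ~ dnorm(R[region[s]], prec_site) }
    for (r in 1:E) {
      R[r] ~ dnorm(g[r], prec_eco)
      g[r] <- mu + b_div * d[r]
    }
    b0 ~ dnorm(0, prior_prec)
    for (j in 1:J) { gamma[j] ~ dnorm(0, prior_prec) }
    mu ~ dnorm(0, prior_prec)
    b_div ~ dnorm(0, prior_prec)
    k ~ dgamma(k_shape, k_rate)
    sd_site ~ dt(0, hc_prec, 1) T(0, )
    sd_eco ~ dt(0, hc_prec, 1) T(0, )
    prec_site <- pow(sd_site, -2)
    prec_eco <- pow(sd_eco, -2)
  }"
}

#' Fit the hierarchical bleaching model by MCMC
#'
#' Samples the posterior of the negative-binomial mixed model with JAGS.
#' Chains are initialised at neutral values with per-chain
#' Wichmann-Hill RNG seeds derived from `spec$seed`, so two runs with
#' the same spec and data produce identical draws. After sampling, a
#' convergence check (split R-hat, effective sample size) is run on the
#' top-level parameters and a warning names any parameter with
#' R-hat > 1.1.
#'
#' @param table an [build_analysis_table()] result.
#' @param spec a [model_spec()].
#' @return an object of class `posterior_draws`: list with `samples`
#'   (a `coda::mcmc.list`), `covariate_names`, `sites`, `ecoregions`,
#'   `data` (the model data actually used), `spec` and `convergence`.
#' @export
fit_bleaching_model <- function(table, spec = model_spec()) {
  stopifnot(inherits(table, "analysis_table"), inherits(spec, "model_spec"))
  if (length(table$o) == 0) stop("empty analysis table")
  sites <- unique(table$site_ids)
  site_idx <- match(table$site_ids, sites)
  eco <- table$ecoregions
  region_of_site <- match(table$ecoregion_ids[match(sites, table$site_ids)],
                          eco)
  if (anyNA(region_of_site))
    stop("every site must map to an ecoregion with a diversity value")

  J <- ncol(table$z)
  data <- list(o = table$o, Z = table$z, site = site_idx,
               region = region_of_site,
               d = as.numeric(table$z_diversity[eco]),
               N = length(table$o), S = length(sites), E = length(eco),
               J = J,
               prior_prec = spec$prior_sd_coefficients^-2,
               k_shape = spec$k_prior[["shape"]],
               k_rate = spec$k_prior[["rate"]],
               hc_prec = spec$sd_prior_scale^-2)
  inits <- lapply(seq_len(spec$n_chains), function(ch) {
    list(b0 = 0, gamma = rep(0, J), mu = 0, b_div = 0, k = 1,
         sd_site = 0.5, sd_eco = 0.5,
         a = rep(0, data$S), R = rep(0, data$E),
         .RNG.name = "base::Wichmann-Hill",
         .RNG.seed = spec$seed * 100L + ch)
  })
  jm <- rjags::jags.model(textConnection(bugs_model_code()), data = data,
                          inits = inits, n.chains = spec$n_chains,
                          n.adapt = spec$n_adapt, quiet = TRUE)
  if (spec$n_burnin > 0)
    stats::update(jm, n.iter = spec$n_burnin, progress.bar = "none")
  samples <- rjags::coda.samples(
    jm, variable.names = c("b0", "gamma", "mu", "b_div", "k",
                           "sd_site", "sd_eco", "a", "R"),
    n.iter = spec$n_iterations, progress.bar = "none")
  # coda drops the [1] suffix from length-1 vector nodes; restore it so
  # parameter addressing is uniform.
  samples <- coda::as.mcmc.list(lapply(samples, function(s) {
    cn <- colnames(s)
    for (v in c("gamma", "a", "R"))
      cn[cn == v] <- paste0(v, "[1]")
    colnames(s) <- cn
    s
  }))

  draws <- structure(list(samples = samples,
                          covariate_names = table$covariate_names,
                          sites = sites, ecoregions = eco,
                          data = data, spec = spec),
                     class = "posterior_draws")
  draws$convergence <- convergence_check(draws)
  bad <- draws$convergence$parameter[
    !is.na(draws$convergence$rhat) & draws$convergence$rhat > 1.1]
  if (length(bad))
    warning("possible non-convergence (split R-hat > 1.1) for: ",
            paste(bad, collapse = ", "))
  draws
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("<posterior_draws> ", length(x$samples), " chains x ",
      nrow(x$samples[[1]]), " iterations; ",
      length(x$covariate_names), " covariates, ", length(x$sites),
      " sites, ", length(x$ecoregions), " ecoregions\n", sep = "")
  invisible(x)
}

top_level_parameters <- function(draws) {
  c("b0", paste0("gamma[", seq_along(draws$covariate_names), "]"),
    "mu", "b_div", "k", "sd_site", "sd_eco")
}

# Combined draws matrix (all chains stacked) for selected columns.
draws_matrix <- function(draws, columns = NULL) {
  m <- as.matrix(draws$samples)
  if (!is.null(columns)) m <- m[, columns, drop = FALSE]
  m
}

#' Negative-binomial log pmf in mean-dispersion form
#' (mean `mu`, Var = mu + mu^2/k), implemented from the gamma-function
#' form of the pmf.
#' @keywords internal
nb_lpmf <- function(o, mu, k) {
  out <- numeric(length(o))
  z <- mu == 0
  out[z] <- ifelse(o[z] == 0, 0, -Inf)
  if (any(!z)) {
    o1 <- o[!z]; m1 <- mu[!z]
    out[!z] <- lgamma(o1 + k) - lgamma(k) - lfactorial(o1) +
      k * (log(k) - log(k + m1)) + o1 * (log(m1) - log(k + m1))
  }
  out
}

#' Joint log density of the hierarchical model
#'
#' Evaluates, in R and independently of the JAGS backend, the sum of the
#' negative-binomial log pmf over observations plus the normal log
#' densities of the site and ecoregion levels, at a given parameter
#' point. Prior terms are not included: this is the likelihood of the
#' data and latent effects.
#'
#' @param params list with `b0`, `gamma` (length = covariates), `a`
#'   (one per site, in `table` site order), `R` (one per ecoregion),
#'   `mu`, `b_div`, `k` (> 0), `site_sd`, `ecoregion_sd` (> 0 for the
#'   hierarchy terms to be defined).
#' @param table an `analysis_table`.
#' @return the scalar log density, with the three components as
#'   `attr(, "components")`. A non-finite linear predictor yields `-Inf`
#'   with a diagnostic attribute naming the first offending observation.
#' @export
log_likelihood <- function(params, table) {
  stopifnot(inherits(table, "analysis_table"))
  sites <- unique(table$site_ids)
  site_idx <- match(table$site_ids, sites)
  region_of_site <- match(table$ecoregion_ids[match(sites, table$site_ids)],
                          table$ecoregions)
  lp <- params$b0 + drop(table$z %*% params$gamma) + params$a[site_idx]
  if (any(!is.finite(lp))) {
    bad <- which(!is.finite(lp))[1]
    out <- -Inf
    attr(out, "diagnostic") <- paste0("non-finite linear predictor at ",
                                      "observation ", bad)
    return(out)
  }
  ll_data <- sum(nb_lpmf(table$o, exp(lp), params$k))
  ll_site <- sum(stats::dnorm(params$a, params$R[region_of_site],
                              params$site_sd, log = TRUE))
  g <- params$mu + params$b_div * as.numeric(table$z_diversity)
  ll_eco <- sum(stats::dnorm(params$R, g, params$ecoregion_sd, log = TRUE))
  out <- ll_data + ll_site + ll_eco
  attr(out, "components") <- c(data = ll_data, site = ll_site,
                               ecoregion = ll_eco)
  out
}

#' Posterior summaries and effect-sign classification
#'
#' Means, 50% and 95% equal-tailed credible intervals per parameter, and
#' the sign classification used for forest plots: `positive` if the 95%
#' CrI lies entirely above 0, `negative` if entirely below, `null` when
#' it crosses 0.
#'
#' @param draws a `posterior_draws`.
#' @param parameters monitored parameter names; defaults to the
#'   top-level parameters (intercept, coefficients, dispersion, grand
#'   mean, diversity effect, both sds).
#' @return data.frame of class `effect_summary` with columns
#'   `parameter`, `covariate` (for coefficients), `mean`, `l50`, `u50`,
#'   `l95`, `u95`, `classification`.
#' @export
summarize_effects <- function(draws, parameters = NULL) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (is.null(parameters)) parameters <- top_level_parameters(draws)
  m <- draws_matrix(draws, parameters)
  q <- t(apply(m, 2, stats::quantile,
               probs = c(0.025, 0.25, 0.75, 0.975), names = FALSE))
  cls <- ifelse(q[, 1] > 0, "positive", ifelse(q[, 4] < 0, "negative",
                                               "null"))
  cov <- rep(NA_character_, length(parameters))
  is_g <- grepl("^gamma\\[", parameters)
  cov[is_g] <- draws$covariate_names[
    as.integer(sub("^gamma\\[(\\d+)\\]$", "\\1", parameters[is_g]))]
  structure(data.frame(parameter = parameters, covariate = cov,
                       mean = colMeans(m),
                       l50 = q[, 2], u50 = q[, 3], l95 = q[, 1],
                       u95 = q[, 4], classification = cls,
                       row.names = NULL),
            class = c("effect_summary", "data.frame"))
}

split_rhat <- function(chains) {
  # chains: list of equal-length numeric vectors; each is split in half
  halves <- unlist(lapply(chains, function(v) {
    n <- length(v) %/% 2L
    list(v[seq_len(n)], v[n + seq_len(n)])
  }), recursive = FALSE)
  n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Split R-hat and effective sample size per parameter
#'
#' @param draws a `posterior_draws` (>= 2 chains required).
#' @param parameters parameter names; defaults to the top-level set.
#' @return data.frame with `parameter`, `rhat` (split R-hat; `NA` with
#'   `degenerate = TRUE` for constant chains), `ess`.
#' @export
convergence_check <- function(draws, parameters = NULL) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (length(draws$samples) < 2)
    stop("convergence diagnostics need >= 2 chains")
  if (is.null(parameters)) parameters <- top_level_parameters(draws)
  res <- lapply(parameters, function(p) {
    ch <- lapply(draws$samples, function(s) as.numeric(s[, p]))
    rh <- split_rhat(ch)
    ess <- sum(vapply(ch, function(v)
      as.numeric(coda::effectiveSize(coda::mcmc(v))), numeric(1)))
    data.frame(parameter = p, rhat = rh, ess = ess,
               degenerate = is.na(rh) && stats::var(unlist(ch)) == 0)
  })
  do.call(rbind, res)
}
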