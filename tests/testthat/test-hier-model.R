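nb_lpmf <- coralbleach:::nb_lpmf

test_that("negative-binomial log pmf matches closed forms and dnbinom", {
  # o = 0, p = 1, k = 1: pmf = k/(k+p) = 1/2
  expect_equal(nb_lpmf(0, 1, 1), log(0.5), tolerance = 1e-12)
  # oracle equivalence over a grid
  grid <- expand.grid(o = c(0, 1, 2, 7, 50), p = c(0.1, 1, 5, 40),
                      k = c(0.3, 1, 6))
  got <- with(grid, nb_lpmf(o, p, k))
  want <- with(grid, dnbinom(o, mu = p, size = k, log = TRUE))
  expect_equal(got, want, tolerance = 1e-8)
  # mean-zero degenerate case
  expect_equal(nb_lpmf(0, 0, 1), 0)
  expect_equal(nb_lpmf(3, 0, 1), -Inf)
})

test_that("joint log density: additivity and component structure", {
  d <- sim_iid_dataset(40, J = 2, S = 8, E = 2, gamma = c(0.3, -0.2),
                       site_sd = 0.4, eco_sd = 0.3, seed = 21)
  params <- list(b0 = 1, gamma = c(0.3, -0.2),
                 a = rnorm(8, 0, 0.2), R = c(0.1, -0.1), mu = 0,
                 b_div = 0.1, k = 0.8, site_sd = 0.4, ecoregion_sd = 0.3)
  ll <- log_likelihood(params, d$table)
  comp <- attr(ll, "components")
  expect_equal(as.numeric(ll), sum(comp))

  # doubling the observations doubles the data term exactly; the
  # site/ecoregion terms are unchanged (same latent effects)
  t2 <- d$table
  t2$o <- c(t2$o, t2$o)
  t2$z <- rbind(t2$z, t2$z)
  t2$site_ids <- c(t2$site_ids, t2$site_ids)
  t2$ecoregion_ids <- c(t2$ecoregion_ids, t2$ecoregion_ids)
  t2$data <- rbind(t2$data, t2$data)
  ll2 <- log_likelihood(params, t2)
  comp2 <- attr(ll2, "components")
  expect_equal(comp2[["data"]], 2 * comp[["data"]], tolerance = 1e-12)
  expect_equal(comp2[["site"]], comp[["site"]])
  expect_equal(comp2[["ecoregion"]], comp[["ecoregion"]])

  # agreement with a brute-force evaluation via dnbinom + dnorm
  site <- match(d$table$site_ids, unique(d$table$site_ids))
  lp <- params$b0 + drop(d$table$z %*% params$gamma) + params$a[site]
  brute <- sum(dnbinom(d$table$o, mu = exp(lp), size = params$k,
                       log = TRUE))
  expect_equal(comp[["data"]], brute, tolerance = 1e-8)
})

test_that("a non-finite linear predictor yields -Inf with a diagnostic", {
  d <- sim_iid_dataset(20, J = 1, S = 4, E = 2, seed = 22)
  params <- list(b0 = 1, gamma = Inf, a = rep(0, 4), R = c(0, 0),
                 mu = 0, b_div = 0, k = 1, site_sd = 1, ecoregion_sd = 1)
  ll <- log_likelihood(params, d$table)
  expect_identical(as.numeric(ll), -Inf)
  expect_match(attr(ll, "diagnostic"), "linear predictor")
})

test_that("posterior summaries classify effect signs by the 95% CrI", {
  d <- sim_iid_dataset(10, J = 1, S = 2, E = 2, seed = 23)
  dr <- make_fake_draws(d$table$o, d$table$z, d$truth$site,
                        d$truth$region, d$truth$z_div,
                        b0 = 2, n_iter = 500)
  s <- summarize_effects(dr)
  b0row <- s[s$parameter == "b0", ]
  expect_equal(b0row$mean, 2)
  expect_equal(c(b0row$l95, b0row$u95), c(2, 2))
  expect_equal(b0row$classification, "positive")
  # nested intervals
  expect_true(all(s$l95 <= s$l50 & s$u50 <= s$u95))

  # symmetric draws around zero classify as null; Normal(1, 0.1)
  # reproduces the analytic 95% interval
  dr2 <- make_fake_draws(d$table$o, d$table$z, d$truth$site,
                         d$truth$region, d$truth$z_div,
                         b0 = 0, gamma = 1, n_iter = 5000, jitter = 0.1,
                         seed = 99)
  s2 <- summarize_effects(dr2)
  expect_equal(s2$classification[s2$parameter == "b0"], "null")
  g <- s2[s2$parameter == "gamma[1]", ]
  expect_equal(c(g$l95, g$u95), c(0.804, 1.196), tolerance = 0.02)
  expect_equal(g$classification, "positive")
})

test_that("split R-hat separates mixed from unmixed chains", {
  d <- sim_iid_dataset(10, J = 1, S = 2, E = 2, seed = 24)
  dr <- make_fake_draws(d$table$o, d$table$z, d$truth$site,
                        d$truth$region, d$truth$z_div,
                        n_iter = 5000, jitter = 1, seed = 31)
  cc <- convergence_check(dr)
  expect_true(all(cc$rhat < 1.01))
  expect_true(all(cc$ess > 100))

  # chains centred 10 apart
  dr_bad <- dr
  m2 <- dr$samples[[2]] + 10
  dr_bad$samples <- coda::mcmc.list(dr$samples[[1]], coda::mcmc(m2))
  cc_bad <- convergence_check(dr_bad)
  expect_true(all(cc_bad$rhat > 1.1))

  # constant chains are flagged, not NaN-crashed
  dr_const <- make_fake_draws(d$table$o, d$table$z, d$truth$site,
                              d$truth$region, d$truth$z_div, n_iter = 50)
  cc_const <- convergence_check(dr_const)
  expect_true(all(is.na(cc_const$rhat)))
  expect_true(all(cc_const$degenerate))

  dr1 <- dr
  dr1$samples <- coda::mcmc.list(dr$samples[[1]])
  expect_error(convergence_check(dr1), "2 chains")
})

test_that("MCMC is reproducible and recovers the intercept scale", {
  d <- sim_iid_dataset(120, J = 1, S = 24, E = 3, seed = 25)
  spec <- model_spec(n_chains = 2, n_adapt = 100, n_burnin = 100,
                     n_iterations = 150, seed = 7)
  f1 <- suppressWarnings(fit_bleaching_model(d$table, spec))
  f2 <- suppressWarnings(fit_bleaching_model(d$table, spec))
  expect_identical(as.matrix(f1$samples), as.matrix(f2$samples))

  # tau = T = 0 data, gamma = 0: posterior b0 within 3 sd of log(5);
  # the identified location b0 + mu lands there too
  d5 <- sim_iid_dataset(500, J = 1, S = 50, E = 4, b0 = log(5),
                        seed = 26)
  spec5 <- model_spec(n_chains = 2, n_adapt = 200, n_burnin = 400,
                      n_iterations = 500, seed = 8)
  f5 <- suppressWarnings(fit_bleaching_model(d5$table, spec5))
  m <- coralbleach:::draws_matrix(f5, c("b0", "mu", "k"))
  expect_lt(abs(mean(m[, "b0"]) - log(5)), 3 * sd(m[, "b0"]))
  tot <- m[, "b0"] + m[, "mu"]
  expect_lt(abs(mean(tot) - log(5)), 4 * sd(tot) + 0.1)
  # dispersion recovered to the right order
  expect_gt(mean(m[, "k"]), 0.3)
  expect_lt(mean(m[, "k"]), 1.2)
})

test_that("posterior concentrates as the sample size grows", {
  gam <- c(0.5, -0.4)
  sd_g <- function(n, seed) {
    d <- sim_iid_dataset(n, J = 2, S = max(10, n %/% 8), E = 4,
                         gamma = gam, site_sd = 0.2, eco_sd = 0.2,
                         seed = seed)
    spec <- model_spec(n_chains = 2, n_adapt = 150, n_burnin = 250,
                       n_iterations = 300, seed = 9)
    f <- suppressWarnings(fit_bleaching_model(d$table, spec))
    m <- coralbleach:::draws_matrix(f, c("gamma[1]", "gamma[2]"))
    mean(apply(m, 2, sd))
  }
  expect_lt(sd_g(800, 28), sd_g(200, 27))
})
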