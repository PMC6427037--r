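fake_effects <- function(sig = c("dhw"), nonsig = c("depth")) {
  data.frame(
    parameter = paste0("gamma[", seq_along(c(sig, nonsig)), "]"),
    covariate = c(sig, nonsig),
    classification = c(rep("positive", length(sig)),
                       rep("null", length(nonsig))))
}

test_that("ecoregion z-scores standardize across retained ecoregions", {
  tab <- data.frame(
    ecoregion_id = rep(c("E1", "E2", "E3"), each = 12),
    dhw = rep(c(1, 2, 3), each = 12),
    depth = rep(5, 36))
  zs <- ecoregion_zscores(tab, fake_effects(), min_surveys = 10)
  expect_equal(zs$z_dhw, c(-1, 0, 1))
  expect_false("z_depth" %in% names(zs))   # non-significant: excluded

  # identical means give all-zero z-scores
  tab0 <- tab; tab0$dhw <- 2
  zs0 <- ecoregion_zscores(tab0, fake_effects(), 10)
  expect_equal(zs0$z_dhw, c(0, 0, 0))

  # z-scores have mean 0 / sd 1 across ecoregions
  set.seed(61)
  tabr <- data.frame(ecoregion_id = rep(sprintf("E%d", 1:6), each = 15),
                     dhw = rnorm(90))
  zr <- ecoregion_zscores(tabr, fake_effects(nonsig = character(0)), 10)
  expect_lt(abs(mean(zr$z_dhw)), 1e-9)
  expect_lt(abs(sd(zr$z_dhw) - 1), 1e-9)
})

test_that("ecoregions under the survey threshold are excluded", {
  tab <- data.frame(
    ecoregion_id = c(rep("E1", 10), rep("E2", 9), rep("E3", 30)),
    dhw = rnorm(49))
  zs <- ecoregion_zscores(tab, fake_effects(nonsig = character(0)),
                          min_surveys = 10)
  expect_equal(sort(zs$ecoregion_id), c("E1", "E3"))
  expect_equal(attr(zs, "excluded")$ecoregion_id, "E2")
  expect_equal(attr(zs, "excluded")$n_surveys, 9L)
})

test_that("latitude profile bins by absolute latitude", {
  tab <- data.frame(latitude = rep(c(17, -17), 10),
                    bleaching_pct = rep(c(50L, 50L), 10),
                    site_id = sprintf("S%02d", 1:20))
  prof <- latitude_profile(tab, 5)
  hit <- prof[prof$lat_lo == 15, ]
  expect_equal(hit$n_surveys, 20L)
  expect_equal(hit$prevalence, 1)
  expect_equal(hit$mean_bleaching, 50)
  # bands below 15 degrees are present but empty-flagged
  low <- prof[prof$lat_lo == 0, ]
  expect_equal(low$n_surveys, 0L)
  expect_true(is.na(low$prevalence))
})

test_that("a generated world with a mid-latitude effect peaks at 15-20", {
  # sites span 0..20 degrees; bleaching rises with absolute latitude,
  # so the 15-20 band must carry the highest prevalence
  cfg <- sim_config(n_ecoregions = 4, sites_per_ecoregion = 10,
                    weeks = 520, start_year = 2000, lat_extent = 20,
                    true_coefficients = c(abs_latitude = 1.2, depth = 0),
                    intercept = -0.5, seed = 62)
  w <- gen_world(cfg)
  sv <- gen_bleaching(w, cfg)
  tab <- data.frame(latitude = sv$latitude,
                    bleaching_pct = sv$bleaching_pct,
                    site_id = sv$site_id)
  prof <- latitude_profile(tab, 5)
  ok <- !is.na(prof$prevalence)
  expect_equal(prof$lat_lo[ok][which.max(prof$prevalence[ok])], 15)
})

test_that("effort correlation: monotone, constant and small-n cases", {
  prof <- data.frame(lat_lo = seq(0, 25, 5), lat_hi = seq(5, 30, 5),
                     n_surveys = c(10, 20, 30, 40, 50, 60),
                     n_sites = c(10, 20, 30, 40, 50, 60),
                     prevalence = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))
  r <- effort_correlation(prof)
  expect_equal(r$rho, 1)

  prof_const <- prof; prof_const$prevalence <- 0.3
  rc <- effort_correlation(prof_const)
  expect_true(is.na(rc$rho))
  expect_match(rc$flag, "constant")

  expect_error(effort_correlation(prof[1:3, ]), "4 latitude bands")
})

test_that("independent effort and prevalence rarely flag significance", {
  set.seed(63)
  rej <- replicate(500, {
    prof <- data.frame(n_surveys = rpois(8, 30) + 1,
                       n_sites = sample(10:100, 8),
                       prevalence = runif(8))
    effort_correlation(prof)$p_value < 0.05
  })
  expect_lt(mean(rej), 0.10)   # ~5% nominal
})

test_that("annual trend: Wilson intervals and boxplot quantiles", {
  tab <- data.frame(
    year = rep(c(2000, 2001), each = 10),
    bleaching_pct = c(c(0, 0, 0, 0, 0, 10, 20, 30, 40, 50),
                      rep(10L, 10)))
  tr <- annual_trend(tab)
  y0 <- tr[tr$year == 2000, ]
  expect_equal(y0$probability, 0.5)
  # closed-form Wilson interval for 5/10
  z <- qnorm(0.975)
  den <- 1 + z^2 / 10
  ctr <- (0.5 + z^2 / 20) / den
  hw <- z * sqrt(0.5 * 0.5 / 10 + z^2 / 400) / den
  expect_equal(c(y0$ci_lower, y0$ci_upper), c(ctr - hw, ctr + hw),
               tolerance = 1e-10)
  expect_equal(c(y0$ci_lower, y0$ci_upper), c(0.237, 0.763),
               tolerance = 0.01)
  expect_equal(y0$q25, quantile(tab$bleaching_pct[1:10], 0.25,
                                names = FALSE))

  y1 <- tr[tr$year == 2001, ]
  expect_equal(y1$probability, 1)
  expect_equal(y1$ci_upper, 1)
  expect_true(all(tr$ci_lower <= tr$probability &
                    tr$probability <= tr$ci_upper))
})

test_that("years without surveys are skipped and reported", {
  tab <- data.frame(year = c(2000, 2000, 2003),
                    bleaching_pct = c(0L, 5L, 2L))
  tr <- annual_trend(tab)
  expect_equal(tr$year, c(2000, 2003))
  expect_equal(attr(tr, "skipped_years"), c(2001, 2002))
})

test_that("rising anomaly pressure produces a rising annual probability", {
  cfg <- sim_config(n_ecoregions = 4, sites_per_ecoregion = 8,
                    weeks = 1040, start_year = 1998,
                    anomaly_event_rate = 0.05, anomaly_rate_growth = 0.25,
                    warming_trend = 0, intercept = -0.5,
                    true_coefficients = c(dhw = 1.0, depth = 0),
                    survey_years = c(2000, 2017), seed = 64)
  w <- gen_world(cfg)
  set.seed(65)
  sched <- data.frame(
    site_id = sample(w$sites$site_id, 1500, replace = TRUE),
    date = sample(w$grid$week_dates[
      coralbleach:::calendar_year(w$grid$week_dates) >= 2000], 1500,
      replace = TRUE))
  sv <- gen_bleaching(w, cfg, surveys = sched)
  tr <- annual_trend(data.frame(year = coralbleach:::calendar_year(sv$date),
                                bleaching_pct = sv$bleaching_pct))
  slope <- coef(lm(probability ~ year, tr))[2]
  expect_gt(slope, 0)
})
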