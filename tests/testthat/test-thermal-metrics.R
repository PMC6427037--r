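test_that("climatology of simple constructed series", {
  d <- weekly_dates(156)
  # constant series
  cl <- compute_climatology(new_sst_series(d, rep(28, 156)))
  expect_equal(unname(cl$weekly_means), rep(28, 52))
  expect_equal(cl$mmm, 28)

  # two-year series with year 2 = year 1 + 1: weekly means are year 1 + 0.5
  d2 <- weekly_dates(104)
  y1 <- 27 + sin(2 * pi * (1:52) / 52)
  wk <- coralbleach:::week_of_year(d2)
  temps <- numeric(104)
  temps[1:52] <- y1[wk[1:52]]
  temps[53:104] <- y1[wk[53:104]] + 1
  cl2 <- compute_climatology(new_sst_series(d2, temps))
  expect_equal(unname(cl2$weekly_means), unname(y1 + 0.5), tolerance = 1e-12)
})

test_that("sinusoidal series: MMM matches brute-force monthly means", {
  d <- weekly_dates(520)
  doy <- as.POSIXlt(d)$yday
  temps <- 27 + 2 * cos(2 * pi * (doy - 212) / 365.25)  # peak ~Aug 1
  cl <- compute_climatology(new_sst_series(d, temps))
  br <- brute_metrics(d, temps, d[520])
  expect_equal(cl$mmm, br$mmm, tolerance = 1e-12)
  # monthly averaging flattens the +2 peak only slightly
  expect_gt(cl$mmm, 28.8)
  expect_lt(cl$mmm, 29.0)
})

test_that("short baselines are rejected", {
  d <- weekly_dates(80)
  expect_error(compute_climatology(new_sst_series(d, rep(28, 80))),
               "insufficient baseline")
})

test_that("anomalies: SSTA vs weekly climatology, TSA vs MMM", {
  d <- weekly_dates(208)
  wkly <- 26 + 2 * cos(2 * pi * ((1:52) - 30) / 52)
  wk <- coralbleach:::week_of_year(d)
  temps <- wkly[wk]
  ser <- new_sst_series(d, temps)
  cl <- compute_climatology(ser)
  an <- compute_anomalies(ser, cl)
  expect_equal(max(abs(an$ssta)), 0, tolerance = 1e-12)

  ser2 <- new_sst_series(d, rep(cl$mmm + 2, 208))
  an2 <- compute_anomalies(ser2, cl)
  expect_equal(unique(an2$tsa), 2, tolerance = 1e-12)

  # one injected +3 degree spike week -> exactly one SSTA >= 1
  temps3 <- temps
  temps3[100] <- temps3[100] + 3
  an3 <- compute_anomalies(new_sst_series(d, temps3), cl)
  expect_equal(sum(an3$ssta >= 1), 1L)
})

test_that("SSTA means to zero over the climatology baseline", {
  set.seed(1)
  d <- weekly_dates(520)
  temps <- 27 + 2 * sin(2 * pi * (1:520) / 52) + rnorm(520, 0, 0.5)
  ser <- new_sst_series(d, temps)
  cl <- compute_climatology(ser)
  an <- compute_anomalies(ser, cl)
  expect_lt(abs(mean(an$ssta)), 1e-9)
})

test_that("DHW accumulation follows the 12-week >= 1 degree rule", {
  d <- weekly_dates(208)
  base <- rep(28, 208)
  ser <- new_sst_series(d, base)
  cl <- compute_climatology(ser)          # mmm = 28

  expect_equal(compute_dhw(ser, cl, d[100]), 0)

  t12 <- base; t12[89:100] <- 29          # 12 weeks at MMM + 1
  expect_equal(compute_dhw(new_sst_series(d, t12), cl, d[100]), 12)

  # sub-threshold weeks contribute nothing
  tmix <- base; tmix[89:94] <- 28.9; tmix[95:100] <- 30
  expect_equal(compute_dhw(new_sst_series(d, tmix), cl, d[100]), 12)

  expect_error(compute_dhw(ser, cl, d[5]), "window error")
})

test_that("DHW is invariant to shifting series and climatology jointly", {
  set.seed(2)
  d <- weekly_dates(208)
  temps <- 28 + rnorm(208, 0, 1)
  ser <- new_sst_series(d, temps)
  cl <- compute_climatology(ser)
  cl_shift <- cl
  cl_shift$weekly_means <- cl$weekly_means + 5
  cl_shift$mmm <- cl$mmm + 5
  ser_shift <- new_sst_series(d, temps + 5)
  expect_equal(compute_dhw(ser, cl, d[150]),
               compute_dhw(ser_shift, cl_shift, d[150]), tolerance = 1e-12)
})

test_that("rate of SST change handles line, flat and line + seasonal", {
  d <- weekly_dates(520)
  fy <- coralbleach:::frac_year(d)
  expect_equal(compute_rate_of_change(
    new_sst_series(d, 27 + 0.02 * (fy - fy[1]))), 0.02, tolerance = 1e-9)
  expect_equal(compute_rate_of_change(new_sst_series(d, rep(27, 520))), 0)
  # OLS is linear: a superposed seasonal cycle adds exactly its own
  # (tiny) slope contribution, computed here as the independent oracle
  d10 <- weekly_dates(520)
  fy10 <- coralbleach:::frac_year(d10)
  seas <- 2 * sin(2 * pi * fy10)
  temps <- 27 + 0.03 * (fy10 - fy10[1]) + seas
  seas_slope <- cov(fy10, seas) / var(fy10)
  expect_equal(compute_rate_of_change(new_sst_series(d10, temps)),
               0.03 + seas_slope, tolerance = 1e-9)
})

test_that("metrics for a flat series are all at their degenerate values", {
  d <- weekly_dates(156)
  ser <- new_sst_series(d, rep(28, 156))
  cl <- compute_climatology(ser)
  m <- metrics_for_survey(ser, cl, d[150])
  expect_equal(m$ssta_freq, 0)
  expect_equal(m$tsa_freq, 0)
  expect_equal(m$dhw, 0)
  expect_equal(m$sst_stdev, 0)
  expect_false(m$missing_data)
})

test_that("metrics match the brute-force oracle on a 200-week series", {
  set.seed(3)
  d <- weekly_dates(200)
  temps <- 27 + 2.5 * sin(2 * pi * (1:200) / 52) + rnorm(200, 0, 0.8)
  temps[40:43] <- temps[40:43] + 3     # anomaly block
  ser <- new_sst_series(d, temps)
  cl <- compute_climatology(ser)
  m <- metrics_for_survey(ser, cl, d[190])
  br <- brute_metrics(d, temps, d[190])
  expect_equal(unname(cl$weekly_means), br$weekly, tolerance = 1e-10)
  expect_equal(cl$mmm, br$mmm, tolerance = 1e-10)
  for (f in c("sst_at_survey", "sst_min", "sst_max", "sst_stdev", "ssta",
              "ssta_stdev", "ssta_freq", "ssta_freq_stdev", "tsa",
              "tsa_stdev", "tsa_freq", "tsa_freq_stdev", "dhw",
              "rate_of_sst_change"))
    expect_equal(m[[f]], br[[f]], tolerance = 1e-10, label = f)
})

test_that("later surveys accumulate at least as much DHW inside an anomaly", {
  d <- weekly_dates(156)
  temps <- rep(28, 156)
  temps[120:135] <- 30                  # sustained anomaly
  ser <- new_sst_series(d, temps)
  cl <- compute_climatology(new_sst_series(d, rep(28, 156)))
  expect_gte(compute_dhw(ser, cl, d[130]), compute_dhw(ser, cl, d[124]))
})

test_that("excess missing weeks flag the record instead of guessing", {
  d <- weekly_dates(156)
  temps <- rep(28, 156)
  temps[1:40] <- NA
  ser <- new_sst_series(d, temps)
  cl <- compute_climatology(new_sst_series(d, rep(28, 156)))
  m <- metrics_for_survey(ser, cl, d[150], max_gap_frac = 0.1)
  expect_true(m$missing_data)
  expect_true(all(is.na(m[setdiff(names(m), "missing_data")])))
})
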