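# CoRTAD-style thermal-stress metrics from weekly SST series.
#
# Conventions (documented in the methods vignette):
#  * fixed 52-week climatology, week 53 folded into week 52;
#  * MMM = maximum of the long-term calendar-month means;
#  * DHW  = sum of (SST - MMM) over the trailing 12-week window,
#    counting only weeks at least 1 °C above MMM (°C-weeks);
#  * anomaly frequencies count weeks with SSTA (or TSA) >= 1 °C.

#' Long-term weekly climatology and maximum monthly mean
#'
#' @param series an [new_sst_series()].
#' @param baseline_years two-element year range used as baseline;
#'   default the full span of the series.
#' @return class `sst_climatology`: list with `weekly_means` (52 values,
#'   °C), `mmm` (°C, the warmest long-term monthly mean) and
#'   `baseline_years`.
#' @export
compute_climatology <- function(series, baseline_years = NULL) {
  stopifnot(inherits(series, "sst_series"))
  yr <- calendar_year(series$week_dates)
  if (is.null(baseline_years)) baseline_years <- range(yr)
  in_base <- yr >= baseline_years[1] & yr <= baseline_years[2]
  if (sum(in_base) < 104L)
    stop("insufficient baseline: need >= 2 full years (104 weeks) ",
         "inside ", baseline_years[1], "-", baseline_years[2],
         ", have ", sum(in_base), " weeks")
  wk <- week_of_year(series$week_dates[in_base])
  temps <- series$temps[in_base]
  weekly_means <- vapply(1:52, function(w)
    mean(temps[wk == w], na.rm = TRUE), numeric(1))
  mo <- as.POSIXlt(series$week_dates[in_base])$mon + 1L
  monthly_means <- vapply(sort(unique(mo)), function(m)
    mean(temps[mo == m], na.rm = TRUE), numeric(1))
  structure(list(weekly_means = weekly_means,
                 mmm = max(monthly_means),
                 baseline_years = baseline_years),
            class = "sst_climatology")
}

#' Weekly SST and thermal-stress anomalies
#'
#' SSTA is the departure from the week-of-year climatology; TSA is the
#' departure from the maximum monthly mean (the warmest-month baseline).
#'
#' @param series an `sst_series`.
#' @param clim an `sst_climatology`.
#' @return data.frame with `date`, `sst`, `ssta`, `tsa` (°C per week).
#' @export
compute_anomalies <- function(series, clim) {
  stopifnot(inherits(series, "sst_series"), inherits(clim, "sst_climatology"))
  wk <- week_of_year(series$week_dates)
  data.frame(date = series$week_dates,
             sst = series$temps,
             ssta = series$temps - clim$weekly_means[wk],
             tsa = series$temps - clim$mmm)
}

#' Degree Heating Weeks at a date
#'
#' Accumulates thermal stress over the trailing 12-week window ending at
#' `at_date`: weeks at least 1 °C above the maximum monthly mean
#' contribute their full exceedance (°C-weeks); cooler weeks contribute
#' nothing. 8 DHW is the conventional severe-bleaching level.
#'
#' @param series an `sst_series`.
#' @param clim an `sst_climatology`.
#' @param at_date the accumulation endpoint (`Date`).
#' @return DHW in °C-weeks (>= 0).
#' @export
compute_dhw <- function(series, clim, at_date) {
  stopifnot(inherits(series, "sst_series"), inherits(clim, "sst_climatology"))
  at_date <- as.Date(at_date)
  idx <- findInterval(as.numeric(at_date), as.numeric(series$week_dates))
  if (idx < 1L || at_date > max(series$week_dates) + 6)
    stop("at_date ", format(at_date), " outside the series")
  if (idx < 12L)
    stop("window error: need >= 12 weeks of history before ",
         format(at_date), ", have ", idx)
  hot <- series$temps[(idx - 11L):idx] - clim$mmm
  sum(hot[!is.na(hot) & hot >= 1])
}

#' Long-run SST warming rate
#'
#' Ordinary least-squares slope of weekly temperature against time in
#' fractional years.
#'
#' @param series an `sst_series`.
#' @param years optional two-element calendar-year range to restrict to.
#' @return slope in °C per year.
#' @export
compute_rate_of_change <- function(series, years = NULL) {
  stopifnot(inherits(series, "sst_series"))
  yr <- calendar_year(series$week_dates)
  keep <- if (is.null(years)) rep(TRUE, length(yr)) else
    yr >= years[1] & yr <= years[2]
  keep <- keep & !is.na(series$temps)
  if (!any(keep)) stop("empty year range for rate of SST change")
  if (length(unique(yr[keep])) < 2L)
    stop("need >= 2 calendar years to estimate a rate of change")
  t <- frac_year(series$week_dates[keep])
  y <- series$temps[keep]
  stats::cov(t, y) / stats::var(t)
}

#' Full thermal-covariate set for one survey
#'
#' Assembles the per-survey covariate vector used by the bleaching
#' model: the survey-week SST; min/max/standard deviation of SST over
#' the series up to the survey; the survey-week SSTA and TSA with their
#' standard deviations; anomaly frequencies (weeks with SSTA >= 1 °C,
#' resp. TSA >= 1 °C, up to the survey) and the dispersion of those
#' counts across years; DHW at the survey date; the OLS rate of SST
#' change up to the survey; and the climatological SST for the survey
#' week.
#'
#' @param series an `sst_series`.
#' @param clim an `sst_climatology`.
#' @param survey_date survey `Date` (matched to its containing week).
#' @param max_gap_frac maximum tolerated fraction of missing weeks up
#'   to the survey; beyond it every metric is returned `NA` with a
#'   `missing_data` flag so downstream filtering can drop the record.
#' @return one-row data.frame of metrics (column `missing_data` logical).
#' @export
metrics_for_survey <- function(series, clim, survey_date,
                               max_gap_frac = 0.1) {
  stopifnot(inherits(series, "sst_series"), inherits(clim, "sst_climatology"))
  survey_date <- as.Date(survey_date)
  idx <- findInterval(as.numeric(survey_date),
                      as.numeric(series$week_dates))
  if (idx < 1L || survey_date > max(series$week_dates) + 6)
    stop("survey_date ", format(survey_date), " not covered by the series")

  temps <- series$temps[seq_len(idx)]
  dates <- series$week_dates[seq_len(idx)]
  na_frac <- mean(is.na(temps))
  empty <- data.frame(
    sst_at_survey = NA_real_, sst_min = NA_real_, sst_max = NA_real_,
    sst_stdev = NA_real_, ssta = NA_real_, ssta_stdev = NA_real_,
    ssta_freq = NA_real_, ssta_freq_stdev = NA_real_, tsa = NA_real_,
    tsa_stdev = NA_real_, tsa_freq = NA_real_, tsa_freq_stdev = NA_real_,
    dhw = NA_real_, rate_of_sst_change = NA_real_, clim_sst = NA_real_,
    missing_data = TRUE
  )
  if (na_frac > max_gap_frac) return(empty)

  wk <- week_of_year(dates)
  ssta <- temps - clim$weekly_means[wk]
  tsa <- temps - clim$mmm
  yr <- calendar_year(dates)
  yearly_ssta <- tapply(!is.na(ssta) & ssta >= 1, yr, sum)
  yearly_tsa <- tapply(!is.na(tsa) & tsa >= 1, yr, sum)

  data.frame(
    sst_at_survey = temps[idx],
    sst_min = min(temps, na.rm = TRUE),
    sst_max = max(temps, na.rm = TRUE),
    sst_stdev = stats::sd(temps, na.rm = TRUE),
    ssta = ssta[idx],
    ssta_stdev = stats::sd(ssta, na.rm = TRUE),
    ssta_freq = sum(ssta >= 1, na.rm = TRUE),
    ssta_freq_stdev = if (length(yearly_ssta) > 1)
      stats::sd(yearly_ssta) else 0,
    tsa = tsa[idx],
    tsa_stdev = stats::sd(tsa, na.rm = TRUE),
    tsa_freq = sum(tsa >= 1, na.rm = TRUE),
    tsa_freq_stdev = if (length(yearly_tsa) > 1) stats::sd(yearly_tsa) else 0,
    dhw = if (idx >= 12L) compute_dhw(series, clim, survey_date) else
      NA_real_,
    rate_of_sst_change = if (length(unique(yr[!is.na(temps)])) >= 2L)
      compute_rate_of_change(new_sst_series(dates, temps, series$cell))
      else NA_real_,
    clim_sst = clim$weekly_means[wk[idx]],
    missing_data = FALSE
  )
}

#' Covariate table for a set of surveys
#'
#' Computes [metrics_for_survey()] for every survey of a schedule over a
#' synthetic (or any) SST grid, caching the per-cell series and
#' climatology, and appends the non-thermal covariates (absolute
#' latitude, depth, survey year).
#'
#' @param world a `synthetic_world`.
#' @param surveys data.frame with `site_id` and `date` (defaults to the
#'   world's configured survey schedule).
#' @param baseline_years climatology baseline passed to
#'   [compute_climatology()].
#' @param max_gap_frac see [metrics_for_survey()].
#' @return data.frame keyed by `site_id` and `date` with all thermal
#'   metrics plus `abs_latitude`, `latitude`, `depth`, `year`.
#' @export
covariate_table <- function(world, surveys = NULL, baseline_years = NULL,
                            max_gap_frac = 0.1) {
  stopifnot(inherits(world, "synthetic_world"))
  if (is.null(surveys)) surveys <- gen_survey_schedule(world, world$config)
  srow <- match(surveys$site_id, world$sites$site_id)
  if (anyNA(srow)) stop("surveys reference unknown site ids")
  cell_key <- paste(world$sites$lat_idx[srow], world$sites$lon_idx[srow])

  cache <- new.env(parent = emptyenv())
  get_cell <- function(key, lat_idx, lon_idx) {
    if (is.null(cache[[key]])) {
      ser <- sst_series(world$grid, lat_idx, lon_idx)
      cache[[key]] <- list(series = ser,
                           clim = compute_climatology(ser, baseline_years))
    }
    cache[[key]]
  }

  rows <- vector("list", nrow(surveys))
  for (i in seq_len(nrow(surveys))) {
    cc <- get_cell(cell_key[i], world$sites$lat_idx[srow[i]],
                   world$sites$lon_idx[srow[i]])
    rows[[i]] <- metrics_for_survey(cc$series, cc$clim, surveys$date[i],
                                    max_gap_frac)
  }
  met <- do.call(rbind, rows)
  cbind(data.frame(site_id = surveys$site_id,
                   ecoregion_id = world$sites$ecoregion_id[srow],
                   date = as.Date(surveys$date),
                   latitude = world$sites$latitude[srow],
                   abs_latitude = abs(world$sites$latitude[srow]),
                   depth = world$sites$depth[srow],
                   year = calendar_year(surveys$date)),
        met)
}
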