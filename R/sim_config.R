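#' Configuration for the synthetic coral-bleaching world
#'
#' Bundles every knob of the synthetic-data generator: the weekly SST
#' grid (seasonality, warming trend, anomaly regime), the spatial layout
#' (ecoregions, sites, diversity gradient), the survey effort model, and
#' the generative bleaching model
#' \deqn{o_i \sim \mathrm{NB}(p_i, k), \quad
#'       \log p_i = b_0 + \sum_j \gamma_j z_{ij} + a_{s(i)},}
#' with site effects \eqn{a_s \sim N(R_r, \tau)}, ecoregion effects
#' \eqn{R_r \sim N(\mu + b_{div} d_r, T)} and the negative binomial in
#' mean--dispersion form, \eqn{Var(o_i) = p_i + p_i^2/k}.
#'
#' Defaults describe a desk-scale world that mirrors the structure of a
#' global reef-survey compilation: 36 years of weekly SST, sites grouped
#' in latitudinal ecoregions between 30°S and 30°N, a diversity gradient
#' peaking at the Equator, surveys concentrated in the final two decades
#' with a right-skewed per-site revisit count (mean 2.75, sd 3.17), and
#' zero-inflated percent-bleaching counts (roughly half the observations
#' are zero under the defaults).
#'
#' @param n_ecoregions number of latitudinal ecoregions.
#' @param sites_per_ecoregion survey sites per ecoregion.
#' @param weeks length of the weekly SST axis; at least 104 so a
#'   climatology exists.
#' @param start_year first calendar year of the SST axis.
#' @param seasonal_amplitude °C amplitude of the sinusoidal seasonal
#'   cycle (phase flips across the Equator).
#' @param warming_trend long-run SST trend, °C per year.
#' @param anomaly_sd typical magnitude (°C) of positive thermal-anomaly
#'   events.
#' @param anomaly_event_rate expected anomaly events per cell per year.
#' @param anomaly_rate_growth additive yearly increment to the event
#'   rate (events/year/year); 0 keeps the anomaly regime stationary.
#' @param noise_sd °C standard deviation of weekly white noise.
#' @param true_coefficients named vector of generative coefficients
#'   \eqn{\gamma} on the standardized-covariate scale; names must be
#'   columns of the covariate table (thermal metrics, `abs_latitude`,
#'   `depth`, `year`).
#' @param intercept generative intercept \eqn{b_0} (log scale).
#' @param dispersion negative-binomial dispersion \eqn{k > 0}.
#' @param site_sd standard deviation \eqn{\tau} of site effects.
#' @param ecoregion_sd standard deviation \eqn{T} of ecoregion effects.
#' @param diversity_effect coefficient \eqn{b_{div}} of standardized
#'   ecoregion species richness.
#' @param overall_mean grand mean \eqn{\mu} of the ecoregion level.
#' @param survey_years two-element year range in which surveys happen;
#'   default is the final 20 years of the SST axis.
#' @param surveys_per_site_mean,surveys_per_site_sd moments of the
#'   per-site survey count (right-skewed; zero counts promoted to one
#'   visit so every site is observed).
#' @param grid_lon longitudes (°E) of grid-cell centers.
#' @param lat_extent sites and ecoregions span `[-lat_extent, lat_extent]`
#'   degrees latitude; the grid covers the same band at 1° resolution.
#' @param seed integer seed from which all generator sub-streams derive.
#'
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_ecoregions = 4, sites_per_ecoregion = 3, weeks = 520)
#' cfg$dispersion
#' @export
sim_config <- function(n_ecoregions = 20,
                       sites_per_ecoregion = 15,
                       weeks = 1872,
                       start_year = 1982,
                       seasonal_amplitude = 3,
                       warming_trend = 0.02,
                       anomaly_sd = 1.5,
                       anomaly_event_rate = 0.5,
                       anomaly_rate_growth = 0,
                       noise_sd = 0.3,
                       true_coefficients = c(ssta_freq = 0.6,
                                             ssta_stdev = -0.5,
                                             dhw = 0.15,
                                             rate_of_sst_change = 0.2,
                                             depth = 0),
                       intercept = 0.5,
                       dispersion = 0.6,
                       site_sd = 0.3,
                       ecoregion_sd = 0.25,
                       diversity_effect = -0.2,
                       overall_mean = 0,
                       survey_years = NULL,
                       surveys_per_site_mean = 2.75,
                       surveys_per_site_sd = 3.17,
                       grid_lon = seq(150.5, 157.5, by = 1),
                       lat_extent = 30,
                       seed = 1L) {
  cfg <- list(
    n_ecoregions = as.integer(n_ecoregions),
    sites_per_ecoregion = as.integer(sites_per_ecoregion),
    weeks = as.integer(weeks),
    start_year = as.integer(start_year),
    seasonal_amplitude = seasonal_amplitude,
    warming_trend = warming_trend,
    anomaly_sd = anomaly_sd,
    anomaly_event_rate = anomaly_event_rate,
    anomaly_rate_growth = anomaly_rate_growth,
    noise_sd = noise_sd,
    true_coefficients = true_coefficients,
    intercept = intercept,
    dispersion = dispersion,
    site_sd = site_sd,
    ecoregion_sd = ecoregion_sd,
    diversity_effect = diversity_effect,
    overall_mean = overall_mean,
    survey_years = survey_years,
    surveys_per_site_mean = surveys_per_site_mean,
    surveys_per_site_sd = surveys_per_site_sd,
    grid_lon = grid_lon,
    lat_extent = lat_extent,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$weeks < 104L)
    stop("configuration error: 'weeks' must be >= 104 (two full years ",
         "so a climatology can be formed), got ", cfg$weeks)
  if (cfg$n_ecoregions < 1L || cfg$sites_per_ecoregion < 1L)
    stop("configuration error: ecoregion and site counts must be positive")
  if (!is.finite(cfg$dispersion) || cfg$dispersion <= 0)
    stop("configuration error: dispersion k must be > 0")
  if (cfg$site_sd < 0 || cfg$ecoregion_sd < 0)
    stop("configuration error: site_sd and ecoregion_sd must be >= 0")
  if (is.null(names(cfg$true_coefficients)) ||
      any(!nzchar(names(cfg$true_coefficients))))
    stop("configuration error: true_coefficients must be a named vector")
  n_years <- cfg$weeks %/% 52L
  last_year <- cfg$start_year + n_years - 1L
  if (is.null(cfg$survey_years))
    cfg$survey_years <- c(max(cfg$start_year + 2L, last_year - 19L), last_year)
  if (cfg$survey_years[1] > cfg$survey_years[2] ||
      cfg$survey_years[2] > last_year ||
      cfg$survey_years[1] < cfg$start_year)
    stop("configuration error: survey_years must lie inside the SST axis")
  cfg
}
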