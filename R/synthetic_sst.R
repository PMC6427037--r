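#' Generate a weekly gridded SST field
#'
#' Builds a latitude x longitude x week array of sea-surface
#' temperatures. Each cell's series is
#' baseline + seasonal cycle + linear warming trend + white noise +
#' sparse positive anomaly blocks. The baseline decreases away from the
#' Equator; the seasonal phase is flipped by 26 weeks in the southern
#' hemisphere so austral and boreal summers land half a year apart.
#' Anomaly events arrive at `anomaly_event_rate` per year (optionally
#' ramping by `anomaly_rate_growth` per year), last a handful of weeks,
#' and add a positive excursion of magnitude around `anomaly_sd` °C.
#'
#' @param config a [sim_config()].
#' @return an object of class `sst_grid`: a list with `lat`, `lon`
#'   (cell-center coordinate vectors), `week_dates` (a `Date` vector at
#'   7-day spacing) and `sst` (array `[lat, lon, week]`, °C).
#' @examples
#' g <- gen_sst_grid(sim_config(weeks = 156, seed = 7))
#' dim(g$sst)
#' @export
gen_sst_grid <- function(config) {
  config <- validate_sim_config(config)
  lat <- seq(-config$lat_extent + 0.5, config$lat_extent - 0.5, by = 1)
  lon <- config$grid_lon
  weeks <- config$weeks
  week_dates <- as.Date(paste0(config$start_year, "-01-04")) + 7 * (0:(weeks - 1))
  t_years <- frac_year(week_dates) - frac_year(week_dates[1])
  wk <- week_of_year(week_dates)

  # Baseline: warm pool at the Equator, cooling quadratically poleward.
  baseline <- 29.5 - 3.5 * (abs(lat) / 30)^2
  # Seasonal peak near week 33 (boreal late summer) in the north,
  # week 7 in the south.
  peak_n <- 33; peak_s <- 7
  seas_n <- config$seasonal_amplitude * cos(2 * pi * (wk - peak_n) / 52)
  seas_s <- config$seasonal_amplitude * cos(2 * pi * (wk - peak_s) / 52)
  trend <- config$warming_trend * t_years

  n_years <- weeks %/% 52L
  sst <- array(NA_real_, dim = c(length(lat), length(lon), weeks))
  with_seed(stage_seed(config$seed, "sst"), {
    for (i in seq_along(lat)) {
      seas <- if (lat[i] < 0) seas_s else seas_n
      for (j in seq_along(lon)) {
        x <- baseline[i] + seas + trend
        if (config$noise_sd > 0)
          x <- x + stats::rnorm(weeks, 0, config$noise_sd)
        if (config$anomaly_event_rate > 0 || config$anomaly_rate_growth > 0) {
          for (y in seq_len(n_years)) {
            rate <- max(0, config$anomaly_event_rate +
                          config$anomaly_rate_growth * (y - 1))
            n_ev <- stats::rpois(1, rate)
            if (n_ev > 0) {
              for (e in seq_len(n_ev)) {
                start <- (y - 1L) * 52L + sample.int(52L, 1L)
                dur <- 4L + stats::rpois(1, 3)
                mag <- abs(stats::rnorm(1, config$anomaly_sd,
                                        config$anomaly_sd / 3))
                idx <- start:min(weeks, start + dur - 1L)
                x[idx] <- x[idx] + mag
              }
            }
          }
        }
        sst[i, j, ] <- x
      }
    }
  })
  structure(list(lat = lat, lon = lon, week_dates = week_dates, sst = sst),
            class = "sst_grid")
}

#' @export
print.sst_grid <- function(x, ...) {
  cat("<sst_grid> ", length(x$lat), " x ", length(x$lon), " cells, ",
      length(x$week_dates), " weeks (",
      format(x$week_dates[1]), " .. ", format(max(x$week_dates)), ")\n",
      sep = "")
  invisible(x)
}

#' Extract one cell's weekly SST series
#'
#' @param grid an `sst_grid`.
#' @param lat_idx,lon_idx cell indices into `grid$lat` / `grid$lon`.
#' @return an `sst_series`: list with `week_dates`, `temps` (°C) and
#'   `cell = c(lat, lon)`.
#' @export
sst_series <- function(grid, lat_idx, lon_idx) {
  stopifnot(inherits(grid, "sst_grid"))
  new_sst_series(grid$week_dates, grid$sst[lat_idx, lon_idx, ],
                 c(grid$lat[lat_idx], grid$lon[lon_idx]))
}

#' Construct an SST series from raw vectors
#'
#' @param week_dates strictly increasing `Date`s at roughly 7-day
#'   spacing.
#' @param temps weekly temperatures, °C (NA = missing week).
#' @param cell optional `(lat, lon)` of the source cell.
#' @export
new_sst_series <- function(week_dates, temps, cell = c(NA_real_, NA_real_)) {
  week_dates <- as.Date(week_dates)
  if (length(week_dates) != length(temps))
    stop("week_dates and temps must have equal length")
  d <- diff(as.numeric(week_dates))
  if (any(d <= 0)) stop("week_dates must be strictly increasing")
  structure(list(week_dates = week_dates, temps = as.numeric(temps),
                 cell = cell),
            class = "sst_series")
}

# Nearest grid cell (by cell-center distance in degrees) for a site.
nearest_cell <- function(grid, latitude, longitude) {
  c(lat_idx = which.min(abs(grid$lat - latitude)),
    lon_idx = which.min(abs(grid$lon - longitude)))
}
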