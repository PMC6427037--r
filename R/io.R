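# External-format interfaces: CF-style NetCDF for SST grids, CSV for
# tabular artifacts, YAML for configuration.

#' Write an SST grid to a CF-style NetCDF file
#'
#' Dimensions `lat`, `lon`, `time` (days since 1970-01-01) and variable
#' `sst` in °C. Requires the `ncdf4` package.
#'
#' @param grid an `sst_grid`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sst_netcdf <- function(grid, path) {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("writing NetCDF requires the 'ncdf4' package")
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", grid$lat)
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", grid$lon)
  dtime <- ncdf4::ncdim_def("time", "days since 1970-01-01",
                            as.numeric(grid$week_dates), unlim = TRUE)
  vsst <- ncdf4::ncvar_def("sst", "degree_C", list(dlat, dlon, dtime),
                           missval = -9999, prec = "double")
  nc <- ncdf4::nc_create(path, vsst)
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, vsst, grid$sst)
  invisible(path)
}

#' Read an SST grid from a CF-like NetCDF file
#'
#' Expects `lat`, `lon`, `time` dimensions and an `sst` variable; the
#' time axis must be days since 1970-01-01 (as written by
#' [write_sst_netcdf()]).
#'
#' @param path NetCDF file path.
#' @return an `sst_grid`.
#' @export
read_sst_netcdf <- function(path) {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("reading NetCDF requires the 'ncdf4' package")
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  structure(list(lat = as.numeric(nc$dim$lat$vals),
                 lon = as.numeric(nc$dim$lon$vals),
                 week_dates = as.Date(as.numeric(nc$dim$time$vals),
                                      origin = "1970-01-01"),
                 sst = ncdf4::ncvar_get(nc, "sst", collapse_degen = FALSE)),
            class = "sst_grid")
}

#' Load a simulation configuration from YAML or JSON
#'
#' Scalar fields override [sim_config()] defaults;
#' `true_coefficients` must be a named mapping.
#'
#' @param path YAML (or JSON, by extension) file.
#' @return a validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.null(raw$true_coefficients))
    raw$true_coefficients <- unlist(raw$true_coefficients)
  do.call(sim_config, raw)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
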