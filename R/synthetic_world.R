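#' Generate the synthetic survey world
#'
#' Lays ecoregions out as contiguous latitudinal bands spanning
#' `[-lat_extent, lat_extent]`, assigns each a species-richness count
#' that decays away from the Equator (the classic equatorial diversity
#' gradient), scatters survey sites uniformly inside their ecoregion's
#' band, and maps every site to its nearest SST grid cell. Everything is
#' deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return an object of class `synthetic_world`: list with the
#'   `sst_grid`, an `ecoregions` table (id, band edges, center), a
#'   `diversity` table (ecoregion id, species count), a `sites` table
#'   (site id, ecoregion id, latitude, longitude, depth m, grid cell
#'   indices) and the `config`.
#' @examples
#' w <- gen_world(sim_config(n_ecoregions = 2, sites_per_ecoregion = 2,
#'                           weeks = 260))
#' w$sites
#' @export
gen_world <- function(config) {
  config <- validate_sim_config(config)
  grid <- gen_sst_grid(config)
  E <- config$n_ecoregions
  width <- 2 * config$lat_extent / E
  lat_min <- -config$lat_extent + width * (seq_len(E) - 1)
  ecoregions <- data.frame(
    ecoregion_id = sprintf("E%02d", seq_len(E)),
    lat_min = lat_min,
    lat_max = lat_min + width,
    lat_center = lat_min + width / 2
  )

  world <- with_seed(stage_seed(config$seed, "world"), {
    # Diversity: equatorial peak ~600 species falling towards ~150 at
    # the band edges, with mild ecoregion-level scatter.
    div <- round(150 + 450 * exp(-(abs(ecoregions$lat_center) / 15)^2) +
                   stats::rnorm(E, 0, 10))
    diversity <- data.frame(ecoregion_id = ecoregions$ecoregion_id,
                            species_count = pmax(20, div))

    n_sites <- E * config$sites_per_ecoregion
    site_eco <- rep(seq_len(E), each = config$sites_per_ecoregion)
    lat <- stats::runif(n_sites, ecoregions$lat_min[site_eco],
                        ecoregions$lat_max[site_eco])
    lon <- stats::runif(n_sites, min(grid$lon) - 0.5, max(grid$lon) + 0.5)
    depth <- stats::runif(n_sites, 2, 12)
    cells <- t(vapply(seq_len(n_sites),
                      function(i) nearest_cell(grid, lat[i], lon[i]),
                      c(lat_idx = 0, lon_idx = 0)))
    sites <- data.frame(
      site_id = sprintf("S%04d", seq_len(n_sites)),
      ecoregion_id = ecoregions$ecoregion_id[site_eco],
      latitude = lat, longitude = lon, depth = depth,
      lat_idx = as.integer(cells[, "lat_idx"]),
      lon_idx = as.integer(cells[, "lon_idx"])
    )
    list(diversity = diversity, sites = sites)
  })

  structure(list(grid = grid, ecoregions = ecoregions,
                 diversity = world$diversity, sites = world$sites,
                 config = config),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("<synthetic_world> ", nrow(x$sites), " sites in ",
      nrow(x$ecoregions), " ecoregions; SST ", length(x$grid$week_dates),
      " weeks\n", sep = "")
  invisible(x)
}

# Survey schedule: per-site revisit counts follow a right-skewed count
# distribution matched to the configured mean/sd (negative binomial with
# k = m^2/(v - m)); zero counts are promoted to one visit. Dates are
# uniform over the survey window.
gen_survey_schedule <- function(world, config) {
  m <- config$surveys_per_site_mean
  v <- config$surveys_per_site_sd^2
  n_sites <- nrow(world$sites)
  with_seed(stage_seed(config$seed, "surveys"), {
    n_i <- if (v > m) {
      stats::rnbinom(n_sites, mu = m, size = m^2 / (v - m))
    } else {
      stats::rpois(n_sites, m)
    }
    n_i <- pmax(1L, n_i)
    wd <- world$grid$week_dates
    yr <- calendar_year(wd)
    ok <- which(yr >= config$survey_years[1] & yr <= config$survey_years[2])
    site_rows <- rep(seq_len(n_sites), n_i)
    week_idx <- ok[sample.int(length(ok), length(site_rows), replace = TRUE)]
    data.frame(site_id = world$sites$site_id[site_rows],
               date = wd[week_idx])[order(site_rows, week_idx), ,
                                    drop = FALSE]
  })
}

#' Generate bleaching observations from the hierarchical model
#'
#' Draws percent-bleaching counts for a schedule of surveys from the
#' generative model: ecoregion effects \eqn{R_r \sim N(\mu + b_{div}
#' z^{div}_r, T)}, site effects \eqn{a_s \sim N(R_{r(s)}, \tau)}, a
#' log-linear predictor over standardized thermal covariates,
#' \eqn{\log p_i = b_0 + \sum_j \gamma_j z_{ij} + a_{s(i)}}, and
#' negative-binomial counts with mean \eqn{p_i} and dispersion \eqn{k}
#' (variance \eqn{p_i + p_i^2/k}). Counts are capped at 100 so they
#' remain interpretable as percentages; the cap rate is recorded and is
#' far below 0.1% under default configurations.
#'
#' The latent truth (coefficients, site and ecoregion effects, the
#' standardized design matrix and standardization parameters) is
#' attached as `attr(, "truth")` for parameter-recovery experiments.
#'
#' @param world a [gen_world()] result.
#' @param config the same [sim_config()]; `names(config$true_coefficients)`
#'   select covariate-table columns as predictors.
#' @param surveys optional survey schedule (`site_id`, `date`); by
#'   default one is drawn from the configured effort model.
#' @param covariates optional precomputed [covariate_table()] for
#'   `surveys`; supplying it avoids recomputing thermal metrics when
#'   many bleaching realisations are drawn over one world.
#' @return a data.frame of survey records (site id, ecoregion id,
#'   latitude, longitude, depth, date, `bleaching_pct` integer 0..100)
#'   with attributes `truth` and `cap_rate`.
#' @export
gen_bleaching <- function(world, config = world$config, surveys = NULL,
                          covariates = NULL) {
  stopifnot(inherits(world, "synthetic_world"))
  config <- validate_sim_config(config)
  if (is.null(surveys)) surveys <- gen_survey_schedule(world, config)
  if (is.null(covariates)) covariates <- covariate_table(world, surveys)
  gam <- config$true_coefficients
  miss <- setdiff(names(gam), names(covariates))
  if (length(miss))
    stop("true_coefficients name unknown covariates: ",
         paste(miss, collapse = ", "))
  X <- as.matrix(covariates[names(gam)])
  for (nm in names(gam)) {
    if (any(!is.finite(X[, nm])))
      stop("generation error: non-finite covariate '", nm,
           "' for ", sum(!is.finite(X[, nm])), " survey(s)")
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0))
    stop("generation error: constant covariate '",
         names(gam)[which(scl == 0)[1]], "'")
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  eco_ids <- world$ecoregions$ecoregion_id
  d <- world$diversity$species_count[match(eco_ids,
                                           world$diversity$ecoregion_id)]
  z_div <- as.numeric(scale(d))
  site_eco <- match(world$sites$ecoregion_id, eco_ids)
  obs_site <- match(covariates$site_id, world$sites$site_id)

  res <- with_seed(stage_seed(config$seed, "bleaching"), {
    g <- config$overall_mean + config$diversity_effect * z_div
    R <- stats::rnorm(length(eco_ids), g, config$ecoregion_sd)
    a <- stats::rnorm(nrow(world$sites), R[site_eco], config$site_sd)
    lp <- config$intercept + drop(Z %*% gam) + a[obs_site]
    if (any(!is.finite(lp)))
      stop("generation error: non-finite linear predictor at survey ",
           which(!is.finite(lp))[1])
    o_raw <- stats::rnbinom(length(lp), mu = exp(lp), size = config$dispersion)
    list(o = pmin(o_raw, 100L), cap_rate = mean(o_raw > 100L),
         g = g, R = R, a = a)
  })

  out <- data.frame(
    site_id = covariates$site_id,
    ecoregion_id = world$sites$ecoregion_id[obs_site],
    latitude = world$sites$latitude[obs_site],
    longitude = world$sites$longitude[obs_site],
    depth = world$sites$depth[obs_site],
    date = covariates$date,
    bleaching_pct = as.integer(res$o)
  )
  attr(out, "truth") <- list(
    intercept = config$intercept, gamma = gam, dispersion = config$dispersion,
    site_sd = config$site_sd, ecoregion_sd = config$ecoregion_sd,
    overall_mean = config$overall_mean,
    diversity_effect = config$diversity_effect,
    site_effects = stats::setNames(res$a, world$sites$site_id),
    ecoregion_effects = stats::setNames(res$R, eco_ids),
    z = Z, center = ctr, scale = scl, z_div = stats::setNames(z_div, eco_ids)
  )
  attr(out, "cap_rate") <- res$cap_rate
  out
}
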