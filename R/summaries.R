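# Descriptive spatial and temporal layers: ecoregion covariate
# z-scores, latitude-band bleaching prevalence, the sampling-effort
# check, and the annual bleaching-probability trend.

#' Ecoregion z-scores of the significant covariates
#'
#' For every covariate whose 95% credible interval excludes zero in the
#' fitted model, computes the ecoregion mean of the (natural-scale)
#' covariate and expresses it as the number of standard deviations from
#' the covariate's mean over all retained ecoregions. Ecoregions with
#' fewer than `min_surveys` surveys are excluded and reported.
#'
#' @param table data.frame with `ecoregion_id` and covariate columns
#'   (e.g. the `data` element of an `analysis_table`).
#' @param effects an [summarize_effects()] result (or any data.frame
#'   with `covariate` and `classification` columns).
#' @param min_surveys minimum surveys for an ecoregion to be retained
#'   (default 10).
#' @return data.frame with `ecoregion_id`, `n_surveys` and one `z_*`
#'   column per significant covariate; excluded ecoregions in
#'   `attr(, "excluded")`.
#' @export
ecoregion_zscores <- function(table, effects, min_surveys = 10) {
  sig <- effects$covariate[!is.na(effects$covariate) &
                             effects$classification != "null"]
  if (!length(sig)) stop("no significant covariates to summarize")
  stopifnot(all(sig %in% names(table)))
  n <- table(table$ecoregion_id)
  keep <- names(n)[n >= min_surveys]
  if (length(keep) < 2)
    stop("fewer than 2 ecoregions with >= ", min_surveys,
         " surveys; z-scores undefined")
  excluded <- data.frame(ecoregion_id = names(n)[n < min_surveys],
                         n_surveys = as.integer(n[n < min_surveys]))
  sub <- table[table$ecoregion_id %in% keep, , drop = FALSE]
  out <- data.frame(ecoregion_id = keep,
                    n_surveys = as.integer(n[keep]))
  for (v in sig) {
    m <- tapply(sub[[v]], sub$ecoregion_id, mean)[keep]
    s <- stats::sd(m)
    out[[paste0("z_", v)]] <- if (s == 0) rep(0, length(m)) else
      as.numeric((m - mean(m)) / s)
  }
  attr(out, "excluded") <- excluded
  out
}

#' Bleaching prevalence by absolute-latitude band
#'
#' Bins surveys into absolute-latitude bands of the given width and
#' reports per band the number of surveys, the number of distinct
#' sites, the mean percent bleaching, and the bleaching prevalence
#' (fraction of surveys with bleaching > 0). Empty bands are reported
#' with `n_surveys = 0` and `NA` prevalence.
#'
#' @param table data.frame with `latitude` (or `abs_latitude`),
#'   `bleaching_pct` and optionally `site_id`.
#' @param band_width degrees per band (default 5).
#' @return data.frame of class `latitude_profile` with `lat_lo`,
#'   `lat_hi`, `n_surveys`, `n_sites`, `mean_bleaching`, `prevalence`.
#' @export
latitude_profile <- function(table, band_width = 5) {
  al <- if ("abs_latitude" %in% names(table)) table$abs_latitude else
    abs(table$latitude)
  stopifnot(!is.null(al), "bleaching_pct" %in% names(table))
  edges <- seq(0, ceiling(max(al) / band_width) * band_width,
               by = band_width)
  band <- findInterval(al, edges, rightmost.closed = TRUE)
  out <- do.call(rbind, lapply(seq_len(length(edges) - 1), function(b) {
    in_b <- band == b
    data.frame(
      lat_lo = edges[b], lat_hi = edges[b + 1],
      n_surveys = sum(in_b),
      n_sites = if ("site_id" %in% names(table))
        length(unique(table$site_id[in_b])) else sum(in_b),
      mean_bleaching = if (any(in_b)) mean(table$bleaching_pct[in_b])
        else NA_real_,
      prevalence = if (any(in_b)) mean(table$bleaching_pct[in_b] > 0)
        else NA_real_)
  }))
  class(out) <- c("latitude_profile", "data.frame")
  out
}

#' Spearman check of bleaching prevalence against sampling effort
#'
#' Rank correlation (tie-corrected, two-sided) between per-band
#' bleaching prevalence and per-band site counts, to verify that the
#' latitudinal prevalence pattern is not an artefact of where surveys
#' were concentrated.
#'
#' @param profile a [latitude_profile()].
#' @return list with `rho`, `p_value`, `n_bands`, and `flag` (set when
#'   rho is undefined because prevalence or effort is constant).
#' @export
effort_correlation <- function(profile) {
  ok <- profile$n_surveys > 0 & !is.na(profile$prevalence)
  if (sum(ok) < 4) stop("need >= 4 latitude bands with data, have ",
                        sum(ok))
  prev <- profile$prevalence[ok]
  eff <- profile$n_sites[ok]
  if (stats::sd(prev) == 0 || stats::sd(eff) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n_bands = sum(ok),
                flag = "constant input: rho undefined"))
  ct <- suppressWarnings(stats::cor.test(prev, eff, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_bands = sum(ok), flag = NA_character_)
}

# Wilson score interval for a binomial proportion.
wilson_interval <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ph <- x / n
  den <- 1 + z^2 / n
  ctr <- (ph + z^2 / (2 * n)) / den
  hw <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

#' Annual bleaching probability and percent-bleaching distribution
#'
#' Per calendar year: the fraction of surveys with any bleaching
#' (with a Wilson 95% confidence interval) and the distribution of
#' percent bleaching (mean, interquartile range, 95% range) matching
#' the usual box-plot summaries. Years without surveys are skipped and
#' listed in `attr(, "skipped_years")`.
#'
#' @param table data.frame with `bleaching_pct` and `year` (or `date`).
#' @return data.frame with `year`, `n_surveys`, `probability`,
#'   `ci_lower`, `ci_upper`, `mean_bleaching`, `q25`, `q75`, `q025`,
#'   `q975`.
#' @export
annual_trend <- function(table) {
  yr <- if ("year" %in% names(table)) table$year else
    calendar_year(as.Date(table$date))
  years <- sort(unique(yr))
  if (length(years) < 2) stop("need surveys from >= 2 years")
  out <- do.call(rbind, lapply(years, function(y) {
    b <- table$bleaching_pct[yr == y]
    ci <- wilson_interval(sum(b > 0), length(b))
    q <- stats::quantile(b, c(0.25, 0.75, 0.025, 0.975), names = FALSE)
    data.frame(year = y, n_surveys = length(b),
               probability = mean(b > 0),
               ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
               mean_bleaching = mean(b),
               q25 = q[1], q75 = q[2], q025 = q[3], q975 = q[4])
  }))
  all_years <- seq(min(years), max(years))
  attr(out, "skipped_years") <- setdiff(all_years, years)
  out
}
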