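# Survey/covariate preprocessing: missing-data removal, collinearity
# pruning, covariate standardization, assembly of the model table.

#' Drop surveys with missing covariates or unmapped ecoregions
#'
#' @param table data.frame of surveys with covariate columns.
#' @param covariate_names columns that must be complete.
#' @param diversity optional data.frame (`ecoregion_id`,
#'   `species_count`); rows whose ecoregion is absent are removed with
#'   reason "outside ecoregion".
#' @return the filtered table with attributes `dropped_rows` (row index,
#'   reason) and `dropped_fraction`.
#' @export
drop_incomplete <- function(table, covariate_names, diversity = NULL) {
  stopifnot(all(covariate_names %in% names(table)))
  reason <- rep(NA_character_, nrow(table))
  miss <- rowSums(!is.finite(as.matrix(table[covariate_names]))) > 0
  reason[miss] <- "missing covariate"
  if (!is.null(diversity) && "ecoregion_id" %in% names(table)) {
    un <- !(table$ecoregion_id %in% diversity$ecoregion_id) & is.na(reason)
    reason[un] <- "outside ecoregion"
  }
  drop <- !is.na(reason)
  if (all(drop)) stop("empty table: every row was removed ",
                      "(missing covariates / unmapped ecoregions)")
  out <- table[!drop, , drop = FALSE]
  attr(out, "dropped_rows") <- data.frame(row = which(drop),
                                          reason = reason[drop])
  attr(out, "dropped_fraction") <- mean(drop)
  out
}

#' Greedy collinearity pruning of a covariate set
#'
#' Computes pairwise Pearson correlations and, while any pair exceeds
#' the threshold in absolute value, drops the member of the currently
#' worst pair having the larger mean absolute correlation with all other
#' covariates (ties broken by column order). Constant columns are
#' excluded up front with a warning, since their correlation is
#' undefined. Every drop is recorded with the pair that triggered it.
#'
#' @param table data.frame or matrix of numeric covariates.
#' @param threshold absolute-correlation cutoff (default 0.65).
#' @return list with `retained` (names), `dropped` (data.frame: name,
#'   partner, correlation, reason) and the final correlation matrix.
#' @export
collinearity_prune <- function(table, threshold = 0.65) {
  X <- as.data.frame(table)
  stopifnot(ncol(X) >= 2, nrow(X) >= 3)
  dropped <- data.frame(name = character(), partner = character(),
                        correlation = numeric(), reason = character())
  const <- vapply(X, function(x) stats::sd(x) == 0 || !all(is.finite(x)),
                  logical(1))
  if (any(const)) {
    warning("excluding constant/non-finite covariate(s) before pruning: ",
            paste(names(X)[const], collapse = ", "))
    dropped <- rbind(dropped, data.frame(
      name = names(X)[const], partner = NA_character_,
      correlation = NA_real_, reason = "constant"))
    X <- X[!const]
  }
  repeat {
    if (ncol(X) < 2) break
    r <- abs(stats::cor(X))
    diag(r) <- 0
    if (max(r) <= threshold) break
    worst <- which(r == max(r), arr.ind = TRUE)[1, ]
    pair <- colnames(r)[worst]
    mean_abs <- colMeans(abs(stats::cor(X)))[pair]  # includes self = 1, same for both
    victim <- pair[which.max(mean_abs)]             # ties -> first in order
    partner <- setdiff(pair, victim)[1]
    dropped <- rbind(dropped, data.frame(
      name = victim, partner = partner,
      correlation = stats::cor(X[[victim]], X[[partner]]),
      reason = "collinear"))
    X <- X[setdiff(names(X), victim)]
  }
  list(retained = names(X), dropped = dropped,
       correlations = stats::cor(X))
}

#' Standardize covariates to mean 0, sd 1
#'
#' Centers and scales each column with the sample standard deviation
#' (n - 1); the per-column parameters are returned so fitted
#' coefficients can be mapped back to natural units.
#'
#' @param table data.frame of numeric covariates.
#' @return list with `z` (standardized data.frame) and `params`
#'   (data.frame: name, center, scale).
#' @export
standardize_covariates <- function(table) {
  X <- as.data.frame(table)
  ctr <- vapply(X, mean, numeric(1))
  scl <- vapply(X, stats::sd, numeric(1))
  if (any(scl == 0))
    stop("cannot standardize constant column(s): ",
         paste(names(X)[scl == 0], collapse = ", "))
  z <- as.data.frame(mapply(function(x, m, s) (x - m) / s, X, ctr, scl,
                            SIMPLIFY = FALSE))
  list(z = z, params = data.frame(name = names(X), center = ctr,
                                  scale = scl, row.names = NULL))
}

#' Map a standardized-scale coefficient back to natural units
#'
#' @param gamma coefficient on the standardized scale.
#' @param scale the covariate's standardization sd.
#' @return effect per natural unit of the covariate.
#' @export
unstandardize_coef <- function(gamma, scale) gamma / scale

#' Assemble the analysis table for the hierarchical model
#'
#' Applies, in order: missing-data removal ([drop_incomplete()]),
#' collinearity pruning ([collinearity_prune()]) and standardization
#' ([standardize_covariates()]), and joins the standardized ecoregion
#' diversity covariate.
#'
#' @param covariates a [covariate_table()]-like data.frame including
#'   `site_id`, `ecoregion_id` and `bleaching_pct`.
#' @param diversity data.frame `ecoregion_id`, `species_count`.
#' @param covariate_names candidate predictors (default: all thermal
#'   metrics plus absolute latitude, depth and year).
#' @param prune_threshold absolute-correlation cutoff; `NULL` or a
#'   value >= 1 disables pruning.
#' @return an object of class `analysis_table`: list with `data` (the
#'   retained surveys), `z` (standardized design matrix),
#'   `covariate_names`, `standardization`, `dropped_covariates`,
#'   `dropped_rows`, `site_ids`, `ecoregion_ids`, `z_diversity` (one
#'   standardized value per ecoregion) and the observation vector `o`.
#' @export
build_analysis_table <- function(covariates, diversity,
                                 covariate_names = NULL,
                                 prune_threshold = 0.65) {
  if (is.null(covariate_names))
    covariate_names <- intersect(
      c("sst_at_survey", "sst_min", "sst_max", "sst_stdev", "ssta",
        "ssta_stdev", "ssta_freq", "ssta_freq_stdev", "tsa", "tsa_stdev",
        "tsa_freq", "tsa_freq_stdev", "dhw", "rate_of_sst_change",
        "clim_sst", "abs_latitude", "depth", "year"),
      names(covariates))
  stopifnot("bleaching_pct" %in% names(covariates),
            "ecoregion_id" %in% names(covariates))
  dat <- drop_incomplete(covariates, covariate_names, diversity)

  if (!is.null(prune_threshold) && prune_threshold < 1) {
    pr <- collinearity_prune(dat[covariate_names], prune_threshold)
    kept <- pr$retained
    dropped_cov <- pr$dropped
  } else {
    kept <- covariate_names
    dropped_cov <- data.frame(name = character(), partner = character(),
                              correlation = numeric(), reason = character())
  }
  std <- standardize_covariates(dat[kept])

  eco <- sort(unique(dat$ecoregion_id))
  d <- diversity$species_count[match(eco, diversity$ecoregion_id)]
  z_div <- if (length(eco) > 1 && stats::sd(d) > 0) as.numeric(scale(d))
           else rep(0, length(eco))

  structure(list(
    data = dat,
    z = as.matrix(std$z),
    o = as.integer(dat$bleaching_pct),
    covariate_names = kept,
    standardization = std$params,
    dropped_covariates = dropped_cov,
    dropped_rows = attr(dat, "dropped_rows"),
    dropped_fraction = attr(dat, "dropped_fraction"),
    site_ids = as.character(dat$site_id),
    ecoregion_ids = as.character(dat$ecoregion_id),
    ecoregions = eco,
    z_diversity = stats::setNames(z_div, eco)
  ), class = "analysis_table")
}

#' @export
print.analysis_table <- function(x, ...) {
  cat("<analysis_table> ", length(x$o), " surveys, ",
      length(unique(x$site_ids)), " sites, ", length(x$ecoregions),
      " ecoregions\n  covariates: ",
      paste(x$covariate_names, collapse = ", "), "\n  dropped: ",
      nrow(x$dropped_covariates), " covariate(s), ",
      nrow(x$dropped_rows %||% data.frame()), " row(s)\n", sep = "")
  invisible(x)
}
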