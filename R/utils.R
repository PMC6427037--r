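# Small shared helpers: calendar arithmetic on weekly time axes and
# seed management for reproducible sub-streams.

#' Week-of-year index on a fixed 52-week calendar
#'
#' Maps dates to a week-of-year in 1..52; the occasional 53rd week is
#' folded into week 52 so climatologies have exactly 52 entries.
#'
#' @param dates a `Date` vector.
#' @return integer vector in 1..52.
#' @keywords internal
week_of_year <- function(dates) {
  yday <- as.POSIXlt(dates)$yday  # 0-based day of year
  pmin(52L, yday %/% 7L + 1L)
}

#' Fractional calendar year
#' @param dates a `Date` vector.
#' @return numeric years, e.g. 1998.5 for mid-1998.
#' @keywords internal
frac_year <- function(dates) {
  lt <- as.POSIXlt(dates)
  1900 + lt$year + lt$yday / 365.25
}

calendar_year <- function(dates) as.POSIXlt(dates)$year + 1900L

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generators are deterministic
#' given their seed without clobbering the caller's RNG stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Named sub-stream seeds derived from one global seed, so no stage
# consumes unseeded randomness and stages stay independent.
.stage_offsets <- c(
  sst = 11L, world = 23L, surveys = 37L, bleaching = 41L,
  fit = 53L, ppc = 67L, decades = 71L, acceptance = 83L
)

#' @keywords internal
stage_seed <- function(seed, stage) {
  stopifnot(stage %in% names(.stage_offsets))
  (as.integer(seed) %% 20000000L) * 100L + .stage_offsets[[stage]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ISO-timestamped one-line logger used by the pipeline driver.
log_line <- function(..., file = NULL) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ", ...)
  if (!is.null(file)) cat(msg, "\n", file = file, append = TRUE, sep = "")
  message(msg)
  invisible(msg)
}
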