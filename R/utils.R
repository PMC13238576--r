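#' Linear-interpolation percentile
#'
#' Percentile of a numeric vector using linear interpolation between order
#' statistics (\code{stats::quantile} type 7). Pinned here so climatology and
#' severity thresholds use one definition throughout the package.
#'
#' @param x numeric vector, NAs dropped.
#' @param p percentile in (0, 100).
#' @return the interpolated percentile value.
#' @keywords internal
pctl <- function(x, p) {
  stopifnot(is.numeric(x), p > 0, p < 100)
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("no finite values to take a percentile of")
  unname(stats::quantile(x, p / 100, type = 7, names = FALSE))
}

#' Round half-up at a fixed number of decimals
#'
#' Base R rounds half-to-even; published epidemiology tables round half-up.
#' Used wherever table percentages are formatted.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Number of location-days in a span of calendar years
#'
#' One location-day is one region on one calendar day; leap years contribute
#' 366 days. For 68 regions over 2001-2023 this gives 571,200.
#'
#' @param n_regions number of spatial units.
#' @param start_year,end_year inclusive calendar-year span.
#' @return integer count of location-days.
#' @export
location_days <- function(n_regions, start_year, end_year) {
  stopifnot(n_regions >= 1, end_year >= start_year)
  yrs <- start_year:end_year
  leap <- (yrs %% 4 == 0 & yrs %% 100 != 0) | yrs %% 400 == 0
  as.integer(n_regions * sum(ifelse(leap, 366L, 365L)))
}

# shared logging: functions that can drop/clamp data attach a "log" attribute
hw_log <- function(x, msg) {
  lg <- attr(x, "hw_log")
  attr(x, "hw_log") <- c(lg, msg)
  x
}

#' Retrieve processing log messages attached to a result
#' @param x an object returned by a package function.
#' @return character vector of log messages (possibly empty).
#' @export
processing_log <- function(x) {
  lg <- attr(x, "hw_log")
  if (is.null(lg)) character(0) else lg
}
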