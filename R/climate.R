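#' Construct a gridded climate field
#'
#' A grid field holds one variable (temperature or dewpoint, degrees C) on a
#' regular 2-D grid over a strictly increasing, equally spaced time axis.
#' Values are stored as a time x cell matrix; cells are indexed row-major from
#' the north-west corner so that weight files referencing flat cell indices
#' are portable. Kelvin input (unit attribute "K") is converted by -273.15.
#'
#' @param values numeric matrix, rows = time steps, columns = grid cells
#'   (row-major from the NW corner), or a 3-d array (time, y, x).
#' @param time POSIXct or Date vector, one per row of \code{values}.
#' @param variable "temperature" or "dewpoint".
#' @param unit "C" (default) or "K"; Kelvin is converted on construction.
#' @return an object of class \code{grid_field}.
#' @export
grid_field <- function(values, time, variable = c("temperature", "dewpoint"),
                       unit = c("C", "K")) {
  variable <- match.arg(variable)
  unit <- match.arg(unit)
  if (is.array(values) && length(dim(values)) == 3L) {
    d <- dim(values)
    # (time, y, x) row-major flatten: cell index runs along x fastest
    values <- matrix(aperm(values, c(3, 2, 1)), nrow = d[1], byrow = TRUE)
  }
  values <- as.matrix(values)
  if (nrow(values) != length(time)) stop("time axis length != rows of values")
  dt <- diff(as.numeric(time))
  if (length(dt) > 0 && (any(dt <= 0) || any(abs(dt - dt[1]) > 1e-6)))
    stop("time axis must be strictly increasing and equally spaced")
  if (unit == "K") values <- values - 273.15
  fin <- values[is.finite(values)]
  if (length(fin) && (min(fin) < -20 || max(fin) > 60))
    stop(sprintf("%s values outside plausible range [-20, 60] degC", variable))
  structure(list(values = values, time = time, variable = variable),
            class = "grid_field")
}

#' Read a gridded field from long-format CSV
#'
#' Columns: \code{time} (ISO-8601 date or datetime), \code{cell_index}
#' (1-based flat index, row-major from NW), \code{value}.
#'
#' @param path CSV path.
#' @inheritParams grid_field
#' @return a \code{grid_field}.
#' @export
read_grid_csv <- function(path, variable = c("temperature", "dewpoint"),
                          unit = c("C", "K")) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time", "cell_index", "value") %in% names(d)))
  tm <- sort(unique(d$time))
  cells <- seq_len(max(d$cell_index))
  m <- matrix(NA_real_, length(tm), length(cells))
  m[cbind(match(d$time, tm), d$cell_index)] <- d$value
  time <- if (all(nchar(tm) > 10)) as.POSIXct(tm, tz = "UTC") else as.Date(tm)
  grid_field(m, time, variable = match.arg(variable), unit = match.arg(unit))
}

#' Relative humidity from temperature and dewpoint
#'
#' Magnus saturation vapour pressure with Alduchov-Eskridge constants,
#' e_s(T) = 6.1094 exp(17.625 T / (T + 243.04)) hPa, giving
#' RH = 100 e_s(Td) / e_s(T), clamped to [0, 100]. A dewpoint above the
#' temperature is physically inconsistent; such pairs are clamped to 100%
#' and counted in the result's processing log.
#'
#' @param temperature air temperature, degrees C.
#' @param dewpoint dewpoint temperature, degrees C.
#' @return relative humidity in percent, same length as the inputs, with a
#'   processing-log attribute when clamping occurred.
#' @export
derive_relative_humidity <- function(temperature, dewpoint) {
  if (length(temperature) != length(dewpoint))
    stop("temperature and dewpoint must have equal length")
  if (any(!is.finite(temperature)) || any(!is.finite(dewpoint)))
    stop("non-finite temperature or dewpoint")
  es <- function(t) 6.1094 * exp(17.625 * t / (t + 243.04))
  rh <- 100 * es(dewpoint) / es(temperature)
  n_clamp <- sum(dewpoint > temperature)
  rh <- pmin(pmax(rh, 0), 100)
  if (n_clamp > 0) {
    warning(sprintf("%d dewpoint(s) exceeded temperature; RH clamped to 100%%",
                    n_clamp))
    rh <- hw_log(rh, sprintf("rh_clamped:%d", n_clamp))
  }
  rh
}

#' Aggregate an hourly grid field to daily means
#'
#' Per cell and local calendar day, the arithmetic mean of the hourly values.
#' The day boundary is local Northern Territory civil time (UTC+9:30, no
#' daylight saving). A day is valid only when at most \code{max_missing_hours}
#' of its 24 hours are missing (default 0); otherwise the day is masked.
#' Partially covered first/last days are dropped and counted in the log.
#'
#' @param field hourly \code{grid_field}.
#' @param tz_offset_hours offset from UTC of the local civil day, default 9.5.
#' @param max_missing_hours missing hours tolerated per day, default 0.
#' @return a daily \code{grid_field} with a \code{Date} time axis.
#' @export
daily_aggregate <- function(field, tz_offset_hours = 9.5,
                            max_missing_hours = 0L) {
  stopifnot(inherits(field, "grid_field"))
  tt <- as.POSIXct(field$time, tz = "UTC")
  local <- tt + tz_offset_hours * 3600
  day <- as.Date(local, tz = "UTC")
  tab <- table(day)
  full <- names(tab)[tab == 24L]
  n_drop <- sum(tab != 24L)
  keep <- day %in% as.Date(full)
  v <- field$values[keep, , drop = FALSE]
  g <- factor(as.character(day[keep]), levels = full)
  means <- rowsum(ifelse(is.na(v), 0, v), g) / pmax(rowsum((!is.na(v)) * 1, g), 1)
  nmiss <- rowsum(is.na(v) * 1, g)
  means[nmiss > max_missing_hours] <- NA_real_
  out <- grid_field(means, as.Date(full), variable = field$variable)
  if (n_drop > 0) out <- hw_log(out, sprintf("partial_days_dropped:%d", n_drop))
  if (any(nmiss > max_missing_hours))
    out <- hw_log(out, sprintf("days_masked_missing_hours:%d",
                               sum(nmiss > max_missing_hours)))
  out
}

#' Region weights for zonal aggregation
#'
#' @param region_id character/factor region per row.
#' @param cell_index 1-based flat grid-cell index (row-major from NW).
#' @param weight non-negative weight; must sum to 1 per region (tol 1e-9).
#' @return data.frame of class \code{region_weights}.
#' @export
region_weights <- function(region_id, cell_index, weight) {
  if (any(weight < 0)) stop("weights must be non-negative")
  s <- tapply(weight, region_id, sum)
  if (any(abs(s - 1) > 1e-9))
    stop("weights must sum to 1 per region (tolerance 1e-9)")
  structure(data.frame(region_id = as.character(region_id),
                       cell_index = as.integer(cell_index),
                       weight = as.numeric(weight),
                       stringsAsFactors = FALSE),
            class = c("region_weights", "data.frame"))
}

#' Read region weights from CSV (columns region_id, cell_index, weight)
#' @param path CSV path.
#' @return a \code{region_weights} data frame.
#' @export
read_region_weights <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("region_id", "cell_index", "weight") %in% names(d)))
  region_weights(d$region_id, d$cell_index, d$weight)
}

#' Area-weighted zonal mean of a daily grid field
#'
#' Per region and day, sum(weight_c * value_c) over non-masked cells with the
#' weights renormalised over the non-masked subset. A region-day with every
#' referenced cell masked propagates NA and is counted in the log.
#'
#' @param field daily \code{grid_field}.
#' @param weights a \code{region_weights} data frame.
#' @return data.frame region_id, date, value (long format).
#' @export
zonal_mean <- function(field, weights) {
  stopifnot(inherits(field, "grid_field"), inherits(weights, "region_weights"))
  if (max(weights$cell_index) > ncol(field$values))
    stop("weights reference cells outside the grid")
  regions <- unique(weights$region_id)
  out <- vector("list", length(regions))
  n_allmask <- 0L
  for (k in seq_along(regions)) {
    w <- weights[weights$region_id == regions[k], ]
    v <- field$values[, w$cell_index, drop = FALSE]
    ok <- is.finite(v)
    wmat <- matrix(w$weight, nrow(v), length(w$weight), byrow = TRUE)
    wmat[!ok] <- 0
    tot <- rowSums(wmat)
    val <- rowSums(ifelse(ok, v, 0) * wmat) / ifelse(tot > 0, tot, NA_real_)
    n_allmask <- n_allmask + sum(tot == 0)
    out[[k]] <- data.frame(region_id = regions[k], date = field$time,
                           value = val, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (n_allmask > 0) res <- hw_log(res, sprintf("region_days_all_masked:%d",
                                                n_allmask))
  res
}

#' Assemble a per-region daily climate series
#'
#' The canonical per-region input to the heatwave engine: consecutive daily
#' dates with daily mean temperature (degC) and relative humidity (%). RH can
#' be supplied directly or derived from dewpoint via
#' \code{\link{derive_relative_humidity}}.
#'
#' @param region_id single region identifier.
#' @param date Date vector, consecutive days with no gaps.
#' @param tmean_c daily mean temperature, degrees C.
#' @param rh_pct daily mean relative humidity, percent, or NULL.
#' @param dewpoint_c daily mean dewpoint, degrees C, used when rh_pct is NULL.
#' @return data.frame of class \code{region_daily_series} with columns
#'   region_id, date, tmean_c, rh_pct.
#' @export
region_daily_series <- function(region_id, date, tmean_c, rh_pct = NULL,
                                dewpoint_c = NULL) {
  date <- as.Date(date)
  if (length(date) > 1 && any(diff(date) != 1))
    stop("dates must be consecutive daily with no gaps")
  if (is.null(rh_pct)) {
    if (is.null(dewpoint_c)) stop("supply rh_pct or dewpoint_c")
    rh_pct <- suppressWarnings(derive_relative_humidity(tmean_c, dewpoint_c))
  }
  if (any(rh_pct < 0 | rh_pct > 100, na.rm = TRUE))
    stop("relative humidity outside [0, 100]")
  n <- length(date)
  if (length(tmean_c) != n || length(rh_pct) != n)
    stop("column lengths differ")
  structure(data.frame(region_id = as.character(region_id[1]), date = date,
                       tmean_c = as.numeric(tmean_c),
                       rh_pct = as.numeric(rh_pct),
                       stringsAsFactors = FALSE),
            class = c("region_daily_series", "data.frame"))
}

#' Read per-region daily climate CSV
#'
#' Columns: region_id, date (ISO-8601), tmean_c, and either rh_pct or
#' dewpoint_c. Returns one \code{region_daily_series} per region.
#'
#' @param path CSV path.
#' @return named list of \code{region_daily_series}, one per region.
#' @export
read_region_daily_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("region_id", "date", "tmean_c") %in% names(d)))
  has_rh <- "rh_pct" %in% names(d)
  if (!has_rh && !"dewpoint_c" %in% names(d))
    stop("need rh_pct or dewpoint_c column")
  sp <- split(d, d$region_id)
  lapply(sp, function(x) {
    x <- x[order(as.Date(x$date)), ]
    region_daily_series(x$region_id[1], x$date, x$tmean_c,
                        rh_pct = if (has_rh) x$rh_pct else NULL,
                        dewpoint_c = if (!has_rh) x$dewpoint_c else NULL)
  })
}
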