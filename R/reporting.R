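#' Cross-tabulate heatwave location-days between the two index variants
#'
#' Counts location-days by heatwave status (any severity vs none) under the
#' temperature-only and the temperature-plus-humidity calendars, and derives
#' the discordance percentages: the share of each variant's heatwave days
#' not flagged by the other, computed from the discordant cell over that
#' variant's margin and rounded half-up to 1 decimal.
#'
#' @param cal_t,cal_th \code{heatwave_calendar}s over identical region-days.
#' @return list of class \code{index_crosstab}: \code{cells} (2x2 matrix,
#'   rows = TH status, cols = T status), \code{total},
#'   \code{pct_t_not_th} and \code{pct_th_not_t}.
#' @export
crosstab_indexes <- function(cal_t, cal_th) {
  kt <- paste(cal_t$region_id, cal_t$date)
  kh <- paste(cal_th$region_id, cal_th$date)
  if (length(kt) != length(kh) || !setequal(kt, kh))
    stop("calendars must cover identical region-days")
  hw_t <- cal_t$severity != "none"
  hw_th <- (cal_th$severity != "none")[match(kt, kh)]
  cells <- matrix(c(sum(!hw_th & !hw_t), sum(!hw_th & hw_t),
                    sum(hw_th & !hw_t), sum(hw_th & hw_t)),
                  2, 2, byrow = TRUE,
                  dimnames = list(TH = c("non-heatwave", "heatwave"),
                                  T = c("non-heatwave", "heatwave")))
  crosstab_from_cells(cells)
}

#' Discordance percentages from printed cross-tabulation cells
#'
#' Derives the two discordance percentages directly from a 2x2 cell matrix
#' (rows = heatwave status under the humidity-inclusive index, columns =
#' status under the temperature-only index), so published tables can be
#' re-checked without the underlying calendars.
#'
#' @param cells 2x2 integer matrix (row 1 / col 1 = non-heatwave).
#' @return an \code{index_crosstab} (see \code{\link{crosstab_indexes}}).
#' @export
crosstab_from_cells <- function(cells) {
  cells <- as.matrix(cells)
  stopifnot(all(dim(cells) == c(2, 2)), all(cells >= 0))
  margin_t <- cells[1, 2] + cells[2, 2]    # heatwave under T
  margin_th <- cells[2, 1] + cells[2, 2]   # heatwave under TH
  structure(list(cells = cells, total = sum(cells),
                 pct_t_not_th = round_half_up(100 * cells[1, 2] / margin_t, 1),
                 pct_th_not_t = round_half_up(100 * cells[2, 1] / margin_th, 1)),
            class = "index_crosstab")
}

#' @export
print.index_crosstab <- function(x, ...) {
  cat("Heatwave location-day agreement between index variants\n")
  print(x$cells)
  cat(sprintf("T-days missed by TH: %.1f%%   TH-days missed by T: %.1f%%\n",
              x$pct_t_not_th, x$pct_th_not_t))
  invisible(x)
}

#' Annual heatwave location-day counts and Gamma log-link trend
#'
#' Counts heatwave location-days per calendar year (optionally within one
#' climate zone and/or intensity subset) and fits a Gamma GLM with log link
#' of count on year index. Years with zero count are excluded from the fit
#' (the Gamma family has positive support) and noted.
#'
#' @param calendar a \code{heatwave_calendar}.
#' @param zone_map optional data.frame region_id, zone; with \code{zone} set,
#'   restricts to that zone.
#' @param zone optional zone name to filter on.
#' @param intensity "any", "low" or "severe_extreme".
#' @return list of class \code{trend_series}: \code{annual} (year, count),
#'   \code{intercept}, \code{slope} (log scale, per year),
#'   \code{years_excluded}.
#' @export
heatwave_trend <- function(calendar, zone_map = NULL, zone = NULL,
                           intensity = c("any", "low", "severe_extreme")) {
  intensity <- match.arg(intensity)
  cal <- calendar
  if (!is.null(zone_map) && !is.null(zone)) {
    keep <- cal$region_id %in% zone_map$region_id[zone_map$zone == zone]
    cal <- cal[keep, , drop = FALSE]
  }
  is_hw <- switch(intensity,
                  any = cal$severity != "none",
                  low = cal$severity == "low",
                  severe_extreme = cal$severity %in% c("severe", "extreme"))
  yr <- as.integer(format(cal$date, "%Y"))
  years <- sort(unique(yr))
  if (length(years) < 3) stop("need at least 3 years of data for a trend")
  counts <- vapply(years, function(y) sum(is_hw & yr == y), numeric(1))
  fit_annual_trend(years, counts)
}

#' Gamma log-link trend on annual counts
#'
#' Fits count ~ year index with a Gamma family and log link (IRLS via
#' \code{stats::glm}); the fitted curve is positive everywhere. Years with
#' zero count are outside the Gamma support and are excluded from the fit,
#' not imputed; an all-zero series skips the fit.
#'
#' @param year calendar years.
#' @param count non-negative annual counts (need not be integer).
#' @return list of class \code{trend_series}: \code{annual},
#'   \code{intercept} and \code{slope} on the log scale (slope per year),
#'   \code{years_excluded}, \code{skipped}.
#' @export
fit_annual_trend <- function(year, count) {
  stopifnot(length(year) == length(count), all(count >= 0))
  pos <- count > 0
  excluded <- year[!pos]
  if (!any(pos)) {
    return(structure(list(annual = data.frame(year = year, count = count),
                          intercept = NA_real_, slope = NA_real_,
                          years_excluded = excluded, skipped = TRUE),
                     class = "trend_series"))
  }
  t_idx <- year - year[1]
  # suppressWarnings: on noise-free data the fit is exact and glm's Gamma AIC
  # evaluates dgamma at zero dispersion (NaN warning); the coefficients are fine
  fit <- suppressWarnings(
    stats::glm(count[pos] ~ t_idx[pos],
               family = stats::Gamma(link = "log"),
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
  structure(list(annual = data.frame(year = year, count = count),
                 intercept = unname(coef(fit)[1]),
                 slope = unname(coef(fit)[2]),
                 years_excluded = excluded, skipped = FALSE),
            class = "trend_series")
}

#' Characteristics table of presentations on heatwave days
#'
#' Counts presentations falling on heatwave location-days of each intensity
#' (low vs severe/extreme) under one calendar, broken down by a grouping
#' column, with column percentages of the intensity total (half-up, 1
#' decimal). Percentages are suppressed (NA) for empty intensity columns.
#'
#' @param records ED records with \code{exposure_region} and the grouping
#'   column present.
#' @param calendar a \code{heatwave_calendar}.
#' @param by name of the grouping column (e.g. "indigenous_status",
#'   "age_band", "condition_group").
#' @return data.frame group, intensity, n, pct.
#' @export
descriptive_table <- function(records, calendar, by) {
  stopifnot(by %in% names(records))
  key <- paste(records$exposure_region, records$date)
  cal_key <- paste(calendar$region_id, calendar$date)
  expo <- calendar$exposure_level[match(key, cal_key)]
  on_hw <- !is.na(expo) & expo != "none"
  rec <- records[on_hw, , drop = FALSE]
  intensity <- droplevels(factor(expo[on_hw],
                                 levels = c("low", "severe_extreme")))
  g <- factor(rec[[by]])
  tab <- table(group = g, intensity = intensity)
  totals <- colSums(tab)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("group", "intensity", "n")
  out$pct <- ifelse(totals[out$intensity] > 0,
                    round_half_up(100 * out$n / totals[out$intensity], 1),
                    NA_real_)
  out
}

#' Heatwave prevalence change between two periods
#'
#' Percentage of location-days meeting heatwave criteria (at the given
#' intensity) in an early and a late period, and the difference in
#' percentage points, all half-up at 1 decimal.
#'
#' @param calendar a \code{heatwave_calendar}.
#' @param early,late length-2 integer vectors (start year, end year),
#'   non-overlapping and within the calendar span.
#' @param intensity "any", "low" or "severe_extreme".
#' @return data.frame pct_early, pct_late, change_points.
#' @export
period_comparison <- function(calendar, early, late,
                              intensity = c("any", "low", "severe_extreme")) {
  intensity <- match.arg(intensity)
  stopifnot(length(early) == 2, length(late) == 2)
  if (max(early) >= min(late) && max(late) >= min(early))
    stop("periods must not overlap")
  yr <- as.integer(format(calendar$date, "%Y"))
  if (!all(early[1]:early[2] %in% yr) || !all(late[1]:late[2] %in% yr))
    stop("period outside the calendar span")
  is_hw <- switch(intensity,
                  any = calendar$severity != "none",
                  low = calendar$severity == "low",
                  severe_extreme = calendar$severity %in% c("severe", "extreme"))
  share <- function(per) {
    sel <- yr >= per[1] & yr <= per[2]
    100 * sum(is_hw[sel]) / sum(sel)
  }
  pe <- share(early); pl <- share(late)
  data.frame(pct_early = round_half_up(pe, 1), pct_late = round_half_up(pl, 1),
             change_points = round_half_up(pl - pe, 1))
}
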