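#' Parameters for the Excess Heat Factor engine
#'
#' @param variant "T" (daily mean temperature drives the index) or "TH" (the
#'   heat index of temperature and relative humidity drives it).
#' @param ref_start,ref_end reference period (calendar years, inclusive) for
#'   the climatological and severity thresholds; default 1960-2011.
#' @param clim_pctl percentile defining the climatological threshold T95,
#'   default 95.
#' @param sev_pctl severity percentile of positive reference-period EHF,
#'   default 85.
#' @param sig_window significance window length in days, default 3.
#' @param accl_window acclimatisation window length in days, default 30.
#' @param sig_orientation "forward" (day i labelled from days i..i+2, the
#'   preceding 30 days as acclimatisation) or "trailing" (day i labelled from
#'   days i-2..i).
#' @param extreme_multiplier extreme threshold as a multiple of the severe
#'   threshold, default 3.
#' @param label "point" labels day i by EHF(i) alone; "paint" additionally
#'   propagates each window's label to all days it covers.
#' @return list of class \code{ehf_params}.
#' @export
ehf_params <- function(variant = c("T", "TH"), ref_start = 1960,
                       ref_end = 2011, clim_pctl = 95, sev_pctl = 85,
                       sig_window = 3L, accl_window = 30L,
                       sig_orientation = c("forward", "trailing"),
                       extreme_multiplier = 3, label = c("point", "paint")) {
  variant <- match.arg(variant)
  stopifnot(ref_start <= ref_end, clim_pctl > 0, clim_pctl < 100,
            sev_pctl > 0, sev_pctl < 100, sig_window >= 1, accl_window >= 1,
            extreme_multiplier > 0)
  structure(list(variant = variant, ref_start = ref_start, ref_end = ref_end,
                 clim_pctl = clim_pctl, sev_pctl = sev_pctl,
                 sig_window = as.integer(sig_window),
                 accl_window = as.integer(accl_window),
                 sig_orientation = match.arg(sig_orientation),
                 extreme_multiplier = extreme_multiplier,
                 label = match.arg(label)),
            class = "ehf_params")
}

#' Driver series for an EHF variant
#'
#' The two heatwave variants share one code path differing only in the daily
#' driver: the daily mean temperature (variant T) or the heat index of daily
#' mean temperature and relative humidity (variant TH).
#'
#' @param series a \code{region_daily_series}.
#' @param variant "T" or "TH".
#' @return numeric vector of daily driver values, degrees C.
#' @export
driver_series <- function(series, variant = c("T", "TH")) {
  variant <- match.arg(variant)
  if (variant == "T") series$tmean_c
  else compute_heat_index(series$tmean_c, series$rh_pct)
}

#' Climatological threshold of the daily driver
#'
#' The configured percentile (default 95th, linear interpolation) of the daily
#' driver values over all calendar days whose year falls in the reference
#' period.
#'
#' @param series a \code{region_daily_series}.
#' @param params an \code{ehf_params}.
#' @return scalar threshold, degrees C.
#' @export
compute_climatology_threshold <- function(series, params) {
  yr <- as.integer(format(series$date, "%Y"))
  drv <- driver_series(series, params$variant)
  sel <- yr >= params$ref_start & yr <= params$ref_end & is.finite(drv)
  if (!any(sel))
    stop("reference period does not overlap the series dates")
  pctl(drv[sel], params$clim_pctl)
}

rolling_mean <- function(x, k, align = c("left", "right")) {
  # mean of x[i .. i+k-1] (left) or x[i-k+1 .. i] (right); NA where incomplete
  align <- match.arg(align)
  n <- length(x)
  cs <- c(0, cumsum(x))
  out <- rep(NA_real_, n)
  if (n >= k) {
    v <- (cs[(k + 1):(n + 1)] - cs[1:(n - k + 1)]) / k
    if (align == "left") out[1:(n - k + 1)] <- v else out[k:n] <- v
  }
  out
}

#' Excess Heat Factor daily series
#'
#' For each day i the significance index EHI_sig compares the mean driver over
#' the significance window (default the 3 days starting at i) with the
#' climatological threshold; the acclimatisation index EHI_accl compares that
#' same mean with the mean over the preceding 30 days. The EHF is
#' EHI_sig x max(1, EHI_accl), in squared degrees C. Days whose windows are
#' incomplete are NA.
#'
#' @param series a \code{region_daily_series}.
#' @param t95 climatological threshold from
#'   \code{\link{compute_climatology_threshold}}.
#' @param params an \code{ehf_params}.
#' @return data.frame of class \code{ehf_series}: region_id, date, variant,
#'   driver_c, ehi_sig, ehi_accl, ehf.
#' @export
compute_ehf_series <- function(series, t95, params) {
  drv <- driver_series(series, params$variant)
  n <- length(drv)
  k <- params$sig_window
  m <- params$accl_window
  if (params$sig_orientation == "forward") {
    sig_mean <- rolling_mean(drv, k, "left")
    prev30 <- rolling_mean(drv, m, "right")           # mean of i-m+1 .. i
    accl_mean <- c(NA_real_, prev30[-n])              # mean of i-m .. i-1
  } else {
    sig_mean <- rolling_mean(drv, k, "right")         # days i-k+1 .. i
    prevm <- rolling_mean(drv, m, "right")
    accl_mean <- rep(NA_real_, n)                     # days i-k-m+1 .. i-k
    if (n > k) accl_mean[(k + 1):n] <- prevm[1:(n - k)]
  }
  ehi_sig <- sig_mean - t95
  ehi_accl <- sig_mean - accl_mean
  ehf <- ehi_sig * pmax(1, ehi_accl)
  out <- data.frame(region_id = series$region_id, date = series$date,
                    variant = params$variant, driver_c = drv,
                    ehi_sig = ehi_sig, ehi_accl = ehi_accl, ehf = ehf,
                    stringsAsFactors = FALSE)
  class(out) <- c("ehf_series", "data.frame")
  if (all(is.na(ehf)))
    out <- hw_log(out, "series shorter than acclimatisation + significance window; all days undefined")
  out
}

#' Severity threshold from reference-period EHF
#'
#' The severity percentile (default 85th, linear interpolation) of the
#' strictly positive EHF values with dates inside the reference period.
#'
#' @param ehf an \code{ehf_series}.
#' @param params an \code{ehf_params}.
#' @return scalar threshold EHF85, squared degrees C.
#' @export
compute_severity_thresholds <- function(ehf, params) {
  yr <- as.integer(format(ehf$date, "%Y"))
  pos <- ehf$ehf[yr >= params$ref_start & yr <= params$ref_end &
                   is.finite(ehf$ehf) & ehf$ehf > 0]
  if (length(pos) == 0)
    stop("no positive EHF in the reference period; climate input is degenerate for severity thresholds")
  pctl(pos, params$sev_pctl)
}

#' Classify heatwave days by severity
#'
#' A day is a heatwave day iff its EHF is positive (the multi-day significance
#' window embeds the persistence requirement). Severity is extreme when
#' EHF >= extreme_multiplier x EHF85, severe when EHF >= EHF85, otherwise
#' low; thresholds are closed from below. The analysis exposure level
#' collapses severe and extreme, which are individually rare, into one
#' "severe_extreme" level. With \code{label = "paint"} each day additionally
#' inherits the strongest label of any significance window covering it.
#'
#' @param ehf an \code{ehf_series}.
#' @param ehf85 severity threshold from
#'   \code{\link{compute_severity_thresholds}}.
#' @param params an \code{ehf_params}.
#' @return data.frame of class \code{heatwave_calendar}: region_id, date,
#'   variant, ehf, severity (none/low/severe/extreme), exposure_level
#'   (none/low/severe_extreme).
#' @export
classify_heatwave_days <- function(ehf, ehf85, params) {
  stopifnot(ehf85 > 0)
  lev <- c("none", "low", "severe", "extreme")
  sev_of <- function(e) {
    s <- rep("none", length(e))
    s[is.finite(e) & e > 0] <- "low"
    s[is.finite(e) & e >= ehf85] <- "severe"
    s[is.finite(e) & e >= params$extreme_multiplier * ehf85] <- "extreme"
    s
  }
  sev <- sev_of(ehf$ehf)
  if (params$label == "paint") {
    idx <- match(sev, lev)
    painted <- idx
    for (off in seq_len(params$sig_window) - 1L) {
      if (off == 0) next
      shifted <- if (params$sig_orientation == "forward")
        c(rep(1L, off), idx[seq_len(length(idx) - off)])
      else c(idx[-seq_len(off)], rep(1L, off))
      # forward window at i covers days i..i+k-1, so day j inherits from i=j-off
      painted <- pmax(painted, shifted)
    }
    sev <- lev[painted]
  }
  severity <- factor(sev, levels = lev)
  exposure <- factor(ifelse(sev %in% c("severe", "extreme"), "severe_extreme",
                            ifelse(sev == "low", "low", "none")),
                     levels = c("none", "low", "severe_extreme"))
  out <- data.frame(region_id = ehf$region_id, date = ehf$date,
                    variant = ehf$variant, ehf = ehf$ehf,
                    severity = severity, exposure_level = exposure,
                    stringsAsFactors = FALSE)
  class(out) <- c("heatwave_calendar", "data.frame")
  out
}

#' Full heatwave detection for one region
#'
#' Convenience wrapper chaining threshold computation, the EHF series and
#' severity classification for one \code{region_daily_series}.
#'
#' @param series a \code{region_daily_series}.
#' @param params an \code{ehf_params}.
#' @return list with elements \code{thresholds} (region_id, variant, t95,
#'   ehf85), \code{ehf} (the \code{ehf_series}) and \code{calendar} (the
#'   \code{heatwave_calendar}).
#' @export
detect_heatwaves <- function(series, params = ehf_params()) {
  t95 <- compute_climatology_threshold(series, params)
  ehf <- compute_ehf_series(series, t95, params)
  ehf85 <- compute_severity_thresholds(ehf, params)
  cal <- classify_heatwave_days(ehf, ehf85, params)
  list(thresholds = data.frame(region_id = series$region_id[1],
                               variant = params$variant,
                               t95 = t95, ehf85 = ehf85,
                               stringsAsFactors = FALSE),
       ehf = ehf, calendar = cal)
}

#' Heatwave calendars for a set of regions
#'
#' Runs \code{\link{detect_heatwaves}} on each region's series and binds the
#' calendars.
#'
#' @param series_list list of \code{region_daily_series}.
#' @param params an \code{ehf_params}.
#' @return a combined \code{heatwave_calendar} plus a \code{thresholds}
#'   attribute (one row per region).
#' @export
detect_heatwaves_all <- function(series_list, params = ehf_params()) {
  res <- lapply(series_list, detect_heatwaves, params = params)
  cal <- do.call(rbind, lapply(res, `[[`, "calendar"))
  rownames(cal) <- NULL
  class(cal) <- c("heatwave_calendar", "data.frame")
  attr(cal, "thresholds") <- do.call(rbind, lapply(res, `[[`, "thresholds"))
  cal
}
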