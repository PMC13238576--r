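#' Configuration for the synthetic weather generator
#'
#' Daily temperature is an annual sinusoid plus AR(1) noise plus injected
#' multi-day heat episodes; dewpoint is temperature minus a seasonally
#' varying depression (small in the wet season, large in the dry season),
#' bounded at zero. Defaults emulate a tropical-savanna regime: mean 27 degC,
#' amplitude 4 degC peaking in late November, AR(1) 0.7 with innovation sd
#' 1.5 degC, six heat episodes per region-year of 3-7 days at +8 degC placed
#' in the warm season (late October - January), dewpoint depression 5 +/- 3
#' degC over the year.
#'
#' @param seed master seed; the weather stream is derived from it.
#' @param n_regions number of regions.
#' @param start_date,end_date span (Dates or ISO strings), at least one year.
#' @param mean_c,amplitude_c,peak_doy seasonal sinusoid: annual mean, semi-
#'   amplitude (degC) and day-of-year of the temperature peak.
#' @param ar1,innov_sd day-to-day noise: AR(1) coefficient in [0,1) and
#'   innovation sd (degC).
#' @param episodes_per_year Poisson rate of injected heat episodes per year.
#' @param episode_duration length-2 integer range of episode durations
#'   (days); minimum 3 so episodes can satisfy the persistence window.
#' @param episode_anomaly_c added temperature anomaly on episode days (degC).
#' @param dew_depression_c,dew_seasonal_amplitude_c mean and semi-amplitude
#'   of the dewpoint depression (degC); depression peaks in the dry season.
#' @return list of class \code{weather_gen_config}.
#' @export
weather_gen_config <- function(seed = 1L, n_regions = 2L,
                               start_date = "2001-01-01",
                               end_date = "2002-12-31",
                               mean_c = 27, amplitude_c = 4, peak_doy = 330,
                               ar1 = 0.7, innov_sd = 1.5,
                               episodes_per_year = 6,
                               episode_duration = c(3L, 7L),
                               episode_anomaly_c = 8,
                               dew_depression_c = 5,
                               dew_seasonal_amplitude_c = 3) {
  stopifnot(ar1 >= 0, ar1 < 1, innov_sd >= 0, episode_duration[1] >= 3,
            episode_duration[2] >= episode_duration[1],
            episodes_per_year >= 0)
  structure(list(seed = as.integer(seed), n_regions = as.integer(n_regions),
                 start_date = as.Date(start_date), end_date = as.Date(end_date),
                 mean_c = mean_c, amplitude_c = amplitude_c,
                 peak_doy = peak_doy, ar1 = ar1, innov_sd = innov_sd,
                 episodes_per_year = episodes_per_year,
                 episode_duration = as.integer(episode_duration),
                 episode_anomaly_c = episode_anomaly_c,
                 dew_depression_c = dew_depression_c,
                 dew_seasonal_amplitude_c = dew_seasonal_amplitude_c),
            class = "weather_gen_config")
}

# component streams split from one master seed so changing one generator
# cannot perturb another
stream_seed <- function(seed, component) {
  offs <- c(weather = 101L, counts = 202L, demographics = 303L, pm25 = 404L)
  # double arithmetic: 1009 * seed overflows integer range for large seeds
  as.integer((abs(as.numeric(seed)) * 1009 + offs[[component]]) %%
               .Machine$integer.max)
}

seasonal_curve <- function(date, mean_c, amplitude_c, peak_doy) {
  doy <- as.integer(format(date, "%j"))
  mean_c + amplitude_c * cos(2 * pi * (doy - peak_doy) / 365.25)
}

#' Simulate per-region daily temperature and dewpoint
#'
#' @param config a \code{weather_gen_config}.
#' @return list with \code{series} (named list of
#'   \code{region_daily_series}, RH derived from dewpoint), \code{dewpoint}
#'   (data.frame region_id, date, dewpoint_c) and \code{episodes}
#'   (data.frame region_id, start, duration of every injected episode).
#' @export
simulate_weather <- function(config) {
  dates <- seq(config$start_date, config$end_date, by = "day")
  if (length(dates) < 365) stop("span must cover at least one year")
  set.seed(stream_seed(config$seed, "weather"))
  n <- length(dates)
  seas <- seasonal_curve(dates, config$mean_c, config$amplitude_c,
                         config$peak_doy)
  doy <- as.integer(format(dates, "%j"))
  # warm-season placement window around the seasonal peak
  warm <- which((doy - config$peak_doy) %% 365 <= 65 |
                  (config$peak_doy - doy) %% 365 <= 30)
  years <- length(unique(format(dates, "%Y")))
  regions <- sprintf("R%02d", seq_len(config$n_regions))
  series <- list(); eps <- list(); dews <- list()
  for (r in regions) {
    noise <- as.numeric(stats::filter(stats::rnorm(n, 0, config$innov_sd),
                                      config$ar1, method = "recursive"))
    anom <- numeric(n)
    n_ep <- stats::rpois(1, config$episodes_per_year * years)
    ep_start <- if (n_ep > 0) sort(sample(warm, n_ep, replace = TRUE)) else integer(0)
    ep_dur <- if (n_ep > 0)
      sample(config$episode_duration[1]:config$episode_duration[2], n_ep,
             replace = TRUE) else integer(0)
    for (k in seq_len(n_ep)) {
      idx <- ep_start[k]:min(n, ep_start[k] + ep_dur[k] - 1L)
      anom[idx] <- pmax(anom[idx], config$episode_anomaly_c)
      ep_dur[k] <- length(idx)             # truncated at the series end
    }
    tmean <- seas + noise + anom
    dep <- pmax(0, config$dew_depression_c +
                  config$dew_seasonal_amplitude_c *
                  cos(2 * pi * (doy - (config$peak_doy + 182.6)) / 365.25))
    dew <- tmean - dep
    series[[r]] <- region_daily_series(r, dates, tmean, dewpoint_c = dew)
    dews[[r]] <- data.frame(region_id = r, date = dates, dewpoint_c = dew,
                            stringsAsFactors = FALSE)
    eps[[r]] <- if (n_ep > 0)
      data.frame(region_id = r, start = dates[ep_start],
                 duration = ep_dur, stringsAsFactors = FALSE)
    else data.frame(region_id = character(0), start = as.Date(character(0)),
                    duration = integer(0))
  }
  list(series = series,
       dewpoint = do.call(rbind, dews),
       episodes = do.call(rbind, eps))
}

#' Configuration for the synthetic presentation-count generator
#'
#' Daily counts are Poisson with log-linear structure: baseline rate,
#' day-of-week multipliers, true rate ratios for low and severe/extreme
#' heatwave days, a public-holiday rate ratio and a log-linear PM2.5 slope.
#' Individual records draw demographics and condition groups from fixed
#' mixtures. Default effect sizes sit in the range reported for tropical
#' heatwave morbidity (severe/extreme RR about 1.04-1.06, low about
#' 1.01-1.016).
#'
#' @param seed master seed (count and demographic streams are derived).
#' @param baseline_rate events/day/region.
#' @param dow_mult length-7 multipliers, Monday first.
#' @param rr_low,rr_severe true rate ratios for the two exposure levels.
#' @param rr_holiday public-holiday rate ratio.
#' @param pm25_coef log-rate change per ug/m3 PM2.5.
#' @param p_aboriginal,p_male mixture probabilities.
#' @param age_band_probs named probabilities over the five age bands.
#' @param residency_probs named probabilities over nt/non_nt/unknown.
#' @return list of class \code{ed_gen_config}.
#' @export
ed_gen_config <- function(seed = 1L, baseline_rate = 20,
                          dow_mult = c(1, 0.95, 0.95, 0.95, 1, 1.1, 1.05),
                          rr_low = 1.015, rr_severe = 1.06,
                          rr_holiday = 1.1, pm25_coef = 0.002,
                          p_aboriginal = 0.35, p_male = 0.5,
                          age_band_probs = c("<5" = 0.11, "5-18" = 0.13,
                                             "19-49" = 0.52, "50-64" = 0.16,
                                             ">=65" = 0.08),
                          residency_probs = c(nt = 0.94, non_nt = 0.055,
                                              unknown = 0.005)) {
  stopifnot(baseline_rate > 0, length(dow_mult) == 7, all(dow_mult > 0),
            rr_low > 0, rr_severe > 0, rr_holiday > 0,
            abs(sum(age_band_probs) - 1) < 1e-8,
            abs(sum(residency_probs) - 1) < 1e-8)
  structure(list(seed = as.integer(seed), baseline_rate = baseline_rate,
                 dow_mult = dow_mult, rr_low = rr_low, rr_severe = rr_severe,
                 rr_holiday = rr_holiday, pm25_coef = pm25_coef,
                 p_aboriginal = p_aboriginal, p_male = p_male,
                 age_band_probs = age_band_probs,
                 residency_probs = residency_probs),
            class = "ed_gen_config")
}

#' Simulate daily PM2.5 per region
#'
#' Log-normal with mild dry-season seasonality (biomass-burning peak opposite
#' the temperature peak). With \code{confound_calendar} supplied, PM2.5 is
#' additionally elevated on heatwave days, providing a confounded variant for
#' exercising the sensitivity analysis.
#'
#' @param regions character vector of region ids.
#' @param dates Date vector.
#' @param seed master seed.
#' @param median_ugm3 median level.
#' @param seasonal_log_amplitude,log_sd seasonality and noise on the log scale.
#' @param confound_calendar optional \code{heatwave_calendar}; heatwave days
#'   get \code{confound_log_shift} added on the log scale.
#' @param confound_log_shift log-scale elevation on heatwave days.
#' @return data.frame region_id, date, pm25_ugm3.
#' @export
simulate_pm25 <- function(regions, dates, seed = 1L, median_ugm3 = 6,
                          seasonal_log_amplitude = 0.3, log_sd = 0.35,
                          confound_calendar = NULL, confound_log_shift = 0.3) {
  set.seed(stream_seed(seed, "pm25"))
  doy <- as.integer(format(dates, "%j"))
  seas <- seasonal_log_amplitude * cos(2 * pi * (doy - 182) / 365.25)
  out <- do.call(rbind, lapply(regions, function(r) {
    lp <- log(median_ugm3) + seas + stats::rnorm(length(dates), 0, log_sd)
    data.frame(region_id = r, date = dates, pm25_ugm3 = exp(lp),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(confound_calendar)) {
    hw <- confound_calendar$severity != "none"
    key <- paste(confound_calendar$region_id, confound_calendar$date)
    m <- match(paste(out$region_id, out$date), key)
    bump <- !is.na(m) & hw[m]
    out$pm25_ugm3[bump] <- out$pm25_ugm3[bump] * exp(confound_log_shift)
  }
  out
}

#' Fixed-date public holidays over a span (territory scope)
#'
#' @param dates Date vector defining the span.
#' @return data.frame date, scope.
#' @export
synthetic_holidays <- function(dates) {
  md <- format(dates, "%m-%d")
  hol <- dates[md %in% c("01-01", "01-26", "04-25", "12-25", "12-26")]
  data.frame(date = hol, scope = "territory", stringsAsFactors = FALSE)
}

#' Simulate stratum-day counts against a heatwave calendar
#'
#' The count-level generator: one Poisson draw per region-day with
#' log mu = log baseline + log dow multiplier + log RR(level) +
#' log RR(holiday) + pm25_coef x PM2.5. Returns a ready-to-fit
#' \code{stratum_day} table together with the truth (mu per row).
#'
#' @param calendar a \code{heatwave_calendar}.
#' @param config an \code{ed_gen_config}.
#' @param holidays data.frame date, scope, or NULL.
#' @param pm25 data.frame region_id, date, pm25_ugm3, or NULL.
#' @return \code{stratum_day} data.frame with an extra \code{mu} column.
#' @export
simulate_stratum_counts <- function(calendar, config, holidays = NULL,
                                    pm25 = NULL) {
  set.seed(stream_seed(config$seed, "counts"))
  d <- data.frame(region_id = calendar$region_id, date = calendar$date,
                  exposure_level = calendar$exposure_level,
                  stringsAsFactors = FALSE)
  d$year <- as.integer(format(d$date, "%Y"))
  d$month <- as.integer(format(d$date, "%m"))
  d$dow <- as.integer(format(d$date, "%u"))
  d$holiday <- if (is.null(holidays)) FALSE
               else d$date %in% as.Date(holidays$date[holidays$scope == "territory"])
  d$pm25 <- if (is.null(pm25)) 0
            else pm25$pm25_ugm3[match(paste(d$region_id, d$date),
                                      paste(pm25$region_id, as.Date(pm25$date)))]
  log_mu <- log(config$baseline_rate) + log(config$dow_mult[d$dow]) +
    ifelse(d$exposure_level == "low", log(config$rr_low), 0) +
    ifelse(d$exposure_level == "severe_extreme", log(config$rr_severe), 0) +
    ifelse(d$holiday, log(config$rr_holiday), 0) +
    config$pm25_coef * d$pm25
  d$mu <- exp(log_mu)
  d$count <- stats::rpois(nrow(d), d$mu)
  d$stratum <- paste(d$region_id, d$year, d$month, d$dow, sep = ":")
  class(d) <- c("stratum_day", "data.frame")
  d
}

#' Expand stratum-day counts into an ED line list
#'
#' Draws demographics, residency and a shortlist ICD code for each simulated
#' presentation from the configured mixtures, using a demographic stream
#' independent of the count stream.
#'
#' @param counts output of \code{\link{simulate_stratum_counts}}.
#' @param config an \code{ed_gen_config}.
#' @return data.frame in the ED line-list schema (date, hospital_id,
#'   region_id, residency_hint, age_years, sex, indigenous_status, icd_code);
#'   each region hosts one hospital named \code{H_<region>}.
#' @export
simulate_ed_records <- function(counts, config) {
  set.seed(stream_seed(config$seed, "demographics"))
  idx <- rep(seq_len(nrow(counts)), counts$count)
  n <- length(idx)
  bands <- names(config$age_band_probs)
  band <- sample(bands, n, replace = TRUE, prob = config$age_band_probs)
  age_lo <- c("<5" = 0, "5-18" = 5, "19-49" = 19, "50-64" = 50, ">=65" = 65)
  age_hi <- c("<5" = 4, "5-18" = 18, "19-49" = 49, "50-64" = 64, ">=65" = 95)
  age <- floor(stats::runif(n, age_lo[band], age_hi[band] + 1))
  res <- sample(names(config$residency_probs), n, replace = TRUE,
                prob = config$residency_probs)
  icd_pool <- c("A09", "E11", "F10", "I10", "J18", "K52", "L03", "M54",
                "N39", "S01", "T67", "R55", "Z99")
  data.frame(date = counts$date[idx],
             hospital_id = paste0("H_", counts$region_id[idx]),
             region_id = ifelse(res == "nt", counts$region_id[idx], ""),
             residency_hint = res,
             age_years = age,
             sex = sample(c("male", "female"), n, TRUE,
                          prob = c(config$p_male, 1 - config$p_male)),
             indigenous_status = sample(c("Aboriginal", "non-Aboriginal"), n,
                                        TRUE, prob = c(config$p_aboriginal,
                                                       1 - config$p_aboriginal)),
             icd_code = sample(icd_pool, n, TRUE),
             stringsAsFactors = FALSE)
}

#' Write a named synthetic fixture to disk
#'
#' Generates a coherent input file set (climate, ED line list, PM2.5,
#' holidays, region weights) plus a manifest of every seed and true
#' parameter. Three fixtures are defined: \code{"tiny"} (2 regions x 2
#' years, baseline 5/day), \code{"null"} (same size, all true rate ratios
#' 1), and \code{"powered"} (10 regions x 3 years, baseline 20/day, true
#' RR severe/extreme 1.06 and low 1.015).
#'
#' @param name one of "tiny", "null", "powered".
#' @param dir output directory (created if needed).
#' @param seed master seed.
#' @return invisibly, the manifest list.
#' @export
make_fixture <- function(name = c("tiny", "null", "powered"), dir,
                         seed = 1L) {
  name <- match.arg(name)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcfg <- switch(name,
    tiny = weather_gen_config(seed, n_regions = 2, start_date = "2001-01-01",
                              end_date = "2002-12-31"),
    null = weather_gen_config(seed, n_regions = 2, start_date = "2001-01-01",
                              end_date = "2002-12-31"),
    powered = weather_gen_config(seed, n_regions = 10,
                                 start_date = "2001-01-01",
                                 end_date = "2003-12-31"))
  ecfg <- switch(name,
    tiny = ed_gen_config(seed, baseline_rate = 5),
    null = ed_gen_config(seed, baseline_rate = 5, rr_low = 1, rr_severe = 1,
                         rr_holiday = 1, pm25_coef = 0),
    powered = ed_gen_config(seed, baseline_rate = 20, rr_low = 1.015,
                            rr_severe = 1.06))
  w <- simulate_weather(wcfg)
  params <- ehf_params("T", ref_start = as.integer(format(wcfg$start_date, "%Y")),
                       ref_end = as.integer(format(wcfg$end_date, "%Y")))
  cal <- detect_heatwaves_all(w$series, params)
  dates <- w$series[[1]]$date
  regions <- names(w$series)
  pm <- simulate_pm25(regions, dates, seed = seed)
  hol <- synthetic_holidays(dates)
  counts <- simulate_stratum_counts(cal, ecfg, hol, pm)
  records <- simulate_ed_records(counts, ecfg)
  climate <- do.call(rbind, c(lapply(seq_along(w$series), function(i) {
    s <- w$series[[i]]
    data.frame(region_id = s$region_id, date = as.character(s$date),
               tmean_c = s$tmean_c,
               dewpoint_c = w$dewpoint$dewpoint_c[w$dewpoint$region_id ==
                                                    s$region_id[1]],
               stringsAsFactors = FALSE)
  }), make.row.names = FALSE))
  wts <- data.frame(region_id = regions, cell_index = seq_along(regions),
                    weight = 1)
  wf <- function(d, f) utils::write.csv(d, file.path(dir, f),
                                        row.names = FALSE)
  wf(climate, "climate.csv")
  wf(records, "ed.csv")
  wf(pm, "pm25.csv")
  wf(hol, "holidays.csv")
  wf(wts, "weights.csv")
  manifest <- list(name = name, seed = seed,
                   stream_seeds = list(weather = stream_seed(seed, "weather"),
                                       counts = stream_seed(seed, "counts"),
                                       demographics = stream_seed(seed,
                                                                  "demographics"),
                                       pm25 = stream_seed(seed, "pm25")),
                   n_regions = wcfg$n_regions,
                   span = c(as.character(wcfg$start_date),
                            as.character(wcfg$end_date)),
                   truth = list(rr_low = ecfg$rr_low,
                                rr_severe = ecfg$rr_severe,
                                rr_holiday = ecfg$rr_holiday,
                                pm25_coef = ecfg$pm25_coef,
                                baseline_rate = ecfg$baseline_rate))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
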