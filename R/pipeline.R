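#' Run the full heatwave case-crossover pipeline on an input directory
#'
#' Reads the standard input file set (climate.csv, ed.csv, pm25.csv,
#' holidays.csv as written by \code{\link{make_fixture}} or prepared to the
#' same schema), detects heatwaves for the requested variant, aggregates
#' presentations to zero-filled stratum-days and fits the conditional
#' quasi-Poisson case-crossover model. All stages are deterministic, so a
#' given input directory always produces byte-identical outputs.
#'
#' @param input_dir directory with climate.csv, ed.csv, pm25.csv,
#'   holidays.csv.
#' @param out_dir output directory; created if needed.
#' @param variant "T" or "TH".
#' @param ref_years reference period for thresholds as c(start, end); NULL
#'   uses the climate span.
#' @param use_pm25 include PM2.5 in the model.
#' @return invisibly, a list with the fit, calendar and thresholds.
#' @export
run_pipeline <- function(input_dir, out_dir, variant = c("T", "TH"),
                         ref_years = NULL, use_pm25 = TRUE) {
  variant <- match.arg(variant)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  series <- read_region_daily_csv(file.path(input_dir, "climate.csv"))
  if (is.null(ref_years)) {
    yrs <- range(as.integer(format(series[[1]]$date, "%Y")))
    ref_years <- yrs
  }
  params <- ehf_params(variant, ref_start = ref_years[1],
                       ref_end = ref_years[2])
  cal <- detect_heatwaves_all(series, params)
  thresholds <- attr(cal, "thresholds")
  records <- parse_ed_records(file.path(input_dir, "ed.csv"))
  regions <- unique(cal$region_id)
  registry <- data.frame(hospital_id = paste0("H_", regions),
                         region_id = regions, stringsAsFactors = FALSE)
  records <- assign_exposure_region(records, registry)
  records <- derive_demographics(records)
  pm <- utils::read.csv(file.path(input_dir, "pm25.csv"),
                        stringsAsFactors = FALSE)
  hol <- utils::read.csv(file.path(input_dir, "holidays.csv"),
                         stringsAsFactors = FALSE)
  sd <- aggregate_counts(records, cal, holidays = hol, pm25 = pm)
  fit <- fit_heatwave_model(sd, use_pm25 = use_pm25)
  rr <- rate_ratios(fit, format = TRUE)
  utils::write.csv(cal[, c("region_id", "date", "variant", "severity",
                           "exposure_level")],
                   file.path(out_dir, "calendar.csv"), row.names = FALSE)
  utils::write.csv(rr, file.path(out_dir, "rate_ratios.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(variant = variant,
                            thresholds = thresholds,
                            coefficients = as.list(coef(fit)),
                            dispersion = fit$dispersion,
                            n_strata = fit$n_strata,
                            dropped = as.list(fit$dropped)),
                       file.path(out_dir, "fit.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(fit = fit, calendar = cal, thresholds = thresholds))
}
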