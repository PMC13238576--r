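#' Load the condition-group map
#'
#' Reads the ordered ICD-10-AM shortlist condition groups shipped with the
#' package (or a user-supplied YAML of the same shape) and compiles each
#' entry into a matcher. Entry grammar: a 3-character range such as
#' \code{"S00-S99"} matches every code whose 3-character stem falls in the
#' range (decimal children included); a bare 3-character code such as
#' \code{"R10"} matches the code and its decimal children; a decimal-specific
#' code such as \code{"R19.0"} matches only that exact code; a decimal range
#' such as \code{"U07.1-U07.2"} is enumerated at one decimal digit and each
#' member matches exactly.
#'
#' @param path YAML file; defaults to the map shipped in \code{extdata}.
#' @return object of class \code{condition_group_map}.
#' @export
load_condition_groups <- function(path = system.file("extdata",
                                                     "condition_groups.yaml",
                                                     package = "heatwavecc")) {
  spec <- yaml::read_yaml(path)
  groups <- lapply(spec$groups, function(g) {
    stems_lo <- character(0); stems_hi <- character(0)
    exact <- character(0); stem_single <- character(0)
    for (e in g$codes) {
      e <- gsub(" ", "", e)
      if (grepl("-", e, fixed = TRUE)) {
        parts <- strsplit(e, "-", fixed = TRUE)[[1]]
        if (grepl(".", parts[1], fixed = TRUE)) {
          stem <- substr(parts[1], 1, 3)
          lo <- as.integer(sub("^.*\\.", "", parts[1]))
          hi <- as.integer(sub("^.*\\.", "", parts[2]))
          exact <- c(exact, paste0(stem, ".", lo:hi))
        } else {
          if (substr(parts[1], 1, 1) != substr(parts[2], 1, 1))
            stop("range must stay within one letter block: ", e)
          stems_lo <- c(stems_lo, parts[1]); stems_hi <- c(stems_hi, parts[2])
        }
      } else if (grepl(".", e, fixed = TRUE)) {
        exact <- c(exact, e)
      } else {
        stem_single <- c(stem_single, e)
      }
    }
    list(name = g$name, stems_lo = stems_lo, stems_hi = stems_hi,
         exact = exact, stem_single = stem_single)
  })
  structure(list(groups = groups), class = "condition_group_map")
}

#' Map an ICD-10-AM shortlist code to its condition group
#'
#' First matching group in map order wins; codes matching no group (or
#' malformed codes / missing values) map to \code{"other/unclassified"}.
#'
#' @param code character vector of ICD codes.
#' @param map a \code{condition_group_map}; default loads the shipped map.
#' @return character vector of group names.
#' @export
map_icd_group <- function(code, map = load_condition_groups()) {
  code <- toupper(trimws(as.character(code)))
  ok <- !is.na(code) & grepl("^[A-Z][0-9]{2}(\\.[0-9A-Z]{1,4})?$", code)
  stem <- substr(code, 1, 3)
  out <- rep("other/unclassified", length(code))
  unassigned <- ok
  for (g in map$groups) {
    hit <- rep(FALSE, length(code))
    if (length(g$exact)) hit <- hit | code %in% g$exact
    if (length(g$stem_single)) hit <- hit | stem %in% g$stem_single
    for (i in seq_along(g$stems_lo)) {
      same_letter <- substr(stem, 1, 1) == substr(g$stems_lo[i], 1, 1)
      hit <- hit | (same_letter & stem >= g$stems_lo[i] & stem <= g$stems_hi[i])
    }
    take <- unassigned & hit
    out[take] <- g$name
    unassigned <- unassigned & !hit
  }
  out
}

#' Parse an emergency-department line list
#'
#' Expects columns date, hospital_id, region_id, residency_hint, age_years,
#' sex, indigenous_status, icd_code. Unknown category values are preserved as
#' "unknown", never dropped; rows with unparseable dates are rejected and
#' counted by reason in the \code{rejections} attribute.
#'
#' @param path CSV path, or a data.frame already in memory.
#' @return data.frame of parsed records with a \code{rejections} attribute
#'   (named integer vector of rejection counts by reason).
#' @export
parse_ed_records <- function(path) {
  d <- if (is.data.frame(path)) path
       else utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = "character")
  req <- c("date", "hospital_id", "region_id", "residency_hint", "age_years",
           "sex", "indigenous_status", "icd_code")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  rej <- c(bad_date = 0L, negative_age = 0L)
  dt <- as.Date(as.character(d$date), format = "%Y-%m-%d")
  bad <- is.na(dt)
  rej["bad_date"] <- sum(bad)
  d <- d[!bad, , drop = FALSE]; dt <- dt[!bad]
  age <- suppressWarnings(as.numeric(d$age_years))
  neg <- !is.na(age) & age < 0
  rej["negative_age"] <- sum(neg)
  d <- d[!neg, , drop = FALSE]; dt <- dt[!neg]; age <- age[!neg]
  norm_cat <- function(x, map) {
    x <- tolower(trimws(as.character(x)))
    out <- map[x]
    out[is.na(out)] <- "unknown"
    unname(out)
  }
  sex <- norm_cat(d$sex, c(m = "male", male = "male",
                           f = "female", female = "female"))
  ind <- norm_cat(d$indigenous_status,
                  c(aboriginal = "Aboriginal", a = "Aboriginal",
                    "non-aboriginal" = "non-Aboriginal",
                    non_aboriginal = "non-Aboriginal", n = "non-Aboriginal"))
  icd <- toupper(trimws(as.character(d$icd_code)))
  icd[icd == ""] <- NA_character_
  out <- data.frame(date = dt, hospital_id = as.character(d$hospital_id),
                    region_id = ifelse(trimws(d$region_id) == "", NA,
                                       as.character(d$region_id)),
                    residency_hint = tolower(trimws(d$residency_hint)),
                    age_years = age, sex = sex, indigenous_status = ind,
                    icd_code = icd, stringsAsFactors = FALSE)
  attr(out, "rejections") <- rej
  out
}

#' Assign an exposure region and residency class to each presentation
#'
#' NT residents are exposed in their residential region; visitors (non-NT
#' address) and presentations with missing or unknown address are exposed in
#' the region of the hospital attended.
#'
#' @param records parsed ED records.
#' @param hospital_regions data.frame with columns hospital_id, region_id.
#' @return records with columns \code{exposure_region} and
#'   \code{residency_class} (resident / visitor / unknown) added; rows whose
#'   hospital is absent from the registry are dropped and counted in the
#'   \code{rejections} attribute.
#' @export
assign_exposure_region <- function(records, hospital_regions) {
  hreg <- hospital_regions$region_id[match(records$hospital_id,
                                           hospital_regions$hospital_id)]
  bad <- is.na(hreg)
  rej <- attr(records, "rejections")
  if (any(bad)) {
    rej <- c(rej, unknown_hospital = sum(bad))
    records <- records[!bad, , drop = FALSE]
    hreg <- hreg[!bad]
  }
  is_nt <- records$residency_hint == "nt" & !is.na(records$region_id)
  is_visitor <- records$residency_hint == "non_nt"
  records$residency_class <- ifelse(is_nt, "resident",
                                    ifelse(is_visitor, "visitor", "unknown"))
  records$exposure_region <- ifelse(is_nt, records$region_id, hreg)
  attr(records, "rejections") <- rej
  records
}

#' Derive analysis demographics
#'
#' Attaches an age band, an IRSD disadvantage band and (via
#' \code{\link{map_icd_group}}) a condition group, without mutating the raw
#' fields. Two IRSD banding presets are provided, reflecting the two
#' groupings in circulation for decile data: \code{"deciles137"} bands
#' 1-3 / 4-7 / 8-10 and \code{"deciles136"} bands 1-3 / 4-6 / 7-10.
#'
#' @param records records with \code{exposure_region} assigned.
#' @param irsd data.frame region_id, irsd_decile, or NULL to skip IRSD.
#' @param irsd_scheme one of "deciles137", "deciles136".
#' @param map condition-group map.
#' @return records with columns age_band, irsd_band, condition_group added.
#' @export
derive_demographics <- function(records, irsd = NULL,
                                irsd_scheme = c("deciles137", "deciles136"),
                                map = load_condition_groups()) {
  irsd_scheme <- match.arg(irsd_scheme)
  a <- records$age_years
  records$age_band <- ifelse(is.na(a), "unknown",
                      ifelse(a < 5, "<5",
                      ifelse(a <= 18, "5-18",
                      ifelse(a <= 49, "19-49",
                      ifelse(a <= 64, "50-64", ">=65")))))
  if (!is.null(irsd)) {
    dec <- irsd$irsd_decile[match(records$region_id, irsd$region_id)]
    cut1 <- if (irsd_scheme == "deciles137") 7 else 6
    records$irsd_band <- ifelse(is.na(dec), "unknown",
                         ifelse(dec <= 3, "most_disadvantaged",
                         ifelse(dec <= cut1, "moderate", "most_advantaged")))
  } else {
    records$irsd_band <- "unknown"
  }
  records$condition_group <- ifelse(is.na(records$icd_code),
                                    "other/unclassified",
                                    map_icd_group(records$icd_code, map))
  records
}

#' Aggregate presentations to zero-filled stratum-days
#'
#' Produces one row per exposure-region and calendar day over the span of the
#' heatwave calendar: the presentation count (zero where none), the exposure
#' level, a public-holiday flag and PM2.5, together with the case-crossover
#' stratum key (region, year, month, ISO day-of-week). Zero-count days are
#' kept because the within-stratum contrast needs the full risk set of days.
#'
#' @param records records with \code{exposure_region} assigned.
#' @param calendar a \code{heatwave_calendar} covering the analysis span.
#' @param holidays data.frame date, scope ("territory" or a region id); NULL
#'   for none.
#' @param pm25 data.frame region_id, date, pm25_ugm3; NULL to omit PM2.5.
#' @param filter optional logical vector (length nrow(records)) or function
#'   of the records returning one, selecting the outcome subset.
#' @return data.frame of class \code{stratum_day}: region_id, date, year,
#'   month, dow, stratum, count, exposure_level, holiday, pm25. Records dated
#'   outside the calendar span are excluded and counted in the log.
#' @export
aggregate_counts <- function(records, calendar, holidays = NULL, pm25 = NULL,
                             filter = NULL) {
  if (!is.null(filter)) {
    keep <- if (is.function(filter)) filter(records) else filter
    records <- records[keep, , drop = FALSE]
  }
  cal_key <- paste(calendar$region_id, calendar$date)
  grid <- unique(calendar[, c("region_id", "date")])
  n_outside <- sum(!(paste(records$exposure_region, records$date) %in% cal_key))
  cnt <- table(paste(records$exposure_region, records$date))
  key <- paste(grid$region_id, grid$date)
  count <- as.integer(cnt[key]); count[is.na(count)] <- 0L
  expo <- calendar$exposure_level[match(key, cal_key)]
  hol <- rep(FALSE, nrow(grid))
  if (!is.null(holidays)) {
    hd <- as.Date(holidays$date)
    territory <- hd[holidays$scope == "territory"]
    hol <- grid$date %in% territory
    reg_h <- holidays[holidays$scope != "territory", , drop = FALSE]
    if (nrow(reg_h))
      hol <- hol | key %in% paste(reg_h$scope, as.Date(reg_h$date))
  }
  pm <- rep(NA_real_, nrow(grid))
  if (!is.null(pm25))
    pm <- pm25$pm25_ugm3[match(key, paste(pm25$region_id, as.Date(pm25$date)))]
  out <- data.frame(region_id = grid$region_id, date = grid$date,
                    year = as.integer(format(grid$date, "%Y")),
                    month = as.integer(format(grid$date, "%m")),
                    dow = as.integer(format(grid$date, "%u")),
                    count = count, exposure_level = expo, holiday = hol,
                    pm25 = pm, stringsAsFactors = FALSE)
  out$stratum <- paste(out$region_id, out$year, out$month, out$dow, sep = ":")
  class(out) <- c("stratum_day", "data.frame")
  if (n_outside > 0)
    out <- hw_log(out, sprintf("records_outside_calendar_span:%d", n_outside))
  out
}
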