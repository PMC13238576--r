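ed_row <- function(date = "2001-01-05", hospital_id = "H1", region_id = "DarwinCity",
                   residency_hint = "nt", age_years = "30", sex = "F",
                   indigenous_status = "Aboriginal", icd_code = "K52") {
  data.frame(date = date, hospital_id = hospital_id, region_id = region_id,
             residency_hint = residency_hint, age_years = age_years,
             sex = sex, indigenous_status = indigenous_status,
             icd_code = icd_code, stringsAsFactors = FALSE)
}

test_that("line-list parsing keeps unknowns and rejects malformed rows", {
  d <- rbind(ed_row(), ed_row(sex = "U"), ed_row(date = "2024-13-40"),
             ed_row(age_years = "-3"))
  r <- parse_ed_records(d)
  expect_equal(nrow(r), 2L)
  expect_equal(r$sex, c("female", "unknown"))
  rej <- attr(r, "rejections")
  expect_equal(unname(rej["bad_date"]), 1L)
  expect_equal(unname(rej["negative_age"]), 1L)
  expect_error(parse_ed_records(d[, -1]), "mandatory column")
})

test_that("ICD shortlist codes map to the published condition groups", {
  m <- load_condition_groups()
  cases <- c(K52 = "Digestive", T67 = "Effects heat and light",
             T66 = "Injury", T68 = "Injury", S01 = "Injury",
             Z99 = "other/unclassified", A09 = "Infectious",
             B99 = "Infectious", U07.1 = "Infectious",
             N39 = "Urinary", R45 = "Mental/behavioral",
             I51 = "Cardiovascular", I52 = "other/unclassified",
             J18 = "Respiratory", L03 = "Skin", M54 = "Musculoskeletal",
             E11 = "Diabetes", E12 = "other/unclassified")
  expect_equal(map_icd_group(names(cases), m), unname(cases))
  # decimal handling: exact-decimal entries vs decimal children of ranges
  expect_equal(map_icd_group("R19.0", m), "Digestive")
  expect_equal(map_icd_group("R19.5", m), "other/unclassified")
  expect_equal(map_icd_group("R00.1", m), "Cardiovascular")
  expect_equal(map_icd_group("R00.3", m), "other/unclassified")
  expect_equal(map_icd_group("U07.3", m), "other/unclassified")
  expect_equal(map_icd_group("S01.81", m), "Injury")
  expect_equal(map_icd_group("R06.1", m), "Respiratory")
  expect_equal(map_icd_group("bad-code", m), "other/unclassified")
})

test_that("every code maps to exactly one group (partition property)", {
  m <- load_condition_groups()
  set.seed(8)
  codes <- paste0(sample(LETTERS, 300, TRUE),
                  sprintf("%02d", sample(0:99, 300, TRUE)))
  g <- map_icd_group(codes, m)
  expect_equal(length(g), 300L)
  expect_true(all(!is.na(g)))
})

registry <- data.frame(hospital_id = c("H1", "H2"),
                       region_id = c("DarwinCity", "AliceSprings"),
                       stringsAsFactors = FALSE)

test_that("exposure region follows residence for locals, hospital otherwise", {
  d <- rbind(ed_row(),                                     # NT resident
             ed_row(residency_hint = "non_nt", region_id = "", hospital_id = "H2"),
             ed_row(residency_hint = "", region_id = "", hospital_id = "H2"),
             ed_row(hospital_id = "H9"))
  r <- assign_exposure_region(parse_ed_records(d), registry)
  expect_equal(nrow(r), 3L)
  expect_equal(r$exposure_region, c("DarwinCity", "AliceSprings", "AliceSprings"))
  expect_equal(r$residency_class, c("resident", "visitor", "unknown"))
  expect_equal(unname(attr(r, "rejections")["unknown_hospital"]), 1L)
  # idempotent and always inside the registry
  r2 <- assign_exposure_region(r, registry)
  expect_equal(r2$exposure_region, r$exposure_region)
  expect_true(all(r$exposure_region %in% registry$region_id))
})

test_that("age bands and IRSD bands follow the published groupings", {
  d <- do.call(rbind, lapply(c(4, 5, 18, 19, 49, 50, 64, 65, NA),
                             function(a) ed_row(age_years = as.character(a))))
  r <- derive_demographics(assign_exposure_region(parse_ed_records(d), registry))
  expect_equal(r$age_band, c("<5", "5-18", "5-18", "19-49", "19-49",
                             "50-64", "50-64", ">=65", "unknown"))
  irsd <- data.frame(region_id = "DarwinCity", irsd_decile = 3)
  r3 <- derive_demographics(assign_exposure_region(parse_ed_records(ed_row()),
                                                   registry), irsd)
  expect_equal(r3$irsd_band, "most_disadvantaged")
  # decile 7 is where the two published groupings disagree
  irsd7 <- data.frame(region_id = "DarwinCity", irsd_decile = 7)
  rec <- assign_exposure_region(parse_ed_records(ed_row()), registry)
  expect_equal(derive_demographics(rec, irsd7, "deciles137")$irsd_band,
               "moderate")
  expect_equal(derive_demographics(rec, irsd7, "deciles136")$irsd_band,
               "most_advantaged")
})

mini_calendar <- function(regions = c("DarwinCity", "AliceSprings"),
                          days = 14, start = "2001-01-01") {
  dates <- as.Date(start) + seq_len(days) - 1
  g <- expand.grid(region_id = regions, date = dates,
                   stringsAsFactors = FALSE)
  g$variant <- "T"
  g$ehf <- 0
  g$severity <- factor("none", levels = c("none", "low", "severe", "extreme"))
  g$exposure_level <- factor("none", levels = c("none", "low", "severe_extreme"))
  class(g) <- c("heatwave_calendar", "data.frame")
  g
}

test_that("stratum-day aggregation zero-fills and conserves counts", {
  cal <- mini_calendar()
  d <- rbind(ed_row(), ed_row(), ed_row(sex = "M"),
             ed_row(date = "2001-01-09", indigenous_status = "non-Aboriginal"),
             ed_row(date = "1999-01-01"))
  recs <- derive_demographics(
    assign_exposure_region(parse_ed_records(d), registry))
  sd <- aggregate_counts(recs, cal)
  expect_equal(nrow(sd), 2 * 14)            # zero-filled over all region-days
  expect_equal(sum(sd$count), 4L)           # 1999 record excluded
  expect_match(processing_log(sd), "outside_calendar_span:1")
  expect_equal(sd$count[sd$region_id == "DarwinCity" &
                          sd$date == as.Date("2001-01-05")], 3L)
  # filtered aggregation conserves the filtered total
  sd_ab <- aggregate_counts(recs, cal,
                            filter = function(r) r$indigenous_status == "Aboriginal")
  expect_equal(sum(sd_ab$count),
               sum(recs$indigenous_status == "Aboriginal" &
                     recs$date >= min(cal$date) & recs$date <= max(cal$date)))
  # stratum key separates day-of-week within the same region-month
  fri <- sd$stratum[sd$date == as.Date("2001-01-05")][1]
  mon <- sd$stratum[sd$date == as.Date("2001-01-08")][1]
  expect_false(fri == mon)
  expect_equal(sd$dow[sd$date == as.Date("2001-01-08")][1], 1L)  # ISO Monday
})

test_that("holiday and PM2.5 covariates join by region and date", {
  cal <- mini_calendar()
  hol <- data.frame(date = "2001-01-01", scope = "territory")
  hol2 <- rbind(hol, data.frame(date = "2001-01-02", scope = "DarwinCity"))
  pm <- data.frame(region_id = "DarwinCity", date = "2001-01-03",
                   pm25_ugm3 = 9.5)
  recs <- derive_demographics(
    assign_exposure_region(parse_ed_records(ed_row()), registry))
  sd <- aggregate_counts(recs, cal, holidays = hol2, pm25 = pm)
  expect_true(all(sd$holiday[sd$date == as.Date("2001-01-01")]))
  jan2 <- sd[sd$date == as.Date("2001-01-02"), ]
  expect_equal(jan2$holiday[jan2$region_id == "DarwinCity"], TRUE)
  expect_equal(jan2$holiday[jan2$region_id == "AliceSprings"], FALSE)
  expect_equal(sd$pm25[sd$region_id == "DarwinCity" &
                         sd$date == as.Date("2001-01-03")], 9.5)
  expect_true(is.na(sd$pm25[sd$region_id == "AliceSprings" &
                              sd$date == as.Date("2001-01-03")]))
})
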