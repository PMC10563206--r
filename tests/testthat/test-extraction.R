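test_that("daily maximum temperature uses the half-open day window", {
  rec <- tiny_records()
  expect_equal(daily_max_temperature(rec, as.Date("2020-01-01")), 38.9)
  expect_equal(daily_max_temperature(rec, as.Date("2020-01-02")), 39.2)
  expect_null(daily_max_temperature(rec, as.Date("2020-01-05")))
  # a 23:59 reading belongs to its own day, not the next
  v <- data.frame(episode_id = "E1", datetime = utc("2020-01-01 23:59:00"),
                  measure_id = "body_temperature", value = 39.2,
                  stringsAsFactors = FALSE)
  expect_equal(daily_max_temperature(v, as.Date("2020-01-01")), 39.2)
  expect_null(daily_max_temperature(v, as.Date("2020-01-02")))
})

test_that("daily maximum temperature equals a brute-force scan", {
  set.seed(42)
  n <- 300
  v <- data.frame(
    episode_id = "E1",
    datetime = utc("2020-01-01 00:00:00") + runif(n, 0, 10 * 86400),
    measure_id = "body_temperature",
    value = round(runif(n, 35, 42), 1), stringsAsFactors = FALSE)
  for (day in as.list(seq(as.Date("2020-01-01"), by = "day", length.out = 10))) {
    t0 <- hai_ts(day); t1 <- t0 + 86400
    keep <- v$datetime >= t0 & v$datetime < t1 & v$value >= 30 & v$value <= 45
    expected <- if (any(keep)) max(v$value[keep]) else NULL
    expect_equal(daily_max_temperature(v, day), expected)
  }
})

test_that("hospital days follow the calendar-day convention", {
  expect_equal(hospital_days(utc("2020-01-01 09:00:00"), as.Date("2020-01-01")), 1L)
  expect_equal(hospital_days(utc("2020-01-01 09:00:00"), as.Date("2020-01-05")), 5L)
  # admitted just before midnight: next morning is already day 2
  expect_equal(hospital_days(utc("2020-01-01 23:50:00"), as.Date("2020-01-02")), 2L)
  expect_error(hospital_days(utc("2020-01-05 09:00:00"), as.Date("2020-01-04")),
               "precedes admission")
})

test_that("structured extraction maps orders, labs and presence flags", {
  rec <- tiny_records()
  day2 <- extract_structured(rec, as.Date("2020-01-02"), the_registry)[["E1"]]
  expect_equal(day2$MO$urinary_catheter$value, 1)   # order active on the day
  expect_equal(day2$CL$has_pct_lab$value, 0)        # no PCT lab anywhere
  expect_equal(day2$CL$pleural_wbc$value, 1500)
  expect_equal(day2$CL$pleural_micro_positive$value, 1)
  expect_equal(day2$OP$recent_operation$value, 1)
  expect_equal(day2$PS$hospital_days$value, 2L)
  expect_equal(day2$DE$age$value, 70L)
  # same-day duplicate labs: the later timestamp wins
  day1 <- extract_structured(rec, as.Date("2020-01-01"), the_registry)[["E1"]]
  expect_equal(day1$CL$crp$value, 42)
  expect_equal(day1$MO$urinary_catheter$value, 0)   # order not yet active
  expect_equal(day1$CL$pleural_micro_positive$value, 0)
})

test_that("keyword flags respect note type, date and negation cues", {
  rec <- tiny_records()
  flags <- extract_keywords(rec, the_lexicon, as.Date("2020-01-02"))
  expect_equal(unname(flags["chest_pain"]), 1)
  expect_equal(unname(flags["ir_pleural_effusion"]), 1)
  expect_equal(unname(flags["cough_sputum"]), 0)    # absent keyword -> 0
  # imaging note postdates day 1, so its flag is still 0 there
  flags1 <- extract_keywords(rec, the_lexicon, as.Date("2020-01-01"))
  expect_equal(unname(flags1["ir_pleural_effusion"]), 0)
  # sentence-level negation suppresses the flag
  neg <- data.frame(episode_id = "E1", datetime = utc("2020-01-01 12:00:00"),
                    note_type = "progress",
                    text = "There is no chest pain. Appetite is good.",
                    stringsAsFactors = FALSE)
  fneg <- extract_keywords(neg, the_lexicon, as.Date("2020-01-02"))
  expect_equal(unname(fneg["chest_pain"]), 0)
})

test_that("adding keywords to the lexicon never clears a flag", {
  rec <- tiny_records()
  base <- extract_keywords(rec, the_lexicon, as.Date("2020-01-02"))
  richer <- the_lexicon
  for (i in seq_along(richer$entries)) {
    richer$entries[[i]]$keywords <- c(richer$entries[[i]]$keywords, "patient")
  }
  more <- extract_keywords(rec, richer, as.Date("2020-01-02"))
  expect_true(all(more[names(base)] >= base))
})

test_that("build_cases yields one validated tuple per episode per day", {
  rec <- tiny_records()
  cases <- build_cases(rec, the_lexicon, the_registry)
  expect_length(cases, 3)                     # 3-day stay -> 3 tuples
  expect_equal(vapply(cases, function(cs) fmt <- format(cs$as_of_date), ""),
               c("2020-01-01", "2020-01-02", "2020-01-03"))
  for (cs in cases) expect_equal(nrow(validate_case(cs, the_registry)), 0)
  expect_length(build_cases(new_records(), the_lexicon, the_registry), 0)
})

test_that("case counts equal total length of stay on a generated cohort", {
  cohort <- generate_cohort(cohort_spec(n_patients = 50, seed = 11),
                            the_rules, the_catalog, the_lexicon, the_registry)
  adm <- cohort$records$admissions
  los <- as.integer(as.Date(adm$discharge_datetime) -
                      as.Date(adm$admission_datetime)) + 1L
  cases <- build_cases(cohort$records, the_lexicon, the_registry)
  expect_length(cases, sum(los))
})

test_that("extraction is deterministic at the byte level", {
  rec <- tiny_records()
  t1 <- withr::local_tempfile(fileext = ".jsonl")
  t2 <- withr::local_tempfile(fileext = ".jsonl")
  write_cases(build_cases(rec, the_lexicon, the_registry), t1)
  write_cases(build_cases(rec, the_lexicon, the_registry), t2)
  expect_identical(readLines(t1), readLines(t2))
})

test_that("unparseable datetimes are skipped and reported, not fatal", {
  d <- withr::local_tempdir()
  rec <- tiny_records()
  write_records(rec, d)
  labs <- read.csv(file.path(d, "labs.csv"), stringsAsFactors = FALSE)
  labs$datetime[2] <- "not-a-date"
  write.csv(labs, file.path(d, "labs.csv"), row.names = FALSE)
  again <- read_records(d)
  issues <- attr(again, "issues")
  expect_true(any(grepl("labs row 2", issues$where)))
  expect_equal(nrow(again$labs), nrow(rec$labs) - 1)
})

test_that("record validation flags orphans and out-of-stay timestamps", {
  rec <- tiny_records()
  rec$labs <- rbind(rec$labs, data.frame(
    episode_id = "E9", datetime = utc("2020-01-02 09:00:00"), test_id = "CRP",
    value = 1, unit = "mg/L", abnormal_flag = 0, stringsAsFactors = FALSE))
  rec$vitals <- rbind(rec$vitals, data.frame(
    episode_id = "E1", datetime = utc("2020-02-15 09:00:00"),
    measure_id = "body_temperature", value = 37, stringsAsFactors = FALSE))
  issues <- validate_records(rec)
  expect_true(any(issues$issue == "episode not in admissions"))
  expect_true(any(grepl("outside admission", issues$issue)))
})
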