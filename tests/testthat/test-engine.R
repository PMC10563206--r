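test_that("condition evaluation follows closed-open and missing-is-false", {
  case <- conformant_case()       # temp 38.6, chest_pain 1, no pleural_wbc
  cond <- function(fid, op, rhs) list(factor_id = fid, operator = op, operand = rhs)
  expect_true(evaluate_condition(cond("body_temperature_max", "in_range",
                                      c(38, 39)), case))
  case$groups$VS$body_temperature_max$value <- 39.0
  expect_false(evaluate_condition(cond("body_temperature_max", "in_range",
                                       c(38, 39)), case))   # right edge open
  case$groups$VS$body_temperature_max$value <- 38.0
  expect_true(evaluate_condition(cond("body_temperature_max", "in_range",
                                      c(38, 39)), case))    # left edge closed
  expect_false(evaluate_condition(cond("pleural_wbc", "gt", 1000), case))
  expect_true(evaluate_condition(cond("pleural_wbc", "gt", 1000), case,
                                 missing_fires = TRUE))
  expect_true(evaluate_condition(cond("chest_pain", "eq", 1), case))
  expect_true(evaluate_condition(cond("chest_pain", "contains_flag", NA), case))
})

test_that("a rule fires only when its whole conjunction holds", {
  rec <- tiny_records()
  cases <- build_cases(rec, the_lexicon, the_registry)
  # day 2: temp 39.2, chest pain note, imaging effusion, pleural wbc 1500,
  # positive pleural culture -> all three PCI rules fire
  fired2 <- match_rules(cases[[2]], the_rules)
  expect_setequal(fired2$rule_id, c("10301", "10302", "10303"))
  # day 1: no imaging note yet, no pleural lab -> nothing fires
  fired1 <- match_rules(cases[[1]], the_rules)
  expect_equal(nrow(fired1), 0)
})

test_that("best-rule selection keeps the max probability, ties to lowest id", {
  fired <- data.frame(
    rule_id = c("20105", "20102", "30001"),
    diagnosis_code = c("LRI", "LRI", "PCI"),
    site_code = c("RTI", "RTI", "RTI"),
    probability = c(0.8, 0.8, 0.7),
    patient_id = "P1", episode_id = "E1",
    as_of_date = as.Date("2020-01-05"), stringsAsFactors = FALSE)
  sel <- select_per_diagnosis(fired)
  expect_equal(sort(sel$rule_id), c("20102", "30001"))
  fired$probability <- c(0.7, 0.9, 0.7)
  expect_equal(select_per_diagnosis(fired)$rule_id[1], "20102")
  expect_equal(nrow(select_per_diagnosis(fired[0, ])), 0)
})

test_that("onset classification uses a strict 48-hour boundary", {
  cfg <- engine_config()
  expect_equal(cfg$onset_cutoff_hours, 48)
  day <- as.Date("2020-01-10")
  end_of_day <- hai_ts(day) + 86400
  mk <- function(admission) {
    new_case("P1", "E1", day, list(PS = list(
      admission_datetime = factor_value("admission_datetime", "date", admission),
      hospital_days = factor_value("hospital_days", "integer",
                                   hospital_days(admission, day)))))
  }
  expect_equal(classify_onset(mk(end_of_day - 20 * 3600), cfg), "community_acquired")
  expect_equal(classify_onset(mk(end_of_day - 48 * 3600), cfg), "community_acquired")
  expect_equal(classify_onset(mk(end_of_day - 49 * 3600), cfg), "hospital_acquired")
  naked <- new_case("P1", "E1", day)
  expect_error(classify_onset(naked, cfg), "admission_datetime")
})

test_that("threshold gating is strict and defaults to pass", {
  w <- data.frame(diagnosis_code = c("LRI", "LRI", "UTI"),
                  probability = c(0.60, 0.70, 0.50),
                  status = "alerted", stringsAsFactors = FALSE)
  out <- apply_thresholds(w, list(LRI = 0.70))
  expect_equal(out$status, c("below_threshold", "alerted", "alerted"))
})

test_that("RTI suppression is keyed by patient and site within the window", {
  mk <- function(day, site, patient = "P1") {
    data.frame(patient_id = patient, episode_id = paste0("E-", patient),
               infection_time = as.Date("2020-01-01") + day - 1,
               site_code = site, diagnosis_code = "LRI", probability = 0.8,
               rule_id = "20101", status = "alerted", stringsAsFactors = FALSE)
  }
  out <- apply_rti(rbind(mk(1, "RTI"), mk(10, "RTI")), engine_config(rti_days = 14))
  expect_equal(out$status, c("alerted", "suppressed_rti"))
  out <- apply_rti(rbind(mk(1, "RTI"), mk(16, "RTI")), engine_config(rti_days = 14))
  expect_equal(out$status, c("alerted", "alerted"))
  out <- apply_rti(rbind(mk(1, "RTI"), mk(5, "USI")), engine_config(rti_days = 14))
  expect_equal(out$status, c("alerted", "alerted"))
  # a suppressed warning must not extend the window
  out <- apply_rti(rbind(mk(1, "RTI"), mk(13, "RTI"), mk(20, "RTI")),
                   engine_config(rti_days = 14))
  expect_equal(out$status, c("alerted", "suppressed_rti", "alerted"))
})

test_that("the engine matches the brute-force oracle on random cases", {
  cases <- random_cases(60, seed = 101)
  cfg <- engine_config(thresholds = list(LRI = 0.6, UTI = 0.6))
  got <- run_surveillance(cases, the_rules, cfg)
  want <- oracle_pipeline(cases, the_rules, cfg)
  attr(got, "issues") <- NULL; attr(got, "counts") <- NULL
  got <- got[order(got$patient_id, got$infection_time, got$site_code,
                   got$diagnosis_code, got$rule_id), ]
  rownames(got) <- rownames(want) <- NULL
  expect_true(nrow(want) > 0)       # the fixture actually exercises the engine
  expect_equal(got, want)
  # same under the guideline-only scenario
  cfg_g <- engine_config(scenario = "guideline_only")
  got_g <- run_surveillance(cases, the_rules, cfg_g)
  attr(got_g, "issues") <- NULL; attr(got_g, "counts") <- NULL
  got_g <- got_g[order(got_g$patient_id, got_g$infection_time, got_g$site_code,
                       got_g$diagnosis_code, got_g$rule_id), ]
  want_g <- oracle_pipeline(cases, the_rules, cfg_g)
  rownames(got_g) <- rownames(want_g) <- NULL
  expect_equal(got_g, want_g)
})

test_that("guideline-only fired rules are a subset of the full scenario's", {
  cases <- random_cases(40, seed = 77)
  for (case in cases) {
    f_g <- match_rules(case, filter_by_source(the_rules, "guideline_only"))
    f_ge <- match_rules(case, filter_by_source(the_rules, "guideline_plus_expert"))
    expect_true(all(f_g$rule_id %in% f_ge$rule_id))
  }
})

test_that("surveillance output respects its structural invariants", {
  cohort <- generate_cohort(cohort_spec(n_patients = 150, prevalence = 0.15,
                                        seed = 23),
                            the_rules, the_catalog, the_lexicon, the_registry)
  cases <- build_cases(cohort$records, the_lexicon, the_registry)
  w <- run_surveillance(cases, the_rules)
  al <- w[w$status == "alerted", ]
  # at most one alerted warning per (patient, diagnosis, day)
  expect_false(any(duplicated(al[, c("patient_id", "diagnosis_code",
                                     "infection_time")])))
  # no two alerted warnings share (patient, site) within the RTI window
  for (k in unique(paste(al$patient_id, al$site_code))) {
    times <- sort(al$infection_time[paste(al$patient_id, al$site_code) == k])
    if (length(times) > 1) expect_true(all(diff(times) >= 14))
  }
  # determinism
  w2 <- run_surveillance(cases, the_rules)
  expect_identical(as.data.frame(w), as.data.frame(w2))
  # raising a threshold never increases the alerted count
  for (thr in c(0.3, 0.6, 0.95)) {
    w_thr <- run_surveillance(cases, the_rules,
                              engine_config(thresholds = list(LRI = thr)))
    expect_lte(sum(w_thr$status == "alerted"), sum(w$status == "alerted"))
  }
})

test_that("confirmed infections are not re-alerted", {
  cohort <- generate_cohort(cohort_spec(n_patients = 80, prevalence = 0.2,
                                        seed = 31),
                            the_rules, the_catalog, the_lexicon, the_registry)
  cases <- build_cases(cohort$records, the_lexicon, the_registry)
  inf <- cohort$gold[cohort$gold$infected == 1, ]
  cfg <- engine_config(confirmed = data.frame(episode_id = inf$episode_id,
                                              site_code = inf$site_code,
                                              stringsAsFactors = FALSE))
  w <- run_surveillance(cases, the_rules, cfg)
  al <- w[w$status == "alerted", ]
  expect_false(any(paste(al$episode_id, al$site_code) %in%
                     paste(inf$episode_id, inf$site_code)))
})
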