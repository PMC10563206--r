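mk_warning <- function(episode, site, diag, day = "2020-01-05",
                       status = "alerted", patient = sub("^E", "P", episode)) {
  data.frame(patient_id = patient, episode_id = episode,
             infection_time = as.Date(day), site_code = site,
             diagnosis_code = diag, probability = 0.8, rule_id = "20101",
             status = status, stringsAsFactors = FALSE)
}

mk_gold <- function(n_inf, n_clean, diag = "LRI", site = "RTI",
                    month = "2020-01") {
  inf <- if (n_inf > 0) data.frame(
    patient_id = sprintf("Pi%03d", seq_len(n_inf)),
    episode_id = sprintf("Ei%03d", seq_len(n_inf)), infected = 1L,
    diagnosis_code = diag, site_code = site,
    onset_datetime = utc("2020-01-05 12:00:00"), report_month = month,
    stringsAsFactors = FALSE)
  clean <- if (n_clean > 0) data.frame(
    patient_id = sprintf("Pc%03d", seq_len(n_clean)),
    episode_id = sprintf("Ec%03d", seq_len(n_clean)), infected = 0L,
    diagnosis_code = NA_character_, site_code = NA_character_,
    onset_datetime = utc(NA), report_month = month, stringsAsFactors = FALSE)
  rbind(inf, clean)
}

test_that("metric identities hold and zero denominators give NA", {
  m <- hai_metrics(confusion_counts(TP = 8, FN = 2, TN = 85, FP = 5))
  expect_equal(unname(m["sen"]), 0.8)
  expect_equal(unname(m["spe"]), 85 / 90)
  expect_equal(unname(m["acc"]), 0.93)
  m0 <- hai_metrics(confusion_counts())
  expect_true(all(is.na(m0)))
  m_noinf <- hai_metrics(confusion_counts(TN = 10, FP = 2))
  expect_true(is.na(m_noinf["sen"]))
  expect_false(is.na(m_noinf["spe"]))
})

test_that("episode-level scoring matches the textbook cases", {
  gold <- mk_gold(10, 90)
  w <- do.call(rbind, lapply(gold$episode_id[gold$infected == 1],
                             mk_warning, site = "RTI", diag = "LRI"))
  cc <- score_episode_level(w, gold)
  expect_equal(unlist(cc), c(TP = 10L, FP = 0L, FN = 0L, TN = 90L))
  expect_equal(unname(hai_metrics(cc)[c("sen", "spe")]), c(1, 1))

  # 83 of 100 infected episodes alerted -> SEN 0.83
  gold2 <- mk_gold(100, 50)
  w2 <- do.call(rbind, lapply(gold2$episode_id[1:83], mk_warning,
                              site = "RTI", diag = "LRI"))
  expect_equal(unname(hai_metrics(score_episode_level(w2, gold2))["sen"]), 0.83)

  # a wrong-site alert on an infected episode is a miss under site matching
  gold3 <- mk_gold(1, 1)
  w3 <- mk_warning(gold3$episode_id[1], "USI", "UTI")
  expect_equal(score_episode_level(w3, gold3)$FN, 1L)
  expect_equal(score_episode_level(w3, gold3, match_on = "any")$TP, 1L)

  # warnings for unknown episodes are an error
  expect_error(score_episode_level(mk_warning("E999", "RTI", "LRI"), gold3),
               "absent from gold")
})

test_that("episode scoring equals an independent recount on random fixtures", {
  set.seed(99)
  for (rep in 1:3) {
    n <- 150
    gold <- mk_gold(30, n - 30)
    sites <- c("RTI", "USI", "SST")
    picks <- sample(gold$episode_id, 60, replace = FALSE)
    w <- do.call(rbind, lapply(picks, function(e) {
      mk_warning(e, sample(sites, 1), "LRI",
                 status = sample(c("alerted", "below_threshold"), 1))
    }))
    got <- unlist(score_episode_level(w, gold))
    expect_equal(got, oracle_confusion(w, gold))
  }
})

test_that("monthly strata partition the episodes and sum to the overall", {
  gold <- rbind(mk_gold(5, 40, month = "2020-01"),
                mk_gold(3, 30, month = "2020-02"))
  gold$episode_id <- sprintf("E%03d", seq_len(nrow(gold)))
  gold$patient_id <- sprintf("P%03d", seq_len(nrow(gold)))
  inf <- gold$episode_id[gold$infected == 1]
  w <- do.call(rbind, lapply(inf[-1], mk_warning, site = "RTI", diag = "LRI"))
  rep_m <- stratified_report(list(full = w), gold, by = "month")
  overall <- rep_m[rep_m$stratum == "overall", ]
  months <- rep_m[rep_m$stratum != "overall", ]
  for (col in c("TP", "FP", "FN", "TN")) {
    expect_equal(sum(months[[col]]), overall[[col]])
  }
  # a stratum with no episodes reports NA metrics, not zeros
  rep_empty <- stratified_report(list(full = w), gold, by = "month",
                                 strata = c("2020-01", "2020-02", "2020-03"))
  empty_row <- rep_empty[rep_empty$stratum == "2020-03", ]
  expect_true(all(is.na(empty_row[, c("acc", "sen", "spe")])))
  expect_equal(empty_row$TP + empty_row$FP + empty_row$FN + empty_row$TN, 0L)
})

test_that("expert rules that add coverage raise sensitivity, not lower it", {
  gold <- mk_gold(10, 60)
  inf <- gold$episode_id[gold$infected == 1]
  w_g <- do.call(rbind, lapply(inf[1:6], mk_warning, site = "RTI", diag = "LRI"))
  w_ge <- rbind(w_g, do.call(rbind, lapply(inf[7:9], mk_warning,
                                           site = "RTI", diag = "LRI")))
  rep2 <- stratified_report(list(guideline_only = w_g,
                                 guideline_plus_expert = w_ge),
                            gold, by = "month")
  sen <- function(s) rep2$sen[rep2$scenario == s & rep2$stratum == "overall"]
  expect_gte(sen("guideline_plus_expert"), sen("guideline_only"))
  expect_equal(sen("guideline_only"), 0.6)
  expect_equal(sen("guideline_plus_expert"), 0.9)
})

test_that("diagnosis and site strata count uninvolved episodes as negatives", {
  gold <- rbind(mk_gold(4, 50, diag = "LRI", site = "RTI"),
                mk_gold(2, 0, diag = "UTI", site = "USI"))
  gold$episode_id <- sprintf("E%03d", seq_len(nrow(gold)))
  gold$patient_id <- sprintf("P%03d", seq_len(nrow(gold)))
  lri <- gold$episode_id[gold$infected == 1 & gold$diagnosis_code == "LRI"]
  uti <- gold$episode_id[gold$infected == 1 & gold$diagnosis_code == "UTI"]
  w <- rbind(do.call(rbind, lapply(lri[1:3], mk_warning, site = "RTI", diag = "LRI")),
             mk_warning(uti[1], "USI", "UTI"),
             mk_warning(gold$episode_id[gold$infected == 0][1], "USI", "UTI"))
  rep_d <- stratified_report(list(x = w), gold, by = "diagnosis")
  lri_row <- rep_d[rep_d$stratum == "LRI", ]
  expect_equal(lri_row$TP, 3L); expect_equal(lri_row$FN, 1L)
  expect_equal(lri_row$FP, 0L); expect_equal(lri_row$TN, 52L)
  uti_row <- rep_d[rep_d$stratum == "UTI", ]
  expect_equal(uti_row$TP, 1L); expect_equal(uti_row$FP, 1L)
  # specificity is inflated by the abundant true negatives
  expect_gt(lri_row$spe, 0.98)
  rep_s <- stratified_report(list(x = w), gold, by = "site")
  expect_setequal(setdiff(rep_s$stratum, "overall"), c("RTI", "USI"))
})

test_that("report writers emit the tabular structure", {
  gold <- mk_gold(2, 10)
  w <- mk_warning(gold$episode_id[1], "RTI", "LRI")
  rep1 <- stratified_report(list(s = w), gold, by = "month")
  tf <- withr::local_tempfile(fileext = ".csv")
  write_eval_report(rep1, tf)
  back <- read.csv(tf)
  expect_setequal(names(back), c("stratum", "scenario", "TP", "FP", "FN",
                                 "TN", "acc", "sen", "spe"))
  tfj <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep1, tfj)
  expect_silent(jsonlite::fromJSON(tfj))
})
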