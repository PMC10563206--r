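test_that("cohort specs validate their rates and weights", {
  expect_error(cohort_spec(prevalence = 1.2), "\\[0, 1\\]")
  expect_error(cohort_spec(mixture = c(LRI = 0.7, UTI = 0.2)), "sum to 1")
  expect_error(cohort_spec(mixture = c(0.5, 0.5)), "named")
})

test_that("zero prevalence yields a fully clean cohort", {
  cohort <- generate_cohort(cohort_spec(n_patients = 200, prevalence = 0,
                                        seed = 7),
                            the_rules, the_catalog, the_lexicon, the_registry)
  expect_equal(sum(cohort$gold$infected), 0)
  expect_true(all(is.na(cohort$gold$diagnosis_code)))
  # and no rule can fire on it
  cases <- build_cases(cohort$records, the_lexicon, the_registry)
  w <- run_surveillance(cases, the_rules)
  expect_equal(sum(w$status == "alerted"), 0)
})

test_that("generation is deterministic in the seed", {
  s <- cohort_spec(n_patients = 60, prevalence = 0.2, note_noise = 0.1, seed = 13)
  a <- generate_cohort(s, the_rules, the_catalog, the_lexicon, the_registry)
  b <- generate_cohort(s, the_rules, the_catalog, the_lexicon, the_registry)
  expect_identical(a, b)
  c_ <- generate_cohort(cohort_spec(n_patients = 60, prevalence = 0.2,
                                    note_noise = 0.1, seed = 14),
                        the_rules, the_catalog, the_lexicon, the_registry)
  expect_false(identical(a$records$admissions, c_$records$admissions))
})

test_that("generated records satisfy the extraction preconditions", {
  cohort <- generate_cohort(cohort_spec(n_patients = 80, prevalence = 0.2,
                                        note_noise = 0.2, seed = 3),
                            the_rules, the_catalog, the_lexicon, the_registry)
  expect_equal(nrow(validate_records(cohort$records)), 0)
  # every infected episode has onset > 48 h after admission
  inf <- cohort$gold[cohort$gold$infected == 1, ]
  adm <- cohort$records$admissions
  hrs <- as.numeric(difftime(inf$onset_datetime,
                             adm$admission_datetime[match(inf$episode_id,
                                                          adm$episode_id)],
                             units = "hours"))
  expect_true(all(hrs > 48))
})

test_that("infection injection realizes each rule condition in the records", {
  cohort <- generate_cohort(cohort_spec(n_patients = 5, prevalence = 0, seed = 2,
                                        mean_los = 8),
                            the_rules, the_catalog, the_lexicon, the_registry)
  rec <- cohort$records
  pci_rule <- Filter(function(r) r$rule_id == "10302", the_rules$rules)[[1]]
  eid <- rec$admissions$episode_id[1]
  onset <- as.Date(rec$admissions$admission_datetime[1]) + 3
  rec2 <- inject_infection(rec, eid, "PCI", pci_rule, onset,
                           the_lexicon, the_registry)
  lab <- rec2$labs[rec2$labs$episode_id == eid &
                     rec2$labs$test_id == "PLEURAL_WBC", ]
  expect_equal(nrow(lab), 1)
  expect_gt(lab$value, 1000)
  expect_equal(sum(rec2$micro$episode_id == eid &
                     rec2$micro$specimen == "pleural_fluid" &
                     rec2$micro$positive_flag == 1), 1)
  # the engine sees the injected infection on the onset day
  cases <- build_cases(rec2, the_lexicon, the_registry)
  onset_case <- Filter(function(cs) cs$episode_id == eid &&
                         cs$as_of_date == onset, cases)[[1]]
  expect_true("10302" %in% match_rules(onset_case, the_rules)$rule_id)

  # early onsets violate the hospital-acquired precondition
  early <- as.Date(rec$admissions$admission_datetime[1]) + 1
  expect_error(inject_infection(rec, eid, "PCI", pci_rule, early,
                                the_lexicon, the_registry), "48 h")
  # rule/diagnosis mismatch is rejected
  expect_error(inject_infection(rec, eid, "LRI", pci_rule, onset,
                                the_lexicon, the_registry), "targets PCI")
})

test_that("requesting a diagnosis without packaged rules fails loudly", {
  spec <- cohort_spec(n_patients = 20, prevalence = 0.5,
                      mixture = c(MEN = 1), seed = 1)
  expect_error(generate_cohort(spec, the_rules, the_catalog, the_lexicon,
                               the_registry),
               "no packaged rule: MEN")
})

test_that("noise-free cohorts are recovered perfectly end to end", {
  cohort <- generate_cohort(cohort_spec(n_patients = 200, prevalence = 0.05,
                                        dropout = 0, note_noise = 0, seed = 17),
                            the_rules, the_catalog, the_lexicon, the_registry)
  cases <- build_cases(cohort$records, the_lexicon, the_registry)
  w <- run_surveillance(cases, the_rules)
  m <- hai_metrics(score_episode_level(w, cohort$gold))
  expect_equal(unname(m["sen"]), 1)
  expect_equal(unname(m["spe"]), 1)
})

test_that("factor dropout degrades sensitivity monotonically, not specificity", {
  sens <- vapply(c(0, 0.2, 0.5), function(q) {
    cohort <- generate_cohort(cohort_spec(n_patients = 150, prevalence = 0.2,
                                          dropout = q, seed = 29),
                              the_rules, the_catalog, the_lexicon, the_registry)
    cases <- build_cases(cohort$records, the_lexicon, the_registry)
    m <- hai_metrics(score_episode_level(run_surveillance(cases, the_rules),
                                         cohort$gold))
    expect_equal(unname(m["spe"]), 1)
    unname(m["sen"])
  }, 0)
  expect_equal(sens[1], 1)
  expect_true(all(diff(sens) <= 0))
  expect_lt(sens[3], sens[1])
})

test_that("diagnosis frequencies follow the long-tail mixture", {
  counts <- c(LRI = 0, UTI = 0, ST = 0, PCI = 0)
  for (seed in c(41, 42)) {
    cohort <- generate_cohort(cohort_spec(n_patients = 2500, prevalence = 0.5,
                                          seed = seed),
                              the_rules, the_catalog, the_lexicon, the_registry)
    tab <- table(cohort$gold$diagnosis_code[cohort$gold$infected == 1])
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
  }
  weights <- c(LRI = 0.50, UTI = 0.25, ST = 0.15, PCI = 0.10)
  p <- stats::chisq.test(counts, p = weights)$p.value
  expect_gt(p, 0.01)
  # the observed ranking matches the long tail
  expect_equal(names(sort(counts, decreasing = TRUE)),
               c("LRI", "UTI", "ST", "PCI"))
})

test_that("the infected fraction is binomially consistent with prevalence", {
  cohort <- generate_cohort(cohort_spec(n_patients = 2000, prevalence = 0.05,
                                        seed = 53),
                            the_rules, the_catalog, the_lexicon, the_registry)
  k <- sum(cohort$gold$infected)
  p <- stats::binom.test(k, 2000, p = 0.05)$p.value
  expect_gt(p, 0.01)
})
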