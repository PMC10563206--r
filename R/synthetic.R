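# Synthetic inpatient cohort generator.
#
# Emulates the shape of a real surveillance cohort - many short uninfected
# episodes, a low HAI prevalence, and a long-tail mixture of infection
# diagnoses dominated by lower respiratory tract infection, then urinary
# tract infection, then soft tissue infection - while guaranteeing that every
# injected infection is realized in the records so that one packaged rule's
# conditions are satisfiable by factor extraction at onset. Uninfected
# episodes carry physiologic baselines (temperature 36-37.2 degC, normal
# labs, benign notes). The generator is entirely synthetic plumbing: it
# emulates no real hospital's physiology, only the record-level structure
# the pipeline consumes.

#' Cohort specification
#'
#' @param n_patients number of episodes (one episode per patient).
#' @param start_date,end_date admission date range.
#' @param prevalence probability an episode acquires an HAI, in `[0, 1]`.
#' @param mixture named weights over infection diagnosis codes; must sum to
#'   1 and every positively weighted diagnosis must have at least one
#'   packaged rule. The default long tail puts LRI heaviest, then UTI, then
#'   ST.
#' @param mean_los mean length of stay in calendar days (admission and
#'   discharge day both count).
#' @param dropout factor-dropout rate q in `[0, 1]`: the probability that an
#'   injected infection's supporting record for one condition is omitted,
#'   degrading sensitivity.
#' @param note_noise probability that a clean episode's notes contain a
#'   lexicon keyword, in `[0, 1]`.
#' @param seed integer RNG seed; the cohort is a deterministic function of
#'   the spec.
#' @return Object of class `hai_cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 500,
                        start_date = "2020-01-01", end_date = "2020-12-31",
                        prevalence = 0.03,
                        mixture = c(LRI = 0.50, UTI = 0.25, ST = 0.15, PCI = 0.10),
                        mean_los = 6, dropout = 0, note_noise = 0, seed = 1) {
  for (p in c(prevalence = prevalence, dropout = dropout, note_noise = note_noise)) {
    if (!is.numeric(p) || p < 0 || p > 1) {
      stop_hai("prevalence, dropout and note_noise must lie in [0, 1]")
    }
  }
  if (abs(sum(mixture) - 1) > 1e-8) stop_hai("mixture weights must sum to 1")
  if (any(mixture < 0)) stop_hai("mixture weights must be >= 0")
  if (is.null(names(mixture)) || any(!nzchar(names(mixture)))) {
    stop_hai("mixture weights must be named by diagnosis code")
  }
  if (mean_los < 2) stop_hai("mean_los must be >= 2")
  structure(list(n_patients = as.integer(n_patients),
                 start_date = hai_date(start_date),
                 end_date = hai_date(end_date),
                 prevalence = prevalence, mixture = mixture,
                 mean_los = mean_los, dropout = dropout,
                 note_noise = note_noise, seed = as.integer(seed)),
            class = "hai_cohort_spec")
}

# specimen to draw for each microbiology flag factor (inverse of MICRO_MAP)
micro_specimen_for <- function(factor_id) {
  hit <- names(MICRO_MAP)[MICRO_MAP == factor_id]
  if (length(hit) == 0) return(NULL)
  hit[1]
}

ORGANISMS <- c("Escherichia coli", "Klebsiella pneumoniae",
               "Pseudomonas aeruginosa", "Staphylococcus aureus",
               "Acinetobacter baumannii")

# a numeric value satisfying the condition's comparison
satisfying_value <- function(cond, bump) {
  op <- cond$operator
  rhs <- cond$operand
  switch(op,
         eq = rhs, ne = rhs + bump, ge = rhs + bump, gt = rhs + bump,
         le = rhs - bump, lt = rhs - bump,
         in_range = min(rhs[1] + bump, (rhs[1] + rhs[2]) / 2),
         contains_flag = 1,
         stop_hai("no satisfying value for operator %s", op))
}

# record-level realization of one rule condition at the onset day; returns a
# list of rows keyed by record table (possibly plus an admissions override),
# or NULL for inherent conditions that need no record
realize_condition <- function(cond, adm, onset_day, lexicon, registry) {
  fid <- cond$factor_id
  eid <- adm$episode_id
  t_onset <- hai_time(onset_day) + 10 * 3600            # 10:00 on onset day

  if (fid == "hospital_days") {
    hd <- hospital_days(adm$admission_datetime, onset_day)
    probe <- new_case(adm$patient_id, eid, onset_day,
                      list(PS = list(hospital_days = fv(registry, "hospital_days", hd))))
    if (!evaluate_condition(cond, probe)) {
      stop_hai("onset on hospital day %d cannot satisfy the rule's hospital_days condition", hd)
    }
    return(NULL)
  }
  if (fid == "age") {
    target <- min(95, max(0, satisfying_value(cond, 5)))
    return(list(admissions = list(age = as.integer(target))))
  }
  if (fid == "body_temperature_max") {
    val <- round(satisfying_value(cond, 0.6), 1)
    return(list(vitals = data.frame(episode_id = eid, datetime = t_onset,
                                    measure_id = "body_temperature",
                                    value = val, stringsAsFactors = FALSE)))
  }
  if (fid == "defecation_frequency") {
    val <- as.integer(satisfying_value(cond, 2))
    return(list(vitals = data.frame(episode_id = eid, datetime = t_onset,
                                    measure_id = "defecation_frequency",
                                    value = val, stringsAsFactors = FALSE)))
  }
  lab_ids <- vapply(names(LAB_MAP), function(tid) LAB_MAP[[tid]]$value %||% "", "")
  abn_ids <- vapply(names(LAB_MAP), function(tid) LAB_MAP[[tid]]$abnormal %||% "", "")
  pres_ids <- vapply(names(LAB_MAP), function(tid) LAB_MAP[[tid]]$presence %||% "", "")
  lab_row <- function(tid, value, abnormal) {
    list(labs = data.frame(episode_id = eid, datetime = t_onset, test_id = tid,
                           value = value, unit = "", abnormal_flag = abnormal,
                           stringsAsFactors = FALSE))
  }
  if (fid %in% lab_ids) {                                # numeric lab condition
    tid <- names(LAB_MAP)[match(fid, lab_ids)]
    bump <- if (fid == "pleural_wbc") 500 else if (fid == "urine_wbc") 40 else 2
    return(lab_row(tid, satisfying_value(cond, bump), 1))
  }
  if (fid %in% abn_ids) {                                # abnormal-flag condition
    tid <- names(LAB_MAP)[match(fid, abn_ids)]
    defaults <- c(URINE_WBC = 50, URINE_BACT = 1, PLEURAL_WBC = 1500)
    return(lab_row(tid, unname(defaults[tid]) %||% 1, 1))
  }
  if (fid %in% pres_ids) {                               # presence flag (has_*_lab)
    tid <- names(LAB_MAP)[match(fid, pres_ids)]
    return(lab_row(tid, 2.5, 1))
  }
  specimen <- micro_specimen_for(fid)
  if (!is.null(specimen)) {
    return(list(micro = data.frame(episode_id = eid, datetime = t_onset,
                                   specimen = specimen,
                                   organism = sample(ORGANISMS, 1),
                                   positive_flag = 1, stringsAsFactors = FALSE)))
  }
  lex_ids <- vapply(lexicon$entries, `[[`, "", "factor_id")
  if (fid %in% lex_ids) {
    entry <- lexicon$entries[[match(fid, lex_ids)]]
    return(list(notes = data.frame(
      episode_id = eid, datetime = t_onset, note_type = entry$note_type,
      text = sprintf("Patient presents with %s today.", entry$keywords[1]),
      stringsAsFactors = FALSE)))
  }
  if (fid %in% c("urinary_catheter", "ventilator")) {
    return(list(orders = data.frame(episode_id = eid,
                                    start = hai_time(adm$admission_datetime),
                                    end = hai_time(adm$discharge_datetime),
                                    order_type = fid, stringsAsFactors = FALSE)))
  }
  if (fid == "recent_operation") {
    return(list(operations = data.frame(episode_id = eid,
                                        datetime = t_onset - 86400,
                                        procedure_name = "exploratory procedure",
                                        stringsAsFactors = FALSE)))
  }
  stop_hai("no record-level realization defined for factor '%s'", fid)
}

# realize all (kept) conditions of one rule; returns rows per table plus
# admission overrides
infection_rows <- function(rule, adm, onset_day, lexicon, registry, keep) {
  rows <- list()
  overrides <- list()
  for (i in seq_along(rule$conditions)) {
    cond <- rule$conditions[[i]]
    piece <- realize_condition(cond, adm, onset_day, lexicon, registry)
    if (is.null(piece)) next                       # inherent, nothing to drop
    if (!keep[i]) next                             # factor dropout
    if (!is.null(piece$admissions)) {
      overrides <- modifyList(overrides, piece$admissions)
      piece$admissions <- NULL
    }
    for (nm in names(piece)) rows[[nm]] <- c(rows[[nm]] %||% list(), list(piece[[nm]]))
  }
  list(rows = rows, overrides = overrides)
}

#' Inject a rule-consistent infection into a record set
#'
#' Appends (or edits) records for one episode so that every condition of
#' `rule` is satisfiable by factor extraction on the onset day: a
#' temperature reading inside the rule's range, a laboratory row exceeding
#' its cutoff, a positive culture, a note containing a lexicon keyword for
#' the required flag, an order spanning the onset, and so on. The onset must
#' lie within the stay and more than 48 hours after admission.
#'
#' @param records a `hai_records`.
#' @param episode_id episode to infect.
#' @param diagnosis_code the infection diagnosis; must be the rule's target.
#' @param rule the knowledge rule to realize.
#' @param onset onset day (`Date`).
#' @param lexicon,registry lexicon and registry used for realization.
#' @return The modified `hai_records`.
#' @export
inject_infection <- function(records, episode_id, diagnosis_code, rule, onset,
                             lexicon = load_lexicon(),
                             registry = load_registry()) {
  stopifnot(inherits(records, "hai_records"))
  if (rule$diagnosis_code != diagnosis_code) {
    stop_hai("rule %s targets %s, not %s", rule$rule_id, rule$diagnosis_code,
             diagnosis_code)
  }
  i <- match(episode_id, records$admissions$episode_id)
  if (is.na(i)) stop_hai("unknown episode: %s", episode_id)
  adm <- records$admissions[i, , drop = FALSE]
  onset <- hai_date(onset)
  if (onset > hai_date(adm$discharge_datetime)) {
    stop_hai("onset %s after discharge", fmt_date(onset))
  }
  hrs <- as.numeric(difftime(hai_time(onset) + 86400,
                             hai_time(adm$admission_datetime), units = "hours"))
  if (hrs <= 48) {
    stop_hai("onset %s is within 48 h of admission (not hospital-acquired)",
             fmt_date(onset))
  }
  real <- infection_rows(rule, adm, onset, lexicon, registry,
                         keep = rep(TRUE, length(rule$conditions)))
  for (nm in names(real$overrides)) {
    records$admissions[i, nm] <- real$overrides[[nm]]
  }
  for (nm in names(real$rows)) {
    records[[nm]] <- rbind(records[[nm]], do.call(rbind, real$rows[[nm]]))
  }
  records
}

#' Generate a synthetic cohort with gold labels
#'
#' Deterministic given the spec's seed (a single RNG stream; the caller's
#' RNG state is restored afterwards). Each infected episode receives an
#' onset more than 48 hours after admission and records satisfying every
#' condition of one randomly chosen packaged rule for its diagnosis, minus
#' conditions removed by factor dropout; uninfected episodes carry
#' physiologic baselines plus optional note noise.
#'
#' @param spec a `hai_cohort_spec`.
#' @param rule_base rules available for injection (default: packaged base).
#' @param catalog,lexicon,registry supporting configuration.
#' @return Object of class `hai_cohort`: list with `records`
#'   (`hai_records`), `gold` (gold-label `data.frame`) and `spec`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_patients = 50, seed = 7))
#' table(cohort$gold$infected)
#' @export
generate_cohort <- function(spec, rule_base = load_rule_base(),
                            catalog = load_catalog(),
                            lexicon = load_lexicon(),
                            registry = load_registry()) {
  stopifnot(inherits(spec, "hai_cohort_spec"))
  mix <- spec$mixture[spec$mixture > 0]
  rules_for <- lapply(names(mix), function(d) {
    Filter(function(r) r$diagnosis_code == d, rule_base$rules)
  })
  names(rules_for) <- names(mix)
  empty <- names(mix)[vapply(rules_for, length, 0L) == 0]
  if (length(empty)) {
    stop_hai("mixture requests diagnosis with no packaged rule: %s",
             paste(empty, collapse = ", "))
  }

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)

  n <- spec$n_patients
  days_pool <- seq(spec$start_date, spec$end_date, by = "day")
  adm_day <- sample(days_pool, n, replace = TRUE)
  adm_time <- hai_time(adm_day) + sample(6:20, n, TRUE) * 3600 +
    sample(0:59, n, TRUE) * 60
  infected <- rbinom(n, 1, spec$prevalence)
  los <- 1 + rpois(n, max(0, spec$mean_los - 1))
  los[infected == 1] <- pmax(los[infected == 1], 5)
  los <- pmax(los, 2)
  dis_day <- adm_day + (los - 1)
  admissions <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    episode_id = sprintf("E%05d", seq_len(n)),
    admission_datetime = adm_time,
    discharge_datetime = hai_time(dis_day) + 11 * 3600,
    age = sample(18:95, n, TRUE),
    gender = rbinom(n, 1, 0.5),
    department = sample(c("internal medicine", "surgery", "ICU",
                          "respiratory", "urology"), n, TRUE),
    stringsAsFactors = FALSE)

  # physiologic baselines, vectorized over episode-days
  day_idx <- sequence(los) - 1
  ep_rep <- rep(seq_len(n), los)
  day_vec <- adm_day[ep_rep] + day_idx
  t0 <- hai_time(day_vec)
  n_days <- length(day_vec)
  vitals <- data.frame(
    episode_id = rep(admissions$episode_id[ep_rep], 3),
    datetime = c(t0 + 8 * 3600, t0 + 16 * 3600, t0 + 20 * 3600),
    measure_id = rep(c("body_temperature", "body_temperature",
                       "defecation_frequency"), each = n_days),
    value = c(round(runif(n_days, 36, 37.2), 1),
              round(runif(n_days, 36, 37.2), 1),
              sample(0:3, n_days, TRUE)),
    stringsAsFactors = FALSE)

  has_crp <- which(rbinom(n, 1, 0.4) == 1)
  labs <- data.frame(
    episode_id = admissions$episode_id[has_crp],
    datetime = adm_time[has_crp] + 3600,
    test_id = "CRP", value = round(runif(length(has_crp), 1, 8), 1),
    unit = "mg/L", abnormal_flag = 0, stringsAsFactors = FALSE)

  notes <- data.frame(
    episode_id = admissions$episode_id,
    datetime = adm_time + 1800,
    note_type = "progress",
    text = "Patient admitted for evaluation. Resting comfortably.",
    stringsAsFactors = FALSE)

  kw_pool <- do.call(rbind, lapply(lexicon$entries, function(e) {
    data.frame(kw = e$keywords, type = e$note_type, stringsAsFactors = FALSE)
  }))
  noisy <- which(infected == 0 & runif(n) < spec$note_noise)
  if (length(noisy)) {
    pick <- sample(nrow(kw_pool), length(noisy), replace = TRUE)
    notes <- rbind(notes, data.frame(
      episode_id = admissions$episode_id[noisy],
      datetime = hai_time(adm_day[noisy] + 1) + 9 * 3600,
      note_type = kw_pool$type[pick],
      text = sprintf("Patient presents with %s today.", kw_pool$kw[pick]),
      stringsAsFactors = FALSE))
  }

  extra <- list(vitals = list(), labs = list(), micro = list(),
                notes = list(), operations = list(), orders = list())
  gold_rows <- vector("list", n)
  inf_idx <- which(infected == 1)
  diag_pick <- if (length(inf_idx)) {
    sample(names(mix), length(inf_idx), replace = TRUE, prob = mix)
  } else character()
  for (j in seq_along(inf_idx)) {
    i <- inf_idx[j]
    d <- diag_pick[j]
    cand <- rules_for[[d]]
    rule <- cand[[sample.int(length(cand), 1)]]
    offsets <- 3:(los[i] - 1)
    onset_day <- adm_day[i] + offsets[sample.int(length(offsets), 1)]
    keep <- runif(length(rule$conditions)) >= spec$dropout
    real <- infection_rows(rule, admissions[i, , drop = FALSE], onset_day,
                           lexicon, registry, keep)
    for (nm in names(real$overrides)) {
      admissions[i, nm] <- real$overrides[[nm]]
    }
    for (nm in names(real$rows)) {
      extra[[nm]] <- c(extra[[nm]], real$rows[[nm]])
    }
    gold_rows[[i]] <- data.frame(
      patient_id = admissions$patient_id[i], episode_id = admissions$episode_id[i],
      infected = 1L, diagnosis_code = d, site_code = site_of(catalog, d),
      onset_datetime = hai_time(onset_day) + 12 * 3600,
      report_month = month_key(onset_day), stringsAsFactors = FALSE)
  }
  for (i in which(infected == 0)) {
    gold_rows[[i]] <- data.frame(
      patient_id = admissions$patient_id[i], episode_id = admissions$episode_id[i],
      infected = 0L, diagnosis_code = NA_character_, site_code = NA_character_,
      onset_datetime = hai_time(NA), report_month = month_key(adm_day[i]),
      stringsAsFactors = FALSE)
  }
  gold <- do.call(rbind, gold_rows)

  bind_extra <- function(base, pieces) {
    if (length(pieces) == 0) return(base)
    rbind(base, do.call(rbind, pieces))
  }
  records <- new_records(
    admissions = admissions,
    vitals = bind_extra(vitals, extra$vitals),
    labs = bind_extra(labs, extra$labs),
    micro = if (length(extra$micro)) do.call(rbind, extra$micro) else NULL,
    notes = bind_extra(notes, extra$notes),
    operations = if (length(extra$operations)) do.call(rbind, extra$operations) else NULL,
    orders = if (length(extra$orders)) do.call(rbind, extra$orders) else NULL)
  structure(list(records = records, gold = gold, spec = spec),
            class = "hai_cohort")
}

#' @export
print.hai_cohort <- function(x, ...) {
  cat(sprintf("<hai_cohort> %d episodes, %d infected (seed %d)\n",
              nrow(x$gold), sum(x$gold$infected), x$spec$seed))
  invisible(x)
}
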