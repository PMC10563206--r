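# Forward inference engine and warning post-processing.
#
# Pipeline, in order: match every rule against every case (a rule fires iff
# all its conditions hold); keep the best-probability rule per diagnosis;
# classify onset against the 48-hour rule; gate on per-diagnosis probability
# thresholds; suppress repeats within the repeat-infection timeframe (RTI).
# RTI runs last so that suppressed or rejected warnings never consume the
# window; every fired rule leaves the pipeline with an explicit status, so
# each exclusion is auditable.

WARNING_STATUSES <- c("alerted", "suppressed_rti", "below_threshold",
                      "community_acquired")

#' Engine configuration
#'
#' @param rti_days repeat-infection timeframe in days (default 14): a new
#'   warning for the same patient and infection site within this window of a
#'   previous alert is suppressed as a recurrence.
#' @param onset_cutoff_hours hospital-onset cutoff (default 48): an infection
#'   whose onset is strictly more than this many hours after admission is
#'   classified hospital-acquired, otherwise community-acquired.
#' @param thresholds named numeric vector/list, diagnosis code to minimum
#'   probability in `[0, 1]`; unconfigured diagnoses default to 0 (always
#'   pass).
#' @param tie_break tie-break among equal-probability rules for one
#'   diagnosis; only `"lowest_rule_id"` is defined.
#' @param scenario rule-base scenario, see [filter_by_source()].
#' @param rti_key whether the RTI window is keyed by infection `"site"`
#'   (default) or by `"diagnosis"`.
#' @param missing_fires if `TRUE`, a condition on a missing factor evaluates
#'   true instead of false. Default `FALSE` (a rule cannot fire on unknown
#'   data); exposed because the choice trades sensitivity for false alarms.
#' @param confirmed optional data.frame (`episode_id`, `site_code`) of
#'   infections already confirmed by physicians; warnings matching a
#'   confirmed episode+site are suppressed regardless of the RTI window, so
#'   physicians are not re-alerted about patients they have already
#'   identified.
#' @return Object of class `hai_engine_config`.
#' @export
engine_config <- function(rti_days = 14, onset_cutoff_hours = 48,
                          thresholds = list(),
                          tie_break = "lowest_rule_id",
                          scenario = c("guideline_plus_expert", "guideline_only"),
                          rti_key = c("site", "diagnosis"),
                          missing_fires = FALSE,
                          confirmed = NULL) {
  scenario <- match.arg(scenario)
  rti_key <- match.arg(rti_key)
  if (!identical(tie_break, "lowest_rule_id")) {
    stop_hai("unknown tie_break: %s", tie_break)
  }
  if (!is.numeric(rti_days) || rti_days < 0) stop_hai("rti_days must be >= 0")
  thr <- unlist(thresholds)
  if (length(thr) && (any(thr < 0) || any(thr > 1))) {
    stop_hai("thresholds must lie in [0, 1]")
  }
  structure(list(rti_days = rti_days,
                 onset_cutoff_hours = onset_cutoff_hours,
                 thresholds = as.list(thr %||% list()),
                 tie_break = tie_break, scenario = scenario,
                 rti_key = rti_key, missing_fires = missing_fires,
                 confirmed = confirmed),
            class = "hai_engine_config")
}

#' Evaluate a single rule condition against a case
#'
#' Standard comparison semantics; `in_range` is the closed-open interval
#' `[low, high)`; `contains_flag` tests a binary factor for 1. A condition on
#' a factor absent from the case evaluates false (a rule cannot fire on
#' unknown data) unless the engine is configured otherwise.
#'
#' @param cond a condition (`factor_id`, `operator`, `operand`).
#' @param case a `hai_case`.
#' @param missing_fires see [engine_config()].
#' @return Logical scalar.
#' @export
evaluate_condition <- function(cond, case, missing_fires = FALSE) {
  v <- case_factor(case, cond$factor_id)
  if (is.null(v) || (length(v) == 1 && is.na(v))) return(isTRUE(missing_fires))
  op <- cond$operator
  rhs <- cond$operand
  if (inherits(v, "Date") || inherits(v, "POSIXct")) {
    v <- as.numeric(hai_time(v))
    rhs <- as.numeric(hai_time(rhs))
  }
  switch(op,
         eq = isTRUE(v == rhs),
         ne = isTRUE(v != rhs),
         lt = isTRUE(v < rhs),
         le = isTRUE(v <= rhs),
         gt = isTRUE(v > rhs),
         ge = isTRUE(v >= rhs),
         in_range = isTRUE(v >= rhs[1] && v < rhs[2]),
         contains_flag = isTRUE(v == 1),
         stop_hai("unknown operator: %s", op))
}

empty_fired <- function() {
  data.frame(rule_id = character(), diagnosis_code = character(),
             site_code = character(), probability = numeric(),
             patient_id = character(), episode_id = character(),
             as_of_date = as.Date(character()), stringsAsFactors = FALSE)
}

#' Match all rules against one case
#'
#' A rule fires iff every one of its conditions evaluates true on the case.
#' Output rows are ordered by rule id, so matching is deterministic.
#'
#' @param case a `hai_case`.
#' @param rule_base a `hai_rulebase` (or plain list of rules).
#' @param config a `hai_engine_config`.
#' @param confidence optional `hai_confidence_state`; when given, the fired
#'   probability is the rule's current confidence rather than its packaged
#'   initial value.
#' @return `data.frame` of fired rules: `rule_id`, `diagnosis_code`,
#'   `site_code`, `probability`, `patient_id`, `episode_id`, `as_of_date`.
#' @export
match_rules <- function(case, rule_base, config = engine_config(),
                        confidence = NULL) {
  rules <- if (inherits(rule_base, "hai_rulebase")) rule_base$rules else rule_base
  rows <- lapply(rules, function(rule) {
    for (cond in rule$conditions) {
      if (!evaluate_condition(cond, case, config$missing_fires)) return(NULL)
    }
    pr <- rule$probability
    if (!is.null(confidence)) {
      pr <- confidence_of(confidence, rule$rule_id) %||% pr
    }
    data.frame(rule_id = rule$rule_id, diagnosis_code = rule$diagnosis_code,
               site_code = rule$site_code, probability = pr,
               patient_id = case$patient_id, episode_id = case$episode_id,
               as_of_date = case$as_of_date, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) return(empty_fired())
  out <- do.call(rbind, rows)
  out <- out[order(out$rule_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep the best rule per diagnosis
#'
#' When several rules fire for the same infection diagnosis on one case,
#' only the rule with the highest infection probability is kept; exact ties
#' are broken by the lowest rule id.
#'
#' @param fired `data.frame` of fired rules from [match_rules()].
#' @return Subset of `fired` with at most one row per diagnosis code.
#' @export
select_per_diagnosis <- function(fired) {
  if (nrow(fired) == 0) return(fired)
  ord <- order(fired$diagnosis_code, -fired$probability, fired$rule_id)
  out <- fired[ord, , drop = FALSE]
  out <- out[!duplicated(out$diagnosis_code), , drop = FALSE]
  out <- out[order(out$rule_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify infection onset as hospital- or community-acquired
#'
#' An infection whose onset falls strictly more than `onset_cutoff_hours`
#' (default 48) after admission is hospital-acquired; onsets at or below the
#' cutoff are community-acquired. For a daily surveillance case the onset
#' time is taken as the end of the surveillance day (`as_of_date` + 1 day,
#' 00:00): the classification asks whether the whole day lies within the
#' window that can still be attributed to admission.
#'
#' @param case a `hai_case` (PS must carry `admission_datetime`), or an
#'   onset `POSIXct` when `admission` is given directly.
#' @param config a `hai_engine_config`.
#' @param admission optional admission datetime overriding the case's PS
#'   group (used with a raw onset time).
#' @return `"hospital_acquired"` or `"community_acquired"`.
#' @export
classify_onset <- function(case, config = engine_config(), admission = NULL) {
  if (inherits(case, "hai_case")) {
    adm <- case_factor(case, "admission_datetime")
    if (is.null(adm)) stop_hai("case %s has no PS.admission_datetime", case$episode_id)
    onset <- hai_time(case$as_of_date) + 86400
  } else {
    if (is.null(admission)) stop_hai("admission datetime required")
    adm <- admission
    onset <- hai_time(case)
  }
  hours <- as.numeric(difftime(onset, hai_time(adm), units = "hours"))
  if (hours > config$onset_cutoff_hours) "hospital_acquired" else "community_acquired"
}

#' Gate warnings on per-diagnosis probability thresholds
#'
#' A warning whose probability is strictly below the configured threshold
#' for its diagnosis is marked `below_threshold` and not sent; a diagnosis
#' with no configured threshold defaults to 0 and always passes. Only rows
#' currently `alerted` are re-examined.
#'
#' @param warnings warning `data.frame` with columns `diagnosis_code`,
#'   `probability`, `status`.
#' @param thresholds named list/vector, diagnosis code to threshold.
#' @return `warnings` with updated `status`.
#' @export
apply_thresholds <- function(warnings, thresholds = list()) {
  if (nrow(warnings) == 0) return(warnings)
  thr <- vapply(warnings$diagnosis_code,
                function(d) as.numeric(thresholds[[d]] %||% 0), 0)
  reject <- warnings$status == "alerted" & warnings$probability < thr
  warnings$status[reject] <- "below_threshold"
  warnings
}

#' Suppress repeat warnings within the RTI window
#'
#' Decisions are made in time order per patient: a warning is suppressed iff
#' the same patient already has an earlier *alerted* warning for the same
#' infection site (or diagnosis, per `config$rti_key`) strictly less than
#' `rti_days` days before it. Suppressed warnings do not start or extend a
#' window. Warnings matching a physician-confirmed episode+site (see
#' [engine_config()]) are suppressed outright.
#'
#' @param warnings warning `data.frame` sorted by (patient, infection_time);
#'   must carry `patient_id`, `infection_time`, `site_code`,
#'   `diagnosis_code`, `status`.
#' @param config a `hai_engine_config` (or a number of days).
#' @return `warnings` with updated `status`.
#' @export
apply_rti <- function(warnings, config = engine_config()) {
  if (is.numeric(config)) config <- engine_config(rti_days = config)
  if (nrow(warnings) == 0) return(warnings)
  ord <- order(warnings$patient_id, warnings$infection_time,
               warnings$site_code, warnings$diagnosis_code, warnings$rule_id)
  warnings <- warnings[ord, , drop = FALSE]
  confirmed_key <- character()
  if (!is.null(config$confirmed) && nrow(config$confirmed) > 0) {
    confirmed_key <- paste(config$confirmed$episode_id, config$confirmed$site_code)
  }
  last_alert <- list()   # per patient+key: time of last alerted warning
  for (i in seq_len(nrow(warnings))) {
    if (warnings$status[i] != "alerted") next
    if (paste(warnings$episode_id[i], warnings$site_code[i]) %in% confirmed_key) {
      warnings$status[i] <- "suppressed_rti"
      next
    }
    keyv <- if (config$rti_key == "site") warnings$site_code[i] else
      warnings$diagnosis_code[i]
    k <- paste(warnings$patient_id[i], keyv)
    prev <- last_alert[[k]]
    if (!is.null(prev) &&
        as.numeric(warnings$infection_time[i] - prev) < config$rti_days) {
      warnings$status[i] <- "suppressed_rti"
    } else {
      last_alert[[k]] <- warnings$infection_time[i]
    }
  }
  rownames(warnings) <- NULL
  warnings
}

empty_warnings <- function() {
  data.frame(patient_id = character(), episode_id = character(),
             infection_time = as.Date(character()), site_code = character(),
             diagnosis_code = character(), probability = numeric(),
             rule_id = character(), status = character(),
             stringsAsFactors = FALSE)
}

#' Run the full surveillance pipeline over a set of cases
#'
#' Composes, in order: rule matching, best-rule-per-diagnosis selection,
#' hospital-onset classification, per-diagnosis threshold gating, and
#' repeat-infection suppression. Every fired rule is accounted for in the
#' output with an explicit status; nothing is silently dropped. The result
#' is deterministic for fixed inputs. Per-case errors (e.g. a case without an
#' admission time) are collected and reported in the `issues` attribute while
#' the remaining cases are processed.
#'
#' @param cases list of `hai_case` objects.
#' @param rule_base a `hai_rulebase`; the configured scenario filter is
#'   applied first.
#' @param config a `hai_engine_config`.
#' @param confidence optional `hai_confidence_state` supplying current rule
#'   confidences.
#' @return Warning `data.frame`: `patient_id`, `episode_id`,
#'   `infection_time` (the case day), `site_code`, `diagnosis_code`,
#'   `probability`, `rule_id`, `status`; attributes `issues` and `counts`
#'   (per-stage audit counts).
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_spec(n_patients = 60, seed = 1))
#' cases <- build_cases(cohort$records)
#' w <- run_surveillance(cases, load_rule_base())
#' table(w$status)
#' }
#' @export
run_surveillance <- function(cases, rule_base, config = engine_config(),
                             confidence = NULL) {
  rb <- filter_by_source(rule_base, config$scenario)
  issues <- issue_df()
  per_case <- lapply(cases, function(case) {
    fired <- tryCatch(match_rules(case, rb, config, confidence),
                      error = function(e) e)
    if (inherits(fired, "error")) {
      return(list(warn = NULL, issue = issue_df(case$episode_id, conditionMessage(fired))))
    }
    fired <- select_per_diagnosis(fired)
    if (nrow(fired) == 0) return(list(warn = NULL, issue = NULL))
    onset <- tryCatch(classify_onset(case, config), error = function(e) e)
    if (inherits(onset, "error")) {
      return(list(warn = NULL, issue = issue_df(case$episode_id, conditionMessage(onset))))
    }
    warn <- data.frame(patient_id = fired$patient_id,
                       episode_id = fired$episode_id,
                       infection_time = fired$as_of_date,
                       site_code = fired$site_code,
                       diagnosis_code = fired$diagnosis_code,
                       probability = fired$probability,
                       rule_id = fired$rule_id,
                       status = if (onset == "hospital_acquired") "alerted"
                                else "community_acquired",
                       stringsAsFactors = FALSE)
    list(warn = warn, issue = NULL)
  })
  warnings <- do.call(rbind, c(list(empty_warnings()),
                               Filter(Negate(is.null),
                                      lapply(per_case, `[[`, "warn"))))
  issues <- do.call(bind_issues, c(list(issues),
                                   Filter(Negate(is.null),
                                          lapply(per_case, `[[`, "issue"))))
  n_fired <- nrow(warnings)
  warnings <- apply_thresholds(warnings, config$thresholds)
  warnings <- apply_rti(warnings, config)
  rownames(warnings) <- NULL
  attr(warnings, "issues") <- issues
  attr(warnings, "counts") <- c(cases = length(cases), fired = n_fired,
                                table(factor(warnings$status,
                                             levels = WARNING_STATUSES)))
  warnings
}

#' Write / read warnings
#'
#' Writers for the warning table: CSV (one row per warning, all fields
#' including status) and JSON lines (one object per warning).
#'
#' @param warnings warning `data.frame` from [run_surveillance()].
#' @param path output (input) file path; `.jsonl` selects JSON lines.
#' @return `write_warnings()` returns `path` invisibly; `read_warnings()`
#'   the warning `data.frame`.
#' @export
write_warnings <- function(warnings, path) {
  out <- warnings
  out$infection_time <- fmt_date(out$infection_time)
  if (grepl("\\.jsonl$", path)) {
    lines <- vapply(seq_len(nrow(out)), function(i) {
      as.character(jsonlite::toJSON(as.list(out[i, ]), auto_unbox = TRUE,
                                    digits = NA))
    }, "")
    writeLines(lines, path)
  } else {
    write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_warnings
#' @export
read_warnings <- function(path) {
  if (grepl("\\.jsonl$", path)) {
    rows <- lapply(readLines(path), function(l) {
      as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  } else {
    out <- read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(rule_id = "character"))
  }
  out$infection_time <- hai_date(out$infection_time)
  out
}
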