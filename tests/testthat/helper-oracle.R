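# Independent brute-force oracle for the inference engine: every rule is
# evaluated on every case with plain loops and literal comparison logic,
# then post-processed with straightforward passes. Shares no code with the
# engine beyond the data structures.

oracle_factor <- function(case, fid) {
  for (g in case$groups) {
    if (fid %in% names(g)) return(g[[fid]]$value)
  }
  NULL
}

oracle_condition <- function(cond, case) {
  v <- oracle_factor(case, cond$factor_id)
  if (is.null(v)) return(FALSE)
  if (inherits(v, "POSIXct") || inherits(v, "Date")) {
    v <- as.numeric(as.POSIXct(v, tz = "UTC"))
  }
  rhs <- cond$operand
  if (cond$operator == "eq") return(v == rhs)
  if (cond$operator == "ne") return(v != rhs)
  if (cond$operator == "lt") return(v < rhs)
  if (cond$operator == "le") return(v <= rhs)
  if (cond$operator == "gt") return(v > rhs)
  if (cond$operator == "ge") return(v >= rhs)
  if (cond$operator == "in_range") return(v >= rhs[1] && v < rhs[2])
  if (cond$operator == "contains_flag") return(v == 1)
  stop("oracle: unknown operator ", cond$operator)
}

# full naive pipeline: fire -> best per diagnosis -> onset -> threshold -> RTI
oracle_pipeline <- function(cases, rule_base, config) {
  rules <- rule_base$rules
  if (config$scenario == "guideline_only") {
    rules <- Filter(function(r) r$source == "guideline", rules)
  }
  rows <- list()
  for (case in cases) {
    fired <- list()
    for (rule in rules) {
      all_ok <- TRUE
      for (cond in rule$conditions) {
        if (!oracle_condition(cond, case)) { all_ok <- FALSE; break }
      }
      if (all_ok) fired[[length(fired) + 1]] <- rule
    }
    if (length(fired) == 0) next
    # best rule per diagnosis, ties to the lowest rule id
    by_diag <- split(fired, vapply(fired, function(r) r$diagnosis_code, ""))
    for (d in names(by_diag)) {
      cand <- by_diag[[d]]
      probs <- vapply(cand, function(r) r$probability, 0)
      best <- cand[probs == max(probs)]
      ids <- vapply(best, function(r) r$rule_id, "")
      rule <- best[[which.min(match(ids, sort(ids)))]]
      adm <- oracle_factor(case, "admission_datetime")
      hrs <- as.numeric(difftime(hai_ts(case$as_of_date) + 86400,
                                 as.POSIXct(adm, tz = "UTC"), units = "hours"))
      status <- if (hrs > config$onset_cutoff_hours) "alerted"
                else "community_acquired"
      if (status == "alerted") {
        thr <- config$thresholds[[rule$diagnosis_code]]
        if (!is.null(thr) && rule$probability < thr) status <- "below_threshold"
      }
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = case$patient_id, episode_id = case$episode_id,
        infection_time = case$as_of_date, site_code = rule$site_code,
        diagnosis_code = rule$diagnosis_code, probability = rule$probability,
        rule_id = rule$rule_id, status = status, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(patient_id = character(), episode_id = character(),
                      infection_time = as.Date(character()),
                      site_code = character(), diagnosis_code = character(),
                      probability = numeric(), rule_id = character(),
                      status = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$patient_id, out$infection_time, out$site_code,
                   out$diagnosis_code, out$rule_id), , drop = FALSE]
  seen <- list()   # patient|site -> date of last surviving alert
  for (i in seq_len(nrow(out))) {
    if (out$status[i] != "alerted") next
    k <- paste(out$patient_id[i], out$site_code[i])
    prev <- seen[[k]]
    if (!is.null(prev) &&
        as.numeric(out$infection_time[i] - prev) < config$rti_days) {
      out$status[i] <- "suppressed_rti"
    } else {
      seen[[k]] <- out$infection_time[i]
    }
  }
  rownames(out) <- NULL
  out
}

# independent confusion recount used by the evaluation tests: literal
# per-episode double loop over the warning/gold join
oracle_confusion <- function(warnings, gold) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(gold))) {
    eid <- gold$episode_id[i]
    al <- warnings[warnings$episode_id == eid & warnings$status == "alerted", ]
    if (gold$infected[i] == 1) {
      if (any(al$site_code == gold$site_code[i])) tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (nrow(al) > 0) fp <- fp + 1L else tn <- tn + 1L
    }
  }
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

# numeric root of the implicit confidence update equation
#   p = pr_prev + alpha * (acc - p) / pr_prev
# found with uniroot, independently of the closed form under test
oracle_update <- function(pr_prev, acc, alpha = 0.75) {
  f <- function(p) p - pr_prev - alpha * (acc - p) / pr_prev
  stats::uniroot(f, c(-10, 10), tol = 1e-14)$root
}
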