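# Factor extraction: builds case tuples from raw multi-source records.
#
# A raw record set mirrors the tables a hospital integration layer would
# export: admissions, vital-sign time series, laboratory results,
# microbiology reports, free-text notes (progress / imaging), operations and
# medical orders. Structured factors are mapped directly (latest result on or
# before the surveillance day wins), daily maximum temperature is derived
# from the temperature chart, and text factors are binary keyword-lexicon
# flags with sentence-level negation cues.

RECORD_TABLES <- c("admissions", "vitals", "labs", "micro", "notes",
                   "operations", "orders")

record_columns <- list(
  admissions = c("patient_id", "episode_id", "admission_datetime",
                 "discharge_datetime", "age", "gender", "department"),
  vitals     = c("episode_id", "datetime", "measure_id", "value"),
  labs       = c("episode_id", "datetime", "test_id", "value", "unit",
                 "abnormal_flag"),
  micro      = c("episode_id", "datetime", "specimen", "organism",
                 "positive_flag"),
  notes      = c("episode_id", "datetime", "note_type", "text"),
  operations = c("episode_id", "datetime", "procedure_name"),
  orders     = c("episode_id", "start", "end", "order_type"))

# lab test_id -> (value factor, abnormal-flag factor, presence factor)
LAB_MAP <- list(
  PCT         = list(value = "pct", presence = "has_pct_lab"),
  CRP         = list(value = "crp"),
  BLOOD_WBC   = list(value = "blood_wbc"),
  URINE_WBC   = list(value = "urine_wbc", abnormal = "urine_wbc_abnormal"),
  URINE_BACT  = list(abnormal = "urine_bacteria_abnormal"),
  PLEURAL_WBC = list(value = "pleural_wbc"))

# microbiology specimen -> positive flag factor
MICRO_MAP <- c(pleural_fluid = "pleural_micro_positive",
               urine = "urine_micro_positive",
               sputum = "sputum_micro_positive",
               wound = "wound_micro_positive",
               blood = "blood_micro_positive")

empty_records_table <- function(name) {
  cols <- record_columns[[name]]
  df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                      stringsAsFactors = FALSE)
  for (col in intersect(cols, c("admission_datetime", "discharge_datetime",
                                "datetime", "start", "end"))) {
    df[[col]] <- as.POSIXct(character(0), tz = "UTC")
  }
  for (col in intersect(cols, c("age", "gender", "value", "abnormal_flag",
                                "positive_flag"))) {
    df[[col]] <- numeric(0)
  }
  df
}

#' Construct a raw multi-source record set
#'
#' @param admissions,vitals,labs,micro,notes,operations,orders data frames
#'   with the documented columns (see the vignette); missing tables default
#'   to empty.
#' @return Object of class `hai_records`: a named list of the seven tables.
#' @export
new_records <- function(admissions = NULL, vitals = NULL, labs = NULL,
                        micro = NULL, notes = NULL, operations = NULL,
                        orders = NULL) {
  given <- list(admissions = admissions, vitals = vitals, labs = labs,
                micro = micro, notes = notes, operations = operations,
                orders = orders)
  out <- lapply(RECORD_TABLES, function(nm) {
    df <- given[[nm]]
    if (is.null(df) || nrow(df) == 0) return(empty_records_table(nm))
    missing_cols <- setdiff(record_columns[[nm]], names(df))
    if (length(missing_cols)) {
      stop_hai("records table '%s' missing column(s): %s", nm,
               paste(missing_cols, collapse = ", "))
    }
    df <- df[, record_columns[[nm]], drop = FALSE]
    for (col in intersect(names(df), c("admission_datetime", "discharge_datetime",
                                       "datetime", "start", "end"))) {
      df[[col]] <- hai_time(df[[col]])
    }
    rownames(df) <- NULL
    df
  })
  structure(setNames(out, RECORD_TABLES), class = "hai_records")
}

#' @export
print.hai_records <- function(x, ...) {
  cat("<hai_records>\n")
  for (nm in RECORD_TABLES) cat(sprintf("  %-11s %6d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}

#' Write / read a record set as one CSV per table
#'
#' `read_records()` skips rows whose timestamps fail to parse and reports
#' them (with table and row number) in the `issues` attribute of the result
#' rather than aborting the load.
#'
#' @param records a `hai_records`.
#' @param dir directory holding `admissions.csv`, `vitals.csv`, `labs.csv`,
#'   `micro.csv`, `notes.csv`, `operations.csv`, `orders.csv`.
#' @return `write_records()` returns `dir` invisibly; `read_records()` a
#'   `hai_records` (attribute `issues`: `data.frame(where, issue)`).
#' @export
write_records <- function(records, dir) {
  stopifnot(inherits(records, "hai_records"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in RECORD_TABLES) {
    df <- records[[nm]]
    for (col in intersect(names(df), c("admission_datetime", "discharge_datetime",
                                       "datetime", "start", "end"))) {
      df[[col]] <- fmt_time(df[[col]])
    }
    write.csv(df, file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_records
#' @export
read_records <- function(dir) {
  issues <- issue_df()
  tabs <- list()
  for (nm in RECORD_TABLES) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) {
      tabs[[nm]] <- empty_records_table(nm)
      next
    }
    df <- read.csv(path, stringsAsFactors = FALSE)
    bad <- rep(FALSE, nrow(df))
    for (col in intersect(names(df), c("admission_datetime", "discharge_datetime",
                                       "datetime", "start", "end"))) {
      parsed <- suppressWarnings(hai_time(df[[col]]))
      bad <- bad | (is.na(parsed) & !is.na(df[[col]]) & nzchar(df[[col]]))
      df[[col]] <- parsed
    }
    if (any(bad)) {
      issues <- bind_issues(issues, issue_df(
        sprintf("%s row %d", nm, which(bad)), "unparseable datetime; row skipped"))
      df <- df[!bad, , drop = FALSE]
    }
    tabs[[nm]] <- df
  }
  out <- do.call(new_records, tabs)
  attr(out, "issues") <- issues
  out
}

#' Validate a record set
#'
#' Checks referential integrity (every child record's episode exists in
#' admissions), that child timestamps lie within admission - 1 day and
#' discharge + 1 day, and that temperature readings are physiologically
#' plausible (30-45 degC).
#'
#' @param records a `hai_records`.
#' @return `data.frame(where, issue)`; zero rows on a clean set.
#' @export
validate_records <- function(records) {
  issues <- issue_df()
  adm <- records$admissions
  known <- adm$episode_id
  lo <- setNames(adm$admission_datetime - 86400, adm$episode_id)
  hi <- setNames(adm$discharge_datetime + 86400, adm$episode_id)
  for (nm in setdiff(RECORD_TABLES, "admissions")) {
    df <- records[[nm]]
    if (nrow(df) == 0) next
    orphan <- !df$episode_id %in% known
    if (any(orphan)) {
      issues <- bind_issues(issues, issue_df(
        sprintf("%s row %d", nm, which(orphan)), "episode not in admissions"))
    }
    tcol <- if (nm == "orders") "start" else "datetime"
    ok <- !orphan
    t <- df[[tcol]]
    out_of_stay <- ok & (t < lo[df$episode_id] | t > hi[df$episode_id])
    if (any(out_of_stay, na.rm = TRUE)) {
      issues <- bind_issues(issues, issue_df(
        sprintf("%s row %d", nm, which(out_of_stay)),
        "timestamp outside admission-1d .. discharge+1d"))
    }
  }
  v <- records$vitals
  if (nrow(v)) {
    temp <- v$measure_id == "body_temperature"
    implaus <- temp & (v$value < 30 | v$value > 45)
    if (any(implaus)) {
      issues <- bind_issues(issues, issue_df(
        sprintf("vitals row %d", which(implaus)),
        "temperature outside plausible range 30-45 degC"))
    }
  }
  rownames(issues) <- NULL
  issues
}

# ---- derived numeric factors ----------------------------------------------

#' Highest body temperature of a day
#'
#' Maximum over all temperature readings timestamped within the half-open
#' day window `[day 00:00, day+1 00:00)`. Readings outside the plausible
#' 30-45 degC range are ignored (they are flagged by [validate_records()]).
#'
#' @param vitals vitals table (or a `hai_records`), rows with
#'   `measure_id == "body_temperature"` are used.
#' @param day the calendar day (`Date`).
#' @param episode_id optional episode filter.
#' @return Numeric scalar in degC, or `NULL` when the day has no reading.
#' @examples
#' v <- data.frame(episode_id = "E1",
#'                 datetime = as.POSIXct(c("2020-01-05 08:00", "2020-01-05 16:00"),
#'                                       tz = "UTC"),
#'                 measure_id = "body_temperature", value = c(36.8, 38.9))
#' daily_max_temperature(v, as.Date("2020-01-05"))  # 38.9
#' @export
daily_max_temperature <- function(vitals, day, episode_id = NULL) {
  if (inherits(vitals, "hai_records")) vitals <- vitals$vitals
  day <- hai_date(day)
  t0 <- hai_time(day)
  t1 <- t0 + 86400
  sel <- vitals$measure_id == "body_temperature" &
    vitals$datetime >= t0 & vitals$datetime < t1 &
    vitals$value >= 30 & vitals$value <= 45
  if (!is.null(episode_id)) sel <- sel & vitals$episode_id == episode_id
  vals <- vitals$value[sel]
  if (length(vals) == 0) return(NULL)
  max(vals)
}

#' Calendar hospital day
#'
#' Calendar-day convention: the admission day counts as hospital day 1, so
#' the value is the calendar-day difference plus one regardless of the
#' admission clock time (a patient admitted at 23:50 is on day 2 the next
#' morning).
#'
#' @param admission admission datetime.
#' @param as_of surveillance day (`Date`).
#' @return Integer >= 1.
#' @export
hospital_days <- function(admission, as_of) {
  adm_day <- hai_date(admission)
  as_of <- hai_date(as_of)
  if (as_of < adm_day) stop_hai("as_of (%s) precedes admission (%s)",
                                fmt_date(as_of), fmt_date(adm_day))
  as.integer(as_of - adm_day) + 1L
}

# ---- keyword lexicon -------------------------------------------------------

#' Load a keyword lexicon
#'
#' @param path YAML lexicon; defaults to the packaged English lexicon.
#' @param registry optional `hai_registry`; when given, every lexicon factor
#'   must be registered as binary.
#' @return Object of class `hai_lexicon`: list with `default_negation_cues`
#'   and `entries` (each: `factor_id`, `note_type`, `keywords`,
#'   `negation_cues`, `case_sensitive`).
#' @export
load_lexicon <- function(path = hais_extdata("lexicon.yaml"), registry = NULL) {
  raw <- yaml::read_yaml(path)
  cues <- as.character(raw$default_negation_cues %||% character())
  entries <- lapply(raw$entries %||% list(), function(e) {
    kws <- as.character(unlist(e$keywords))
    if (length(kws) == 0) stop_hai("lexicon entry '%s' has no keywords", e$factor_id)
    if (!is.null(registry)) {
      reg <- registry_row(registry, e$factor_id)
      if (is.null(reg)) stop_hai("lexicon factor '%s' is not registered", e$factor_id)
      if (reg$kind != "binary") {
        stop_hai("lexicon factor '%s' must be binary, is %s", e$factor_id, reg$kind)
      }
    }
    list(factor_id = as.character(e$factor_id),
         note_type = as.character(e$note_type %||% "progress"),
         keywords = kws,
         negation_cues = as.character(unlist(e$negation_cues %||% cues)),
         case_sensitive = isTRUE(e$case_sensitive))
  })
  structure(list(default_negation_cues = cues, entries = entries),
            class = "hai_lexicon")
}

split_sentences <- function(text) {
  s <- strsplit(text, "[.!?;\n]+")[[1]]
  s[nzchar(trimws(s))]
}

lexicon_flag <- function(texts, entry) {
  for (txt in texts) {
    for (sentence in split_sentences(txt)) {
      s <- if (entry$case_sensitive) gsub("[[:space:]]+", " ", sentence)
           else normalize_text(sentence)
      cues <- if (entry$case_sensitive) entry$negation_cues
              else tolower(entry$negation_cues)
      kws <- if (entry$case_sensitive) entry$keywords
             else tolower(entry$keywords)
      hit <- any(vapply(kws, function(k) grepl(k, s, fixed = TRUE), TRUE))
      if (!hit) next
      negated <- length(cues) > 0 &&
        any(vapply(cues, function(k) grepl(k, s, fixed = TRUE), TRUE))
      if (!negated) return(1)
    }
  }
  0
}

#' Extract keyword flags from free-text notes
#'
#' For each lexicon entry, the flag is 1 iff any note of the matching type,
#' dated on or before `day` within the episode, contains at least one of the
#' entry's keywords as a substring (after case folding and whitespace
#' normalization) in a sentence that carries no negation cue. Flags are never
#' missing: absence of evidence yields 0.
#'
#' @param notes notes table (or a `hai_records`).
#' @param lexicon a `hai_lexicon`.
#' @param day the surveillance day; notes after the end of this day are
#'   ignored.
#' @param episode_id optional episode filter.
#' @return Named numeric vector of 0/1 flags, one per lexicon entry.
#' @export
extract_keywords <- function(notes, lexicon, day, episode_id = NULL) {
  if (inherits(notes, "hai_records")) notes <- notes$notes
  cutoff <- hai_time(hai_date(day)) + 86400
  if (!is.null(episode_id)) {
    notes <- notes[notes$episode_id == episode_id, , drop = FALSE]
  }
  notes <- notes[notes$datetime < cutoff, , drop = FALSE]
  flags <- vapply(lexicon$entries, function(entry) {
    texts <- notes$text[notes$note_type == entry$note_type]
    if (length(texts) == 0) return(0)
    lexicon_flag(texts, entry)
  }, 0)
  setNames(flags, vapply(lexicon$entries, `[[`, "", "factor_id"))
}

# ---- structured extraction -------------------------------------------------

fv <- function(registry, fid, value) {
  reg <- registry_row(registry, fid)
  factor_value(fid, reg$kind, value, reg$unit)
}

# structured factors (DE, PS, CL, OP, MO) for one episode on one day;
# ep = list of that episode's record subsets, adm = its admissions row
episode_structured <- function(ep, adm, day, registry) {
  cutoff <- hai_time(day) + 86400
  DE <- list()
  if (!is.na(adm$age)) DE$age <- fv(registry, "age", as.integer(adm$age))
  if (!is.na(adm$gender)) DE$gender <- fv(registry, "gender", as.numeric(adm$gender))

  PS <- list(admission_datetime = fv(registry, "admission_datetime",
                                     adm$admission_datetime),
             hospital_days = fv(registry, "hospital_days",
                                hospital_days(adm$admission_datetime, day)))

  CL <- list()
  labs <- ep$labs[ep$labs$datetime < cutoff, , drop = FALSE]
  for (tid in names(LAB_MAP)) {
    spec <- LAB_MAP[[tid]]
    rows <- labs[labs$test_id == tid, , drop = FALSE]
    if (!is.null(spec$presence)) {
      CL[[spec$presence]] <- fv(registry, spec$presence,
                                as.numeric(nrow(rows) > 0))
    }
    if (nrow(rows) == 0) {
      # unmeasured numeric labs stay missing; abnormal flags default to 0
      if (!is.null(spec$abnormal)) CL[[spec$abnormal]] <- fv(registry, spec$abnormal, 0)
      next
    }
    latest <- rows[order(rows$datetime), , drop = FALSE]
    latest <- latest[nrow(latest), , drop = FALSE]     # later timestamp wins
    if (!is.null(spec$value)) {
      CL[[spec$value]] <- fv(registry, spec$value, as.numeric(latest$value))
    }
    if (!is.null(spec$abnormal)) {
      CL[[spec$abnormal]] <- fv(registry, spec$abnormal,
                                as.numeric(latest$abnormal_flag %in% 1))
    }
  }
  micro <- ep$micro[ep$micro$datetime < cutoff, , drop = FALSE]
  for (specimen in names(MICRO_MAP)) {
    fid <- MICRO_MAP[[specimen]]
    pos <- any(micro$specimen == specimen & micro$positive_flag %in% 1)
    CL[[fid]] <- fv(registry, fid, as.numeric(pos))
  }

  OP <- list(recent_operation = fv(registry, "recent_operation",
                                   as.numeric(any(ep$operations$datetime < cutoff))))

  MO <- list()
  for (fid in c("urinary_catheter", "ventilator")) {
    act <- ep$orders$order_type == fid &
      hai_date(ep$orders$start) <= day & hai_date(ep$orders$end) >= day
    MO[[fid]] <- fv(registry, fid, as.numeric(any(act)))
  }
  list(DE = DE, PS = PS, CL = CL, OP = OP, MO = MO)
}

episode_subset <- function(records, eid) {
  list(labs = records$labs[records$labs$episode_id == eid, , drop = FALSE],
       micro = records$micro[records$micro$episode_id == eid, , drop = FALSE],
       vitals = records$vitals[records$vitals$episode_id == eid, , drop = FALSE],
       notes = records$notes[records$notes$episode_id == eid, , drop = FALSE],
       operations = records$operations[records$operations$episode_id == eid, ,
                                       drop = FALSE],
       orders = records$orders[records$orders$episode_id == eid, , drop = FALSE])
}

#' Extract structured factors for all in-hospital episodes on a day
#'
#' Direct mapping of structured records into tuple groups: DE gets age and
#' gender; PS gets the admission timestamp and the calendar hospital day;
#' CL gets the latest laboratory value on or before the day (same-day
#' duplicates: the later timestamp wins), laboratory abnormal flags,
#' presence flags such as whether a PCT result exists, and microbiology
#' positive flags; OP and MO get binary flags for operations performed and
#' orders active on the day.
#'
#' @param records a validated `hai_records`.
#' @param day surveillance day (`Date`).
#' @param registry a `hai_registry`.
#' @return Named list (by episode id, episodes in hospital on `day`), each a
#'   list of tuple groups `DE`, `PS`, `CL`, `OP`, `MO` mapping factor id to
#'   factor values.
#' @export
extract_structured <- function(records, day, registry = load_registry()) {
  day <- hai_date(day)
  adm <- records$admissions
  sel <- hai_date(adm$admission_datetime) <= day &
    hai_date(adm$discharge_datetime) >= day
  out <- list()
  for (i in which(sel)) {
    eid <- adm$episode_id[i]
    out[[eid]] <- episode_structured(episode_subset(records, eid),
                                     adm[i, , drop = FALSE], day, registry)
  }
  out
}

# ---- case assembly ---------------------------------------------------------

episode_case <- function(ep, adm, day, lexicon, registry) {
  groups <- episode_structured(ep, adm, day, registry)
  VS <- list()
  tmax <- daily_max_temperature(ep$vitals, day)
  if (!is.null(tmax)) VS$body_temperature_max <- fv(registry, "body_temperature_max", tmax)
  t0 <- hai_time(day); t1 <- t0 + 86400
  defec <- ep$vitals[ep$vitals$measure_id == "defecation_frequency" &
                       ep$vitals$datetime >= t0 & ep$vitals$datetime < t1, ,
                     drop = FALSE]
  if (nrow(defec)) {
    VS$defecation_frequency <- fv(registry, "defecation_frequency",
                                  as.integer(defec$value[nrow(defec)]))
  }
  groups$VS <- VS
  flags <- extract_keywords(ep$notes, lexicon, day)
  PN <- list(); IR <- list()
  for (fid in names(flags)) {
    reg <- registry_row(registry, fid)
    grp <- if (is.null(reg)) "PN" else reg$group
    if (grp == "IR") IR[[fid]] <- fv(registry, fid, flags[[fid]])
    else PN[[fid]] <- fv(registry, fid, flags[[fid]])
  }
  groups$PN <- PN
  groups$IR <- IR
  new_case(adm$patient_id, adm$episode_id, day, groups)
}

#' Build case tuples from raw records
#'
#' One case tuple per episode per in-hospital calendar day (admission day
#' through discharge day, optionally clipped to `day_range`). Every returned
#' tuple passes [validate_case()] against the supplied registry. Record-level
#' problems found by [validate_records()] are attached as the `issues`
#' attribute; no episode is silently dropped.
#'
#' @param records a `hai_records`.
#' @param lexicon a `hai_lexicon`.
#' @param registry a `hai_registry`.
#' @param day_range optional `Date` vector of length 2 clipping the
#'   surveillance days.
#' @return List of `hai_case`, ordered by (patient, episode, day), with
#'   attribute `issues`.
#' @export
build_cases <- function(records, lexicon = load_lexicon(),
                        registry = load_registry(), day_range = NULL) {
  stopifnot(inherits(records, "hai_records"))
  issues <- validate_records(records)
  adm <- records$admissions
  if (nrow(adm) == 0) {
    out <- list()
    attr(out, "issues") <- issues
    return(out)
  }
  adm <- adm[order(adm$patient_id, adm$episode_id), , drop = FALSE]
  cases <- list()
  for (i in seq_len(nrow(adm))) {
    row <- adm[i, , drop = FALSE]
    d0 <- hai_date(row$admission_datetime)
    d1 <- hai_date(row$discharge_datetime)
    if (!is.null(day_range)) {
      d0 <- max(d0, hai_date(day_range[1]))
      d1 <- min(d1, hai_date(day_range[2]))
    }
    if (d1 < d0) next
    ep <- episode_subset(records, row$episode_id)
    for (day in as.list(seq(d0, d1, by = "day"))) {
      cases[[length(cases) + 1]] <- episode_case(ep, row, day, lexicon, registry)
    }
  }
  attr(cases, "issues") <- issues
  cases
}
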