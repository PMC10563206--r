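# Stratified evaluation against gold labels.
#
# The scoring unit is the inpatient episode. An episode counts as a true
# positive when its gold label is infected and at least one alerted warning
# matches it at the chosen granularity (infection site by default); as a
# false negative when infected but unmatched; as a false positive when
# uninfected but alerted; as a true negative otherwise. Metrics follow the
# usual confusion identities: ACC = (TP+TN)/(P+N), SEN = TP/(TP+FN),
# SPE = TN/(TN+FP); a metric whose denominator is zero is reported as NA,
# never as 0.

#' Confusion counts
#'
#' @param TP,FP,FN,TN non-negative integers.
#' @return Object of class `hai_confusion`.
#' @export
confusion_counts <- function(TP = 0, FP = 0, FN = 0, TN = 0) {
  counts <- c(TP = as.integer(TP), FP = as.integer(FP),
              FN = as.integer(FN), TN = as.integer(TN))
  if (any(counts < 0)) stop_hai("confusion counts must be >= 0")
  structure(as.list(counts), class = "hai_confusion")
}

#' @export
print.hai_confusion <- function(x, ...) {
  m <- hai_metrics(x)
  cat(sprintf("<hai_confusion> TP=%d FP=%d FN=%d TN=%d  acc=%.4g sen=%.4g spe=%.4g\n",
              x$TP, x$FP, x$FN, x$TN, m["acc"], m["sen"], m["spe"]))
  invisible(x)
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' @param counts a `hai_confusion` (or list with `TP`, `FP`, `FN`, `TN`).
#' @return Named numeric vector `c(acc, sen, spe)`; `NA` where the
#'   denominator is zero.
#' @examples
#' hai_metrics(confusion_counts(TP = 8, FN = 2, TN = 85, FP = 5))
#' @export
hai_metrics <- function(counts) {
  with(counts, {
    P <- TP + FN
    N <- TN + FP
    c(acc = if (P + N > 0) (TP + TN) / (P + N) else NA_real_,
      sen = if (P > 0) TP / P else NA_real_,
      spe = if (N > 0) TN / N else NA_real_)
  })
}

# classify each gold episode against the alerted warnings; match_on controls
# what an alert must share with the gold label to count as detection
episode_outcomes <- function(warnings, gold,
                             match_on = c("site", "diagnosis", "any")) {
  match_on <- match.arg(match_on)
  al <- warnings[warnings$status == "alerted", , drop = FALSE]
  stray <- setdiff(unique(al$episode_id), gold$episode_id)
  if (length(stray)) {
    stop_hai("warning episode(s) absent from gold labels: %s",
             paste(stray, collapse = ", "))
  }
  hit <- vapply(seq_len(nrow(gold)), function(i) {
    rows <- al[al$episode_id == gold$episode_id[i], , drop = FALSE]
    if (nrow(rows) == 0) return(FALSE)
    if (gold$infected[i] != 1) return(TRUE)       # any alert on a clean episode
    switch(match_on,
           any = TRUE,
           site = any(rows$site_code == gold$site_code[i]),
           diagnosis = any(rows$diagnosis_code == gold$diagnosis_code[i]))
  }, TRUE)
  data.frame(episode_id = gold$episode_id,
             infected = gold$infected,
             detected = as.integer(hit),
             stringsAsFactors = FALSE)
}

#' Episode-level confusion counts
#'
#' @param warnings warning `data.frame` from [run_surveillance()]; only
#'   `alerted` rows count.
#' @param gold gold labels, one row per episode ([load_gold_labels()]).
#' @param match_on what an alert must share with an infected episode's gold
#'   label to count as detection: `"site"` (default), `"diagnosis"`, or
#'   `"any"` alert.
#' @return A `hai_confusion`.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_spec(n_patients = 100, seed = 2))
#' w <- run_surveillance(build_cases(cohort$records), load_rule_base())
#' score_episode_level(w, cohort$gold)
#' }
#' @export
score_episode_level <- function(warnings, gold, match_on = "site") {
  oc <- episode_outcomes(warnings, gold, match_on)
  confusion_counts(TP = sum(oc$infected == 1 & oc$detected == 1),
                   FN = sum(oc$infected == 1 & oc$detected == 0),
                   FP = sum(oc$infected == 0 & oc$detected == 1),
                   TN = sum(oc$infected == 0 & oc$detected == 0))
}

score_stratum <- function(warnings, gold, stratum, key) {
  if (key == "month") {
    sub_gold <- gold[gold$report_month == stratum, , drop = FALSE]
    sub_w <- warnings[warnings$episode_id %in% sub_gold$episode_id, , drop = FALSE]
    return(score_episode_level(sub_w, sub_gold, match_on = "site"))
  }
  # diagnosis / site strata: score every episode for involvement with the
  # stratum; episodes with neither a gold label nor a warning for it are the
  # (abundant) true negatives
  al <- warnings[warnings$status == "alerted", , drop = FALSE]
  col <- if (key == "diagnosis") "diagnosis_code" else "site_code"
  alerted_eps <- unique(al$episode_id[al[[col]] == stratum])
  gold_pos <- gold$infected == 1 & !is.na(gold[[col]]) & gold[[col]] == stratum
  det <- gold$episode_id %in% alerted_eps
  confusion_counts(TP = sum(gold_pos & det), FN = sum(gold_pos & !det),
                   FP = sum(!gold_pos & det), TN = sum(!gold_pos & !det))
}

#' Stratified evaluation report
#'
#' Scores one or more surveillance runs against gold labels, stratified by
#' reporting month, infection diagnosis or infection site, with an overall
#' row per scenario. Month strata partition the episodes (their confusion
#' counts sum to the overall counts). Diagnosis and site strata score every
#' episode for involvement with the stratum, so their many uninvolved
#' episodes appear as true negatives - which is why per-diagnosis
#' specificity is typically very high.
#'
#' @param warnings a warning `data.frame`, or a named list of them (name =
#'   scenario label) to compare scenarios side by side.
#' @param gold gold labels.
#' @param by stratification key: `"month"`, `"diagnosis"` or `"site"`.
#' @param strata optional character vector of stratum keys to report;
#'   default: all values present in the gold labels or warnings.
#' @return Object of class `hai_eval_report`: a `data.frame` with columns
#'   `stratum`, `scenario`, `TP`, `FP`, `FN`, `TN`, `acc`, `sen`, `spe`
#'   (metrics `NA` where undefined).
#' @export
stratified_report <- function(warnings, gold,
                              by = c("month", "diagnosis", "site"),
                              strata = NULL) {
  by <- match.arg(by)
  if (is.data.frame(warnings)) warnings <- list(default = warnings)
  if (is.null(names(warnings)) || any(!nzchar(names(warnings)))) {
    stop_hai("scenario warning sets must be named")
  }
  if (is.null(strata)) {
    strata <- switch(by,
      month = sort(unique(gold$report_month)),
      diagnosis = sort(unique(c(gold$diagnosis_code[gold$infected == 1],
                                unlist(lapply(warnings, function(w)
                                  w$diagnosis_code[w$status == "alerted"]))))),
      site = sort(unique(c(gold$site_code[gold$infected == 1],
                           unlist(lapply(warnings, function(w)
                             w$site_code[w$status == "alerted"]))))))
  }
  rows <- list()
  for (scen in names(warnings)) {
    w <- warnings[[scen]]
    for (st in c(strata, "overall")) {
      cc <- if (st == "overall") {
        score_episode_level(w, gold, match_on = "site")
      } else {
        score_stratum(w, gold, st, by)
      }
      m <- hai_metrics(cc)
      rows[[length(rows) + 1]] <- data.frame(
        stratum = st, scenario = scen, TP = cc$TP, FP = cc$FP, FN = cc$FN,
        TN = cc$TN, acc = m["acc"], sen = m["sen"], spe = m["spe"],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("hai_eval_report", "data.frame")
  attr(out, "by") <- by
  out
}

#' Unweighted average of a metric over defined strata
#'
#' Mean over the strata (excluding the overall row) where the metric is
#' defined; strata with undefined metrics are skipped rather than counted
#' as zero.
#'
#' @param report a `hai_eval_report`.
#' @param metric `"acc"`, `"sen"` or `"spe"`.
#' @param scenario scenario label (default: first).
#' @return Numeric scalar (or `NA` if no stratum defines the metric).
#' @export
report_average <- function(report, metric = c("sen", "spe", "acc"),
                           scenario = NULL) {
  metric <- match.arg(metric)
  scenario <- scenario %||% report$scenario[1]
  vals <- report[[metric]][report$scenario == scenario &
                             report$stratum != "overall"]
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

#' Write an evaluation report
#'
#' @param report a `hai_eval_report`.
#' @param path output path; `.json` writes JSON, anything else CSV with the
#'   column structure stratum, scenario, TP, FP, FN, TN, ACC, SEN, SPE.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.data.frame(report), path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows", na = "null")
  } else {
    write.csv(as.data.frame(report), path, row.names = FALSE, na = "")
  }
  invisible(path)
}
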