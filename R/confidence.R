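# Monthly confidence feedback.
#
# Every rule carries a confidence Pr in (0, 1], initialized from expert
# experience and updated monthly from physician confirmations. The update is
# defined implicitly:
#
#     Pr(i) = Pr(i-1) + alpha * (Acc(i) - Pr(i)) / Pr(i-1)
#
# with Acc(i) the rule's confirmed-alert fraction for the month and alpha an
# adjusting parameter (default 0.75). Solving for Pr(i) gives the exact
# closed form
#
#     Pr(i) = (Pr(i-1)^2 + alpha * Acc(i)) / (Pr(i-1) + alpha)
#
# which is used by default: it is self-normalizing to (0, 1], has its fixed
# point at Acc = Pr(i-1), and is strictly increasing in Acc with slope
# alpha / (Pr(i-1) + alpha). A literal reading that replaces the numerator's
# Pr(i) by Pr(i-1) (`explicit_form = TRUE`) is provided for comparison; that
# form can leave (0, 1] (e.g. 0.5 + 0.75 * (1 - 0.5)/0.5 = 1.25) and is
# therefore clamped to [0.01, 1].

#' Per-rule confirmation accuracy for one feedback month
#'
#' @param n_alerts number of alerted warnings citing the rule in the month.
#' @param n_confirmed number of those confirmed as true HAIs on review.
#' @return `n_confirmed / n_alerts`, or `NA` when the rule produced no
#'   alerts (no evidence: the confidence is carried forward unchanged).
#' @examples
#' rule_accuracy(10, 8)  # 0.8
#' rule_accuracy(0, 0)   # NA
#' @export
rule_accuracy <- function(n_alerts, n_confirmed) {
  if (n_confirmed > n_alerts) {
    stop_hai("n_confirmed (%d) exceeds n_alerts (%d)", n_confirmed, n_alerts)
  }
  if (n_alerts < 0 || n_confirmed < 0) stop_hai("alert counts must be >= 0")
  if (n_alerts == 0) return(NA_real_)
  n_confirmed / n_alerts
}

#' Confidence update
#'
#' Solves the implicit monthly update equation exactly (see the package
#' vignette). The result always lies in
#' `[pr_prev^2/(pr_prev+alpha), (pr_prev^2+alpha)/(pr_prev+alpha)]`, a subset
#' of (0, 1]; it equals `pr_prev` iff `acc == pr_prev`, and is strictly
#' increasing in `acc`.
#'
#' @param pr_prev previous confidence, in (0, 1].
#' @param acc this month's rule accuracy, in `[0, 1]`.
#' @param alpha adjusting parameter, > 0 (default 0.75).
#' @param explicit_form use the literal non-implicit variant (clamped to
#'   `[0.01, 1]`) instead of the closed-form solution.
#' @return Updated confidence.
#' @examples
#' update_confidence(0.8, 0.8)   # fixed point: 0.8
#' update_confidence(0.5, 1.0)   # 0.8
#' @export
update_confidence <- function(pr_prev, acc, alpha = 0.75,
                              explicit_form = FALSE) {
  if (!is.numeric(pr_prev) || pr_prev <= 0 || pr_prev > 1) {
    stop_hai("pr_prev must be in (0, 1]")
  }
  if (!is.numeric(acc) || acc < 0 || acc > 1) stop_hai("acc must be in [0, 1]")
  if (!is.numeric(alpha) || alpha <= 0) stop_hai("alpha must be > 0")
  if (explicit_form) {
    out <- pr_prev + alpha * (acc - pr_prev) / pr_prev
    return(min(1, max(0.01, out)))
  }
  (pr_prev^2 + alpha * acc) / (pr_prev + alpha)
}

#' Initialize a confidence state from a rule base
#'
#' @param rule_base a `hai_rulebase`; each rule's packaged probability seeds
#'   its confidence.
#' @param alpha adjusting parameter stored with the state.
#' @return Object of class `hai_confidence_state`: `alpha` plus one entry
#'   per rule with current `pr` and an update `history` data.frame
#'   (`month`, `pr`, `acc`, `n_alerts`, `n_confirmed`).
#' @export
confidence_state <- function(rule_base, alpha = 0.75) {
  rules <- setNames(
    lapply(rule_base$rules, function(r) {
      list(pr = r$probability,
           history = data.frame(month = character(), pr = numeric(),
                                acc = numeric(), n_alerts = integer(),
                                n_confirmed = integer(),
                                stringsAsFactors = FALSE))
    }),
    vapply(rule_base$rules, `[[`, "", "rule_id"))
  structure(list(alpha = alpha, rules = rules),
            class = "hai_confidence_state")
}

confidence_of <- function(state, rule_id) {
  state$rules[[rule_id]]$pr
}

#' @export
print.hai_confidence_state <- function(x, ...) {
  cat(sprintf("<hai_confidence_state> %d rules, alpha = %g\n",
              length(x$rules), x$alpha))
  invisible(x)
}

#' Apply one month of confirmation feedback
#'
#' Updates the confidence of every rule with at least one alert in the
#' batch; rules without alerts (or absent from the batch) are carried
#' forward unchanged. The input state is not mutated; a new state with the
#' appended history is returned. Months must arrive in increasing order per
#' rule.
#'
#' @param state a `hai_confidence_state`.
#' @param batch feedback batch: `data.frame` with columns `month`
#'   (`"YYYY-MM"`), `rule_id`, `n_alerts`, `n_confirmed` (see
#'   [read_feedback()], [feedback_from_gold()]).
#' @param explicit_form see [update_confidence()].
#' @return The updated `hai_confidence_state`.
#' @export
monthly_update <- function(state, batch, explicit_form = FALSE) {
  stopifnot(inherits(state, "hai_confidence_state"))
  if (nrow(batch) == 0) return(state)
  months <- unique(batch$month)
  if (length(months) != 1) stop_hai("a feedback batch must cover one month")
  dup <- batch$rule_id[duplicated(batch$rule_id)]
  if (length(dup)) stop_hai("duplicate rule id in feedback batch: %s", dup[1])
  new_state <- state
  for (i in seq_len(nrow(batch))) {
    rid <- as.character(batch$rule_id[i])
    entry <- new_state$rules[[rid]]
    if (is.null(entry)) stop_hai("feedback for unknown rule id: %s", rid)
    hist <- entry$history
    if (nrow(hist) && max(hist$month) >= months) {
      stop_hai("out-of-order feedback month %s for rule %s (last: %s)",
               months, rid, max(hist$month))
    }
    acc <- rule_accuracy(batch$n_alerts[i], batch$n_confirmed[i])
    if (!is.na(acc)) {
      entry$pr <- update_confidence(entry$pr, acc, new_state$alpha,
                                    explicit_form)
    }
    entry$history <- rbind(hist, data.frame(
      month = months, pr = entry$pr, acc = acc,
      n_alerts = as.integer(batch$n_alerts[i]),
      n_confirmed = as.integer(batch$n_confirmed[i]),
      stringsAsFactors = FALSE))
    new_state$rules[[rid]] <- entry
  }
  new_state
}

#' Derive a monthly feedback batch from warnings and gold labels
#'
#' Emulates physician review: an alerted warning counts as confirmed iff its
#' episode's gold label is infected and the warning's site matches the gold
#' site. Counts are aggregated per rule over the warnings whose infection
#' time falls in `month`.
#'
#' @param warnings warning `data.frame` from [run_surveillance()].
#' @param gold gold labels ([load_gold_labels()]).
#' @param month `"YYYY-MM"`; default: every month present in the warnings
#'   (one batch row set per month, bound together).
#' @return Feedback `data.frame(month, rule_id, n_alerts, n_confirmed)`.
#' @export
feedback_from_gold <- function(warnings, gold, month = NULL) {
  al <- warnings[warnings$status == "alerted", , drop = FALSE]
  if (nrow(al) == 0) {
    return(data.frame(month = character(), rule_id = character(),
                      n_alerts = integer(), n_confirmed = integer(),
                      stringsAsFactors = FALSE))
  }
  al$month <- month_key(al$infection_time)
  if (!is.null(month)) al <- al[al$month %in% month, , drop = FALSE]
  gi <- match(al$episode_id, gold$episode_id)
  if (anyNA(gi)) {
    stop_hai("warning episode(s) absent from gold labels: %s",
             paste(unique(al$episode_id[is.na(gi)]), collapse = ", "))
  }
  al$confirmed <- as.integer(gold$infected[gi] == 1 &
                               !is.na(gold$site_code[gi]) &
                               gold$site_code[gi] == al$site_code)
  agg <- aggregate(cbind(n_alerts = rep(1L, nrow(al)), n_confirmed = al$confirmed),
                   by = list(month = al$month, rule_id = al$rule_id), FUN = sum)
  agg <- agg[order(agg$month, agg$rule_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Read / write a feedback batch CSV
#'
#' @param path CSV with header `month, rule_id, n_alerts, n_confirmed`.
#' @param batch feedback `data.frame`.
#' @return `read_feedback()` returns the typed `data.frame`;
#'   `write_feedback()` returns `path` invisibly.
#' @export
read_feedback <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(rule_id = "character"))
  needed <- c("month", "rule_id", "n_alerts", "n_confirmed")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop_hai("feedback file missing column(s): %s",
             paste(missing_cols, collapse = ", "))
  }
  bad <- df$n_confirmed > df$n_alerts
  if (any(bad)) {
    stop_hai("n_confirmed exceeds n_alerts for rule %s", df$rule_id[bad][1])
  }
  df
}

#' @rdname read_feedback
#' @export
write_feedback <- function(batch, path) {
  write.csv(batch, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a confidence state as JSON
#'
#' The full per-rule history is preserved; a written state reads back
#' identical.
#'
#' @param state a `hai_confidence_state`.
#' @param path output (input) file path.
#' @return `write_confidence_state()` returns `path` invisibly;
#'   `read_confidence_state()` the state.
#' @export
write_confidence_state <- function(state, path) {
  obj <- list(alpha = state$alpha,
              rules = lapply(names(state$rules), function(rid) {
                entry <- state$rules[[rid]]
                list(rule_id = rid, pr = entry$pr, history = entry$history)
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_confidence_state
#' @export
read_confidence_state <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rules <- setNames(
    lapply(obj$rules, function(r) {
      hist <- if (length(r$history) == 0) {
        data.frame(month = character(), pr = numeric(), acc = numeric(),
                   n_alerts = integer(), n_confirmed = integer(),
                   stringsAsFactors = FALSE)
      } else {
        do.call(rbind, lapply(r$history, function(h) {
          data.frame(month = h$month, pr = h$pr,
                     acc = if (is.null(h$acc)) NA_real_ else h$acc,
                     n_alerts = as.integer(h$n_alerts),
                     n_confirmed = as.integer(h$n_confirmed),
                     stringsAsFactors = FALSE)
        }))
      }
      list(pr = r$pr, history = hist)
    }),
    vapply(obj$rules, `[[`, "", "rule_id"))
  structure(list(alpha = obj$alpha, rules = rules),
            class = "hai_confidence_state")
}
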