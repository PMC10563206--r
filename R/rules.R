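# Decision-table rule dialect and the knowledge rule base.
#
# A decision table is a plain CSV with a four-line header:
#   1  RuleSet,<name>,<source>[,authored]      source: guideline | expert
#   2  Diagnosis,<diagnosis code>
#   3  column kinds: CONDITION ... ACTION ...
#   4  column bindings: "<factor_id> <operator>" per CONDITION column,
#      "rule_id" / "probability" per ACTION column
# Each later row is one complete conjunctive rule: a blank CONDITION cell
# means the condition is absent (don't care); a rule fires only when every
# non-blank condition holds. `in_range` operands are written "low,high"
# (quoted) and are closed-open intervals [low, high).

RULE_OPERATORS <- c("eq", "ne", "lt", "le", "gt", "ge", "in_range", "contains_flag")

new_condition <- function(factor_id, operator, operand) {
  if (!operator %in% RULE_OPERATORS) stop_hai("unknown operator: %s", operator)
  structure(list(factor_id = factor_id, operator = operator, operand = operand),
            class = "hai_condition")
}

new_rule <- function(rule_id, diagnosis_code, site_code, source, conditions,
                     probability) {
  if (length(conditions) == 0) {
    stop_hai("rule %s has an empty condition set", rule_id)
  }
  if (!is.numeric(probability) || is.na(probability) ||
      probability <= 0 || probability > 1) {
    stop_hai("rule %s: probability must be in (0, 1]", rule_id)
  }
  structure(list(rule_id = as.character(rule_id),
                 diagnosis_code = diagnosis_code, site_code = site_code,
                 source = source, conditions = conditions,
                 probability = probability),
            class = "hai_rule")
}

split_csv_line <- function(line) {
  scan(text = line, what = "", sep = ",", quote = "\"", quiet = TRUE,
       strip.white = FALSE, blank.lines.skip = FALSE)
}

#' Parse a decision-table rule file
#'
#' Reads one decision table in the package's CSV dialect (see
#' `vignette("hai-surveillance")`) into a set of knowledge rules, one per
#' data row. Blank condition cells are omitted from the rule's conjunction;
#' a row whose condition cells are all blank is rejected, as are unknown
#' factors, probabilities outside (0, 1] and duplicate rule ids.
#'
#' @param path path to a decision-table CSV.
#' @param registry `hai_registry` used to resolve factor bindings.
#' @param catalog `hai_catalog` used to resolve the diagnosis to its site.
#' @return Object of class `hai_decision_table`: list with `ruleset_name`,
#'   `diagnosis_code`, `site_code`, `source`, `authored`, `columns`
#'   (binding spec), and `rules` (list of rules).
#' @examples
#' tab <- parse_decision_table(hais_extdata("rules", "pci_guideline.csv"),
#'                             load_registry(), load_catalog())
#' length(tab$rules)
#' @export
parse_decision_table <- function(path, registry = load_registry(),
                                 catalog = load_catalog()) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 5) stop_hai("decision table too short: %s", path)

  h1 <- split_csv_line(lines[1])
  if (toupper(h1[1]) != "RULESET" || length(h1) < 3) {
    stop_hai("%s: line 1 must be 'RuleSet,<name>,<source>'", path)
  }
  ruleset_name <- h1[2]
  source <- h1[3]
  if (!source %in% c("guideline", "expert")) {
    stop_hai("%s: rule source must be 'guideline' or 'expert', got '%s'",
             path, source)
  }
  authored <- length(h1) >= 4 && tolower(h1[4]) == "authored"

  h2 <- split_csv_line(lines[2])
  if (toupper(h2[1]) != "DIAGNOSIS" || length(h2) < 2) {
    stop_hai("%s: line 2 must be 'Diagnosis,<code>'", path)
  }
  diagnosis_code <- h2[2]
  if (!diagnosis_code %in% catalog$table$diagnosis_code) {
    stop_hai("%s: unknown diagnosis code '%s'", path, diagnosis_code)
  }
  site_code <- site_of(catalog, diagnosis_code)

  kinds <- toupper(split_csv_line(lines[3]))
  if (!all(kinds %in% c("CONDITION", "ACTION"))) {
    stop_hai("%s: line 3 cells must be CONDITION or ACTION", path)
  }
  bindings <- split_csv_line(lines[4])
  if (length(bindings) != length(kinds)) {
    stop_hai("%s: line 4 must bind every column of line 3", path)
  }

  cond_idx <- which(kinds == "CONDITION")
  act_idx <- which(kinds == "ACTION")
  cond_cols <- lapply(cond_idx, function(i) {
    parts <- strsplit(trimws(bindings[i]), "[[:space:]]+")[[1]]
    if (length(parts) != 2) {
      stop_hai("%s: column %d binding must be '<factor_id> <operator>'", path, i)
    }
    fid <- parts[1]; op <- parts[2]
    reg <- registry_row(registry, fid)
    if (is.null(reg)) stop_hai("%s: column %d binds unknown factor '%s'", path, i, fid)
    if (!op %in% RULE_OPERATORS) {
      stop_hai("%s: column %d has unknown operator '%s'", path, i, op)
    }
    if (op == "in_range" && !reg$kind %in% c("integer", "real")) {
      stop_hai("%s: in_range on non-numeric factor '%s'", path, fid)
    }
    if (reg$kind == "binary" && !op %in% c("eq", "ne", "contains_flag")) {
      stop_hai("%s: operator '%s' not valid for binary factor '%s'", path, op, fid)
    }
    list(idx = i, factor_id = fid, operator = op, kind = reg$kind)
  })
  act_names <- tolower(trimws(bindings[act_idx]))
  if (!all(c("rule_id", "probability") %in% act_names)) {
    stop_hai("%s: ACTION columns must include rule_id and probability", path)
  }
  id_col <- act_idx[match("rule_id", act_names)]
  pr_col <- act_idx[match("probability", act_names)]

  rules <- list()
  prov <- list()
  for (r in seq(5, length(lines))) {
    cells <- split_csv_line(lines[r])
    length(cells) <- length(kinds)           # pad short rows with NA
    cells[is.na(cells)] <- ""
    rid <- trimws(cells[id_col])
    if (!nzchar(rid)) stop_hai("%s row %d: missing rule_id", path, r)
    if (rid %in% names(rules)) stop_hai("%s row %d: duplicate rule id '%s'", path, r, rid)
    pr <- suppressWarnings(as.numeric(cells[pr_col]))
    if (is.na(pr) || pr <= 0 || pr > 1) {
      stop_hai("%s row %d (rule %s): probability must be in (0, 1]", path, r, rid)
    }
    conds <- list()
    for (cc in cond_cols) {
      cell <- trimws(cells[cc$idx])
      if (!nzchar(cell)) next
      operand <- if (cc$operator == "in_range") {
        lohi <- suppressWarnings(as.numeric(strsplit(cell, ",")[[1]]))
        if (length(lohi) != 2 || anyNA(lohi) || lohi[1] >= lohi[2]) {
          stop_hai("%s row %d: bad in_range operand '%s'", path, r, cell)
        }
        lohi
      } else {
        v <- suppressWarnings(as.numeric(cell))
        if (is.na(v)) stop_hai("%s row %d: non-numeric operand '%s'", path, r, cell)
        if (cc$kind == "binary" && !v %in% c(0, 1)) {
          stop_hai("%s row %d: binary operand must be 0 or 1", path, r)
        }
        v
      }
      conds[[length(conds) + 1]] <- new_condition(cc$factor_id, cc$operator, operand)
    }
    if (length(conds) == 0) {
      stop_hai("%s row %d (rule %s): all condition cells blank", path, r, rid)
    }
    rules[[rid]] <- new_rule(rid, diagnosis_code, site_code, source, conds, pr)
    prov[[rid]] <- data.frame(rule_id = rid, file = basename(path), row = r,
                              source = source, authored = authored,
                              stringsAsFactors = FALSE)
  }
  structure(list(ruleset_name = ruleset_name, diagnosis_code = diagnosis_code,
                 site_code = site_code, source = source, authored = authored,
                 columns = cond_cols, rules = unname(rules),
                 provenance = do.call(rbind, unname(prov))),
            class = "hai_decision_table")
}

#' Load a rule base from one or more decision tables
#'
#' @param paths character vector of decision-table files, or a directory
#'   containing them. Defaults to the packaged exemplar tables.
#' @param registry,catalog see [parse_decision_table()].
#' @return Object of class `hai_rulebase`: list with `rules` (flat list of
#'   rules) and `provenance` (`data.frame`: rule_id, file, row, source,
#'   authored).
#' @examples
#' rb <- load_rule_base()
#' length(rb$rules)
#' table(vapply(rb$rules, `[[`, "", "source"))
#' @export
load_rule_base <- function(paths = hais_extdata("rules"),
                           registry = load_registry(),
                           catalog = load_catalog()) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- sort(list.files(paths, pattern = "\\.csv$", full.names = TRUE))
  }
  if (length(paths) == 0) stop_hai("no decision-table files given")
  tables <- lapply(paths, parse_decision_table, registry = registry,
                   catalog = catalog)
  rules <- do.call(c, lapply(tables, `[[`, "rules"))
  prov <- do.call(rbind, lapply(tables, `[[`, "provenance"))
  ids <- vapply(rules, `[[`, "", "rule_id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop_hai("duplicate rule id across tables: %s", dup[1])
  rules <- rules[order(ids)]
  rownames(prov) <- NULL
  structure(list(rules = rules, provenance = prov[order(prov$rule_id), ]),
            class = "hai_rulebase")
}

#' @export
print.hai_rulebase <- function(x, ...) {
  src <- vapply(x$rules, `[[`, "", "source")
  cat(sprintf("<hai_rulebase> %d rules (%d guideline, %d expert)\n",
              length(x$rules), sum(src == "guideline"), sum(src == "expert")))
  invisible(x)
}

#' Cross-validate a rule base against catalog and registry
#'
#' Pure check, mirrors [validate_case()]: issues are returned, not raised.
#' Reported issues: unknown diagnosis, diagnosis/site mismatch, unknown
#' factor, operator incompatible with factor kind, probability outside
#' (0, 1], duplicate rule ids.
#'
#' @param rule_base a `hai_rulebase`.
#' @param catalog a `hai_catalog`.
#' @param registry a `hai_registry`.
#' @return `data.frame(where, issue)`; zero rows on a clean base.
#' @export
validate_rule_base <- function(rule_base, catalog = load_catalog(),
                               registry = load_registry()) {
  issues <- issue_df()
  ids <- vapply(rule_base$rules, `[[`, "", "rule_id")
  for (d in unique(ids[duplicated(ids)])) {
    issues <- bind_issues(issues, issue_df(d, "duplicate rule id"))
  }
  for (rule in rule_base$rules) {
    w <- rule$rule_id
    if (!rule$diagnosis_code %in% catalog$table$diagnosis_code) {
      issues <- bind_issues(issues, issue_df(
        w, sprintf("unknown diagnosis '%s'", rule$diagnosis_code)))
    } else if (site_of(catalog, rule$diagnosis_code) != rule$site_code) {
      issues <- bind_issues(issues, issue_df(
        w, sprintf("diagnosis '%s' does not belong to site '%s'",
                   rule$diagnosis_code, rule$site_code)))
    }
    if (rule$probability <= 0 || rule$probability > 1) {
      issues <- bind_issues(issues, issue_df(w, "probability outside (0, 1]"))
    }
    for (cond in rule$conditions) {
      reg <- registry_row(registry, cond$factor_id)
      if (is.null(reg)) {
        issues <- bind_issues(issues, issue_df(
          w, sprintf("unknown factor '%s'", cond$factor_id)))
        next
      }
      bad <- (cond$operator == "in_range" && !reg$kind %in% c("integer", "real")) ||
        (reg$kind == "binary" && !cond$operator %in% c("eq", "ne", "contains_flag")) ||
        (reg$kind == "date" && cond$operator %in% c("in_range", "contains_flag"))
      if (bad) {
        issues <- bind_issues(issues, issue_df(
          w, sprintf("operator '%s' incompatible with %s factor '%s'",
                     cond$operator, reg$kind, cond$factor_id)))
      }
    }
  }
  rownames(issues) <- NULL
  issues
}

#' Restrict a rule base to an evaluation scenario
#'
#' Two scenarios are compared throughout: rules derived from clinical
#' guidelines only, or guideline rules supplemented with rules from experts'
#' common understanding.
#'
#' @param rule_base a `hai_rulebase`.
#' @param scenario `"guideline_only"` or `"guideline_plus_expert"`.
#' @return A `hai_rulebase` containing the retained rules.
#' @export
filter_by_source <- function(rule_base,
                             scenario = c("guideline_plus_expert", "guideline_only")) {
  scenario <- match.arg(scenario)
  keep <- if (scenario == "guideline_only") {
    vapply(rule_base$rules, function(r) r$source == "guideline", TRUE)
  } else {
    rep(TRUE, length(rule_base$rules))
  }
  prov <- rule_base$provenance
  structure(list(rules = rule_base$rules[keep],
                 provenance = prov[prov$rule_id %in%
                                     vapply(rule_base$rules[keep], `[[`, "", "rule_id"),
                                   , drop = FALSE]),
            class = "hai_rulebase")
}

# ---- rule base JSON export -------------------------------------------------

rule_to_list <- function(rule) {
  list(rule_id = rule$rule_id, diagnosis_code = rule$diagnosis_code,
       site_code = rule$site_code, source = rule$source,
       probability = rule$probability,
       conditions = lapply(rule$conditions, function(cond) {
         list(factor_id = cond$factor_id, operator = cond$operator,
              operand = cond$operand)
       }))
}

#' Export / import a rule base as JSON
#'
#' The JSON form carries full rule semantics (conditions, probability, id,
#' source) and round-trips losslessly.
#'
#' @param rule_base a `hai_rulebase`.
#' @param path output (input) file path.
#' @return `write_rule_base()` returns `path` invisibly; `read_rule_base()`
#'   returns a `hai_rulebase`.
#' @export
write_rule_base <- function(rule_base, path) {
  obj <- list(rules = lapply(rule_base$rules, rule_to_list),
              provenance = rule_base$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rule_base
#' @export
read_rule_base <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rules <- lapply(obj$rules, function(r) {
    conds <- lapply(r$conditions, function(cond) {
      new_condition(cond$factor_id, cond$operator, as.numeric(unlist(cond$operand)))
    })
    new_rule(r$rule_id, r$diagnosis_code, r$site_code, r$source, conds,
             as.numeric(r$probability))
  })
  prov <- do.call(rbind, lapply(obj$provenance, function(p) {
    data.frame(rule_id = p$rule_id, file = p$file, row = p$row,
               source = p$source, authored = isTRUE(p$authored),
               stringsAsFactors = FALSE)
  }))
  structure(list(rules = rules, provenance = prov), class = "hai_rulebase")
}
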