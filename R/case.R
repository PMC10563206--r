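# The eight-group case tuple and the factor registry.
#
# A case tuple describes one episode on one surveillance day through eight
# factor groups: DE demographics, PS hospitalization status, PN progress-note
# flags, IR imaging-report flags, VS vital signs, CL clinical laboratory,
# OP operations, MO medical orders. Binary factors encode suspicion
# (0 unsuspected / 1 suspected); numeric factors carry units; unmeasured
# numeric factors are absent (missing), which is distinct from 0.

#' The eight case-tuple group codes
#' @return Character vector `c("DE","PS","PN","IR","VS","CL","OP","MO")`.
#' @export
case_groups <- function() c("DE", "PS", "PN", "IR", "VS", "CL", "OP", "MO")

#' Load the factor registry
#'
#' The registry declares every known infection factor: its identifier, kind
#' (`integer`, `real`, `date` or `binary`), measurement unit (empty where
#' dimensionless) and owning tuple group. Rules may only reference registered
#' factors; unknown factors in a case are reported as validation issues, not
#' errors, so the engine degrades gracefully on unexpected data.
#'
#' @param path YAML registry file; defaults to the packaged registry.
#' @return Object of class `hai_registry`: a `data.frame` with columns
#'   `id`, `kind`, `unit`, `group`, `description`.
#' @export
load_registry <- function(path = hais_extdata("factor_registry.yaml")) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$factors)) stop_hai("registry file has no 'factors' key: %s", path)
  df <- do.call(rbind, lapply(raw$factors, function(f) {
    data.frame(id = as.character(f$id), kind = as.character(f$kind),
               unit = as.character(f$unit %||% ""),
               group = as.character(f$group),
               description = as.character(f$description %||% ""),
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  dup <- df$id[duplicated(df$id)]
  if (length(dup)) stop_hai("duplicate factor id in registry: %s", dup[1])
  bad_kind <- setdiff(unique(df$kind), c("integer", "real", "date", "binary"))
  if (length(bad_kind)) stop_hai("unknown factor kind in registry: %s", bad_kind[1])
  bad_grp <- setdiff(unique(df$group), case_groups())
  if (length(bad_grp)) stop_hai("unknown tuple group in registry: %s", bad_grp[1])
  structure(df, class = c("hai_registry", "data.frame"))
}

registry_row <- function(registry, factor_id) {
  i <- match(factor_id, registry$id)
  if (is.na(i)) return(NULL)
  registry[i, , drop = FALSE]
}

#' Construct a case tuple
#'
#' @param patient_id,episode_id identifiers.
#' @param as_of_date the surveillance day this tuple describes (`Date`).
#' @param groups named list with exactly the keys [case_groups()]; each entry
#'   a named list mapping factor id to a factor value as produced by
#'   [factor_value()]. Missing groups are filled with empty maps.
#' @return Object of class `hai_case`.
#' @export
new_case <- function(patient_id, episode_id, as_of_date, groups = list()) {
  g <- setNames(vector("list", length(case_groups())), case_groups())
  for (k in case_groups()) g[[k]] <- groups[[k]] %||% list()
  extra <- setdiff(names(groups), case_groups())
  if (length(extra)) stop_hai("unknown case group: %s", extra[1])
  structure(list(patient_id = as.character(patient_id),
                 episode_id = as.character(episode_id),
                 as_of_date = hai_date(as_of_date),
                 groups = g),
            class = "hai_case")
}

#' Construct a typed factor value
#'
#' @param factor_id registered factor identifier.
#' @param kind one of `"integer"`, `"real"`, `"date"`, `"binary"`.
#' @param value the value (`0`/`1` for binary; a `Date`/`POSIXct` for date).
#' @param unit measurement unit string (may be empty).
#' @return A list with class `hai_factor`.
#' @export
factor_value <- function(factor_id, kind, value, unit = "") {
  structure(list(factor_id = as.character(factor_id), kind = kind,
                 value = value, unit = unit),
            class = "hai_factor")
}

#' Look up a factor value in a case tuple
#'
#' @param case a `hai_case`.
#' @param factor_id factor identifier.
#' @return The raw value, or `NULL` when the factor is not present
#'   (missing / unmeasured).
#' @export
case_factor <- function(case, factor_id) {
  for (g in case$groups) {
    f <- g[[factor_id]]
    if (!is.null(f)) return(f$value)
  }
  NULL
}

#' @export
print.hai_case <- function(x, ...) {
  n <- sum(vapply(x$groups, length, 0L))
  cat(sprintf("<hai_case> %s / %s @ %s: %d factors\n", x$patient_id,
              x$episode_id, fmt_date(x$as_of_date), n))
  invisible(x)
}

#' Validate a case tuple against the factor registry
#'
#' Pure check: returns a (possibly empty) issue table instead of raising.
#' Checks performed: all eight group keys present; every factor registered;
#' every factor in its declared group; value type matches the declared kind
#' (binary values exactly 0 or 1, numeric kinds numeric, dates calendar
#' timestamps); no factor id appears in more than one group; PS carries
#' `admission_datetime` and a `hospital_days` of at least 1. Repeated calls
#' return identical results (idempotent, side-effect free).
#'
#' @param case a `hai_case`.
#' @param registry a `hai_registry`.
#' @return `data.frame` with columns `where`, `issue`; zero rows when the
#'   case is fully conformant.
#' @export
validate_case <- function(case, registry) {
  issues <- issue_df()
  if (!inherits(case, "hai_case")) {
    return(issue_df("case", "not a hai_case object"))
  }
  missing_groups <- setdiff(case_groups(), names(case$groups))
  for (mg in missing_groups) {
    issues <- bind_issues(issues, issue_df(mg, "missing group"))
  }
  seen <- character()
  for (gname in intersect(names(case$groups), case_groups())) {
    grp <- case$groups[[gname]]
    for (fid in names(grp)) {
      f <- grp[[fid]]
      if (fid %in% seen) {
        issues <- bind_issues(issues, issue_df(fid, "factor in more than one group"))
      }
      seen <- c(seen, fid)
      reg <- registry_row(registry, fid)
      if (is.null(reg)) {
        issues <- bind_issues(issues, issue_df(fid, "unregistered factor"))
        next
      }
      if (reg$group != gname) {
        issues <- bind_issues(issues, issue_df(
          fid, sprintf("factor in group %s but registered under %s", gname, reg$group)))
      }
      v <- f$value
      ok <- switch(reg$kind,
        binary  = is_binary01(v),
        integer = is.numeric(v) && length(v) == 1 && !is.na(v) && v == round(v),
        real    = is.numeric(v) && length(v) == 1 && !is.na(v),
        date    = inherits(v, "Date") || inherits(v, "POSIXct"))
      if (!ok) {
        what <- if (reg$kind == "binary") "binary out of domain"
                else sprintf("value does not match declared kind '%s'", reg$kind)
        issues <- bind_issues(issues, issue_df(fid, what))
      }
    }
  }
  ps <- case$groups$PS %||% list()
  if (is.null(ps$admission_datetime)) {
    issues <- bind_issues(issues, issue_df("PS.admission_datetime", "required factor absent"))
  }
  hd <- ps$hospital_days$value
  if (is.null(hd)) {
    issues <- bind_issues(issues, issue_df("PS.hospital_days", "required factor absent"))
  } else if (is.numeric(hd) && !is.na(hd) && hd < 1) {
    issues <- bind_issues(issues, issue_df("PS.hospital_days", "must be >= 1"))
  }
  rownames(issues) <- NULL
  issues
}

# ---- case serialization (JSON lines) ---------------------------------------

case_to_list <- function(case) {
  groups <- lapply(case$groups, function(grp) {
    if (length(grp)) grp <- grp[order(names(grp))]
    lapply(grp, function(f) {
      v <- f$value
      if (inherits(v, "Date")) v <- fmt_date(v)
      if (inherits(v, "POSIXct")) v <- fmt_time(v)
      list(kind = f$kind, value = v, unit = f$unit)
    })
  })
  list(patient_id = case$patient_id, episode_id = case$episode_id,
       as_of_date = fmt_date(case$as_of_date), groups = groups)
}

case_from_list <- function(x) {
  groups <- lapply(x$groups, function(grp) {
    out <- lapply(names(grp), function(fid) {
      f <- grp[[fid]]
      v <- f$value
      if (f$kind == "date") v <- hai_time(v)
      factor_value(fid, f$kind, v, f$unit %||% "")
    })
    setNames(out, names(grp))
  })
  new_case(x$patient_id, x$episode_id, x$as_of_date, groups)
}

#' Write / read case tuples as JSON lines
#'
#' One JSON object per line per case tuple, with factors sorted by id within
#' each group so that identical inputs always serialize byte-identically.
#'
#' @param cases list of `hai_case` objects.
#' @param path output (input) file path.
#' @return `write_cases()` returns `path` invisibly; `read_cases()` returns a
#'   list of `hai_case` objects.
#' @export
write_cases <- function(cases, path) {
  lines <- vapply(cases, function(cs) {
    as.character(jsonlite::toJSON(case_to_list(cs), auto_unbox = TRUE, digits = NA))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_cases
#' @export
read_cases <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(l) case_from_list(jsonlite::fromJSON(l, simplifyVector = FALSE)))
}
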