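# Infection catalog: the fixed taxonomy of infection sites and diagnoses that
# rules, warnings, gold labels and evaluation strata all refer to.

#' Load an infection catalog
#'
#' Reads a catalog of infection sites and their diagnoses from a YAML (or
#' JSON) file and validates it: site codes must be distinct, diagnosis codes
#' must be distinct, and every diagnosis belongs to exactly one site. The
#' packaged default catalog (`hais_extdata("catalog.yaml")`) covers the 40
#' infection diagnoses in 12 infection sites used throughout the package,
#' from upper respiratory tract infection (UR) under RTI to unconfirmed
#' other infections (OTH).
#'
#' @param path path to a catalog file. Defaults to the packaged catalog.
#' @return An object of class `hai_catalog`: a list with element `sites`
#'   (each site a list with `code`, `name`, `diagnoses`), plus a flat
#'   `data.frame` lookup in element `table` with columns `site_code`,
#'   `site_name`, `diagnosis_code`, `diagnosis_name`.
#' @seealso [diagnoses_for_site()], [site_of()], [write_catalog()]
#' @examples
#' cat <- load_catalog()
#' length(cat$sites)                  # 12
#' nrow(cat$table)                    # 40
#' diagnoses_for_site(cat, "RTI")
#' @export
load_catalog <- function(path = hais_extdata("catalog.yaml")) {
  if (!file.exists(path)) stop_hai("catalog file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$sites)) stop_hai("catalog file has no 'sites' key: %s", path)
  sites <- lapply(raw$sites, function(s) {
    if (is.null(s$code) || !nzchar(s$code)) stop_hai("catalog site without a code")
    diagnoses <- lapply(s$diagnoses %||% list(), function(d) {
      if (is.null(d$code) || !nzchar(d$code)) {
        stop_hai("diagnosis without a code under site '%s'", s$code)
      }
      list(code = as.character(d$code), name = as.character(d$name %||% d$code))
    })
    list(code = as.character(s$code), name = as.character(s$name %||% s$code),
         diagnoses = diagnoses)
  })
  site_codes <- vapply(sites, `[[`, "", "code")
  dup <- site_codes[duplicated(site_codes)]
  if (length(dup)) stop_hai("duplicate site code in catalog: %s", dup[1])
  rows <- do.call(rbind, lapply(sites, function(s) {
    if (length(s$diagnoses) == 0) return(NULL)
    data.frame(site_code = s$code, site_name = s$name,
               diagnosis_code = vapply(s$diagnoses, `[[`, "", "code"),
               diagnosis_name = vapply(s$diagnoses, `[[`, "", "name"),
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  dup <- rows$diagnosis_code[duplicated(rows$diagnosis_code)]
  if (length(dup)) stop_hai("duplicate diagnosis code in catalog: %s", dup[1])
  structure(list(sites = sites, table = rows), class = "hai_catalog")
}

#' @export
print.hai_catalog <- function(x, ...) {
  cat(sprintf("<hai_catalog> %d sites, %d diagnoses\n",
              length(x$sites), nrow(x$table)))
  for (s in x$sites) {
    cat(sprintf("  %-6s %s: %s\n", s$code, s$name,
                paste(vapply(s$diagnoses, `[[`, "", "code"), collapse = ", ")))
  }
  invisible(x)
}

#' Write a catalog back to YAML
#'
#' Serialization is the exact inverse of [load_catalog()]: a written catalog
#' loads back identical (round-trip property).
#'
#' @param catalog a `hai_catalog`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "hai_catalog"))
  yaml::write_yaml(list(sites = catalog$sites), path)
  invisible(path)
}

#' Diagnosis codes belonging to an infection site
#'
#' @param catalog a `hai_catalog`.
#' @param site_code site code, e.g. `"RTI"`.
#' @return Character vector of diagnosis codes.
#' @examples
#' diagnoses_for_site(load_catalog(), "RTI")  # UR, LRI, PCI, VAP
#' @export
diagnoses_for_site <- function(catalog, site_code) {
  stopifnot(inherits(catalog, "hai_catalog"))
  if (!site_code %in% catalog$table$site_code) {
    stop_hai("unknown site code: %s", site_code)
  }
  catalog$table$diagnosis_code[catalog$table$site_code == site_code]
}

#' Infection site of a diagnosis
#'
#' Total and unique over the packaged catalog: every diagnosis code maps to
#' exactly one site.
#'
#' @param catalog a `hai_catalog`.
#' @param diagnosis_code diagnosis code(s), e.g. `"LRI"`.
#' @return Character vector of site codes, same length as `diagnosis_code`.
#' @export
site_of <- function(catalog, diagnosis_code) {
  stopifnot(inherits(catalog, "hai_catalog"))
  idx <- match(diagnosis_code, catalog$table$diagnosis_code)
  if (anyNA(idx)) {
    stop_hai("unknown diagnosis code: %s",
             paste(diagnosis_code[is.na(idx)], collapse = ", "))
  }
  catalog$table$site_code[idx]
}

# ---- gold labels -----------------------------------------------------------

#' Read gold-standard infection labels
#'
#' Gold labels play the role of reviewed infection reporting cards: one row
#' per episode stating whether the episode acquired an HAI and, if so, the
#' confirmed diagnosis, site and onset time, plus the reporting month used
#' for monthly evaluation strata.
#'
#' @param path CSV with header `patient_id, episode_id, infected,
#'   diagnosis_code, site_code, onset_datetime, report_month`.
#' @param catalog optional `hai_catalog`; when given, infected rows are
#'   checked to carry a diagnosis that belongs to the stated site.
#' @return `data.frame` with typed columns (`infected` integer 0/1,
#'   `onset_datetime` POSIXct or NA).
#' @export
load_gold_labels <- function(path, catalog = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  needed <- c("patient_id", "episode_id", "infected", "diagnosis_code",
              "site_code", "onset_datetime", "report_month")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop_hai("gold label file missing column(s): %s",
             paste(missing_cols, collapse = ", "))
  }
  df$infected <- as.integer(df$infected)
  df$diagnosis_code[!nzchar(df$diagnosis_code)] <- NA_character_
  df$site_code[!nzchar(df$site_code)] <- NA_character_
  df$onset_datetime <- ifelse(nzchar(df$onset_datetime), df$onset_datetime, NA)
  df$onset_datetime <- hai_time(df$onset_datetime)
  validate_gold_labels(df, catalog)
  df
}

validate_gold_labels <- function(gold, catalog = NULL) {
  bad <- gold$infected == 1 &
    (is.na(gold$diagnosis_code) | is.na(gold$site_code) | is.na(gold$onset_datetime))
  if (any(bad)) {
    stop_hai("infected gold label without diagnosis/site/onset: episode %s",
             gold$episode_id[bad][1])
  }
  if (!is.null(catalog)) {
    inf <- gold[gold$infected == 1, , drop = FALSE]
    if (nrow(inf)) {
      expect_site <- site_of(catalog, inf$diagnosis_code)
      off <- expect_site != inf$site_code
      if (any(off)) {
        stop_hai("gold label site '%s' does not own diagnosis '%s' (episode %s)",
                 inf$site_code[off][1], inf$diagnosis_code[off][1],
                 inf$episode_id[off][1])
      }
    }
  }
  invisible(gold)
}

#' Write gold labels to CSV
#'
#' @param gold data.frame as returned by [load_gold_labels()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_gold_labels <- function(gold, path) {
  out <- gold
  out$onset_datetime <- ifelse(is.na(out$onset_datetime), "",
                               fmt_time(out$onset_datetime))
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
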