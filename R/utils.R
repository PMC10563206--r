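# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# All timestamps in the package are timezone-naive calendar times; they are
# represented as POSIXct in UTC so arithmetic is never DST-dependent.
hai_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (inherits(x, "Date")) return(as.POSIXct(as.character(x), tz = "UTC"))
  x <- as.character(x)
  # per-element parsing: a malformed value becomes NA instead of aborting
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (f in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M:%OS",
              "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    idx <- which(is.na(out) & !is.na(x) & nzchar(x))
    if (length(idx) == 0) break
    out[idx] <- as.POSIXct(strptime(x[idx], f, tz = "UTC"))
  }
  out
}

hai_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  if (inherits(x, "POSIXct")) return(as.Date(x, tz = "UTC"))
  as.Date(as.character(x))
}

fmt_time <- function(x) format(hai_time(x), "%Y-%m-%d %H:%M:%S", tz = "UTC")
fmt_date <- function(x) format(hai_date(x), "%Y-%m-%d")

# month key "YYYY-MM" for a date/datetime
month_key <- function(x) format(hai_date(x), "%Y-%m")

# uniform issue record used by the validators: zero-row on success
issue_df <- function(where = character(), issue = character()) {
  data.frame(where = as.character(where), issue = as.character(issue),
             stringsAsFactors = FALSE)
}

bind_issues <- function(...) {
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (length(parts) == 0) return(issue_df())
  do.call(rbind, parts)
}

stop_hai <- function(...) stop(sprintf(...), call. = FALSE)

# case-fold + collapse runs of whitespace; the canonical form used for all
# keyword matching
normalize_text <- function(x) {
  x <- tolower(x)
  gsub("[[:space:]]+", " ", x)
}

is_binary01 <- function(v) is.numeric(v) && length(v) == 1 && !is.na(v) && v %in% c(0, 1)

#' Path to a packaged configuration or fixture file
#'
#' Convenience wrapper around [base::system.file()] for the data files shipped
#' with the package: the infection catalog, factor registry, keyword lexicon
#' and exemplar decision tables under `extdata/`.
#'
#' @param ... path components below `inst/extdata`, e.g. `"rules"`,
#'   `"pci_guideline.csv"`. With no arguments, returns the `extdata` directory.
#' @return Absolute file path (empty string if the file does not exist).
#' @examples
#' hais_extdata("catalog.yaml")
#' list.files(hais_extdata("rules"))
#' @export
hais_extdata <- function(...) {
  system.file("extdata", ..., package = "haisentry")
}
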