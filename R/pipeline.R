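# Pipeline orchestration: simulate -> extract -> infer -> evaluate ->
# update-confidence, each stage reading its predecessor's on-disk artifact
# and writing new files into the run directory, plus a manifest for
# reproducibility audits. Used directly or through the command-line wrapper
# in `inst/cli/hais-cli.R`.

stop_missing <- function(...) {
  stop(structure(class = c("hai_missing_artifact", "error", "condition"),
                 list(message = sprintf(...), call = NULL)))
}

#' Assemble a run configuration
#'
#' @param out_dir run directory; all stage artifacts are written here.
#' @param seed integer seed for the simulate stage.
#' @param cohort list of arguments for [cohort_spec()] (the seed is taken
#'   from `seed`).
#' @param engine list of arguments for [engine_config()].
#' @param scenario rule-base scenario.
#' @param catalog_path,registry_path,lexicon_path,rules_path configuration
#'   file paths; defaults are the packaged files.
#' @return Object of class `hai_run_config`.
#' @export
run_config <- function(out_dir, seed = 1, cohort = list(), engine = list(),
                       scenario = c("guideline_plus_expert", "guideline_only"),
                       catalog_path = hais_extdata("catalog.yaml"),
                       registry_path = hais_extdata("factor_registry.yaml"),
                       lexicon_path = hais_extdata("lexicon.yaml"),
                       rules_path = hais_extdata("rules")) {
  scenario <- match.arg(scenario)
  for (p in c(catalog_path, registry_path, lexicon_path, rules_path)) {
    if (!file.exists(p)) stop_hai("configuration file not found: %s", p)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), cohort = cohort,
                 engine = engine, scenario = scenario,
                 catalog_path = catalog_path, registry_path = registry_path,
                 lexicon_path = lexicon_path, rules_path = rules_path),
            class = "hai_run_config")
}

#' Run the surveillance pipeline
#'
#' Executes the requested stages in order. Each stage reads its
#' predecessor's artifact from the run directory (so stages can be run in
#' separate invocations) and never mutates its inputs; rerunning with
#' identical inputs reproduces identical artifacts. A `manifest.json` with
#' the configuration, seed, per-stage counts and artifact checksums is
#' (re)written after every invocation.
#'
#' Stages and artifacts:
#' * `simulate`: synthetic cohort -> `records/*.csv`, `gold.csv`
#' * `extract`: case tuples -> `cases.jsonl`
#' * `infer`: warnings -> `warnings.csv`
#' * `evaluate`: stratified reports -> `eval_month.csv`, `eval_diagnosis.csv`,
#'   `eval_site.csv` (+ `.json`)
#' * `update_confidence`: monthly feedback -> `feedback.csv`,
#'   `confidence.json`
#'
#' @param config a `hai_run_config`.
#' @param stages subset of
#'   `c("simulate", "extract", "infer", "evaluate", "update_confidence")`.
#' @return Invisibly, a list with the manifest and the per-stage outputs.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "extract", "infer",
                                    "evaluate", "update_confidence")) {
  stopifnot(inherits(config, "hai_run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  catalog <- load_catalog(config$catalog_path)
  registry <- load_registry(config$registry_path)
  lexicon <- load_lexicon(config$lexicon_path, registry)
  rule_base <- load_rule_base(config$rules_path, registry, catalog)
  rb_issues <- validate_rule_base(rule_base, catalog, registry)
  if (nrow(rb_issues)) {
    stop_hai("rule base failed validation: %s (%s)", rb_issues$where[1],
             rb_issues$issue[1])
  }
  counts <- list()
  out <- list()

  path_of <- function(...) file.path(config$out_dir, ...)

  if ("simulate" %in% stages) {
    spec <- do.call(cohort_spec, modifyList(config$cohort, list(seed = config$seed)))
    cohort <- generate_cohort(spec, rule_base, catalog, lexicon, registry)
    write_records(cohort$records, path_of("records"))
    write_gold_labels(cohort$gold, path_of("gold.csv"))
    counts$simulate <- c(episodes = nrow(cohort$gold),
                         infected = sum(cohort$gold$infected))
    out$cohort <- cohort
  }

  if ("extract" %in% stages) {
    if (!dir.exists(path_of("records"))) {
      stop_missing("missing records input: run the simulate stage first")
    }
    records <- read_records(path_of("records"))
    cases <- build_cases(records, lexicon, registry)
    write_cases(cases, path_of("cases.jsonl"))
    counts$extract <- c(cases = length(cases),
                        record_issues = nrow(attr(records, "issues") %||% issue_df()))
    out$cases <- cases
  }

  if ("infer" %in% stages) {
    if (!file.exists(path_of("cases.jsonl"))) {
      stop_missing("missing cases input: run the extract stage first")
    }
    cases <- read_cases(path_of("cases.jsonl"))
    eng <- do.call(engine_config,
                   modifyList(config$engine, list(scenario = config$scenario)))
    warnings <- run_surveillance(cases, rule_base, eng)
    write_warnings(warnings, path_of("warnings.csv"))
    counts$infer <- attr(warnings, "counts")
    out$warnings <- warnings
  }

  if ("evaluate" %in% stages) {
    for (need in c("warnings.csv", "gold.csv")) {
      if (!file.exists(path_of(need))) {
        stop_missing("missing %s input for evaluation", need)
      }
    }
    warnings <- read_warnings(path_of("warnings.csv"))
    gold <- load_gold_labels(path_of("gold.csv"), catalog)
    warn_set <- setNames(list(warnings), config$scenario)
    for (by in c("month", "diagnosis", "site")) {
      rep_by <- stratified_report(warn_set, gold, by = by)
      write_eval_report(rep_by, path_of(sprintf("eval_%s.csv", by)))
      write_eval_report(rep_by, path_of(sprintf("eval_%s.json", by)))
      out[[paste0("eval_", by)]] <- rep_by
    }
    overall <- score_episode_level(warnings, gold)
    counts$evaluate <- unlist(overall)
  }

  if ("update_confidence" %in% stages) {
    for (need in c("warnings.csv", "gold.csv")) {
      if (!file.exists(path_of(need))) {
        stop_missing("missing %s input for confidence update", need)
      }
    }
    warnings <- read_warnings(path_of("warnings.csv"))
    gold <- load_gold_labels(path_of("gold.csv"), catalog)
    batch <- feedback_from_gold(warnings, gold)
    write_feedback(batch, path_of("feedback.csv"))
    state <- confidence_state(rule_base)
    for (m in unique(batch$month)) {
      state <- monthly_update(state, batch[batch$month == m, , drop = FALSE])
    }
    write_confidence_state(state, path_of("confidence.json"))
    counts$update_confidence <- c(months = length(unique(batch$month)),
                                  rules_updated = length(unique(batch$rule_id)))
    out$confidence <- state
  }

  artifacts <- sort(setdiff(list.files(config$out_dir, recursive = TRUE),
                            "manifest.json"))
  manifest <- list(
    seed = config$seed,
    scenario = config$scenario,
    stages = stages,
    inputs = list(catalog = config$catalog_path,
                  registry = config$registry_path,
                  lexicon = config$lexicon_path,
                  rules = config$rules_path),
    config_hash = unname(tools::md5sum(
      vapply(c(config$catalog_path, config$registry_path, config$lexicon_path),
             identity, ""))),
    counts = lapply(counts, as.list),
    artifacts = as.list(setNames(
      unname(tools::md5sum(file.path(config$out_dir, artifacts))), artifacts)),
    package_version = as.character(utils::packageVersion("haisentry")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out$manifest <- manifest
  invisible(out)
}
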