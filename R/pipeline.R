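#' Configuration for an end-to-end pipeline run
#'
#' Collects input paths, the strata to run, the signal thresholds (the
#' defaults are the standard dual criterion: lower ROR bound > 1, IC025 >
#' 0, at least 3 cases) and output options for [run_pipeline()].
#'
#' @param reports Path to a report TSV (see [read_reports()]).
#' @param smq Path to a plain-text event term list (see [read_smq()]).
#' @param ki Path to the long Ki table (see [read_ki_table()]).
#' @param props Path to the drug properties table
#'   (see [read_drug_properties()]).
#' @param out_dir Output directory (created if absent).
#' @param drugs Drugs to analyse; default: all drugs in the Ki/properties
#'   tables.
#' @param strata Strata for the disproportionality stage.
#' @param battery_strata Strata for the correlation battery (the age 65+
#'   stratum is excluded by default; see [run_battery()]).
#' @param min_cases Minimum exposed-case count for a reportable row.
#' @param zero_cell_correction See [compute_ror()].
#' @param scatter_predictors Predictor names to export as scatter tables;
#'   default none.
#' @param digits Decimals used in the rendered report tables (full
#'   precision is always kept in the raw outputs).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(reports, smq, ki, props, out_dir,
                            drugs = NULL,
                            strata = stratum_levels,
                            battery_strata = c("total", "female", "male"),
                            min_cases = 3,
                            zero_cell_correction = FALSE,
                            scatter_predictors = character(0),
                            digits = 2) {
  for (p in c(reports, smq, ki, props)) {
    if (!file.exists(p)) abort(sprintf("input file not found: %s", p))
  }
  structure(
    list(reports = reports, smq = smq, ki = ki, props = props,
         out_dir = out_dir, drugs = drugs, strata = strata,
         battery_strata = battery_strata, min_cases = min_cases,
         zero_cell_correction = zero_cell_correction,
         scatter_predictors = scatter_predictors, digits = digits),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Reads the report table, deduplicates, builds case views against the
#' event term set, runs the per-drug per-stratum disproportionality
#' analysis, builds the pharmacology matrix, runs the drug-level
#' correlation battery, optionally exports scatter tables, and writes
#' everything plus a run manifest (row counts at every filter step, config
#' hash) to `out_dir`. The pipeline is deterministic: re-running with the
#' same inputs produces byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with elements `disprop`, `battery`,
#'   `scatters`, `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) inform(sprintf(...))

  reports <- read_reports(config$reports)
  say("read %d report rows from %s", nrow(reports), config$reports)
  smq <- read_smq(config$smq)
  ki <- read_ki_table(config$ki)
  props <- read_drug_properties(config$props)

  deduped <- deduplicate(reports, quiet = quiet)
  say("after deduplication: %d rows (%d conflicting case(s) dropped)",
      nrow(deduped), attr(deduped, "dropped_cases"))
  suspect_rows <- filter_suspect_roles(deduped)
  say("suspect-role rows: %d", nrow(suspect_rows))

  cv <- build_case_views(deduped, smq)
  say("case views: %d cases, %d (%.2f%%) matching '%s'",
      nrow(cv), sum(cv$is_smq_case), 100 * mean(cv$is_smq_case), smq$name)

  drugs <- config$drugs %||% sort(intersect(unique(suspect_rows$drug), props$drug))
  disprop <- run_disproportionality(
    cv, drugs = drugs, strata = config$strata,
    min_cases = config$min_cases,
    zero_cell_correction = config$zero_cell_correction)
  pharm <- build_pharm_matrix(ki, props)
  battery <- run_battery(disprop, pharm, strata = config$battery_strata)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(config$out_dir, f)
  readr::write_tsv(tibble::as_tibble(disprop), path("disproportionality.tsv"), na = "")
  readr::write_tsv(tidy(disprop, digits = config$digits),
                   path("disproportionality_report.tsv"), na = "NA")
  readr::write_tsv(tibble::as_tibble(battery), path("correlation_battery.tsv"), na = "")
  readr::write_tsv(pharm, path("pharm_matrix.tsv"), na = "")

  scatters <- list()
  for (pred in config$scatter_predictors) {
    for (s in config$battery_strata) {
      sc <- tryCatch(export_scatter(disprop, pharm, pred, s),
                     error = function(e) NULL)
      if (is.null(sc)) next
      f <- sprintf("scatter_%s_%s.tsv", pred, s)
      readr::write_tsv(tibble::as_tibble(sc), path(f), na = "")
      scatters[[paste(pred, s, sep = "/")]] <- sc
    }
  }

  stratum_n <- attr(disprop, "stratum_n")
  manifest <- list(
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    inputs = list(reports = config$reports, smq = config$smq,
                  ki = config$ki, props = config$props),
    counts = list(
      input_rows = nrow(reports),
      rows_after_dedup = nrow(deduped),
      dropped_conflicting_cases = attr(deduped, "dropped_cases"),
      suspect_role_rows = nrow(suspect_rows),
      n_cases = nrow(cv),
      n_smq_cases = sum(cv$is_smq_case),
      stratum_n = as.list(stratum_n)
    ),
    n_drugs = length(drugs),
    n_signals = sum(disprop$is_signal),
    battery_tests = nrow(battery),
    battery_significant = sum(battery$significant, na.rm = TRUE)
  )
  jsonlite::write_json(manifest, path("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("wrote outputs to %s", config$out_dir)
  invisible(list(disprop = disprop, battery = battery,
                 scatters = scatters, manifest = manifest))
}
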