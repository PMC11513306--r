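#' Standardised query term sets
#'
#' An `smq_termset` holds the reaction preferred terms that define the
#' clinical concept of interest (here, drug-related hepatic disorders).
#' Matching against case reactions is case-insensitive after whitespace
#' normalisation. `read_smq()` loads a plain-text list with one term per
#' line; blank lines and `#` comments are ignored.
#'
#' @param terms Character vector of preferred terms (non-empty).
#' @param name Label for the query.
#' @param path Path to a plain-text term list.
#' @return An `smq_termset` object.
#' @export
#' @examples
#' smq <- smq_termset(c("Hepatitis", "Liver injury"))
#' smq_match(c("HEPATITIS", "Nausea"), smq)
smq_termset <- function(terms, name = "drug-related hepatic disorders - comprehensive search") {
  if (!is.character(terms)) abort("`terms` must be a character vector")
  terms <- terms[!is.na(terms) & stringr::str_squish(terms) != ""]
  if (length(terms) == 0) abort("`terms` must contain at least one non-empty term")
  structure(
    list(name = name, terms = unique(terms),
         normalized = unique(normalize_term(terms))),
    class = "smq_termset"
  )
}

#' @rdname smq_termset
#' @export
read_smq <- function(path, name = NULL) {
  lines <- readr::read_lines(path)
  lines <- stringr::str_squish(sub("#.*$", "", lines))
  lines <- lines[lines != ""]
  smq_termset(lines, name = name %||% basename(path))
}

#' @export
print.smq_termset <- function(x, ...) {
  cat(sprintf("<smq_termset> %s: %d terms\n", x$name, length(x$terms)))
  invisible(x)
}

#' Membership of reaction terms in a term set
#'
#' @param x Character vector of reaction terms.
#' @param smq An [smq_termset()].
#' @return Logical vector: does each term belong to the query?
#' @export
smq_match <- function(x, smq) {
  stopifnot(inherits(smq, "smq_termset"))
  normalize_term(x) %in% smq$normalized
}

#' Deduplicate a report table
#'
#' Rows that are exact duplicates (identical case id, drug, role, reaction,
#' sex and age) collapse to a single row. A case id whose rows disagree on
#' sex or on age cannot be uniquely identified and is dropped entirely; the
#' number of dropped cases is recorded in the `dropped_cases` attribute and
#' reported as a message. Applying the operation twice equals applying it
#' once.
#'
#' @param reports Report tibble (see [read_reports()] for the schema).
#' @param quiet Suppress the dropped-case message.
#' @return Deduplicated report tibble with attribute `dropped_cases`.
#' @export
deduplicate <- function(reports, quiet = FALSE) {
  validate_reports(reports)
  out <- dplyr::distinct(reports)
  # NA counts as its own value: one row age 70 + one row age NA conflicts
  conflicts <- out |>
    dplyr::distinct(.data$case_id, .data$sex, .data$age_years) |>
    dplyr::count(.data$case_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflicts) > 0) {
    out <- dplyr::filter(out, !.data$case_id %in% conflicts$case_id)
    if (!quiet) {
      inform(sprintf(
        "deduplicate: dropped %d case(s) with conflicting sex or age",
        nrow(conflicts)))
    }
  }
  attr(out, "dropped_cases") <- nrow(conflicts)
  out
}

#' Keep only suspect-role drug rows
#'
#' Exposure in the case/non-case design is defined by drugs recorded as
#' primary or secondary suspect; concomitant and interacting rows are
#' removed. Cases whose rows are all non-suspect lose their drug rows here
#' but remain part of the background when case views are built from the
#' full table.
#'
#' @param reports Report tibble.
#' @return Tibble restricted to suspect-role rows.
#' @export
filter_suspect_roles <- function(reports) {
  validate_reports(reports)
  dplyr::filter(reports, .data$role %in% suspect_roles)
}

#' Collapse reports to one row per case
#'
#' Builds the case-level view that the disproportionality stage consumes:
#' one row per unique case id with its sex, age, whether any of its
#' reactions matches the term set (`is_smq_case`), and the set of drugs for
#' which the case is a primary or secondary suspect exposure
#' (`suspect_drugs`, a list-column; empty for background-only cases). The
#' event flag uses *all* reaction rows of the case, including rows whose
#' drug role is concomitant — role filtering restricts exposure, not the
#' reaction record.
#'
#' @param reports Deduplicated report tibble.
#' @param smq An [smq_termset()].
#' @return Tibble with columns `case_id`, `sex`, `age_years`,
#'   `is_smq_case`, `suspect_drugs`.
#' @export
#' @examples
#' rpt <- simulate_reports(sim_config(n_cases = 200, seed = 1))
#' cv <- build_case_views(deduplicate(rpt, quiet = TRUE),
#'                        smq_termset(hepatic_smq_example()))
#' mean(cv$is_smq_case)
build_case_views <- function(reports, smq) {
  validate_reports(reports)
  stopifnot(inherits(smq, "smq_termset"))
  # vectorised case collapse: demographics are constant within a case after
  # deduplication, so distinct() + membership tests replace a grouped
  # summarise (which is far slower at FAERS-like case counts)
  smq_flag <- smq_match(reports$reaction_pt, smq)
  cases <- dplyr::distinct(reports[, c("case_id", "sex", "age_years")])
  cases <- cases[!duplicated(cases$case_id), ]
  cases$is_smq_case <- cases$case_id %in% unique(reports$case_id[smq_flag])
  exposures <- reports |>
    dplyr::filter(.data$role %in% suspect_roles) |>
    dplyr::distinct(.data$case_id, .data$drug) |>
    tidyr::chop("drug") |>
    dplyr::rename(suspect_drugs = "drug")
  out <- dplyr::left_join(cases, exposures, by = "case_id")
  empty <- vapply(out$suspect_drugs, is.null, logical(1))
  if (any(empty)) out$suspect_drugs[empty] <- list(character(0))
  dplyr::arrange(out, .data$case_id)
}

#' Restrict case views to a subgroup
#'
#' Strata follow good signal detection practice subgroup recommendations:
#' `total` (everyone), `female` / `male` (sex-unknown cases excluded from
#' both), and `age_ge_65` (non-missing age of at least 65; missing ages are
#' excluded).
#'
#' @param case_views Output of [build_case_views()].
#' @param stratum One of `"total"`, `"female"`, `"male"`, `"age_ge_65"`.
#' @return Filtered case-view tibble.
#' @export
stratify <- function(case_views, stratum = c("total", "female", "male", "age_ge_65")) {
  stratum <- match.arg(stratum)
  switch(
    stratum,
    total = case_views,
    female = dplyr::filter(case_views, .data$sex == "female"),
    male = dplyr::filter(case_views, .data$sex == "male"),
    age_ge_65 = dplyr::filter(case_views, !is.na(.data$age_years) & .data$age_years >= 65)
  )
}
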