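#' Default per-drug exposure probabilities for the report simulator
#'
#' Nineteen FDA-approved antipsychotics with exposure probabilities chosen
#' so that widely prescribed drugs (quetiapine, olanzapine, aripiprazole,
#' risperidone, clozapine) dominate the exposed population while older or
#' rarely used drugs (loxapine, pimozide, thiothixene) contribute small
#' exposed groups, as in spontaneous reporting databases.
#'
#' @return Named numeric vector: drug name -> probability a case is exposed.
#' @export
default_drug_exposure <- function() {
  c(
    aripiprazole  = 0.020, asenapine    = 0.002, brexpiprazole = 0.004,
    cariprazine   = 0.003, chlorpromazine = 0.004, clozapine   = 0.015,
    fluphenazine  = 0.002, haloperidol  = 0.008, iloperidone   = 0.001,
    loxapine      = 0.002, lurasidone   = 0.006, olanzapine    = 0.020,
    paliperidone  = 0.007, perphenazine = 0.002, pimozide      = 0.001,
    quetiapine    = 0.025, risperidone  = 0.018, thiothixene   = 0.001,
    ziprasidone   = 0.005
  )
}

#' Default ground-truth reporting odds multipliers
#'
#' True per-drug reporting odds multipliers for the hepatic event, spanning
#' roughly 0.2 to 3.5 across the nineteen drugs so that both protective-
#' looking and elevated drugs are present, with risperidone elevated in the
#' female stratum only (a sex-specific signal for the stratified analysis
#' to recover).
#'
#' @return Named list: drug -> scalar odds multiplier, or a named numeric
#'   vector of per-stratum multipliers (see [sim_config()]).
#' @export
default_drug_theta <- function() {
  list(
    aripiprazole = 0.76, asenapine = 0.33, brexpiprazole = 0.20,
    cariprazine = 0.33, chlorpromazine = 2.59, clozapine = 0.77,
    fluphenazine = 1.63, haloperidol = 1.02, iloperidone = 0.17,
    loxapine = 2.74, lurasidone = 0.27, olanzapine = 1.76,
    paliperidone = 0.29, perphenazine = 1.24, pimozide = 1.14,
    quetiapine = 1.13, risperidone = c(female = 1.50, male = 0.60),
    thiothixene = 0.97, ziprasidone = 0.51
  )
}

#' Configuration for the FAERS-like report simulator
#'
#' Bundles and validates every knob of the synthetic individual-case-safety-
#' report generator. The defaults emulate the composition of a large
#' spontaneous reporting database restricted to an antipsychotic study set:
#' a hepatic-event background rate near 3% of cases, nineteen study drugs
#' with true reporting odds spanning 0.2-3.5 (one of them elevated only in
#' women), exact-duplicate case submissions, and a mix of suspect and
#' concomitant drug roles.
#'
#' @param n_cases Number of unique simulated cases (positive integer).
#' @param drugs Named numeric vector of per-drug exposure probabilities in
#'   \[0, 1\].
#' @param theta Named list mapping each drug to its true reporting odds
#'   multiplier (> 0). An element may be a single number (applies in every
#'   stratum) or a named numeric vector with any of the components
#'   `female`, `male`, `age_lt_65`, `age_ge_65`; matching components
#'   multiply, and a component that does not apply to a case (e.g. a sex
#'   component for a sex-unknown case) contributes a factor of 1.
#' @param background_event_rate Probability that a case with no suspect
#'   exposure to a study drug has a hepatic event.
#' @param duplicate_rate Probability that a case's rows are submitted twice
#'   verbatim (same case id; the deduplication stage's ground truth).
#' @param concomitant_rate Probability that an exposed study-drug row is
#'   recorded with the concomitant role instead of a suspect role.
#'   Concomitant exposures never multiply the event odds.
#' @param smq_terms Character vector of event reaction terms; a case with a
#'   hepatic event receives one of these. Defaults to
#'   [hepatic_smq_example()].
#' @param seed Integer RNG seed; identical config and seed give an
#'   identical report table.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_reports()]
#' @export
#' @examples
#' cfg <- sim_config(n_cases = 1000, seed = 42)
#' cfg$background_event_rate
sim_config <- function(n_cases = 200000,
                       drugs = default_drug_exposure(),
                       theta = default_drug_theta(),
                       background_event_rate = 0.03,
                       duplicate_rate = 0.05,
                       concomitant_rate = 0.20,
                       smq_terms = hepatic_smq_example(),
                       seed = 1L) {
  if (length(n_cases) != 1 || !is.numeric(n_cases) || !is.finite(n_cases) ||
      n_cases < 1 || n_cases != trunc(n_cases)) {
    stop_field("n_cases", "must be a single positive integer")
  }
  if (!is.numeric(drugs) || is.null(names(drugs)) || any(names(drugs) == "") ||
      anyDuplicated(names(drugs))) {
    stop_field("drugs", "must be a named numeric vector with unique drug names")
  }
  if (any(!is.finite(drugs)) || any(drugs < 0) || any(drugs > 1)) {
    stop_field("drugs", "exposure probabilities must be finite and in [0, 1]")
  }
  theta <- as.list(theta)
  if (is.null(names(theta)) || !all(names(theta) %in% names(drugs))) {
    stop_field("theta", "must be named and name only drugs present in `drugs`")
  }
  for (d in names(theta)) {
    th <- theta[[d]]
    if (!is.numeric(th) || any(!is.finite(th)) || any(th <= 0)) {
      stop_field("theta", sprintf("multipliers for '%s' must be finite and > 0", d))
    }
    if (length(th) > 1 || !is.null(names(th))) {
      ok <- c("female", "male", "age_lt_65", "age_ge_65")
      if (is.null(names(th)) || !all(names(th) %in% ok)) {
        stop_field("theta", sprintf(
          "per-stratum multipliers for '%s' must be named with %s",
          d, paste(ok, collapse = "/")))
      }
    }
  }
  check_prob(background_event_rate, "background_event_rate")
  if (background_event_rate >= 1) {
    stop_field("background_event_rate", "must be < 1 so odds are finite")
  }
  check_prob(duplicate_rate, "duplicate_rate")
  check_prob(concomitant_rate, "concomitant_rate")
  if (!is.character(smq_terms) || length(smq_terms) < 1) {
    stop_field("smq_terms", "must be a non-empty character vector")
  }
  if (length(seed) != 1 || !is.numeric(seed) || !is.finite(seed)) {
    stop_field("seed", "must be a single finite integer")
  }
  structure(
    list(
      n_cases = as.integer(n_cases), drugs = drugs, theta = theta,
      background_event_rate = background_event_rate,
      duplicate_rate = duplicate_rate, concomitant_rate = concomitant_rate,
      smq_terms = smq_terms, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Per-case effective log odds multiplier for one drug given its theta entry.
# Scalar entries apply everywhere; named entries multiply the components
# that match the case's sex / age stratum.
theta_log_by_case <- function(th, sex, age) {
  if (length(th) == 1 && is.null(names(th))) {
    return(rep(log(th), length(sex)))
  }
  out <- numeric(length(sex))
  if (!is.na(th["female"])) out <- out + ifelse(sex == "female", log(th[["female"]]), 0)
  if (!is.na(th["male"]))   out <- out + ifelse(sex == "male", log(th[["male"]]), 0)
  if (!is.na(th["age_lt_65"])) {
    out <- out + ifelse(!is.na(age) & age < 65, log(th[["age_lt_65"]]), 0)
  }
  if (!is.na(th["age_ge_65"])) {
    out <- out + ifelse(!is.na(age) & age >= 65, log(th[["age_ge_65"]]), 0)
  }
  out
}

#' Simulate a FAERS-like individual case safety report table
#'
#' Generates one row per case x drug x reaction triple. Each case draws a
#' sex (47.5% female, 47.5% male, 5% unknown), an age from a two-component
#' mixture placing about 20% of cases at 65 or older (8% of ages missing),
#' one background comparator drug, and independent exposures to each study
#' drug. Exposed study-drug rows are labelled concomitant with probability
#' `concomitant_rate`, otherwise primary (80%) or secondary (20%) suspect.
#' The case has a hepatic event with odds equal to the background odds
#' multiplied by the theta of every *suspect-role* study-drug exposure in
#' the case's stratum; concomitant exposures never raise the odds. Every
#' case receives one or two non-hepatic filler reactions; event cases
#' additionally receive one term from `smq_terms`. With probability
#' `duplicate_rate` all rows of a case are emitted twice verbatim.
#'
#' The RNG is R's default Mersenne-Twister (recorded in the `rng_kind`
#' attribute); a fixed config and seed reproduce the table exactly.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with columns `case_id`, `drug`, `role`, `reaction_pt`,
#'   `sex`, `age_years`, sorted deterministically; attribute `rng_kind`
#'   records the RNG algorithm.
#' @export
#' @examples
#' reports <- simulate_reports(sim_config(n_cases = 500, seed = 7))
#' dplyr::count(reports, role)
simulate_reports <- function(config) {
  if (!inherits(config, "sim_config")) {
    config <- do.call(sim_config, as.list(config))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(config$seed, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")

  n <- config$n_cases
  drug_names <- names(config$drugs)
  k <- length(drug_names)

  sex <- sample(sex_levels, n, replace = TRUE, prob = c(0.475, 0.475, 0.05))
  elderly <- runif(n) < 0.20
  age <- ifelse(elderly,
                pmax(65, round(rnorm(n, 74, 6))),
                pmin(64, pmax(18, round(rnorm(n, 44, 12)))))
  age[runif(n) < 0.08] <- NA_real_

  # study-drug exposure and roles
  expo <- matrix(runif(n * k), n, k) < rep(config$drugs, each = n)
  role_mat <- matrix(NA_character_, n, k)
  n_exp <- sum(expo)
  if (n_exp > 0) {
    conc <- runif(n_exp) < config$concomitant_rate
    ps <- runif(n_exp) < 0.8
    role_mat[expo] <- ifelse(conc, "concomitant",
                             ifelse(ps, "primary_suspect", "secondary_suspect"))
  }

  # event odds: background odds times theta of each suspect-role exposure
  log_odds <- rep(log(config$background_event_rate /
                        (1 - config$background_event_rate)), n)
  for (j in seq_len(k)) {
    d <- drug_names[j]
    th <- config$theta[[d]]
    if (is.null(th)) next
    suspect_j <- expo[, j] & role_mat[, j] %in% suspect_roles
    if (!any(suspect_j)) next
    contrib <- theta_log_by_case(th, sex, age)
    log_odds <- log_odds + ifelse(suspect_j, contrib, 0)
  }
  event <- runif(n) < stats::plogis(log_odds)

  # drug rows: one comparator per case plus exposed study drugs
  bg_tbl <- tibble::tibble(
    idx = seq_len(n),
    drug = sample(background_drug_pool, n, replace = TRUE),
    role = sample(suspect_roles, n, replace = TRUE, prob = c(0.8, 0.2))
  )
  ij <- which(expo, arr.ind = TRUE)
  study_tbl <- tibble::tibble(
    idx = ij[, 1],
    drug = drug_names[ij[, 2]],
    role = role_mat[expo]
  )
  drug_tbl <- dplyr::bind_rows(bg_tbl, study_tbl)

  # reaction rows: 1-2 distinct fillers per case, plus one event term
  nf <- length(filler_reaction_terms)
  two_fillers <- runif(n) < 0.5
  f1 <- sample.int(nf, n, replace = TRUE)
  f2 <- (f1 + sample.int(nf - 1, n, replace = TRUE) - 1L) %% nf + 1L
  reac_tbl <- dplyr::bind_rows(
    tibble::tibble(idx = seq_len(n), reaction_pt = filler_reaction_terms[f1]),
    tibble::tibble(idx = which(two_fillers),
                   reaction_pt = filler_reaction_terms[f2[two_fillers]]),
    tibble::tibble(idx = which(event),
                   reaction_pt = sample(config$smq_terms, sum(event), replace = TRUE))
  )

  rows <- dplyr::inner_join(drug_tbl, reac_tbl, by = "idx",
                            relationship = "many-to-many")
  rows <- dplyr::mutate(rows,
    case_id = sprintf("C%08d", .data$idx),
    sex = sex[.data$idx],
    age_years = age[.data$idx]
  )

  dup <- which(runif(n) < config$duplicate_rate)
  if (length(dup) > 0) {
    rows <- dplyr::bind_rows(rows, dplyr::filter(rows, .data$idx %in% dup))
  }

  out <- rows |>
    dplyr::select("case_id", "drug", "role", "reaction_pt", "sex", "age_years") |>
    dplyr::arrange(.data$case_id, .data$drug, .data$role, .data$reaction_pt)
  attr(out, "rng_kind") <- "Mersenne-Twister/Inversion/Rejection"
  out
}

#' Write / read a report table as tab-separated text
#'
#' The on-disk format is UTF-8 TSV with header
#' `case_id  drug  role  reaction_pt  sex  age_years` and missing values as
#' empty fields, so a table round-trips exactly (missing ages stay missing).
#'
#' @param reports A report tibble as returned by [simulate_reports()].
#' @param path File path.
#' @return `write_reports()` returns `path` invisibly; `read_reports()`
#'   returns the validated report tibble.
#' @export
write_reports <- function(reports, path) {
  validate_reports(reports)
  readr::write_tsv(reports, path, na = "")
  invisible(path)
}

#' @rdname write_reports
#' @export
read_reports <- function(path) {
  tbl <- readr::read_tsv(
    path, na = "",
    col_types = readr::cols(
      case_id = readr::col_character(),
      drug = readr::col_character(),
      role = readr::col_character(),
      reaction_pt = readr::col_character(),
      sex = readr::col_character(),
      age_years = readr::col_double()
    )
  )
  validate_reports(tbl, source = path)
  tbl
}

# Schema validation shared by the IO layer and the preprocessing entry
# points. `source` labels errors with the offending file; row numbers are
# body rows (header excluded).
validate_reports <- function(reports, source = "report table") {
  needed <- c("case_id", "drug", "role", "reaction_pt", "sex", "age_years")
  missing_cols <- setdiff(needed, names(reports))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s: missing column(s) %s", source,
                  paste(missing_cols, collapse = ", ")))
  }
  bad_role <- which(!reports$role %in% faers_roles)
  if (length(bad_role) > 0) {
    abort(sprintf(
      "%s: unknown role code(s) %s at row(s) %s",
      source,
      paste(unique(reports$role[head(bad_role, 5)]), collapse = ", "),
      paste(head(bad_role, 5), collapse = ", ")))
  }
  bad_sex <- which(!reports$sex %in% sex_levels)
  if (length(bad_sex) > 0) {
    abort(sprintf("%s: invalid sex value(s) at row(s) %s", source,
                  paste(head(bad_sex, 5), collapse = ", ")))
  }
  bad_age <- which(!is.na(reports$age_years) & reports$age_years < 0)
  if (length(bad_age) > 0) {
    abort(sprintf("%s: negative age at row(s) %s", source,
                  paste(head(bad_age, 5), collapse = ", ")))
  }
  invisible(reports)
}
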