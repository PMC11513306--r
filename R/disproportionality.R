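#' Build the 2x2 case/non-case table for one drug
#'
#' In the case/non-case design, cases are reports whose reactions match the
#' event term set and non-cases are all other reports in the database; the
#' comparator therefore includes every other drug. Cell `a` counts cases
#' with a suspect-role exposure to the drug, `b` exposed non-cases, `c`
#' unexposed cases, `d` unexposed non-cases.
#'
#' @param case_views Output of [build_case_views()], optionally already
#'   passed through [stratify()].
#' @param drug Drug name; a drug absent from the data yields `a = b = 0`.
#' @param stratum Stratum label applied before counting (default `total`).
#' @return One-row tibble with columns `drug`, `stratum`, `a`, `b`, `c`,
#'   `d`, `n` (= a+b+c+d).
#' @export
#' @examples
#' cv <- tibble::tibble(
#'   case_id = as.character(1:4), sex = "female", age_years = 40,
#'   is_smq_case = c(TRUE, FALSE, TRUE, FALSE),
#'   suspect_drugs = list("x", "x", character(0), character(0))
#' )
#' build_contingency(cv, "x")  # (a,b,c,d) = (1,1,1,1)
build_contingency <- function(case_views, drug, stratum = "total") {
  cv <- stratify(case_views, stratum)
  exposed <- vapply(cv$suspect_drugs, function(s) drug %in% s, logical(1))
  a <- sum(exposed & cv$is_smq_case)
  b <- sum(exposed & !cv$is_smq_case)
  c_ <- sum(!exposed & cv$is_smq_case)
  d <- sum(!exposed & !cv$is_smq_case)
  tibble::tibble(drug = drug, stratum = stratum,
                 a = a, b = b, c = c_, d = d, n = a + b + c_ + d)
}

#' Reporting odds ratio with a 95% Wald interval
#'
#' ROR = (a d)/(b c); the 95% confidence interval is
#' exp(log ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)), so the point
#' estimate is the geometric mean of the bounds by construction. With any
#' zero cell the estimate is undefined (`NA`) unless the Haldane-Anscombe
#' correction is enabled, which then adds 0.5 to every cell of that table.
#'
#' @param a,b,c,d Cell counts (vectorised).
#' @param zero_cell_correction Apply +0.5 to all cells of tables with a
#'   zero cell instead of returning `NA` (off by default).
#' @return Tibble with columns `ror`, `ror_low`, `ror_high`.
#' @export
#' @examples
#' compute_ror(20, 80, 100, 1900)  # 4.75 [2.80, 8.07]
compute_ror <- function(a, b, c, d, zero_cell_correction = FALSE) {
  stopifnot(length(b) == length(a), length(c) == length(a), length(d) == length(a))
  if (any(c(a, b, c, d) < 0, na.rm = TRUE)) abort("cell counts must be >= 0")
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  aa <- a; bb <- b; cc <- c; dd <- d
  if (zero_cell_correction) {
    aa <- a + 0.5 * zero; bb <- b + 0.5 * zero
    cc <- c + 0.5 * zero; dd <- d + 0.5 * zero
    usable <- rep(TRUE, length(a))
  } else {
    usable <- !zero
  }
  ror <- ifelse(usable, (aa * dd) / (bb * cc), NA_real_)
  se <- ifelse(usable, sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd), NA_real_)
  z <- qnorm(0.975)
  tibble::tibble(
    ror = ror,
    ror_low = exp(log(ror) - z * se),
    ror_high = exp(log(ror) + z * se)
  )
}

#' Shrinkage information component with 95% credibility bounds
#'
#' The information component compares the observed count of exposed cases
#' O = a with its independence expectation E = (a+b)(a+c)/N:
#' IC = log2((O + 0.5)/(E + 0.5)). The added 0.5 shrinks small-count
#' estimates toward zero. The 95% credibility bounds use the closed-form
#' approximations
#' IC025 = IC - 3.3 (O+0.5)^-1/2 - 2.41 (O+0.5)^-1 and
#' IC975 = IC + 2.4 (O+0.5)^-1/2 - 0.5 (O+0.5)^-1,
#' which are accurate for the shrunken observed-to-expected ratio across
#' the full range of counts, including O = 0.
#'
#' @param a,b,c,d Cell counts (vectorised).
#' @return Tibble with columns `ic`, `ic025`, `ic975`, `o`, `e`.
#' @export
#' @examples
#' compute_ic(20, 80, 100, 1900)
compute_ic <- function(a, b, c, d) {
  n <- a + b + c + d
  if (any(n <= 0)) abort("total count N must be > 0")
  o <- a
  e <- (a + b) * (a + c) / n
  ic <- log2((o + 0.5) / (e + 0.5))
  ic025 <- ic - 3.3 * (o + 0.5)^(-0.5) - 2.41 * (o + 0.5)^(-1)
  ic975 <- ic + 2.4 * (o + 0.5)^(-0.5) - 0.5 * (o + 0.5)^(-1)
  tibble::tibble(ic = ic, ic025 = ic025, ic975 = ic975, o = o, e = e)
}

#' Dual signal-of-disproportionate-reporting criterion
#'
#' A drug-event pair is a signal when the lower 95% bound of the ROR
#' exceeds 1 *and* the lower 95% credibility bound of the information
#' component exceeds 0, with at least `min_cases` exposed cases. Undefined
#' statistics never signal.
#'
#' @param ror_low Lower 95% Wald bound of the ROR.
#' @param ic025 Lower 95% credibility bound of the IC.
#' @param n_cases Number of exposed cases (cell `a`).
#' @param min_cases Minimum case count for a reportable result (default 3).
#' @return Logical vector.
#' @export
classify_signal <- function(ror_low, ic025, n_cases, min_cases = 3) {
  sig <- !is.na(ror_low) & !is.na(ic025) &
    ror_low > 1 & ic025 > 0 & n_cases >= min_cases
  sig
}

#' Per-drug, per-stratum disproportionality analysis
#'
#' Runs the full case/non-case analysis: for every requested drug and
#' stratum it builds the 2x2 table, computes the ROR with its Wald 95%
#' interval and the shrinkage IC with credibility bounds, and applies the
#' dual signal criterion. Rows with fewer than `min_cases` exposed cases
#' are kept but flagged `is_reported = FALSE` (printed as NA in the
#' rendered table).
#'
#' @param case_views Output of [build_case_views()].
#' @param drugs Character vector of drugs to analyse; default all drugs
#'   appearing as suspect exposures.
#' @param strata Stratum labels to run (default all four).
#' @param min_cases Minimum exposed-case count for a reportable row.
#' @param zero_cell_correction See [compute_ror()].
#' @return A tibble of class `dili_disprop` with one row per drug x
#'   stratum: counts `a b c d`, `n_cases`, `ror`, `ror_low`, `ror_high`,
#'   `ic`, `ic025`, `ic975`, `is_reported`, `is_signal`. Stratum sizes are
#'   stored in the `stratum_n` attribute.
#' @export
#' @examples
#' rpt <- simulate_reports(sim_config(n_cases = 5000, seed = 3))
#' cv <- build_case_views(deduplicate(rpt, quiet = TRUE),
#'                        smq_termset(hepatic_smq_example()))
#' res <- run_disproportionality(cv, drugs = c("quetiapine", "loxapine"),
#'                               strata = "total")
#' res
run_disproportionality <- function(case_views,
                                   drugs = NULL,
                                   strata = stratum_levels,
                                   min_cases = 3,
                                   zero_cell_correction = FALSE) {
  strata <- match.arg(strata, stratum_levels, several.ok = TRUE)
  exp_long <- case_views |>
    dplyr::select("case_id", "suspect_drugs") |>
    tidyr::unchop("suspect_drugs", keep_empty = FALSE) |>
    dplyr::rename(drug = "suspect_drugs")
  if (is.null(drugs)) drugs <- sort(unique(exp_long$drug))

  per_stratum <- function(s) {
    cv <- stratify(case_views, s)
    n_total <- nrow(cv)
    n_smq <- sum(cv$is_smq_case)
    counts <- exp_long |>
      dplyr::semi_join(cv, by = "case_id") |>
      dplyr::left_join(dplyr::select(cv, "case_id", "is_smq_case"), by = "case_id") |>
      dplyr::filter(.data$drug %in% drugs) |>
      dplyr::summarise(
        a = sum(.data$is_smq_case),
        exposed = dplyr::n(),
        .by = "drug"
      )
    tibble::tibble(drug = drugs, stratum = s) |>
      dplyr::left_join(counts, by = "drug") |>
      dplyr::mutate(
        a = dplyr::coalesce(.data$a, 0L),
        exposed = dplyr::coalesce(.data$exposed, 0L),
        b = .data$exposed - .data$a,
        c = n_smq - .data$a,
        d = n_total - .data$exposed - .data$c
      ) |>
      dplyr::select("drug", "stratum", "a", "b", "c", "d")
  }

  out <- purrr::map(strata, per_stratum) |> purrr::list_rbind()
  out <- dplyr::bind_cols(
    out,
    compute_ror(out$a, out$b, out$c, out$d,
                zero_cell_correction = zero_cell_correction),
    dplyr::select(compute_ic(out$a, out$b, out$c, out$d), "ic", "ic025", "ic975")
  )
  out <- out |>
    dplyr::mutate(
      n_cases = .data$a,
      is_reported = .data$n_cases >= min_cases,
      is_signal = classify_signal(.data$ror_low, .data$ic025, .data$n_cases,
                                  min_cases = min_cases),
      .after = "d"
    )
  stratum_n <- vapply(strata, function(s) nrow(stratify(case_views, s)), integer(1))
  structure(out,
            class = c("dili_disprop", class(out)),
            stratum_n = stats::setNames(stratum_n, strata),
            min_cases = min_cases)
}

#' @export
print.dili_disprop <- function(x, ...) {
  cat(sprintf("Disproportionality results: %d drugs x %d strata (min %d cases)\n",
              dplyr::n_distinct(x$drug), dplyr::n_distinct(x$stratum),
              attr(x, "min_cases") %||% 3))
  NextMethod()
}

#' @describeIn run_disproportionality `tidy()` returns the results as a
#'   plain tibble, rounded to `digits` decimals for display columns, with
#'   non-reportable rows' statistics masked to `NA` as in a published
#'   signal table.
#' @param x A `dili_disprop` object.
#' @param digits Decimals for the rounded display columns (`NULL` = none).
#' @param ... Unused.
#' @method tidy dili_disprop
#' @export
tidy.dili_disprop <- function(x, digits = NULL, ...) {
  out <- tibble::as_tibble(x)
  stat_cols <- c("ror", "ror_low", "ror_high", "ic", "ic025", "ic975")
  out[!out$is_reported, stat_cols] <- NA_real_
  if (!is.null(digits)) {
    out <- dplyr::mutate(out, dplyr::across(dplyr::all_of(stat_cols),
                                            ~ round(.x, digits)))
  }
  out
}

#' @describeIn run_disproportionality `glance()` summarises the run: drugs,
#'   strata, reportable rows, signals, stratum sizes.
#' @method glance dili_disprop
#' @export
glance.dili_disprop <- function(x, ...) {
  tibble::tibble(
    n_drugs = dplyr::n_distinct(x$drug),
    n_strata = dplyr::n_distinct(x$stratum),
    n_reported = sum(x$is_reported),
    n_signals = sum(x$is_signal),
    n_cases_total = unname(attr(x, "stratum_n")["total"])
  )
}
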