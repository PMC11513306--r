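#' Pearson product-moment correlation on pairwise-complete data
#'
#' Drops pairs with a missing member, then requires at least 3 complete
#' pairs and nonzero variance in both members; otherwise the result is
#' undefined (`NA` with a `reason` attribute).
#'
#' @param x,y Numeric vectors of equal length.
#' @return Pearson r, or `NA` with attribute `reason`.
#' @export
#' @examples
#' pearson_r(1:5, 2 * (1:5))      # 1
#' pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3))  # 0.6
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    return(structure(NA_real_, reason = "fewer than 3 complete pairs"))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(NA_real_, reason = "zero variance"))
  }
  unname(stats::cor(x, y, method = "pearson"))
}

#' Two-sided t-test for a Pearson correlation
#'
#' For a correlation r on n pairs, t = r sqrt((n-2)/(1-r^2)) follows a t
#' distribution with n-2 degrees of freedom under the null of no
#' correlation; the p-value is the two-sided tail probability. An exact
#' fit (|r| = 1) gives p = 0 by convention.
#'
#' @param r Pearson correlation in \[-1, 1\].
#' @param n Number of pairs (>= 3).
#' @return One-row tibble with `t`, `df`, `p`.
#' @export
#' @examples
#' correlation_test(0.46, 19)  # t ~ 2.136, p ~ 0.048
correlation_test <- function(r, n) {
  if (is.na(r)) return(tibble::tibble(t = NA_real_, df = n - 2, p = NA_real_))
  stopifnot(abs(r) <= 1, n >= 3)
  df <- n - 2
  if (abs(r) == 1) {
    return(tibble::tibble(t = Inf * sign(r), df = df, p = 0))
  }
  t <- r * sqrt(df / (1 - r^2))
  tibble::tibble(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Drug-level correlation battery
#'
#' The pharmacoepidemiologic-pharmacodynamic core: for each stratum and
#' each predictor column of the pharmacology matrix, the drugs' reporting
#' odds ratios (the ROR itself, not its logarithm, unless
#' `outcome = "log_ror"`) are correlated with the predictor by Pearson
#' correlation with a two-sided t-test. Pairs are pairwise-complete per
#' predictor; drugs whose ROR is undefined or below the minimum case count
#' are dropped from that stratum. No multiple-testing correction is
#' applied; `significant` uses the uncorrected p < 0.05 threshold.
#'
#' The age 65+ stratum is excluded by default: with few exposed elderly
#' cases many drugs fall below the minimum case count, so the drug-level
#' correlation is not comparably powered there. Pass it via `strata` to
#' include it.
#'
#' @param disprop A `dili_disprop` result from [run_disproportionality()].
#' @param pharm A pharmacology matrix from [build_pharm_matrix()].
#' @param strata Strata to analyse (default total, female, male).
#' @param outcome Correlate the ROR (default) or log(ROR).
#' @param alpha Significance threshold (default 0.05, uncorrected).
#' @return Tibble of class `dili_battery`: `predictor`, `stratum`, `n`,
#'   `df`, `r`, `t`, `p`, `significant`. Rows with fewer than 3 complete
#'   pairs or degenerate variance carry `NA` statistics.
#' @export
run_battery <- function(disprop, pharm,
                        strata = c("total", "female", "male"),
                        outcome = c("ror", "log_ror"),
                        alpha = 0.05) {
  outcome <- match.arg(outcome)
  strata <- match.arg(strata, stratum_levels, several.ok = TRUE)
  preds <- pharm_predictors(pharm)

  one <- function(s, predictor) {
    d <- disprop |>
      tibble::as_tibble() |>
      dplyr::filter(.data$stratum == s, .data$is_reported, !is.na(.data$ror)) |>
      dplyr::inner_join(dplyr::select(pharm, "drug",
                                      value = dplyr::all_of(predictor)),
                        by = "drug")
    y <- if (outcome == "log_ror") log(d$ror) else d$ror
    x <- d$value
    n <- sum(!is.na(x) & !is.na(y))
    r <- pearson_r(x, y)
    ct <- if (is.na(r)) tibble::tibble(t = NA_real_, df = n - 2, p = NA_real_)
          else correlation_test(r, n)
    tibble::tibble(
      predictor = predictor, stratum = s, n = n, df = n - 2,
      r = as.numeric(r), t = ct$t, p = ct$p,
      significant = !is.na(ct$p) & ct$p < alpha
    )
  }

  out <- tidyr::expand_grid(stratum = strata, predictor = preds) |>
    purrr::pmap(function(stratum, predictor) one(stratum, predictor)) |>
    purrr::list_rbind()
  structure(out, class = c("dili_battery", class(out)),
            outcome = outcome, alpha = alpha)
}

#' @export
print.dili_battery <- function(x, ...) {
  cat(sprintf("Correlation battery (%s vs predictors): %d tests, %d significant at p < %g\n",
              attr(x, "outcome") %||% "ror", nrow(x), sum(x$significant, na.rm = TRUE),
              attr(x, "alpha") %||% 0.05))
  NextMethod()
}

#' @describeIn run_battery `tidy()` returns the battery as a plain tibble.
#' @param x A `dili_battery` object.
#' @param ... Unused.
#' @method tidy dili_battery
#' @export
tidy.dili_battery <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @describeIn run_battery `glance()` summarises the battery: number of
#'   tests, computable tests, and significant findings.
#' @method glance dili_battery
#' @export
glance.dili_battery <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x),
    n_computable = sum(!is.na(x$p)),
    n_significant = sum(x$significant, na.rm = TRUE),
    alpha = attr(x, "alpha") %||% 0.05,
    outcome = attr(x, "outcome") %||% "ror"
  )
}

#' Scatter export for one predictor-stratum pair
#'
#' Emits the plot-ready drug-level pairs together with the ordinary least
#' squares fit (`fit`) and a pointwise 95% confidence band (`lwr`, `upr`)
#' for the regression line, as used for the affinity-vs-ROR scatter plots.
#' The band is narrowest at the predictor mean; the slope has the sign of
#' the Pearson correlation.
#'
#' @param disprop A `dili_disprop` result.
#' @param pharm A pharmacology matrix.
#' @param predictor Predictor column name (see [pharm_predictors()]).
#' @param stratum Stratum label.
#' @return Tibble of class `dili_scatter` with columns `drug`, `x`
#'   (predictor value), `ror`, `fit`, `lwr`, `upr`; attributes `slope`,
#'   `intercept`, `r`, `n`, `predictor`, `stratum`.
#' @export
export_scatter <- function(disprop, pharm, predictor, stratum = "total") {
  if (!predictor %in% pharm_predictors(pharm)) {
    abort(sprintf("unknown predictor '%s'", predictor))
  }
  d <- disprop |>
    tibble::as_tibble() |>
    dplyr::filter(.data$stratum == !!stratum, .data$is_reported, !is.na(.data$ror)) |>
    dplyr::inner_join(dplyr::select(pharm, "drug", x = dplyr::all_of(predictor)),
                      by = "drug") |>
    dplyr::filter(!is.na(.data$x)) |>
    dplyr::select("drug", "x", "ror")
  if (nrow(d) < 3) {
    abort(sprintf("scatter for '%s' in stratum '%s' needs >= 3 complete pairs",
                  predictor, stratum))
  }
  fit <- lm(ror ~ x, data = d)
  band <- predict(fit, interval = "confidence", level = 0.95)
  out <- dplyr::bind_cols(d, tibble::as_tibble(band)) |>
    dplyr::arrange(.data$x)
  structure(out, class = c("dili_scatter", class(out)),
            slope = unname(stats::coef(fit)[2]),
            intercept = unname(stats::coef(fit)[1]),
            r = pearson_r(d$x, d$ror), n = nrow(d),
            predictor = predictor, stratum = stratum)
}
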