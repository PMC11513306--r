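#' Aggregate multiple Ki measurements for one drug-receptor pair
#'
#' When several sources report an inhibitory constant for the same drug and
#' receptor, the median is used as a robust representative value (for an
#' even number of sources, the mean of the two central order statistics).
#'
#' @param values Numeric vector of Ki values in nM (all > 0).
#' @return The median Ki in nM, or `NA` for an empty vector.
#' @export
#' @examples
#' aggregate_ki(c(1, 10, 100))  # 10
#' aggregate_ki(c(2, 8))        # 5
aggregate_ki <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) return(NA_real_)
  if (any(!is.finite(values) | values <= 0)) {
    abort("Ki values must be finite and > 0 (nM)")
  }
  median(values)
}

#' Convert an inhibitory constant to a pKi
#'
#' pKi is the negative base-10 logarithm of Ki expressed in molar; with Ki
#' given in nM this is `9 - log10(ki_nM)`. Higher pKi means higher binding
#' affinity, so the ordering of Ki values is reversed.
#'
#' @param ki_nM Ki in nM (> 0; vectorised, `NA` propagates).
#' @return pKi.
#' @export
#' @examples
#' ki_to_pki(c(1, 1000))  # 9, 6
ki_to_pki <- function(ki_nM) {
  if (any(!is.na(ki_nM) & (!is.finite(ki_nM) | ki_nM <= 0))) {
    abort("`ki_nM` must be finite and > 0")
  }
  9 - log10(ki_nM)
}

#' Unbound drug concentration in blood, in nM
#'
#' CU = 1000 * FU * CT / MW, where FU is the unbound fraction, CT the total
#' blood concentration in ng/mL (here, the upper limit of the therapeutic
#' reference range), and MW the molecular weight in g/mol.
#'
#' @param fu Unbound fraction, in (0, 1]. `NA` propagates.
#' @param ct Total blood concentration in ng/mL (> 0). `NA` propagates.
#' @param mw Molecular weight in g/mol (> 0).
#' @return CU in nM.
#' @export
#' @examples
#' compute_cu(fu = 0.1, ct = 500, mw = 500)  # 100 nM
compute_cu <- function(fu, ct, mw) {
  if (any(!is.na(fu) & (fu <= 0 | fu > 1))) {
    abort("`fu` must be in (0, 1]")
  }
  if (any(!is.na(ct) & ct <= 0)) abort("`ct` must be > 0")
  if (any(is.na(mw) | mw <= 0)) abort("`mw` must be > 0")
  1000 * fu * ct / mw
}

#' Receptor occupancy from occupancy theory
#'
#' Occupancy (%) = 100 * CU / (Ki + CU): the fraction of receptors bound at
#' unbound concentration CU, strictly increasing in CU and strictly
#' decreasing in Ki, reaching 50% at CU = Ki and approaching (never
#' reaching) 100% as CU grows.
#'
#' @param cu_nM Unbound concentration in nM (>= 0; `NA` propagates).
#' @param ki_nM Inhibitory constant in nM (> 0; `NA` propagates).
#' @return Occupancy in percent, in \[0, 100).
#' @export
#' @examples
#' compute_occupancy(cu_nM = 100, ki_nM = 25)  # 80
compute_occupancy <- function(cu_nM, ki_nM) {
  if (any(!is.na(cu_nM) & cu_nM < 0)) abort("`cu_nM` must be >= 0")
  if (any(!is.na(ki_nM) & ki_nM <= 0)) abort("`ki_nM` must be > 0")
  100 * cu_nM / (ki_nM + cu_nM)
}

#' Read pharmacology input tables
#'
#' `read_ki_table()` expects a long table `drug, receptor, ki_nM[, source]`
#' (tab- or comma-separated by file extension); `read_drug_properties()`
#' expects `drug, mw, fu, ct, logp, approval_year`. Missing values are
#' empty fields.
#'
#' @param path File path (`.csv` comma-separated, otherwise tab-separated).
#' @return A tibble.
#' @export
read_ki_table <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tbl <- readr::read_delim(path, delim = delim, na = "",
                           show_col_types = FALSE)
  needed <- c("drug", "receptor", "ki_nM")
  if (!all(needed %in% names(tbl))) {
    abort(sprintf("%s: Ki table needs columns %s", path,
                  paste(needed, collapse = ", ")))
  }
  bad <- setdiff(unique(tbl$receptor), receptor_classes())
  if (length(bad) > 0) {
    abort(sprintf("%s: unknown receptor(s) %s", path, paste(bad, collapse = ", ")))
  }
  tbl
}

#' @rdname read_ki_table
#' @export
read_drug_properties <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tbl <- readr::read_delim(path, delim = delim, na = "",
                           show_col_types = FALSE)
  needed <- c("drug", "mw", "fu", "ct", "logp", "approval_year")
  if (!all(needed %in% names(tbl))) {
    abort(sprintf("%s: properties table needs columns %s", path,
                  paste(needed, collapse = ", ")))
  }
  tbl
}

#' Build the drug x predictor pharmacology matrix
#'
#' Aggregates Ki values per drug and receptor (median over sources),
#' converts them to pKi, computes the unbound concentration CU from the
#' drug properties and from it the receptor occupancy, and lays everything
#' out as one row per drug with predictor columns `pki_<receptor>`,
#' `occ_<receptor>` (receptor labels stripped of punctuation, e.g.
#' `pki_5HT1A`), plus `mw`, `logp` and `approval_year`. Missing inputs
#' stay missing; nothing is imputed.
#'
#' @param ki_table Long tibble `drug, receptor, ki_nM[, source]`.
#' @param props Drug properties tibble
#'   `drug, mw, fu, ct, logp, approval_year`.
#' @return Tibble with one row per drug in `props` and 23 predictor
#'   columns (10 pKi, 10 occupancy, mw, logp, approval_year).
#' @export
#' @examples
#' ki <- tibble::tibble(drug = "x", receptor = c("D2", "D2", "H1"),
#'                      ki_nM = c(2, 8, 50))
#' props <- tibble::tibble(drug = "x", mw = 400, fu = 0.1, ct = 200,
#'                         logp = 3.5, approval_year = 1997)
#' build_pharm_matrix(ki, props)$pki_D2  # pKi of median Ki 5 nM
build_pharm_matrix <- function(ki_table, props) {
  stopifnot(all(c("drug", "receptor", "ki_nM") %in% names(ki_table)))
  stopifnot(all(c("drug", "mw", "fu", "ct", "logp", "approval_year") %in% names(props)))
  bad <- setdiff(unique(ki_table$receptor), receptor_classes())
  if (length(bad) > 0) {
    abort(sprintf("unknown receptor(s): %s", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(props$drug)) abort("duplicate drug rows in `props`")

  agg <- ki_table |>
    dplyr::summarise(ki_nM = aggregate_ki(.data$ki_nM),
                     .by = c("drug", "receptor"))
  if (anyDuplicated(agg[c("drug", "receptor")])) {
    abort("duplicate drug x receptor rows after aggregation")
  }
  agg <- agg |>
    dplyr::left_join(dplyr::select(props, "drug", "mw", "fu", "ct"), by = "drug") |>
    dplyr::mutate(
      pki = ki_to_pki(.data$ki_nM),
      cu_nM = ifelse(is.na(.data$fu) | is.na(.data$ct), NA_real_,
                     1000 * .data$fu * .data$ct / .data$mw),
      occ = compute_occupancy(.data$cu_nM, .data$ki_nM),
      rkey = receptor_key(.data$receptor)
    )

  wide <- function(value_col, prefix) {
    agg |>
      dplyr::select("drug", "rkey", dplyr::all_of(value_col)) |>
      tidyr::pivot_wider(names_from = "rkey", values_from = dplyr::all_of(value_col),
                         names_prefix = prefix)
  }
  pki_w <- wide("pki", "pki_")
  occ_w <- wide("occ", "occ_")

  out <- props |>
    dplyr::select("drug", "mw", "logp", "approval_year") |>
    dplyr::left_join(pki_w, by = "drug") |>
    dplyr::left_join(occ_w, by = "drug")

  # every receptor gets a column even if no drug has a Ki for it
  for (r in receptor_classes()) {
    for (p in c("pki_", "occ_")) {
      cn <- paste0(p, receptor_key(r))
      if (!cn %in% names(out)) out[[cn]] <- NA_real_
    }
  }
  order_cols <- c("drug",
                  paste0("pki_", receptor_key(receptor_classes())),
                  paste0("occ_", receptor_key(receptor_classes())),
                  "mw", "logp", "approval_year")
  dplyr::select(out, dplyr::all_of(order_cols))
}

#' Names of the predictor columns of a pharmacology matrix
#'
#' @param pharm A matrix from [build_pharm_matrix()].
#' @return Character vector (everything except the drug key).
#' @export
pharm_predictors <- function(pharm) {
  setdiff(names(pharm), "drug")
}
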