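# Shared fixtures and independent oracles. The oracles deliberately use the
# dumbest possible implementations (explicit loops, direct algebra) so they
# stay independent of the vectorised paths they check.

toy_smq <- function() {
  smq_termset(c("Hepatitis", "Liver injury", "Jaundice"), name = "toy hepatic")
}

# one row per case x drug x reaction, everything defaulted
toy_report_row <- function(case_id, drug = "drugA", role = "primary_suspect",
                           reaction_pt = "Nausea", sex = "female",
                           age_years = 40) {
  tibble::tibble(case_id = case_id, drug = drug, role = role,
                 reaction_pt = reaction_pt, sex = sex, age_years = age_years)
}

random_reports <- function(n_rows, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    case_id = sprintf("R%04d", sample.int(ceiling(n_rows / 2), n_rows, replace = TRUE)),
    drug = sample(c("drugA", "drugB", "drugC"), n_rows, replace = TRUE),
    role = sample(c("primary_suspect", "secondary_suspect", "concomitant",
                    "interacting"), n_rows, replace = TRUE),
    reaction_pt = sample(c("Hepatitis", "Nausea", "Headache", "Rash"),
                         n_rows, replace = TRUE),
    sex = sample(c("female", "male", "unknown"), n_rows, replace = TRUE),
    age_years = ifelse(runif(n_rows) < 0.2, NA_real_,
                       round(runif(n_rows, 18, 90)))
  )) |>
    # demographics must be constant within a case_id for a valid table
    dplyr::group_by(case_id) |>
    dplyr::mutate(sex = sex[1], age_years = age_years[1]) |>
    dplyr::ungroup()
}

# brute-force double loop over cases: the contingency-table oracle
oracle_contingency <- function(case_views, drug) {
  a <- b <- c_ <- d <- 0
  for (i in seq_len(nrow(case_views))) {
    exposed <- drug %in% case_views$suspect_drugs[[i]]
    smq <- case_views$is_smq_case[i]
    if (exposed && smq) a <- a + 1
    else if (exposed) b <- b + 1
    else if (smq) c_ <- c_ + 1
    else d <- d + 1
  }
  c(a = a, b = b, c = c_, d = d)
}

# odds ratio by direct algebra on proportions, independent of compute_ror
oracle_odds_ratio <- function(a, b, c, d) {
  (a / b) / (c / d)
}

# two-sided p for a correlation by numerical integration of the t density
p_by_integration <- function(r, n) {
  df <- n - 2
  tstat <- abs(r) * sqrt(df / (1 - r^2))
  2 * stats::integrate(function(u) stats::dt(u, df), tstat, Inf,
                       rel.tol = 1e-10)$value
}
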