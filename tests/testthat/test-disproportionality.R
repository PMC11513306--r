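test_that("contingency cells match direct enumeration", {
  cv <- tibble::tibble(
    case_id = as.character(1:4),
    sex = "female", age_years = 40,
    is_smq_case = c(TRUE, FALSE, TRUE, FALSE),
    suspect_drugs = list("x", "x", character(0), character(0))
  )
  tab <- build_contingency(cv, "x")
  expect_equal(unlist(tab[c("a", "b", "c", "d")]),
               c(a = 1, b = 1, c = 1, d = 1))

  # drug absent from the data: a = b = 0, no error
  tab0 <- build_contingency(cv, "absent")
  expect_equal(tab0$a + tab0$b, 0)
  expect_equal(tab0$n, 4)
})

test_that("contingency cells equal the brute-force double-loop oracle", {
  rpt <- simulate_reports(sim_config(n_cases = 1000, seed = 42))
  cv <- build_case_views(deduplicate(rpt, quiet = TRUE),
                         smq_termset(hepatic_smq_example()))
  for (drug in c("quetiapine", "olanzapine", "loxapine", "comparator_01")) {
    tab <- build_contingency(cv, drug)
    expect_equal(unlist(tab[c("a", "b", "c", "d")]), oracle_contingency(cv, drug),
                 info = drug)
  }
})

test_that("ROR point estimate and Wald interval match hand computation", {
  sym <- compute_ror(10, 10, 10, 10)
  expect_equal(sym$ror, 1)
  expect_lt(sym$ror_low, 1)
  expect_gt(sym$ror_high, 1)

  r <- compute_ror(20, 80, 100, 1900)
  expect_equal(r$ror, 4.75)
  expect_equal(r$ror_low, 2.796, tolerance = 1e-3)
  expect_equal(r$ror_high, 8.069, tolerance = 1e-3)

  expect_error(compute_ror(-1, 2, 3, 4), ">= 0")
})

test_that("zero cells are undefined unless the correction is enabled", {
  z <- compute_ror(0, 10, 10, 10)
  expect_true(is.na(z$ror))
  zc <- compute_ror(0, 10, 10, 10, zero_cell_correction = TRUE)
  expect_false(is.na(zc$ror))
  expect_equal(zc$ror, (0.5 * 10.5) / (10.5 * 10.5))
  # tables without zero cells are untouched by the flag
  expect_equal(compute_ror(5, 6, 7, 8, zero_cell_correction = TRUE)$ror,
               compute_ror(5, 6, 7, 8)$ror)
})

test_that("the ROR equals the oracle and is invariant to row/column scaling", {
  set.seed(101)
  for (i in 1:50) {
    cells <- sample(1:30, 4, replace = TRUE)
    r <- compute_ror(cells[1], cells[2], cells[3], cells[4])
    expect_equal(r$ror, oracle_odds_ratio(cells[1], cells[2], cells[3], cells[4]))
    # Wald structure: point estimate is the geometric mean of the bounds
    expect_equal(r$ror, sqrt(r$ror_low * r$ror_high))
    # invariance under scaling a row or a column
    k <- runif(1, 0.5, 4)
    expect_equal(compute_ror(cells[1] * k, cells[2] * k, cells[3], cells[4])$ror, r$ror)
    expect_equal(compute_ror(cells[1] * k, cells[2], cells[3] * k, cells[4])$ror, r$ror)
  }
})

test_that("exhaustive small tables agree with the independent oracle", {
  grid <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  r <- compute_ror(grid$a, grid$b, grid$c, grid$d)
  expected <- mapply(oracle_odds_ratio, grid$a, grid$b, grid$c, grid$d)
  expect_equal(r$ror, unname(expected))
})

test_that("IC matches the closed form on worked examples", {
  # observed equals expected: symmetric table, E = 10
  expect_equal(compute_ic(10, 10, 10, 10)$ic, 0)

  # O = 20, E = 4 by construction: (a+b)(a+c)/N = 25*80/500
  ic <- compute_ic(20, 5, 60, 415)
  expect_equal(ic$e, 4)
  expect_equal(ic$ic, log2(20.5 / 4.5))
  expect_equal(ic$ic025, log2(20.5 / 4.5) - 3.3 / sqrt(20.5) - 2.41 / 20.5)
  expect_equal(ic$ic975, log2(20.5 / 4.5) + 2.4 / sqrt(20.5) - 0.5 / 20.5)

  # degenerate table: O = E = 0
  expect_equal(compute_ic(0, 0, 0, 5)$ic, 0)
})

test_that("the IC shrinks toward zero and its bounds bracket it", {
  set.seed(7)
  for (i in 1:100) {
    cells <- sample(1:50, 4, replace = TRUE)
    ic <- compute_ic(cells[1], cells[2], cells[3], cells[4])
    if (ic$o > 0 && ic$e > 0 && ic$o != ic$e) {
      expect_lte(abs(ic$ic), abs(log2(ic$o / ic$e)))
    }
    expect_lt(ic$ic025, ic$ic)
    expect_gt(ic$ic975, ic$ic)
  }
})

test_that("the dual criterion requires both bounds and the minimum cases", {
  expect_true(classify_signal(2.38, 1.00, 100))
  expect_false(classify_signal(1.20, -0.05, 100))
  expect_false(classify_signal(0.95, 1.00, 100))
  expect_false(classify_signal(5, 2, 2))       # below the 3-case rule
  expect_false(classify_signal(NA, 1, 100))
  expect_false(classify_signal(2, NA, 100))
})

test_that("run_disproportionality yields one row per drug and stratum", {
  rpt <- simulate_reports(sim_config(n_cases = 4000, seed = 13))
  cv <- build_case_views(deduplicate(rpt, quiet = TRUE),
                         smq_termset(hepatic_smq_example()))
  res <- run_disproportionality(cv, drugs = names(default_drug_exposure()))
  expect_s3_class(res, "dili_disprop")
  expect_equal(nrow(res), 19 * 4)
  expect_true(all(res$is_reported == (res$n_cases >= 3)))
  for (s in unique(res$stratum)) {
    sub <- res[res$stratum == s, ]
    expect_equal(unique(sub$a + sub$b + sub$c + sub$d),
                 unname(attr(res, "stratum_n")[s]))
  }
})

test_that("the vectorised analysis equals per-drug contingency construction", {
  rpt <- simulate_reports(sim_config(n_cases = 2000, seed = 23))
  cv <- build_case_views(deduplicate(rpt, quiet = TRUE),
                         smq_termset(hepatic_smq_example()))
  res <- run_disproportionality(cv, drugs = c("quetiapine", "clozapine"),
                                strata = c("total", "female"))
  for (i in seq_len(nrow(res))) {
    tab <- build_contingency(cv, res$drug[i], res$stratum[i])
    expect_equal(unlist(res[i, c("a", "b", "c", "d")]),
                 unlist(tab[c("a", "b", "c", "d")]))
  }
})

test_that("tidy() masks non-reportable rows and glance() summarises", {
  rpt <- simulate_reports(sim_config(n_cases = 4000, seed = 13))
  cv <- build_case_views(deduplicate(rpt, quiet = TRUE),
                         smq_termset(hepatic_smq_example()))
  res <- run_disproportionality(cv, drugs = names(default_drug_exposure()))
  td <- tidy(res, digits = 2)
  expect_true(all(is.na(td$ror[!td$is_reported])))
  masked <- td$ror[td$is_reported & !is.na(td$ror)]
  expect_equal(masked, round(masked, 2))
  g <- glance(res)
  expect_equal(g$n_drugs, 19)
  expect_equal(g$n_reported, sum(res$is_reported))
})

test_that("a female-only elevation signals in the female stratum only", {
  cfg <- sim_config(
    n_cases = 80000,
    drugs = c(drugX = 0.02),
    theta = list(drugX = c(female = 3, male = 1)),
    duplicate_rate = 0, concomitant_rate = 0,
    seed = 99
  )
  rpt <- simulate_reports(cfg)
  cv <- build_case_views(deduplicate(rpt, quiet = TRUE),
                         smq_termset(hepatic_smq_example()))
  res <- run_disproportionality(cv, drugs = "drugX",
                                strata = c("female", "male"))
  fem <- res[res$stratum == "female", ]
  mal <- res[res$stratum == "male", ]
  expect_true(fem$is_signal)
  expect_false(mal$is_signal)
  expect_gt(fem$ror, 2)
  expect_lt(mal$ror, 1.6)
})
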