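# a minimal disproportionality-results stand-in for battery tests: the
# battery only consumes drug, stratum, is_reported and ror
fake_disprop <- function(drugs, ror, stratum = "total") {
  tibble::tibble(drug = drugs, stratum = stratum, ror = ror,
                 is_reported = TRUE)
}

test_that("Pearson r matches hand computation and handles degeneracy", {
  expect_equal(pearson_r(1:5, 2 * (1:5)), 1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_equal(pearson_r(c(1, NA, 2, 3, 4), c(2, 9, 1, 4, 3)), 0.6)

  r0 <- pearson_r(c(1, 1, 1), c(1, 2, 3))
  expect_true(is.na(r0))
  expect_match(attr(r0, "reason"), "variance")
  r1 <- pearson_r(c(1, 2), c(1, 2))
  expect_match(attr(r1, "reason"), "3 complete pairs")
})

test_that("r is affine-invariant and sign-flips under negation", {
  set.seed(17)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(15) + 0.5 * x
    r <- pearson_r(x, y)
    expect_equal(pearson_r(3 * x + 7, y), r)
    expect_equal(pearson_r(x, 0.1 * y - 2), r)
    expect_equal(pearson_r(-x, y), -r)
  }
})

test_that("the correlation t-test matches its closed form and conventions", {
  ct <- correlation_test(0, 10)
  expect_equal(ct$t, 0)
  expect_equal(ct$p, 1)
  expect_equal(correlation_test(1, 5)$p, 0)
  expect_equal(correlation_test(0.5, 12)$df, 10)

  # p decreases in |r| at fixed n, and in n at fixed |r|
  p_r <- vapply(seq(0.1, 0.9, by = 0.1),
                function(r) correlation_test(r, 15)$p, numeric(1))
  expect_true(all(diff(p_r) < 0))
  p_n <- vapply(c(5, 10, 20, 40),
                function(n) correlation_test(0.4, n)$p, numeric(1))
  expect_true(all(diff(p_n) < 0))
})

test_that("p-values agree with numerical integration of the t density", {
  for (n in c(3, 5, 10, 19, 35, 50)) {
    for (r in c(-0.9, -0.46, -0.1, 0.2, 0.5, 0.68, 0.95)) {
      expect_equal(correlation_test(r, n)$p, p_by_integration(r, n),
                   tolerance = 1e-6, info = sprintf("n=%d r=%g", n, r))
    }
  }
})

test_that("the battery covers every predictor-stratum pair and drops NAs", {
  set.seed(31)
  drugs <- sprintf("d%02d", 1:19)
  pharm <- tibble::tibble(drug = drugs)
  for (p in c("pki_D2", "pki_5HT1A", "mw")) pharm[[p]] <- rnorm(19)
  pharm$logp <- NA_real_  # entirely missing predictor
  disprop <- dplyr::bind_rows(
    fake_disprop(drugs, exp(rnorm(19)), "total"),
    fake_disprop(drugs, exp(rnorm(19)), "female"),
    fake_disprop(drugs, exp(rnorm(19)), "male")
  )
  bat <- run_battery(disprop, pharm)
  expect_s3_class(bat, "dili_battery")
  expect_equal(nrow(bat), 4 * 3)
  expect_true(all(bat$df == bat$n - 2))
  expect_true(all(sign(bat$t[!is.na(bat$t)]) == sign(bat$r[!is.na(bat$r)])))

  empty_rows <- bat[bat$predictor == "logp", ]
  expect_true(all(is.na(empty_rows$r)))
  expect_true(all(!empty_rows$significant))
  expect_equal(glance(bat)$n_computable, 9)
})

test_that("a 19-drug complete battery reports 17 degrees of freedom", {
  set.seed(8)
  drugs <- sprintf("d%02d", 1:19)
  pharm <- tibble::tibble(drug = drugs, mw = rnorm(19, 400, 50))
  bat <- run_battery(fake_disprop(drugs, exp(rnorm(19))), pharm,
                     strata = "total")
  expect_equal(unique(bat$df), 17)
  expect_equal(unique(bat$n), 19)
})

test_that("a generated linear predictor-outcome link is recovered", {
  set.seed(41)
  drugs <- sprintf("d%02d", 1:19)
  pki <- rnorm(19, 7, 1)
  ror <- pmax(0.05, 2.5 - 0.3 * pki + rnorm(19, sd = 0.1))
  pharm <- tibble::tibble(drug = drugs, pki_5HT1A = pki)
  bat <- run_battery(fake_disprop(drugs, ror), pharm, strata = "total")
  expect_lt(bat$r, -0.6)
  expect_true(bat$significant)
})

test_that("log-ROR mode changes the correlated outcome", {
  set.seed(55)
  drugs <- sprintf("d%02d", 1:10)
  x <- rnorm(10)
  ror <- exp(2 * x)  # exactly linear on the log scale
  pharm <- tibble::tibble(drug = drugs, mw = x)
  bat_log <- run_battery(fake_disprop(drugs, ror), pharm, strata = "total",
                         outcome = "log_ror")
  expect_equal(bat_log$r, 1)
  bat_lin <- run_battery(fake_disprop(drugs, ror), pharm, strata = "total")
  expect_lt(bat_lin$r, 1)
})

test_that("scatter export carries the OLS line and confidence band", {
  set.seed(61)
  drugs <- sprintf("d%02d", 1:12)
  x <- rnorm(12)
  pharm <- tibble::tibble(drug = drugs, mw = x)

  # zero-noise line: slope recovered exactly, band collapses onto the fit
  sc <- export_scatter(fake_disprop(drugs, 2 + 0.7 * x), pharm, "mw")
  expect_equal(attr(sc, "slope"), 0.7)
  expect_equal(sc$fit, sc$ror)

  # noisy case: slope sign equals the sign of r; band narrowest at mean(x)
  for (i in 1:10) {
    ror <- exp(rnorm(12))
    sc <- export_scatter(fake_disprop(drugs, ror), pharm, "mw")
    expect_equal(sign(attr(sc, "slope")), sign(attr(sc, "r")))
    widths <- sc$upr - sc$lwr
    expect_equal(which.min(abs(sc$x - mean(sc$x))), which.min(widths))
  }

  expect_error(export_scatter(fake_disprop(drugs[1:2], c(1, 2)),
                              pharm[1:2, ], "mw"), "3 complete pairs")
  expect_error(export_scatter(fake_disprop(drugs, exp(rnorm(12))),
                              pharm, "nope"), "unknown predictor")
})

test_that("autoplot methods return ggplot objects", {
  set.seed(71)
  drugs <- sprintf("d%02d", 1:10)
  pharm <- tibble::tibble(drug = drugs, mw = rnorm(10))
  disprop <- fake_disprop(drugs, exp(rnorm(10)))
  sc <- export_scatter(disprop, pharm, "mw")
  expect_s3_class(ggplot2::autoplot(sc), "ggplot")
  bat <- run_battery(disprop, pharm, strata = "total")
  expect_s3_class(ggplot2::autoplot(bat), "ggplot")
})
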