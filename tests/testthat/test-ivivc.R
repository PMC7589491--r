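test_that("the packaged reference table loads with expected shape", {
  tab <- drug_reference_table()
  expect_equal(nrow(tab), 20)
  expect_true(all(tab$fa_percent >= 0 & tab$fa_percent <= 100))
  expect_true(all(tab$papp_franz >= 0, na.rm = TRUE))
  expect_true(all(levels(tab$bcs_class) == c("I", "II", "III", "IV")))
  # missing published cells are NA, never zero
  expect_true(is.na(tab$papp_franz[tab$name == "methyldopa"]))
  expect_true(is.na(tab$papp_nonsink[tab$name == "theophylline"]))
  # the AT flags: table flag vs analysis-exclusion trio disagree on ketoprofen
  expect_setequal(tab$name[tab$actively_transported],
                  c("ketoprofen", "verapamil", "ranitidine", "trimethoprim"))
  expect_setequal(tab$name[tab$excluded_at_text],
                  c("verapamil", "ranitidine", "trimethoprim"))
})

test_that("an exact log-linear relationship fits with R2 = 1", {
  papp <- 10^seq(-6, -4, length.out = 6)
  recs <- data.frame(name = letters[1:6], fa_percent = 10 + 25 *
                       (log10(papp) + 6), papp = papp)
  fit <- fit_fa_correlation(recs, "papp", "log-linear")
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 25, tolerance = 1e-9)
})

test_that("coefficients equal the closed-form normal-equations solution", {
  recs <- data.frame(name = c("a", "b", "c"),
                     fa_percent = c(20, 50, 90),
                     papp = c(1e-6, 1e-5, 1e-4))
  fit <- fit_fa_correlation(recs, "papp", "log-linear")
  # independent closed form
  x <- log10(recs$papp); y <- recs$fa_percent
  sxx <- sum((x - mean(x))^2); sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  expect_equal(fit$slope, slope, tolerance = 1e-12)
  expect_equal(fit$intercept, mean(y) - slope * mean(x), tolerance = 1e-12)
  expect_equal(fit$r, sxy / sqrt(sxx * sum((y - mean(y))^2)),
               tolerance = 1e-12)
})

test_that("non-positive permeabilities are dropped with a warning under log form", {
  recs <- data.frame(name = c("a", "b", "c", "d"),
                     fa_percent = c(20, 50, 90, 70),
                     papp = c(1e-6, 1e-5, 1e-4, 0))
  expect_warning(fit <- fit_fa_correlation(recs, "papp", "log-linear"),
                 "non-positive")
  expect_equal(fit$n, 3)
  expect_false("d" %in% fit$included_drugs)
  expect_error(
    suppressWarnings(fit_fa_correlation(recs[c(1, 2, 4), ], "papp",
                                        "log-linear")),
    "fewer than 3")
})

test_that("cross-column correlation matches its definition and symmetry", {
  recs <- data.frame(name = c("a", "b", "c"),
                     p1 = c(1, 4, 9), p2 = c(2, 3, 10))
  res <- cross_column_correlation(recs, "p1", "p2", log_scale = FALSE)
  x <- recs$p1; y <- recs$p2
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  swapped <- cross_column_correlation(recs, "p2", "p1", log_scale = FALSE)
  expect_equal(res$r, swapped$r)
  # self-correlation
  expect_equal(cross_column_correlation(recs, "p1", "p1", FALSE)$r, 1)
})

test_that("r squared equals simple-OLS R2 on the same pairs", {
  tab <- drug_reference_table()
  cc <- cross_column_correlation(tab, "papp_franz", "papp_nonsink",
                                 log_scale = TRUE)
  keep <- is.finite(tab$papp_franz) & is.finite(tab$papp_nonsink) &
    tab$papp_franz > 0 & tab$papp_nonsink > 0
  ols <- summary(stats::lm(log10(papp_nonsink) ~ log10(papp_franz),
                           data = tab[keep, ]))$r.squared
  expect_equal(cc$r_squared, ols, tolerance = 1e-12)
})

test_that("record order does not change any output", {
  tab <- drug_reference_table()
  set.seed(9)
  shuffled <- tab[sample(nrow(tab)), ]
  a <- fit_fa_correlation(tab, "papp_franz", "log-linear")
  b <- fit_fa_correlation(shuffled, "papp_franz", "log-linear")
  expect_equal(a$r_squared, b$r_squared, tolerance = 1e-12)
  expect_setequal(a$included_drugs, b$included_drugs)
})

test_that("removing the actively transported trio improves the Fa% correlation", {
  tab <- drug_reference_table()
  all_drugs <- fit_fa_correlation(tab, "papp_franz", "log-linear")
  passive <- fit_fa_correlation(tab, "papp_franz", "log-linear",
                                exclude = c("ranitidine", "trimethoprim",
                                            "verapamil"))
  expect_gt(passive$r_squared, all_drugs$r_squared)
})

test_that("the correlation report battery runs end to end", {
  rep <- ivivc_report()
  expect_gte(nrow(rep), 6)
  vals <- rep$value[rep$statistic == "R2" & is.finite(rep$value)]
  expect_true(all(vals >= 0 & vals <= 1))
  # every computed row states the drug subset it used
  expect_true(all(nzchar(rep$drugs[is.finite(rep$value)])))
  # the Corti statistics reproduce their published values closely
  corti <- rep$value[rep$comparison == "Fa% vs Corti Papp"]
  expect_equal(corti, 0.904, tolerance = 0.005)
})
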