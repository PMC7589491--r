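test_that("predicted series collapses correctly in limiting cases", {
  exp0 <- make_experiment(true_peff = 1e-6, sample_volume = 0)
  # no transport, no dilution: identically zero
  expect_equal(predict_receiver_series(0, exp0), rep(0, 10))
  # instant equilibration: every prediction at the well-mixed value
  eq <- 1 * 10000 / (7 + 1)
  expect_equal(predict_receiver_series(1, exp0), rep(eq, 10),
               tolerance = 1e-12)
  expect_error(predict_receiver_series(-1e-6, exp0), "peff")
})

test_that("mass-conserving prediction reproduces the noise-free simulator", {
  for (peff in c(1e-6, 1e-5, 1e-4)) {
    exp <- make_experiment(true_peff = peff, noise_cv = 0)
    pred <- predict_receiver_series(peff, exp, "mass_conserving")
    expect_equal(pred, exp$replicates[[1]], tolerance = 1e-9)
  }
})

test_that("constant-Qtotal mode over-predicts once mass has been withdrawn", {
  exp <- make_experiment(true_peff = 1e-5, noise_cv = 0)
  pred_mc <- predict_receiver_series(1e-5, exp, "mass_conserving")
  pred_ct <- predict_receiver_series(1e-5, exp, "constant")
  expect_equal(pred_mc[1], pred_ct[1])        # no withdrawal before t1
  expect_true(all(pred_ct[-1] > pred_mc[-1])) # afterwards Qtotal is inflated
})

test_that("ssr is the plain sum of squared residuals", {
  expect_identical(ssr(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(ssr(c(1, 2), c(0, 0)), 5)
  x <- stats::runif(7)
  expect_equal(ssr(x, x + 0.5), 7 * 0.25, tolerance = 1e-12)
  expect_error(ssr(1:3, 1:4), "length")
})

test_that("predictions are non-decreasing in peff at every time", {
  exp <- make_experiment(true_peff = 1e-5, sample_volume = 0)
  peffs <- 10^seq(-8, -3, length.out = 12)
  series <- sapply(peffs, predict_receiver_series, exp = exp)
  for (t in seq_len(nrow(series))) {
    expect_true(all(diff(series[t, ]) >= -1e-12))
  }
})

test_that("fit_peff recovers ground truth on noise-free experiments", {
  for (peff in c(1e-7, 1e-6, 1e-5, 1e-4)) {
    exp <- make_experiment(true_peff = peff, noise_cv = 0)
    fit <- fit_peff(exp)
    expect_equal(fit$papp_nonsink, peff, tolerance = 1e-3)
    expect_false(fit$degenerate)
  }
})

test_that("fit_peff matches a dense brute-force grid argmin", {
  exp <- make_experiment(true_peff = 3e-6, noise_cv = 0)
  obs <- replicate_mean(exp)
  grid <- 10^seq(-9, -2, length.out = 1e4)
  ssr_grid <- vapply(grid, function(p) {
    ssr(obs, predict_receiver_series(p, exp))
  }, numeric(1))
  best <- grid[which.min(ssr_grid)]
  fit <- fit_peff(exp)
  # within one grid step of the dense argmin
  step <- grid[2] / grid[1]
  expect_true(fit$papp_nonsink / best < step &&
              best / fit$papp_nonsink < step)
  expect_lte(fit$ssr, min(ssr_grid) + 1e-15)
})

test_that("bisection cross-check agrees with the optimizer on noise-free data", {
  # with sample_volume = 0 the predicted concentration at the last time is
  # strictly increasing in peff, so the root of pred(t_end) - obs(t_end)
  # identifies peff independently of SSR minimisation
  exp <- make_experiment(true_peff = 2e-5, noise_cv = 0, sample_volume = 0)
  obs_end <- replicate_mean(exp)[10]
  root <- stats::uniroot(function(p) {
    predict_receiver_series(p, exp)[10] - obs_end
  }, lower = 1e-9, upper = 1e-2, tol = 1e-14)$root
  fit <- fit_peff(exp)
  expect_equal(fit$papp_nonsink, root, tolerance = 1e-4)
})

test_that("noisy triplicate fit recovers truth within 10% at a fixed seed", {
  exp <- make_experiment(true_peff = 1e-5, noise_cv = 0.05,
                         n_replicates = 3, seed = 101)
  fit <- fit_peff(exp)
  expect_equal(fit$papp_nonsink, 1e-5, tolerance = 0.10)
})

test_that("all-zero observations give a degenerate zero fit", {
  geo <- default_geo()
  exp <- permeation_experiment("blank", geo, sampling_schedule(), 1000,
                               list(rep(0, 10)))
  fit <- fit_peff(exp)
  expect_equal(fit$papp_nonsink, 0)
  expect_true(fit$degenerate)
})

test_that("estimate_papp combines both estimators and classifies", {
  exp <- make_experiment(true_peff = 1e-5, noise_cv = 0)
  res <- estimate_papp(exp, papp_reference = 1e-5)
  expect_equal(res$papp_nonsink, 1e-5, tolerance = 1e-3)
  expect_true(res$papp_sink < res$papp_nonsink)
  expect_true(res$classification %in% c("high", "low"))
  expect_s3_class(res$flux, "flux_estimate")
})
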