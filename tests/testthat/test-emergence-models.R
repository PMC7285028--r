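test_that("curve families satisfy their closed-form anchor points", {
  # logistic: half-rise at x0; known value at ln 3
  expect_equal(logistic_curve(5, 0.8, 5, 2), 0.4)
  expect_equal(logistic_curve(log(3), 1, 0, 1), 0.75)
  # gompertz: a/e at x0; solve for the median
  expect_equal(gompertz_curve(10, 1, 10, 3), exp(-1))
  expect_equal(gompertz_curve(-log(log(2)), 1, 0, 1), 0.5)
  # weibull: half-rise at x0, zero at the onset clamp
  expect_equal(weibull_curve(10, 1, 10, 5, 1), 0.5)
  expect_equal(weibull_curve(10, 0.9, 10, 5, 2.2), 0.45)
  onset <- 10 - 5 * log(2)  # c = 1
  expect_equal(weibull_curve(onset, 1, 10, 5, 1), 0)
  expect_equal(weibull_curve(onset - 3, 1, 10, 5, 1), 0)
  # biphasic mixture degeneracies and unit asymptote
  x <- seq(-50, 400, by = 7)
  expect_equal(biphasic_curve(x, 1, 20, 5, 90, 30, 2),
               logistic_curve(x, 1, 20, 5))
  expect_equal(biphasic_curve(x, 0, 20, 5, 90, 30, 2),
               weibull_curve(x, 1, 90, 30, 2))
  expect_equal(biphasic_curve(1e6, 0.3, 20, 5, 90, 30, 2), 1)
})

test_that("all families are non-decreasing and bounded for random parameters", {
  set.seed(30)
  x <- seq(-100, 400, length.out = 300)
  for (rep in 1:40) {
    a <- runif(1, 0.1, 1.05)
    x0 <- runif(1, 0, 200); b <- runif(1, 0.5, 60); cc <- runif(1, 0.3, 6)
    for (fam in c("logistic", "gompertz", "weibull", "biphasic")) {
      p <- switch(fam,
        logistic = list(a = a, x0 = x0, b = b),
        gompertz = list(a = a, x0 = x0, b = b),
        weibull = list(a = a, x0 = x0, b = b, c = cc),
        biphasic = list(w = runif(1), x01 = runif(1, 0, 100),
                        b1 = runif(1, 0.5, 30), x02 = runif(1, 50, 250),
                        b2 = runif(1, 0.5, 60), c2 = cc))
      y <- emergence_curve(x, fam, p)
      expect_true(all(diff(y) >= -1e-12), info = fam)
      ymax <- if (fam == "biphasic") 1 else a
      expect_true(all(y >= -1e-12 & y <= ymax + 1e-12), info = fam)
    }
  }
})

test_that("fit metrics match hand arithmetic", {
  perfect <- goodness_of_fit(c(0, 0.5, 1), c(0, 0.5, 1), k = 1)
  expect_equal(perfect$sse, 0)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$r_squared, 1)

  g <- goodness_of_fit(c(0, 1), c(0.5, 0.5), k = 1)
  expect_equal(g$sse, 0.5)
  expect_equal(g$rmse, 0.5)
  expect_equal(g$r_squared, 0)

  set.seed(31)
  obs <- runif(10); pred <- obs + rnorm(10, 0, 0.02)
  sse <- sum((obs - pred)^2)
  a <- goodness_of_fit(obs, pred, k = 3)
  expect_equal(a$aic, 10 * log(sse / 10) + 8)

  const <- goodness_of_fit(rep(0.4, 5), runif(5), k = 1)
  expect_true(const$tss_zero)
  expect_true(is.na(const$r_squared))
  expect_error(goodness_of_fit(1:3, 1:3, k = 3), "n > k")
})

test_that("noise-free generating parameters are recovered", {
  days <- seq(0, 140, by = 10)  # 15 points spanning the rise
  y <- gompertz_curve(days, 1, 60, 12)
  fit <- fit_emergence_model(tibble::tibble(day = days, y = y), "gompertz",
                             n_starts = 6, seed = 1)
  expect_lt(abs(fit$params$x0 - 60) / 60, 1e-4)
  expect_lt(abs(fit$params$b - 12) / 12, 1e-4)
  expect_lt(fit$rmse, 1e-6)
})

test_that("a mismatched family fits strictly worse on exact data", {
  days <- seq(0, 140, by = 10)
  y <- gompertz_curve(days, 1, 60, 12)
  d <- tibble::tibble(day = days, y = y)
  gom <- fit_emergence_model(d, "gompertz", n_starts = 6, seed = 1)
  log_ <- fit_emergence_model(d, "logistic", n_starts = 6, seed = 1)
  expect_gt(log_$sse, gom$sse)
})

test_that("fitting refuses degenerate or underdetermined input", {
  expect_error(fit_emergence_model(tibble::tibble(day = 1:5, y = 0), "logistic"),
               "all-zero")
  expect_error(fit_emergence_model(tibble::tibble(day = 1:3, y = c(0, .5, 1)),
                                   "weibull"), "more than 4")
})

test_that("fits are reproducible under a fixed seed", {
  set.seed(32)
  days <- seq(0, 120, by = 12)
  y <- pmin(pmax(logistic_curve(days, 1, 50, 15) + rnorm(11, 0, 0.03), 0), 1.05)
  d <- tibble::tibble(day = days, y = y)
  f1 <- fit_emergence_model(d, "biphasic", n_starts = 8, seed = 99)
  f2 <- fit_emergence_model(d, "biphasic", n_starts = 8, seed = 99)
  expect_identical(f1$params, f2$params)
})

test_that("parameter bias shrinks as noise shrinks", {
  days <- seq(0, 140, by = 10)
  truth <- gompertz_curve(days, 1, 60, 12)
  med_err <- vapply(c(0.05, 0.001), function(sd) {
    errs <- vapply(1:15, function(r) {
      set.seed(1000 + r)
      y <- pmax(truth + rnorm(length(days), 0, sd), 0)
      f <- fit_emergence_model(tibble::tibble(day = days, y = y), "gompertz",
                               n_starts = 4, seed = r)
      abs(f$params$x0 - 60)
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_lt(med_err[2], med_err[1])
  expect_lt(med_err[2], 0.5)
})

test_that("count validation measures prediction error without touching the fit", {
  days <- seq(0, 140, by = 10)
  d <- tibble::tibble(day = days, y = gompertz_curve(days, 1, 60, 12))
  fit <- fit_emergence_model(d, "gompertz", n_starts = 4, seed = 1)
  # counts from the same truth curve -> near-zero validation error
  cs <- tibble::tibble(quadrat_id = "Q1", day = days,
                       rel_cum = gompertz_curve(days, 1, 60, 12),
                       degenerate = FALSE)
  v <- validate_against_counts(fit, cs)
  expect_lt(v$validation$rmse, 1e-6)
  # a constant 0.1 offset from the predictions is recovered exactly
  shifted <- tibble::tibble(quadrat_id = "Q1", day = days,
                            rel_cum = predict(fit, days) + 0.1,
                            degenerate = FALSE)
  v2 <- validate_against_counts(fit, shifted)
  expect_equal(v2$validation$rmse, 0.1)
  # permuting the count rows leaves the fitted parameters untouched
  perm <- cs[sample(nrow(cs)), ]
  v3 <- validate_against_counts(fit, perm)
  expect_identical(v3$params, fit$params)
  expect_equal(v3$validation$rmse, v$validation$rmse)
  # degenerate count series is rejected
  expect_error(validate_against_counts(
    fit, dplyr::mutate(cs, degenerate = TRUE)), "degenerate")
})

test_that("model comparison ranks by AIC with deltas to the best", {
  days <- seq(0, 140, by = 10)
  d <- tibble::tibble(day = days,
                      y = gompertz_curve(days, 1, 60, 12))
  gom <- fit_emergence_model(d, "gompertz", n_starts = 4, seed = 1)
  single <- compare_models(list(gom))
  expect_equal(single$rank, 1L)
  expect_equal(single$delta_aic, 0)

  fits <- lapply(c("gompertz", "logistic", "weibull"), function(f) {
    fit_emergence_model(d, f, n_starts = 4, seed = 1)
  })
  cmp <- compare_models(fits)
  expect_equal(cmp$aic, sort(cmp$aic))
  expect_equal(cmp$delta_aic, cmp$aic - min(cmp$aic))
  # fits on different data refuse to compare
  d2 <- dplyr::mutate(d, y = y + 0.01)
  other <- fit_emergence_model(d2, "gompertz", n_starts = 4, seed = 1)
  expect_error(compare_models(list(gom, other)), "different")
})

test_that("tidy and glance expose parameters and summary metrics", {
  days <- seq(0, 140, by = 10)
  d <- tibble::tibble(day = days, y = gompertz_curve(days, 1, 60, 12))
  fit <- fit_emergence_model(d, "gompertz", n_starts = 4, seed = 1)
  td <- tidy(fit)
  expect_equal(td$term, c("a", "x0", "b"))
  gl <- glance(fit)
  expect_equal(gl$family, "gompertz")
  expect_true(is.na(gl$validation_rmse))
  gl2 <- glance(validate_against_counts(
    fit, tibble::tibble(day = days, rel_cum = d$y)))
  expect_false(is.na(gl2$validation_rmse))
})
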