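#' Emergence curve families
#'
#' The four cumulative-emergence curve shapes used for weed seedling
#' phenology. All map days to `[0, a]` and are non-decreasing.
#'
#' * **logistic** (simple sigmoid): `y = a / (1 + exp(-(x - x0)/b))`;
#'   `x0` is the half-rise day, `b` the rise scale in days.
#' * **gompertz**: `y = a * exp(-exp(-(x - x0)/b))`; asymmetric, `x0` the
#'   inflection day where `y = a/e`.
#' * **weibull**: `y = a * (1 - exp(-((x - x0 + b*(ln 2)^(1/c)) / b)^c))` for
#'   arguments above the onset day `x0 - b*(ln 2)^(1/c)` and 0 below; the
#'   offset makes `x0` the half-rise day (`y(x0) = a/2`); `c > 0` is the
#'   shape.
#' * **biphasic** (logistic + Weibull mixture): two emergence flushes,
#'   `y = w * logistic(x; 1, x01, b1) + (1 - w) * weibull(x; 1, x02, b2, c2)`
#'   with phase weight `w` in `[0, 1]` and unit asymptote.
#'
#' @param x Days (vectorized).
#' @param a Upper asymptote (fraction of season total).
#' @param x0,x01,x02 Location parameters in days.
#' @param b,b1,b2 Scale parameters in days (> 0).
#' @param c,c2 Weibull shape (> 0).
#' @param w First-phase weight in `[0, 1]`.
#' @return Numeric vector of relative cumulative emergence.
#' @name emergence_curves
NULL

#' @rdname emergence_curves
#' @export
logistic_curve <- function(x, a, x0, b) {
  if (b <= 0) abort("`b` must be > 0.")
  a * stats::plogis((x - x0) / b)
}

#' @rdname emergence_curves
#' @export
gompertz_curve <- function(x, a, x0, b) {
  if (b <= 0) abort("`b` must be > 0.")
  a * exp(-exp(-(x - x0) / b))
}

#' @rdname emergence_curves
#' @export
weibull_curve <- function(x, a, x0, b, c) {
  if (b <= 0 || c <= 0) abort("`b` and `c` must be > 0.")
  shifted <- x - x0 + b * log(2)^(1 / c)
  ifelse(shifted <= 0, 0, a * (1 - exp(-(pmax(shifted, 0) / b)^c)))
}

#' @rdname emergence_curves
#' @export
biphasic_curve <- function(x, w, x01, b1, x02, b2, c2) {
  if (w < 0 || w > 1) abort("`w` must lie in [0, 1].")
  w * logistic_curve(x, 1, x01, b1) +
    (1 - w) * weibull_curve(x, 1, x02, b2, c2)
}

# family registry: parameter names and free-parameter counts
family_info <- function(family) {
  switch(family,
    logistic = list(par = c("a", "x0", "b"), k = 3L),
    gompertz = list(par = c("a", "x0", "b"), k = 3L),
    weibull  = list(par = c("a", "x0", "b", "c"), k = 4L),
    biphasic = list(par = c("w", "x01", "b1", "x02", "b2", "c2"), k = 6L),
    abort(sprintf("Unknown family '%s'.", family))
  )
}

#' Evaluate an emergence curve by family name
#'
#' @param x Days.
#' @param family `"logistic"`, `"gompertz"`, `"weibull"` or `"biphasic"`.
#' @param params Named list/vector of that family's parameters.
#' @return Numeric vector of curve values.
#' @export
emergence_curve <- function(x, family, params) {
  p <- as.list(params)
  switch(family,
    logistic = logistic_curve(x, p$a, p$x0, p$b),
    gompertz = gompertz_curve(x, p$a, p$x0, p$b),
    weibull  = weibull_curve(x, p$a, p$x0, p$b, p$c),
    biphasic = biphasic_curve(x, p$w, p$x01, p$b1, p$x02, p$b2, p$c2),
    abort(sprintf("Unknown family '%s'.", family))
  )
}

#' Goodness-of-fit metrics
#'
#' Sum of squared errors, RMSE, coefficient of determination, and AIC in the
#' least-squares form `n * ln(SSE/n) + 2*(k + 1)` (the error variance counted
#' as a parameter). Lower (more negative) AIC indicates a better fit among
#' models of the same data.
#'
#' @param observed,predicted Equal-length numeric vectors (`n >= 2`,
#'   `n > k`).
#' @param k Number of free model parameters.
#' @return One-row tibble: `n`, `k`, `sse`, `rmse`, `r_squared`, `aic`,
#'   `tss_zero` (flag: R-squared undefined because the observations are
#'   constant).
#' @export
goodness_of_fit <- function(observed, predicted, k) {
  n <- length(observed)
  if (length(predicted) != n) abort("Lengths differ.")
  if (n < 2 || n <= k) abort("Need n >= 2 and n > k.")
  sse <- sum((observed - predicted)^2)
  tss <- sum((observed - mean(observed))^2)
  tibble::tibble(
    n = n, k = as.integer(k), sse = sse,
    rmse = sqrt(sse / n),
    r_squared = if (tss > 0) 1 - sse / tss else NA_real_,
    aic = n * log(sse / n) + 2 * (k + 1),
    tss_zero = tss == 0
  )
}

# data-driven crossing day of the pooled mean series at level q
day_at_level <- function(day, y, q) {
  o <- order(day)
  d <- tapply(y[o], day[o], mean)
  dd <- as.numeric(names(d))
  yy <- as.numeric(d)
  i <- which(yy >= q)[1]
  if (is.na(i)) return(max(dd))
  if (i == 1) return(dd[1])
  dd[i - 1] + (q - yy[i - 1]) / (yy[i] - yy[i - 1]) * (dd[i] - dd[i - 1])
}

# heuristic start and box bounds for one family
fit_setup <- function(family, day, y) {
  span <- max(diff(range(day)), 1)
  a0 <- min(max(y), 1.05)
  x50 <- day_at_level(day, y, 0.5 * max(y))
  b0 <- max((day_at_level(day, y, 0.75 * max(y)) -
               day_at_level(day, y, 0.25 * max(y))) / 2, span / 50)
  lo_x <- min(day) - span; hi_x <- max(day) + span
  switch(family,
    logistic = list(start = c(a = a0, x0 = x50, b = b0),
                    lower = c(0.05, lo_x, 1e-3),
                    upper = c(1.05, hi_x, 3 * span)),
    gompertz = list(start = c(a = a0, x0 = day_at_level(day, y, 0.37 * max(y)), b = b0),
                    lower = c(0.05, lo_x, 1e-3),
                    upper = c(1.05, hi_x, 3 * span)),
    weibull = list(start = c(a = a0, x0 = x50, b = max(span / 4, 1), c = 2),
                   lower = c(0.05, lo_x, 1e-3, 0.2),
                   upper = c(1.05, hi_x, 3 * span, 10)),
    biphasic = list(start = c(w = 0.5,
                              x01 = day_at_level(day, y, 0.25 * max(y)),
                              b1 = b0,
                              x02 = day_at_level(day, y, 0.75 * max(y)),
                              b2 = max(span / 4, 1), c2 = 2),
                    lower = c(0, lo_x, 1e-3, lo_x, 1e-3, 0.2),
                    upper = c(1, hi_x, 3 * span, hi_x, 3 * span, 10))
  )
}

#' Fit an emergence model by bounded nonlinear least squares
#'
#' Minimizes the sum of squared errors between a pooled relative cumulative
#' series and a curve family, using Levenberg--Marquardt with box
#' constraints and a deterministic multi-start scheme: the first start comes
#' from data-driven heuristics (half-rise day, central-rise span), the rest
#' are seeded jitters of it. The best-SSE converged start wins.
#'
#' @param data Observation table with columns `day` and `y` (e.g. from
#'   [merge_quadrats()]).
#' @param family Curve family name.
#' @param n_starts Number of starting points (default 12).
#' @param seed Integer seed controlling the jittered starts.
#' @return An `emergence_fit` object; see [glance.emergence_fit()] and
#'   [tidy.emergence_fit()].
#' @export
fit_emergence_model <- function(data, family = c("logistic", "gompertz",
                                                 "weibull", "biphasic"),
                                n_starts = 12, seed = 1) {
  family <- match.arg(family)
  info <- family_info(family)
  day <- data$day; y <- data$y
  if (all(y == 0)) abort("Degenerate all-zero series cannot be fitted.")
  if (length(y) <= info$k) {
    abort(sprintf("Need more than %d observations to fit a %s model.",
                  info$k, family))
  }
  setup <- fit_setup(family, day, y)
  span <- max(diff(range(day)), 1)

  starts <- with_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      if (i == 1) return(setup$start)
      s <- setup$start
      for (j in seq_along(s)) {
        nm <- names(s)[j]
        s[j] <- if (nm == "w") runif(1) else if (grepl("^x0", nm)) {
          s[j] + rnorm(1, 0, span / 5)
        } else if (nm == "a") {
          s[j] * exp(rnorm(1, 0, 0.1))
        } else {
          s[j] * exp(rnorm(1, 0, 0.5))
        }
      }
      pmin(pmax(s, setup$lower), setup$upper)
    })
  })

  resid_fn <- function(par) {
    y - emergence_curve(day, family, as.list(setNames(par, info$par)))
  }
  best <- NULL
  diagnostics <- character(0)
  for (s in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = s, lower = setup$lower, upper = setup$upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      diagnostics <- c(diagnostics, conditionMessage(res))
      next
    }
    sse <- res$deviance
    if (is.null(best) || sse < best$sse) {
      best <- list(par = res$par, sse = sse, info = res$info,
                   message = res$message)
    }
  }
  if (is.null(best)) {
    abort(paste0("No start converged for family '", family, "'. Diagnostics: ",
                 paste(unique(diagnostics), collapse = "; ")))
  }
  params <- as.list(setNames(as.numeric(best$par), info$par))
  gof <- goodness_of_fit(y, emergence_curve(day, family, params), info$k)
  structure(list(
    family = family, params = params,
    n = gof$n, k = gof$k, sse = gof$sse, rmse = gof$rmse,
    r_squared = gof$r_squared, aic = gof$aic,
    validation = NULL,
    data = tibble::as_tibble(data[, intersect(c("quadrat_id", "day", "y"),
                                              names(data))]),
    data_hash = rlang::hash(list(round(day, 9), round(y, 12))),
    n_starts = n_starts, seed = seed,
    convergence = list(info = best$info, message = best$message)
  ), class = "emergence_fit")
}

#' @export
print.emergence_fit <- function(x, ...) {
  cat(sprintf("<emergence_fit> %s, n = %d, k = %d\n", x$family, x$n, x$k))
  cat("  params:", paste(sprintf("%s = %.4g", names(x$params),
                                 unlist(x$params)), collapse = ", "), "\n")
  cat(sprintf("  AIC %.2f | RMSE %.4f | R^2 %.4f\n", x$aic, x$rmse,
              x$r_squared))
  if (!is.null(x$validation)) {
    cat(sprintf("  validation RMSE %.4f | R^2 %.4f\n",
                x$validation$rmse, x$validation$r_squared))
  }
  invisible(x)
}

#' Predict from a fitted emergence model
#'
#' @param object An `emergence_fit`.
#' @param newdata Optional tibble with a `day` column (or numeric days);
#'   defaults to the fitted days.
#' @param ... Unused.
#' @return Numeric vector of predicted relative cumulative emergence.
#' @export
predict.emergence_fit <- function(object, newdata = NULL, ...) {
  day <- if (is.null(newdata)) {
    object$data$day
  } else if (is.numeric(newdata)) {
    newdata
  } else {
    newdata$day
  }
  emergence_curve(day, object$family, object$params)
}

#' Validate a pixel-derived model against true-count emergence
#'
#' Evaluates the fitted curve (built from pixel data only) at the days of a
#' count-derived relative cumulative series and reports RMSE and R-squared of
#' predictions versus the count data. The count series never influences the
#' fitted parameters. Days outside the fitted span are extrapolated with a
#' warning, not rejected.
#'
#' @param fit An `emergence_fit`.
#' @param count_series An `emergence_series` built from true counts, or any
#'   table with `day` and `rel_cum` (or `y`) columns.
#' @return The fit with its `validation` element populated (`rmse`,
#'   `r_squared`, `n`).
#' @export
validate_against_counts <- function(fit, count_series) {
  stopifnot(inherits(fit, "emergence_fit"))
  tab <- tibble::as_tibble(count_series)
  ycol <- if ("rel_cum" %in% names(tab)) "rel_cum" else "y"
  if ("degenerate" %in% names(tab)) {
    if (all(tab$degenerate)) abort("Count series is degenerate (all zero).")
    tab <- tab[!tab$degenerate, ]
  }
  obs <- tab[[ycol]]
  span <- range(fit$data$day)
  if (any(tab$day < span[1] | tab$day > span[2])) {
    warn("Some validation days lie outside the fitted span; extrapolating.")
  }
  pred <- emergence_curve(tab$day, fit$family, fit$params)
  sse <- sum((obs - pred)^2)
  tss <- sum((obs - mean(obs))^2)
  fit$validation <- list(rmse = sqrt(sse / length(obs)),
                         r_squared = if (tss > 0) 1 - sse / tss else NA_real_,
                         n = length(obs))
  fit
}

#' Rank fitted models by AIC
#'
#' Compares candidate emergence models fitted to the same observation table,
#' ranked by AIC ascending (more negative is better), with the AIC difference
#' to the best model.
#'
#' @param fits List of `emergence_fit` objects on identical data.
#' @return A `model_comparison` tibble: `family`, `k`, `sse`, `rmse`,
#'   `r_squared`, `aic`, `delta_aic`, `rank`, and `validation_rmse` where
#'   available.
#' @export
compare_models <- function(fits) {
  if (inherits(fits, "emergence_fit")) fits <- list(fits)
  hashes <- vapply(fits, function(f) f$data_hash, character(1))
  if (length(unique(hashes)) != 1) {
    abort("Fits were made on different observation tables; cannot compare AIC.")
  }
  out <- dplyr::bind_rows(lapply(fits, function(f) {
    tibble::tibble(family = f$family, k = f$k, sse = f$sse, rmse = f$rmse,
                   r_squared = f$r_squared, aic = f$aic,
                   validation_rmse = f$validation$rmse %||% NA_real_)
  })) |>
    dplyr::arrange(.data$aic) |>
    dplyr::mutate(delta_aic = .data$aic - .data$aic[1],
                  rank = dplyr::row_number())
  class(out) <- c("model_comparison", class(out))
  out
}

#' @rdname tidy.emergence_fit
#' @export
glance.emergence_fit <- function(x, ...) {
  tibble::tibble(family = x$family, n = x$n, k = x$k, sse = x$sse,
                 rmse = x$rmse, r_squared = x$r_squared, aic = x$aic,
                 validation_rmse = x$validation$rmse %||% NA_real_,
                 validation_r_squared = x$validation$r_squared %||% NA_real_)
}

#' Broom-style accessors for emergence fits
#'
#' `tidy()` returns one row per fitted parameter; `glance()` a one-row model
#' summary including validation metrics when present.
#'
#' @param x An `emergence_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.emergence_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unlist(x$params))
}

#' Serialize a fit to JSON
#'
#' @param fit An `emergence_fit`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(family = fit$family, params = fit$params, n = fit$n, k = fit$k,
              sse = fit$sse, rmse = fit$rmse, r_squared = fit$r_squared,
              aic = fit$aic, validation = fit$validation,
              convergence = fit$convergence, n_starts = fit$n_starts,
              seed = fit$seed, data_hash = fit$data_hash)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
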