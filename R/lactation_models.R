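#' Fit the Wood lactation curve
#'
#' Fits the three-parameter Wood model `DMY = a * DIM^b * exp(-c * DIM)` by
#' nonlinear least squares on all records with `dim >= 1`, regardless of
#' perturbations. Initial values come from ordinary least squares on the
#' log-linearised model `log(dmy) = log(a) + b*log(dim) - c*dim` (rows with
#' `dmy > 0`), followed by Levenberg-Marquardt refinement with the
#' constraints `a > 0`, `c >= 0`. If the refinement fails to converge the
#' best available iterate is returned with `converged = FALSE`.
#'
#' @param series A data frame with columns `dim` (integer days in milk) and
#'   `dmy` (kg/day) for one lactation.
#' @return An object of class `wood_fit`: parameters `a` (kg scale), `b`
#'   (dimensionless shape), `c` (per-day decay), plus `converged`, `rss`,
#'   `n`, and the fitting data.
#' @examples
#' dims <- 1:305
#' series <- data.frame(dim = dims, dmy = 20 * dims^0.2 * exp(-0.003 * dims))
#' fit <- fit_wood(series)
#' coef(fit)
#' @export
fit_wood <- function(series) {
  df <- dplyr::filter(series, .data$dim >= 1, is.finite(.data$dmy))
  if (nrow(df) < 3) abort("degenerate series: fewer than 3 usable records")
  if (all(df$dmy == 0)) abort("degenerate series: all dmy zero")

  pos <- df[df$dmy > 0, , drop = FALSE]
  init <- tryCatch({
    cf <- coef(lm(log(dmy) ~ log(dim) + dim, data = pos))
    list(a = exp(cf[[1]]), b = cf[[2]], c = max(-cf[[3]], 0))
  }, error = function(e) list(a = mean(pos$dmy), b = 0.2, c = 0.003))
  if (!is.finite(init$a) || init$a <= 0) init$a <- max(mean(pos$dmy), 1e-6)

  fit <- tryCatch(
    minpack.lm::nlsLM(dmy ~ a * dim^b * exp(-c * dim), data = df,
                      start = init, lower = c(a = 1e-9, b = -10, c = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  if (is.null(fit)) {
    pars <- init
    pred <- pars$a * df$dim^pars$b * exp(-pars$c * df$dim)
    rss <- sum((df$dmy - pred)^2)
    converged <- FALSE
  } else {
    cf <- coef(fit)
    pars <- list(a = cf[["a"]], b = cf[["b"]], c = cf[["c"]])
    rss <- sum(residuals(fit)^2)
    converged <- fit$convInfo$isConv %||% TRUE
  }
  structure(list(a = pars$a, b = pars$b, c = pars$c, converged = converged,
                 rss = rss, n = nrow(df), data = tibble::as_tibble(df)),
            class = "wood_fit")
}

#' @export
coef.wood_fit <- function(object, ...) {
  c(a = object$a, b = object$b, c = object$c)
}

#' @export
print.wood_fit <- function(x, ...) {
  cat(sprintf("Wood lactation curve: a = %.4g, b = %.4g, c = %.4g (%s, n = %d)\n",
              x$a, x$b, x$c,
              if (x$converged) "converged" else "NOT converged", x$n))
  invisible(x)
}

#' Evaluate a Wood curve
#'
#' @param p A `wood_fit` or a list/vector with elements `a`, `b`, `c`.
#' @param dim Integer day(s) in milk, all `>= 1` (the power `dim^b` is
#'   undefined for non-positive `dim` and real `b`).
#' @return Predicted milk yield in kg/day, same length as `dim`.
#' @export
wood_predict <- function(p, dim) {
  if (any(dim <= 0)) abort("wood_predict requires dim >= 1")
  p <- as.list(coef_abc(p))
  p$a * dim^p$b * exp(-p$c * dim)
}

coef_abc <- function(p) {
  if (inherits(p, "wood_fit")) coef(p) else c(a = p[["a"]], b = p[["b"]], c = p[["c"]])
}

#' Geometry of a fitted Wood curve
#'
#' Summarises the curve shape: peak day `b/c` (clipped to `[1, horizon]`),
#' peak yield, average slopes from day 1 to the peak and from the peak to the
#' horizon, and cumulative yields over days 1-50 and 1-`horizon` (daily
#' summation).
#'
#' @param p A `wood_fit` or list with `a`, `b`, `c`.
#' @param horizon Last day of the standard lactation (default 305).
#' @return A one-row tibble: `peak_dim`, `peak_yield` (kg), `slope_to_peak`
#'   and `slope_after_peak` (kg/day), `cum_yield_50` and `cum_yield_305` (kg).
#' @export
wood_geometry <- function(p, horizon = 305) {
  cf <- coef_abc(p)
  peak_dim <- if (cf[["c"]] > 0) cf[["b"]] / cf[["c"]] else Inf
  peak_dim <- min(max(peak_dim, 1), horizon)
  peak_yield <- wood_predict(p, peak_dim)
  y1 <- wood_predict(p, 1)
  yh <- wood_predict(p, horizon)
  slope_to_peak <- if (peak_dim > 1) (peak_yield - y1) / (peak_dim - 1) else 0
  slope_after_peak <- if (peak_dim < horizon) (yh - peak_yield) / (horizon - peak_dim) else 0
  daily <- wood_predict(p, seq_len(horizon))
  tibble::tibble(peak_dim = peak_dim, peak_yield = peak_yield,
                 slope_to_peak = slope_to_peak,
                 slope_after_peak = slope_after_peak,
                 cum_yield_50 = sum(daily[1:50]),
                 cum_yield_305 = sum(daily))
}

# Pinball (check) loss minimiser: iteratively reweighted least squares with
# an annealed smoothing floor on |residual|. Deterministic: OLS start, fixed
# annealing schedule, no random restarts. Returns the coefficient vector for
# the design matrix X.
fit_pinball <- function(X, y, tau, max_iter = 60, tol = 1e-12,
                        eps_schedule = c(1e-2, 1e-4, 1e-6, 1e-8)) {
  stopifnot(tau > 0, tau < 1)
  beta <- qr.coef(qr(X), y)
  pinball <- function(r) sum(ifelse(r >= 0, tau * r, (tau - 1) * r))
  iters <- 0L
  for (eps in eps_schedule) {
    prev <- Inf
    for (it in seq_len(max_iter)) {
      r <- as.numeric(y - X %*% beta)
      l <- pinball(r)
      iters <- iters + 1L
      if (max(abs(r)) < 1e-12 || abs(prev - l) < tol * (1 + l)) break
      prev <- l
      w <- ifelse(r > 0, tau, 1 - tau) / pmax(abs(r), eps)
      beta_new <- tryCatch(
        solve(crossprod(X, X * w), crossprod(X, w * y)),
        error = function(e) tryCatch(qr.coef(qr(X * sqrt(w)), y * sqrt(w)),
                                     error = function(e2) beta))
      if (any(!is.finite(beta_new))) break
      beta <- beta_new
    }
    if (max(abs(y - X %*% beta)) < 1e-12) break
  }
  r <- as.numeric(y - X %*% beta)
  list(beta = as.numeric(beta), loss = pinball(r), iterations = iters)
}

#' Fit the expected lactation curve
#'
#' Estimates the perturbation-free "expected" production trajectory as a
#' fourth-order polynomial quantile regression of `dmy` on `dim`, fitted on
#' days 11-340 at conditional quantile `tau = 0.7`. The coefficients minimise
#' the check (pinball) loss `sum(rho_tau(dmy - poly(dim)))`; the fit is
#' deterministic. Internally the polynomial basis uses `dim/100` for
#' conditioning; coefficients are stored on the raw `dim` scale.
#'
#' @param series Data frame with columns `dim` and `dmy`.
#' @param tau Conditional quantile, default 0.7.
#' @param window Inclusive fitting window in days, default `c(11, 340)`.
#' @return An object of class `expected_curve` with `coefficients`
#'   (`c0`..`c4`, polynomial in `dim`), `tau`, `window`, the final pinball
#'   `loss` and number of in-window observations `n`. Predictions (see
#'   [predict.expected_curve()]) are clipped at 0 kg.
#' @export
fit_expected_curve <- function(series, tau = 0.7, window = c(11, 340)) {
  df <- dplyr::filter(series, .data$dim >= window[[1]], .data$dim <= window[[2]],
                      is.finite(.data$dmy))
  if (nrow(df) < 5) abort("insufficient window data: need >= 5 records in window")
  x <- df$dim / 100
  X <- cbind(1, x, x^2, x^3, x^4)
  fit <- fit_pinball(X, df$dmy, tau)
  coefs <- fit$beta / 100^(0:4)
  names(coefs) <- paste0("c", 0:4)
  structure(list(coefficients = coefs, tau = tau, window = window,
                 loss = fit$loss, iterations = fit$iterations, n = nrow(df)),
            class = "expected_curve")
}

#' @export
coef.expected_curve <- function(object, ...) object$coefficients

#' Predict from an expected lactation curve
#'
#' @param object An `expected_curve`.
#' @param dim Day(s) in milk.
#' @param ... Unused.
#' @return Predicted expected yield in kg/day, clipped at 0.
#' @export
predict.expected_curve <- function(object, dim, ...) {
  cf <- object$coefficients
  pmax(cf[[1]] + cf[[2]] * dim + cf[[3]] * dim^2 + cf[[4]] * dim^3 + cf[[5]] * dim^4, 0)
}

#' @export
print.expected_curve <- function(x, ...) {
  cat(sprintf("Expected lactation curve: quartic quantile fit, tau = %.2f, days %d-%d, n = %d\n",
              x$tau, x$window[[1]], x$window[[2]], x$n))
  print(signif(x$coefficients, 5))
  invisible(x)
}

#' Construct a curve-residual object
#'
#' Builds the residual container used by the feature operations directly
#' from day, observed and predicted vectors — useful for computing features
#' against an externally supplied expected curve.
#'
#' @param dim Integer days in milk, strictly increasing.
#' @param observed Observed yields (kg/day).
#' @param predicted Predicted yields (kg/day), same length.
#' @param model Label, `"expected"` or `"wood"`.
#' @return A `curve_residuals` tibble with attributes `rmse` and `r2`.
#' @export
curve_residuals <- function(dim, observed, predicted, model = "expected") {
  stopifnot(length(dim) == length(observed),
            length(observed) == length(predicted),
            !is.unsorted(dim, strictly = TRUE))
  new_curve_residuals(dim, observed, predicted, model)
}

new_curve_residuals <- function(dim, observed, predicted, model = "expected") {
  residual <- observed - predicted
  rmse <- sqrt(mean(residual^2))
  sst <- sum((observed - mean(observed))^2)
  r2 <- if (sst > 0) 1 - sum(residual^2) / sst else NA_real_
  structure(tibble::tibble(dim = dim, observed = observed,
                           predicted = predicted, residual = residual),
            rmse = rmse, r2 = r2, model = model,
            class = c("curve_residuals", class(tibble::tibble())))
}

#' Residuals from the expected lactation curve
#'
#' Daily deviations `dmy - max(0, poly(dim))` for observed days inside the
#' curve's fitting window, the basis of the category-4 features, the
#' perturbation detection and the resilience indicators.
#'
#' @param series Data frame with `dim`, `dmy`.
#' @param curve An `expected_curve` from [fit_expected_curve()].
#' @return A `curve_residuals` tibble (`dim`, `observed`, `predicted`,
#'   `residual`) with attributes `rmse` and `r2` computed on the window.
#' @export
expected_residuals <- function(series, curve) {
  df <- dplyr::filter(series, .data$dim >= curve$window[[1]],
                      .data$dim <= curve$window[[2]], is.finite(.data$dmy))
  df <- dplyr::arrange(df, .data$dim)
  new_curve_residuals(df$dim, df$dmy, predict(curve, df$dim), model = "expected")
}

#' Residuals from the Wood curve
#'
#' Daily deviations `dmy - wood(dim)` over all observed days with
#' `dim >= 1`; the basis of the category-2 features.
#'
#' @param series Data frame with `dim`, `dmy`.
#' @param fit A `wood_fit`.
#' @return A `curve_residuals` tibble, as for [expected_residuals()].
#' @export
wood_residuals <- function(series, fit) {
  df <- dplyr::filter(series, .data$dim >= 1, is.finite(.data$dmy))
  df <- dplyr::arrange(df, .data$dim)
  new_curve_residuals(df$dim, df$dmy, wood_predict(fit, df$dim), model = "wood")
}

#' @export
glance.curve_residuals <- function(x, ...) {
  tibble::tibble(model = attr(x, "model"), n = nrow(x),
                 rmse = attr(x, "rmse"), r2 = attr(x, "r2"))
}

#' @export
tidy.wood_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "c"), estimate = c(x$a, x$b, x$c),
                 unit = c("kg", "dimensionless", "per day"))
}

#' @export
glance.wood_fit <- function(x, ...) {
  tibble::tibble(n = x$n, rss = x$rss, rmse = sqrt(x$rss / x$n),
                 converged = x$converged)
}

#' @export
tidy.expected_curve <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @export
glance.expected_curve <- function(x, ...) {
  tibble::tibble(n = x$n, tau = x$tau, pinball_loss = x$loss,
                 iterations = x$iterations)
}

#' Per-animal fitted-model parameter table
#'
#' Fits both lactation models to every animal in a record table and returns
#' one row per animal with the Wood parameters, expected-curve coefficients
#' and goodness-of-fit measures, matching the layout
#' `animal_id,a,b,c,wood_rmse,q0,q1,q2,q3,q4,exp_rmse,exp_r2,converged`.
#'
#' @param records Milk-record tibble covering one or more animals.
#' @return A tibble with one row per animal.
#' @export
model_parameter_table <- function(records) {
  records |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::group_modify(function(df, key) {
      wf <- fit_wood(df)
      ec <- fit_expected_curve(df)
      res <- expected_residuals(df, ec)
      tibble::tibble(a = wf$a, b = wf$b, c = wf$c,
                     wood_rmse = sqrt(wf$rss / wf$n),
                     q0 = ec$coefficients[[1]], q1 = ec$coefficients[[2]],
                     q2 = ec$coefficients[[3]], q3 = ec$coefficients[[4]],
                     q4 = ec$coefficients[[5]],
                     exp_rmse = attr(res, "rmse"), exp_r2 = attr(res, "r2"),
                     converged = wf$converged)
    }) |>
    dplyr::ungroup()
}
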