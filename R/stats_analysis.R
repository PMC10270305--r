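#' Min-max standardisation
#'
#' Rescales a numeric vector to \[0,1\] by `(x - min)/(max - min)`; applied
#' to every sensor feature and to the average-DMY covariate before the group
#' comparisons so regression coefficients are comparable across features.
#'
#' @param x Numeric vector with `max(x) > min(x)`.
#' @return The rescaled vector, with attributes `min` and `max` (so
#'   [minmax_restore()] can invert the transform). `NA`s pass through.
#' @export
minmax_standardize <- function(x) {
  lo <- min(x, na.rm = TRUE)
  hi <- max(x, na.rm = TRUE)
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo) {
    abort("degenerate feature: constant or empty vector")
  }
  structure((x - lo) / (hi - lo), min = lo, max = hi)
}

#' Invert a min-max standardisation
#'
#' @param z Output of [minmax_standardize()] (attributes intact).
#' @return The original-scale vector.
#' @export
minmax_restore <- function(z) {
  lo <- attr(z, "min")
  hi <- attr(z, "max")
  if (is.null(lo) || is.null(hi)) abort("not a minmax_standardize() result")
  as.numeric(z) * (hi - lo) + lo
}

#' Ordinary least squares with leverages and the 1/n mean squared error
#'
#' Fits `response ~ intercept + design` by OLS and returns the pieces the
#' Cook's-distance outlier rule needs: coefficients with two-sided t-test
#' p-values, residuals, hat-diagonal leverages, the number of coefficients
#' `p`, and the mean squared error in its `1/n` form
#' `MSE = mean((y - yhat)^2)`.
#'
#' @param design Data frame of numeric covariates (no intercept column; one
#'   is added). Must be full rank together with the intercept.
#' @param response Numeric response vector.
#' @return An object of class `resil_lm`: list with `coefficients` (tibble:
#'   `term`, `estimate`, `std_error`, `statistic`, `p_value`), `residuals`,
#'   `fitted`, `leverages`, `mse`, `p`, `n`.
#' @export
fit_linear <- function(design, response) {
  stopifnot(is.data.frame(design), nrow(design) == length(response))
  df <- dplyr::bind_cols(tibble::tibble(.y = response), design)
  fit <- lm(.y ~ ., data = df)
  cf <- coef(fit)
  if (anyNA(cf)) {
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(names(cf)[is.na(cf)], collapse = ", ")))
  }
  sm <- summary(fit)$coefficients
  res <- residuals(fit)
  structure(list(
    coefficients = tibble::tibble(
      term = sub("^\\(Intercept\\)$", "intercept", rownames(sm)),
      estimate = unname(sm[, 1]), std_error = unname(sm[, 2]),
      statistic = unname(sm[, 3]), p_value = unname(sm[, 4])),
    residuals = as.numeric(res),
    fitted = as.numeric(fitted(fit)),
    leverages = as.numeric(stats::hatvalues(fit)),
    mse = mean(res^2),
    p = length(cf), n = length(response)),
    class = "resil_lm")
}

#' @export
tidy.resil_lm <- function(x, ...) x$coefficients

#' @export
glance.resil_lm <- function(x, ...) {
  tibble::tibble(n = x$n, p = x$p, mse = x$mse,
                 sum_leverage = sum(x$leverages))
}

#' @export
print.resil_lm <- function(x, ...) {
  cat(sprintf("OLS fit: n = %d, p = %d, MSE (1/n) = %.4g\n", x$n, x$p, x$mse))
  print(x$coefficients)
  invisible(x)
}

#' Cook's distance and the 0.5% influence-removal rule
#'
#' Computes `D_i = r_i^2 / (p * MSE) * h_ii / (1 - h_ii)^2` for every
#' observation of a fitted model (with `MSE` in its `1/n` form) and marks
#' the observations whose distance falls in the top `1 - remove_quantile`
#' tail (default: the 99.5th-to-100th quantile, i.e. the 0.5% most
#' influential observations). The cutoff is the linear-interpolation
#' percentile; observations strictly above it are removed, so for `n`
#' divisible by 200 exactly `0.005 * n` observations are removed (absent
#' ties). An observation with leverage 1 has infinite distance and is always
#' removed.
#'
#' @param fit A `resil_lm` from [fit_linear()].
#' @param remove_quantile Quantile above which observations are removed
#'   (default 0.995).
#' @return A list of class `cooks_result`: `d` (distances), `cutoff`, and
#'   `removed` (logical mask).
#' @export
cooks_distance <- function(fit, remove_quantile = 0.995) {
  stopifnot(inherits(fit, "resil_lm"))
  h <- fit$leverages
  d <- ifelse(h >= 1 - 1e-12, Inf,
              fit$residuals^2 / (fit$p * fit$mse) * h / (1 - h)^2)
  cutoff <- quantile(d[is.finite(d)], remove_quantile, names = FALSE, type = 7)
  structure(list(d = d, cutoff = cutoff, removed = d > cutoff),
            class = "cooks_result")
}

#' @export
print.cooks_result <- function(x, ...) {
  cat(sprintf("Cook's distance: %d of %d observations above the %.4g cutoff\n",
              sum(x$removed), length(x$d), x$cutoff))
  invisible(x)
}

# Fit one min-max-standardised feature, remove the most influential
# observations, refit, and flag Bonferroni-significant terms. Design columns
# that lose all variation after the removal (e.g. a breed represented by a
# couple of animals, all influential) are dropped from the refit.
fit_one_feature <- function(design, y, alpha, remove_quantile) {
  fit0 <- fit_linear(design, y)
  ck <- cooks_distance(fit0, remove_quantile)
  keep <- !ck$removed
  d2 <- design[keep, , drop = FALSE]
  const <- vapply(d2, function(col) diff(range(col)) == 0, logical(1))
  if (any(const)) {
    inform(paste0("term(s) constant after outlier removal, dropped: ",
                  paste(names(d2)[const], collapse = ", ")))
    d2 <- d2[, !const, drop = FALSE]
  }
  fit1 <- fit_linear(d2, y[keep])
  cf <- dplyr::mutate(fit1$coefficients,
                      significant = .data$p_value < alpha)
  list(coefficients = cf, n_removed = sum(ck$removed), n = length(y))
}

analyze_features <- function(data, design, feature_cols, alpha,
                             remove_quantile, model) {
  out <- list(); removed <- list()
  skipped <- character(0)
  for (f in feature_cols) {
    y_raw <- data[[f]]
    if (mean(is.na(y_raw)) > 0.5) {
      inform(paste0("skipping ", f, ": > 50% missing"))
      skipped <- c(skipped, f)
      next
    }
    ok <- !is.na(y_raw)
    if (length(unique(y_raw[ok])) < 2) {
      inform(paste0("skipping ", f, ": constant"))
      skipped <- c(skipped, f)
      next
    }
    y <- minmax_standardize(y_raw[ok])
    r <- fit_one_feature(design[ok, , drop = FALSE], as.numeric(y),
                         alpha, remove_quantile)
    out[[f]] <- dplyr::mutate(r$coefficients, feature = f, .before = 1)
    removed[[f]] <- tibble::tibble(feature = f, n = r$n,
                                   n_removed = r$n_removed)
  }
  structure(list(coefficients = dplyr::bind_rows(out),
                 removed = dplyr::bind_rows(removed),
                 skipped = skipped, alpha = alpha,
                 remove_quantile = remove_quantile, model = model,
                 n = nrow(data)),
            class = "resil_analysis")
}

breed_term_order <- function() {
  c("SIM", "MON", "BSW", "SRB", "NRF", "MRY", "BBL", "JER", "GRO", "DFR", "AYR")
}

#' Breed-group comparison of sensor features
#'
#' For every feature, fits the breed model
#' `SF = intercept + breed proportions + cross + aDMY + error` on
#' min-max-standardised responses: the intercept is the Holstein-Friesian
#' baseline (a purebred HOL row has all breed covariates and `cross` at 0),
#' purebreds carry proportion 1 for their breed, crossbreds 0.5 for their
#' non-HOL breed, `cross` is the heterosis indicator (1 = crossbred), and
#' `aDMY` is the min-max-standardised average daily yield (milk-yield
#' scaling covariate, standardised once per analysis). The 0.5% most
#' influential observations per feature are removed by Cook's distance and
#' the model is refitted; coefficients with `p < alpha` (strict, Bonferroni
#' `0.05/40 = 0.00125` by default) are flagged significant.
#'
#' @param features Feature table from [extract_features()] (must include
#'   `animal_id`, `aDMY` and feature columns).
#' @param classes Classification tibble from [classify_animals()].
#' @param alpha Significance threshold (default `0.05/40`).
#' @param remove_quantile Cook's-distance removal quantile (default 0.995).
#' @param feature_names Features to analyse; defaults to all catalog
#'   features present in `features`.
#' @return A `resil_analysis` object; see [significance_summary()],
#'   [tidy.resil_analysis()].
#' @export
run_breed_analysis <- function(features, classes, alpha = 0.05 / 40,
                               remove_quantile = 0.995,
                               feature_names = NULL) {
  df <- dplyr::inner_join(features, classes, by = "animal_id") |>
    dplyr::filter(.data$class %in% c("purebred", "crossbred"))
  if (nrow(df) == 0) abort("no purebred or crossbred animals")
  design <- tibble::tibble(.rows = nrow(df))
  for (b in breed_term_order()) {
    prop <- ifelse(df$class == "purebred" & df$breed == b, 1,
                   ifelse(df$class == "crossbred" & df$breed == b, 0.5, 0))
    if (any(prop > 0)) design[[b]] <- prop
  }
  absent <- setdiff(breed_term_order(), names(design))
  if (length(absent) > 0) {
    inform(paste0("breed(s) absent from data, no coefficient: ",
                  paste(absent, collapse = ", ")))
  }
  design$cross <- as.numeric(df$class == "crossbred")
  design$aDMY <- as.numeric(minmax_standardize(df$aDMY))
  feature_names <- feature_names %||%
    intersect(feature_catalog()$name, names(features))
  analyze_features(df, design, feature_names, alpha, remove_quantile,
                   model = "breed")
}

#' Herd-group comparison of sensor features (SEL50 vs SEL99)
#'
#' For every feature, fits `SF = intercept + SEL + aDMY + error` on
#' min-max-standardised responses, where `SEL` is 1 for cows in SEL50 herds
#' (mean herd HOL fraction below 0.50) and 0 for SEL99 herds (at least
#' 0.99); a positive coefficient therefore means a higher value in SEL50.
#' Cook's-distance removal and Bonferroni flagging as in
#' [run_breed_analysis()]. With `hol_only = TRUE` the comparison is
#' restricted to purebred Holstein-Friesian cows, isolating the herd
#' environment from breed composition.
#'
#' @param features Feature table with `animal_id`, `herd_id`, `aDMY` and
#'   feature columns.
#' @param herd_labels Labelled herd tibble from [build_subset_B()] (columns
#'   `herd_id`, `label`, `selected`), or any tibble with `herd_id` and
#'   `label` in `c("SEL50", "SEL99")`.
#' @param classes Optional [classify_animals()] output; required when
#'   `hol_only = TRUE`.
#' @param hol_only Restrict to purebred HOL cows (default FALSE).
#' @inheritParams run_breed_analysis
#' @return A `resil_analysis` object.
#' @export
run_herd_analysis <- function(features, herd_labels, classes = NULL,
                              hol_only = FALSE, alpha = 0.05 / 40,
                              remove_quantile = 0.995,
                              feature_names = NULL) {
  labs <- herd_labels
  if ("selected" %in% names(labs)) labs <- labs[labs$selected, , drop = FALSE]
  labs <- dplyr::filter(labs, .data$label %in% c("SEL50", "SEL99"))
  df <- dplyr::inner_join(features, labs[, c("herd_id", "label")],
                          by = "herd_id")
  if (hol_only) {
    if (is.null(classes)) abort("hol_only = TRUE requires `classes`")
    hol_ids <- classes$animal_id[classes$class == "purebred" &
                                 classes$breed == "HOL"]
    df <- dplyr::filter(df, .data$animal_id %in% hol_ids)
  }
  n_groups <- table(df$label)
  if (length(n_groups) < 2 || any(n_groups == 0)) {
    abort("both SEL50 and SEL99 must be non-empty")
  }
  design <- tibble::tibble(
    SEL = as.numeric(df$label == "SEL50"),
    aDMY = as.numeric(minmax_standardize(df$aDMY)))
  feature_names <- feature_names %||%
    intersect(feature_catalog()$name, names(features))
  analyze_features(df, design, feature_names, alpha, remove_quantile,
                   model = "herd")
}

#' @export
tidy.resil_analysis <- function(x, ...) x$coefficients

#' @export
glance.resil_analysis <- function(x, ...) {
  tibble::tibble(model = x$model, n = x$n,
                 n_features = length(unique(x$coefficients$feature)),
                 alpha = x$alpha,
                 n_significant = sum(x$coefficients$significant))
}

#' @export
print.resil_analysis <- function(x, ...) {
  cat(sprintf("%s-model analysis: %d animals, %d features, alpha = %.5g\n",
              x$model, x$n, length(unique(x$coefficients$feature)), x$alpha))
  print(significance_summary(x))
  invisible(x)
}

#' Per-term, per-category significance summary
#'
#' Summarises, for each model term (breed proportion, heterosis or SEL) and
#' each feature category, the percentage of features whose coefficient is
#' Bonferroni-significant — e.g. 8 significant of 11 category-4 features
#' gives 72.7. A `Total` row per term aggregates over all categories.
#'
#' @param x A `resil_analysis`, or a coefficient tibble with columns
#'   `feature`, `term`, `significant`.
#' @param terms Terms to summarise; defaults to all except the intercept and
#'   the `aDMY` covariate.
#' @param catalog Feature catalog mapping features to categories.
#' @return A tibble of class `resil_summary`: `term`, `category` (1-6 or
#'   `"Total"`), `n_significant`, `n_features`, `percentage`.
#' @export
significance_summary <- function(x, terms = NULL,
                                 catalog = feature_catalog()) {
  cf <- if (inherits(x, "resil_analysis")) x$coefficients else
    tibble::as_tibble(x)
  terms <- terms %||% setdiff(unique(cf$term), c("intercept", "aDMY"))
  cf <- dplyr::filter(cf, .data$term %in% terms)
  cf <- dplyr::inner_join(cf, catalog[, c("name", "category")],
                          by = c(feature = "name"))
  by_cat <- cf |>
    dplyr::group_by(.data$term, category = as.character(.data$category)) |>
    dplyr::summarise(n_significant = sum(.data$significant),
                     n_features = dplyr::n(), .groups = "drop")
  total <- cf |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(category = "Total",
                     n_significant = sum(.data$significant),
                     n_features = dplyr::n(), .groups = "drop")
  out <- dplyr::bind_rows(by_cat, total) |>
    dplyr::mutate(percentage = 100 * .data$n_significant / .data$n_features) |>
    dplyr::arrange(.data$term, .data$category)
  class(out) <- c("resil_summary", class(out))
  out
}
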