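#' Detect milk-yield perturbations
#'
#' A perturbation is a maximal run of at least `min_len` consecutive observed
#' days on which the yield lies below the expected curve (negative residual;
#' a missing day breaks the run) *and* that reaches below `major_threshold`
#' (85%) of the expected production on at least one day. Negative-residual
#' runs that never drop below the threshold are ordinary variation around a
#' 0.7-quantile curve (which leaves most days slightly negative by
#' construction) and are counted by `ExpNeg_5d`, not here. An episode is
#' classed *major* when it holds at least `min_len` successive days below
#' the threshold, otherwise *minor*. The deepest day is the (earliest, on
#' ties) day of maximum daily deficit; the development phase runs from the
#' start to the deepest day inclusive, the recovery phase from the day after
#' the deepest day to the end.
#'
#' @param fit A `curve_residuals` object from [expected_residuals()] (or any
#'   data frame with columns `dim`, `observed`, `predicted`, `residual`).
#' @param min_len Minimum episode length in days (default 5).
#' @param major_threshold Fraction of expected yield below which a day
#'   counts as deep (default 0.85); one deep day qualifies an episode,
#'   `min_len` successive deep days make it major.
#' @param tol Numerical guard in kg: a day counts as below the curve only if
#'   its residual is below `-tol` (default 1e-3, one gram of milk), so
#'   floating-point-level deviations from the fitted curve never form an
#'   episode.
#' @return A tibble with one row per perturbation: `start_dim`, `end_dim`,
#'   `deepest_dim`, `severity` (`"minor"`/`"major"`), `dev_days`, `rec_days`,
#'   `milk_loss` (kg, summed deficit over observed episode days) and
#'   `deepest_deficit` (kg). Zero rows when no perturbation is found.
#' @export
detect_perturbations <- function(fit, min_len = 5, major_threshold = 0.85,
                                 tol = 1e-3) {
  d <- detect_perturbations_core(fit$dim, fit$observed, fit$predicted,
                                 min_len, major_threshold, tol)
  tibble::new_tibble(d, nrow = length(d$start_dim))
}

# Episode detection on plain vectors; called per lactation in population
# runs, so it avoids tibble/dplyr overhead.
detect_perturbations_core <- function(dim, observed, predicted,
                                      min_len = 5, major_threshold = 0.85,
                                      tol = 1e-3) {
  empty <- list(start_dim = integer(), end_dim = integer(),
                deepest_dim = integer(), severity = character(),
                dev_days = integer(), rec_days = integer(),
                milk_loss = numeric(), deepest_deficit = numeric())
  n <- length(dim)
  if (n == 0) return(empty)
  if (is.unsorted(dim)) {
    o <- order(dim)
    dim <- dim[o]; observed <- observed[o]; predicted <- predicted[o]
  }
  residual <- observed - predicted
  neg <- residual < -tol
  if (!any(neg)) return(empty)
  # new run whenever negativity starts or observed days are not consecutive
  brk <- c(TRUE, diff(dim) != 1 | !neg[-n] | !neg[-1])
  run_id <- cumsum(brk)
  lens <- tabulate(run_id[neg], nbins = run_id[n])
  keep_runs <- which(lens >= min_len)
  if (length(keep_runs) == 0) return(empty)
  out <- empty
  k <- 0L
  for (rid in keep_runs) {
    ix <- which(run_id == rid)
    deficit <- predicted[ix] - observed[ix]
    ratio <- ifelse(predicted[ix] > 0, observed[ix] / predicted[ix], 1)
    below <- ratio < major_threshold
    if (!any(below)) next
    deep <- which.max(deficit)  # which.max returns the earliest maximum
    # longest stretch of successive deep days decides the severity
    r <- rle(below)
    deep_run <- max(r$lengths[r$values])
    k <- k + 1L
    out$start_dim[k] <- dim[ix[1]]
    out$end_dim[k] <- dim[ix[length(ix)]]
    out$deepest_dim[k] <- dim[ix[deep]]
    out$severity[k] <- if (deep_run >= min_len) "major" else "minor"
    out$dev_days[k] <- dim[ix[deep]] - dim[ix[1]] + 1L
    out$rec_days[k] <- dim[ix[length(ix)]] - dim[ix[deep]]
    out$milk_loss[k] <- sum(deficit)
    out$deepest_deficit[k] <- deficit[deep]
  }
  out
}

# lag-1 autocorrelation over truly consecutive-day pairs only; the overall
# mean and denominator use all residuals in the window.
ac_lag1 <- function(dim, r) {
  rbar <- mean(r)
  den <- sum((r - rbar)^2)
  if (den == 0) return(NA_real_)
  pair <- which(diff(dim) == 1)
  sum((r[pair] - rbar) * (r[pair + 1] - rbar)) / den
}

moment_skewness <- function(r) {
  m2 <- mean((r - mean(r))^2)
  if (m2 == 0) return(NA_real_)
  mean((r - mean(r))^3) / m2^1.5
}

# counts of maximal runs of >= min_len consecutive observed negative days
# (same 1-gram numerical guard as detect_perturbations)
count_neg_runs <- function(dim, r, min_len = 5, tol = 1e-3) {
  neg <- r < -tol
  if (!any(neg)) return(0L)
  brk <- c(TRUE, diff(dim) != 1 | !neg[-length(neg)] | !neg[-1])
  lens <- tabulate(cumsum(brk)[neg])
  sum(lens[lens > 0] >= min_len)
}

one_row <- function(x) tibble::new_tibble(as.list(x), nrow = 1L)

wood_res_core <- function(dim, r) {
  list(WoodResVar = var(r), WoodResAClag1 = ac_lag1(dim, r),
       WoodResSkew = moment_skewness(r), WoodResMaxAbs = max(abs(r)),
       WoodResMeanAbs = mean(abs(r)), WoodResRMSE = sqrt(mean(r^2)))
}

exp_res_core <- function(dim, observed, predicted, min_len = 5) {
  r <- observed - predicted
  ratio <- ifelse(predicted > 0, observed / predicted, 1)
  sgn <- sign(r)
  sst <- sum((observed - mean(observed))^2)
  list(
    ExpRMSE = sqrt(mean(r^2)),
    ExpR2 = if (sst > 0) 1 - sum(r^2) / sst else NA_real_,
    ExpMeanAbsRes = mean(abs(r)), ExpSkew = moment_skewness(r),
    ExpMaxNegRes = min(r), ExpMeanRes = mean(r),
    ExpPercNegative = 100 * mean(r < 0),
    ExpPercLower85 = 100 * mean(ratio < 0.85),
    ExpPercLower70 = 100 * mean(ratio < 0.70),
    ExpNeg_5d = count_neg_runs(dim, r, min_len),
    ExpAutoCorr = sum(sgn[-length(sgn)] * sgn[-1] < 0))
}

pert_core <- function(det) {
  minor <- det$severity == "minor"
  mean0 <- function(x) if (length(x) == 0) 0 else mean(x)
  n <- length(det$severity)
  list(
    PertNoTotal = n, PertNoMinor = sum(minor), PertNoMajor = sum(!minor),
    PertMinDaysDev = mean0(det$dev_days[minor]),
    PertMinDaysRec = mean0(det$rec_days[minor]),
    PertMajDaysDev = mean0(det$dev_days[!minor]),
    PertMajDaysRec = mean0(det$rec_days[!minor]),
    PertMinMilkLoss = sum(det$milk_loss[minor]),
    PertMajMilkLoss = sum(det$milk_loss[!minor]),
    PertTotalLoss = sum(det$milk_loss),
    PertDeepest = if (n == 0) 0 else
      det$deepest_deficit[which.max(det$milk_loss)])
}

resilience_core <- function(dim, r) {
  v <- var(r)
  if (!is.finite(v) || v <= 0) abort("degenerate residuals: zero variance")
  list(LnVar = log(v), ExpAClag1 = ac_lag1(dim, r))
}

#' Category-2 features: Wood-curve residual characteristics
#'
#' Quantifies the day-to-day variation of the yield around the Wood curve
#' fitted on all data: variance, lag-1 autocorrelation (consecutive-day
#' pairs), moment skewness, maximum and mean absolute residual, and RMSE.
#'
#' @param fit A `curve_residuals` object from [wood_residuals()].
#' @return A one-row tibble: `WoodResVar` (kg^2), `WoodResAClag1`,
#'   `WoodResSkew`, `WoodResMaxAbs` (kg), `WoodResMeanAbs` (kg),
#'   `WoodResRMSE` (kg).
#' @export
wood_residual_features <- function(fit) {
  one_row(wood_res_core(fit$dim, fit$residual))
}

#' Category-1 and category-3 features: curve shape
#'
#' Category 1 is the geometry of the fitted Wood curve ([wood_geometry()]).
#' Category 3 summarises the expected lactation curve: its maximum over the
#' integer days of the fitting window (earliest day on ties), the average
#' slope from the window start to the peak, and persistency, defined as the
#' average daily change between day 200 and day 305
#' (`(value@305 - value@200)/105`, kg/day; flatter decline = higher
#' persistency, i.e. closer to zero from below).
#'
#' @param wood A `wood_fit`.
#' @param exp_curve An `expected_curve`.
#' @param horizon Wood-curve horizon in days (default 305).
#' @return A one-row tibble with 10 columns: `WoodPeakYield`, `WoodPeakDIM`,
#'   `WoodSlopeToPeak`, `WoodSlopeAfterPeak`, `WoodCumYield50`,
#'   `WoodCumYield305` (category 1) and `ExpPeakYield`, `ExpPeakDIM`,
#'   `ExpSlopeToPeak`, `ExpPersistency` (category 3).
#' @export
curve_shape_features <- function(wood, exp_curve, horizon = 305) {
  g <- wood_geometry(wood, horizon = horizon)
  one_row(c(list(WoodPeakYield = g$peak_yield, WoodPeakDIM = g$peak_dim,
                 WoodSlopeToPeak = g$slope_to_peak,
                 WoodSlopeAfterPeak = g$slope_after_peak,
                 WoodCumYield50 = g$cum_yield_50,
                 WoodCumYield305 = g$cum_yield_305),
            exp_shape_core(exp_curve)))
}

exp_shape_core <- function(curve) {
  w <- curve$window
  grid <- seq(w[[1]], w[[2]])
  pred <- predict(curve, grid)
  pk <- which.max(pred)
  peak_dim <- grid[[pk]]
  list(
    ExpPeakYield = pred[[pk]], ExpPeakDIM = peak_dim,
    ExpSlopeToPeak = if (peak_dim > w[[1]])
      (pred[[pk]] - pred[[1]]) / (peak_dim - w[[1]]) else 0,
    ExpPersistency = (predict(curve, 305) - predict(curve, 200)) / 105)
}

#' Category-4 features: expected-curve residual characteristics
#'
#' Eleven statistics of the daily deviations from the expected lactation
#' curve and its goodness of fit.
#'
#' @param fit A `curve_residuals` object from [expected_residuals()].
#' @param min_len Run length for `ExpNeg_5d` (default 5).
#' @return A one-row tibble: `ExpRMSE` (kg), `ExpR2`, `ExpMeanAbsRes` (kg),
#'   `ExpSkew`, `ExpMaxNegRes` (kg, the most negative residual),
#'   `ExpMeanRes` (kg), `ExpPercNegative` (% days with negative residual),
#'   `ExpPercLower85` (% days with yield below 85% of expected),
#'   `ExpPercLower70` (% below 70%), `ExpNeg_5d` (number of distinct runs of
#'   >= 5 consecutive negative days), `ExpAutoCorr` (number of sign changes
#'   of the residual sequence).
#' @export
expected_residual_features <- function(fit, min_len = 5) {
  one_row(exp_res_core(fit$dim, fit$observed, fit$predicted, min_len))
}

#' Category-5 features: perturbation characteristics
#'
#' Aggregates detected perturbations into the eleven per-lactation
#' perturbation features. Aggregates of an absent class (e.g. no major
#' perturbation) are 0, not missing, so downstream regressions stay
#' complete-case.
#'
#' @param perts A perturbation tibble from [detect_perturbations()].
#' @return A one-row tibble: `PertNoTotal`, `PertNoMinor`, `PertNoMajor`
#'   (counts), `PertMinDaysDev`, `PertMinDaysRec`, `PertMajDaysDev`,
#'   `PertMajDaysRec` (mean days per class), `PertMinMilkLoss`,
#'   `PertMajMilkLoss`, `PertTotalLoss` (kg), `PertDeepest` (kg deficit at
#'   the deepest day of the perturbation with the largest milk loss).
#' @export
perturbation_features <- function(perts) {
  one_row(pert_core(perts))
}

#' Category-6 features: resilience indicators
#'
#' The two resilience indicators derived from the expected-curve residuals:
#' the natural log of their variance (`LnVar`) and the lag-1 autocorrelation
#' computed over truly consecutive-day pairs (`ExpAClag1`). Lower values of
#' both are interpreted as higher resilience.
#'
#' @param fit A `curve_residuals` object from [expected_residuals()].
#' @return A one-row tibble with `LnVar` (log kg^2) and `ExpAClag1`.
#' @export
resilience_indicators <- function(fit) {
  one_row(resilience_core(fit$dim, fit$residual))
}

#' The 40-feature catalog
#'
#' Names, categories, units and definitions of the 40 sensor features and
#' resilience indicators, in the order produced by [extract_features()].
#' Categories: 1 Wood-curve dynamics (6), 2 Wood residuals (6), 3
#' expected-curve dynamics (4), 4 expected-curve residuals (11), 5
#' perturbations (11), 6 resilience indicators (2).
#'
#' @return A 40-row tibble with columns `name`, `category`, `unit`,
#'   `definition`.
#' @export
feature_catalog <- function() {
  tibble::tribble(
    ~name, ~category, ~unit, ~definition,
    "WoodPeakYield", 1L, "kg", "Wood-curve yield at the peak day",
    "WoodPeakDIM", 1L, "days", "Wood-curve peak day b/c, clipped to [1, horizon]",
    "WoodSlopeToPeak", 1L, "kg/day", "average Wood-curve slope from day 1 to the peak",
    "WoodSlopeAfterPeak", 1L, "kg/day", "average Wood-curve slope from the peak to day 305",
    "WoodCumYield50", 1L, "kg", "Wood-curve cumulative yield, days 1-50",
    "WoodCumYield305", 1L, "kg", "Wood-curve cumulative yield, days 1-305",
    "WoodResVar", 2L, "kg^2", "variance of Wood-curve residuals",
    "WoodResAClag1", 2L, "-", "lag-1 autocorrelation of Wood-curve residuals (consecutive days)",
    "WoodResSkew", 2L, "-", "moment skewness of Wood-curve residuals",
    "WoodResMaxAbs", 2L, "kg", "maximum absolute Wood-curve residual",
    "WoodResMeanAbs", 2L, "kg", "mean absolute Wood-curve residual",
    "WoodResRMSE", 2L, "kg", "root mean squared Wood-curve residual",
    "ExpPeakYield", 3L, "kg", "expected-curve maximum on the fitting window",
    "ExpPeakDIM", 3L, "days", "day of the expected-curve maximum",
    "ExpSlopeToPeak", 3L, "kg/day", "average expected-curve slope from window start to peak",
    "ExpPersistency", 3L, "kg/day", "average expected-curve slope, days 200-305",
    "ExpRMSE", 4L, "kg", "root mean squared expected-curve residual",
    "ExpR2", 4L, "-", "R-squared of the expected curve on its window",
    "ExpMeanAbsRes", 4L, "kg", "mean absolute expected-curve residual",
    "ExpSkew", 4L, "-", "moment skewness of expected-curve residuals",
    "ExpMaxNegRes", 4L, "kg", "most negative expected-curve residual",
    "ExpMeanRes", 4L, "kg", "mean expected-curve residual",
    "ExpPercNegative", 4L, "%", "share of days with a negative residual",
    "ExpPercLower85", 4L, "%", "share of days with yield below 85% of expected",
    "ExpPercLower70", 4L, "%", "share of days with yield below 70% of expected",
    "ExpNeg_5d", 4L, "count", "number of runs of >= 5 consecutive negative-residual days",
    "ExpAutoCorr", 4L, "count", "number of sign changes of the residual sequence",
    "PertNoTotal", 5L, "count", "number of perturbations",
    "PertNoMinor", 5L, "count", "number of minor perturbations",
    "PertNoMajor", 5L, "count", "number of major perturbations",
    "PertMinDaysDev", 5L, "days", "mean development days of minor perturbations",
    "PertMinDaysRec", 5L, "days", "mean recovery days of minor perturbations",
    "PertMajDaysDev", 5L, "days", "mean development days of major perturbations",
    "PertMajDaysRec", 5L, "days", "mean recovery days of major perturbations",
    "PertMinMilkLoss", 5L, "kg", "total milk loss over minor perturbations",
    "PertMajMilkLoss", 5L, "kg", "total milk loss over major perturbations",
    "PertTotalLoss", 5L, "kg", "total milk loss over all perturbations",
    "PertDeepest", 5L, "kg", "deficit at the deepest day of the largest-loss perturbation",
    "LnVar", 6L, "log kg^2", "natural log of the expected-curve residual variance",
    "ExpAClag1", 6L, "-", "lag-1 autocorrelation of expected-curve residuals (consecutive days)")
}

#' Extract the 40 sensor features and resilience indicators
#'
#' Runs the full per-lactation pipeline for every animal in a record table:
#' Wood fit (categories 1-2), expected-curve quantile fit (categories 3-6),
#' perturbation detection, and all feature computations. Restricting
#' `categories` skips the fits that are not needed (the Wood fit is only run
#' when category 1 or 2 is requested), which matters for population-scale
#' runs.
#'
#' @param records Milk-record tibble with columns `animal_id`, `dim`, `dmy`
#'   (and optionally `herd_id`), covering one or more animals; each animal's
#'   series should already have passed [eligibility_check()].
#' @param categories Integer subset of 1:6 selecting feature categories.
#' @param quantile_fit `"exact"` fits each lactation's expected curve with
#'   the fully converged pinball minimiser; `"fast"` uses the batched
#'   shared-grid fit (identical model, fixed iteration schedule), much
#'   faster at population scale with typical prediction differences below
#'   0.05 kg.
#' @param tau,window Expected-curve quantile and fitting window.
#' @param horizon Wood-curve horizon (default 305).
#' @param min_len,major_threshold Perturbation detection parameters.
#' @return A tibble with one row per animal: `animal_id`, `herd_id` (if
#'   present), `aDMY` (the animal's mean daily yield, kg) and the selected
#'   feature columns in [feature_catalog()] order. With `categories = 1:6`
#'   exactly 40 feature columns, with category sizes 6/6/4/11/11/2.
#' @export
extract_features <- function(records, categories = 1:6,
                             quantile_fit = c("exact", "fast"),
                             tau = 0.7, window = c(11, 340), horizon = 305,
                             min_len = 5, major_threshold = 0.85) {
  quantile_fit <- match.arg(quantile_fit)
  stopifnot(all(categories %in% 1:6))
  for (col in c("animal_id", "dim", "dmy")) {
    if (!col %in% names(records)) abort(paste0("column ", col, " required"))
  }
  has_herd <- "herd_id" %in% names(records)
  ord <- order(records$animal_id, records$dim)
  aid <- records$animal_id[ord]
  dim_v <- records$dim[ord]
  dmy_v <- records$dmy[ord]
  ids <- unique(aid)
  f <- factor(aid, levels = ids)
  dims_by <- split(dim_v, f)
  dmy_by <- split(dmy_v, f)
  herd_by <- if (has_herd) vapply(split(records$herd_id[ord], f), `[`,
                                  character(1), 1) else NULL

  need_exp <- any(categories %in% 3:6)
  need_wood <- any(categories %in% c(1, 2))
  n_animals <- length(ids)

  # expected-curve coefficients per animal (5 x n, raw dim scale)
  coefs <- NULL
  if (need_exp) {
    grid <- seq(window[[1]], window[[2]])
    in_win <- dim_v >= window[[1]] & dim_v <= window[[2]]
    n_win <- vapply(split(in_win, f), sum, numeric(1))
    if (any(n_win < 5)) {
      abort(paste0("insufficient window data (< 5 records in [",
                   window[[1]], ",", window[[2]], "]) for animal(s): ",
                   paste(ids[n_win < 5], collapse = ", ")))
    }
    if (quantile_fit == "fast") {
      Y <- matrix(0, length(grid), n_animals)
      W <- matrix(0, length(grid), n_animals)
      ri <- dim_v[in_win] - window[[1]] + 1L
      ci <- as.integer(f)[in_win]
      Y[cbind(ri, ci)] <- dmy_v[in_win]
      W[cbind(ri, ci)] <- 1
      coefs <- fit_pinball_batch(grid, Y, W, tau) / 100^(0:4)
    } else {
      coefs <- vapply(seq_len(n_animals), function(i) {
        fit_expected_curve(
          data.frame(dim = dims_by[[i]], dmy = dmy_by[[i]]),
          tau = tau, window = window)$coefficients
      }, numeric(5))
    }
  }

  cat40 <- feature_catalog()
  keep <- cat40$name[cat40$category %in% sort(categories)]
  feat_mat <- matrix(NA_real_, n_animals, length(keep),
                     dimnames = list(NULL, keep))
  aDMY <- vapply(dmy_by, mean, numeric(1))

  # on the fast path category 5 is computed for all cows at once on the grid
  grid5 <- need_exp && quantile_fit == "fast" && 5 %in% categories
  loop_cats <- if (grid5) setdiff(categories, 5) else categories
  if (grid5) {
    Pm <- pmax(cbind(1, grid, grid^2, grid^3, grid^4) %*% coefs, 0)
    g5 <- pert_features_grid(Y, W, Pm, min_len, major_threshold)
    for (nm in names(g5)) feat_mat[, nm] <- g5[[nm]]
    if (length(loop_cats) == 0) {
      base <- list(animal_id = ids)
      if (has_herd) base$herd_id <- unname(herd_by)
      base$aDMY <- unname(aDMY)
      out <- tibble::new_tibble(
        c(base, lapply(seq_along(keep), function(j) unname(feat_mat[, j]))),
        nrow = n_animals)
      names(out) <- c(names(base), keep)
      return(out)
    }
  }
  categories <- loop_cats

  for (i in seq_len(n_animals)) {
    di <- dims_by[[i]]
    yi <- dmy_by[[i]]
    row <- list()
    wf <- NULL
    if (need_wood) {
      series <- data.frame(dim = di, dmy = yi)
      wf <- fit_wood(series)
      if (2 %in% categories) {
        ok <- di >= 1
        row <- c(row, wood_res_core(di[ok], yi[ok] - wood_predict(wf, di[ok])))
      }
    }
    if (need_exp) {
      cf <- coefs[, i]
      ok <- di >= window[[1]] & di <= window[[2]]
      dw <- di[ok]; yw <- yi[ok]
      pw <- pmax(cf[1] + cf[2] * dw + cf[3] * dw^2 + cf[4] * dw^3 +
                   cf[5] * dw^4, 0)
      if (1 %in% categories) {
        g <- wood_geometry(wf, horizon = horizon)
        row <- c(row, list(WoodPeakYield = g$peak_yield,
                           WoodPeakDIM = g$peak_dim,
                           WoodSlopeToPeak = g$slope_to_peak,
                           WoodSlopeAfterPeak = g$slope_after_peak,
                           WoodCumYield50 = g$cum_yield_50,
                           WoodCumYield305 = g$cum_yield_305))
      }
      if (3 %in% categories) {
        curve <- structure(list(coefficients = cf, tau = tau,
                                window = window),
                           class = "expected_curve")
        row <- c(row, exp_shape_core(curve))
      }
      if (4 %in% categories) row <- c(row, exp_res_core(dw, yw, pw, min_len))
      if (5 %in% categories) {
        row <- c(row, pert_core(detect_perturbations_core(
          dw, yw, pw, min_len, major_threshold)))
      }
      if (6 %in% categories) row <- c(row, resilience_core(dw, yw - pw))
    } else if (1 %in% categories) {
      g <- wood_geometry(wf, horizon = horizon)
      row <- c(row, list(WoodPeakYield = g$peak_yield,
                         WoodPeakDIM = g$peak_dim,
                         WoodSlopeToPeak = g$slope_to_peak,
                         WoodSlopeAfterPeak = g$slope_after_peak,
                         WoodCumYield50 = g$cum_yield_50,
                         WoodCumYield305 = g$cum_yield_305))
    }
    feat_mat[i, names(row)] <- unlist(row)
  }

  base <- list(animal_id = ids)
  if (has_herd) base$herd_id <- unname(herd_by)
  base$aDMY <- unname(aDMY)
  out <- tibble::new_tibble(
    c(base, lapply(seq_along(keep), function(j) unname(feat_mat[, j]))),
    nrow = n_animals)
  names(out) <- c(names(base), keep)
  out
}
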