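test_that("min-max standardisation maps to [0,1] and inverts exactly", {
  expect_equal(as.numeric(minmax_standardize(c(2, 4, 6))), c(0, 0.5, 1))
  z <- c(0, 0.25, 1)
  expect_equal(as.numeric(minmax_standardize(z)), z)  # already spans [0,1]
  set.seed(51)
  x <- rnorm(100, 20, 5)
  expect_equal(minmax_restore(minmax_standardize(x)), x, tolerance = 1e-12)
  expect_error(minmax_standardize(rep(3, 10)), "degenerate feature")
})

test_that("fit_linear recovers exact coefficients and satisfies the hat-trace identity", {
  set.seed(52)
  design <- tibble::tibble(x1 = rnorm(200), x2 = runif(200), x3 = rnorm(200))
  beta <- c(2, -1.5, 0.5)
  y <- 1 + as.matrix(design) %*% beta
  fit <- fit_linear(design, as.numeric(y))
  expect_equal(fit$coefficients$estimate, c(1, beta), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sum(fit$leverages), fit$p, tolerance = 1e-10)
  expect_equal(fit$mse, mean(fit$residuals^2))

  dup <- dplyr::mutate(design, x4 = x1 + x2)  # collinear
  expect_error(fit_linear(dup, as.numeric(y)), "collinear.*x4")
})

test_that("null simulation keeps every coefficient within three standard errors", {
  set.seed(53)
  n <- 10000
  design <- tibble::tibble(x1 = rnorm(n), x2 = rbinom(n, 1, 0.3),
                           x3 = runif(n))
  y <- rnorm(n)
  fit <- fit_linear(design, y)
  expect_true(all(abs(fit$coefficients$estimate) <
                    3 * fit$coefficients$std_error))
})

test_that("Cook's distance matches the leave-one-out refit oracle", {
  # four-point design with one influential point
  df <- tibble::tibble(x = c(0, 1, 2, 3))
  y <- c(0, 1, 2, 10)
  fit <- fit_linear(df, y)
  ck <- cooks_distance(fit)
  expect_equal(ck$d[fit$residuals == 0], numeric(0))  # no exact zeros here

  loo_oracle <- function(design, y) {
    X <- cbind(1, as.matrix(design))
    n <- length(y)
    full <- lm.fit(X, y)
    yhat <- X %*% full$coefficients
    mse <- mean((y - yhat)^2)
    p <- ncol(X)
    sapply(seq_len(n), function(i) {
      fi <- lm.fit(X[-i, , drop = FALSE], y[-i])
      yhat_i <- X %*% fi$coefficients
      sum((yhat - yhat_i)^2) / (p * mse)
    })
  }
  expect_equal(ck$d, loo_oracle(df, y), tolerance = 1e-8)

  # zero residual -> zero distance: residual vector (1, -2, 1, 0) is
  # orthogonal to the design, so the fourth point lies on the fitted line
  fit0 <- fit_linear(df, c(0, 1, 2, 3) + c(1, -2, 1, 0))
  expect_equal(abs(fit0$residuals[4]), 0, tolerance = 1e-12)
  expect_equal(cooks_distance(fit0)$d[4], 0, tolerance = 1e-12)

  # larger random designs, n <= 200
  set.seed(54)
  for (rep in 1:3) {
    n <- sample(50:200, 1)
    design <- tibble::tibble(a = rnorm(n), b = runif(n))
    y <- 1 + design$a - design$b + rnorm(n)
    fit <- fit_linear(design, y)
    expect_equal(cooks_distance(fit)$d, loo_oracle(design, y),
                 tolerance = 1e-8)
  }
})

test_that("the 99.5th-percentile rule removes exactly 0.5% for n divisible by 200", {
  set.seed(55)
  for (n in c(200, 1000, 10000)) {
    design <- tibble::tibble(x = rnorm(n), z = runif(n))
    y <- 0.5 * design$x + rnorm(n)
    fit <- fit_linear(design, y)
    ck <- cooks_distance(fit)
    expect_equal(sum(ck$removed), as.integer(0.005 * n))
  }
})

test_that("the breed design encodes proportions, heterosis and the HOL baseline", {
  set.seed(56)
  n_hol <- 6000; n_sim_p <- 1500; n_sim_c <- 1500; n_mry <- 1000
  classes <- dplyr::bind_rows(
    tibble::tibble(animal_id = sprintf("H%05d", 1:n_hol),
                   class = "purebred", breed = "HOL"),
    tibble::tibble(animal_id = sprintf("S%05d", 1:n_sim_p),
                   class = "purebred", breed = "SIM"),
    tibble::tibble(animal_id = sprintf("C%05d", 1:n_sim_c),
                   class = "crossbred", breed = "SIM"),
    tibble::tibble(animal_id = sprintf("M%05d", 1:n_mry),
                   class = "purebred", breed = "MRY"))
  n <- nrow(classes)
  prop_sim <- c(rep(0, n_hol), rep(1, n_sim_p), rep(0.5, n_sim_c),
                rep(0, n_mry))
  features <- tibble::tibble(
    animal_id = classes$animal_id,
    aDMY = rnorm(n, 25, 3),
    LnVar = rnorm(n, 1, 0.5) - 2 * prop_sim,
    ExpAClag1 = rnorm(n, 0.3, 0.1),
    PertNoTotal = rpois(n, 5),
    ExpRMSE = rnorm(n, 2, 0.3))

  res <- run_breed_analysis(features, classes)
  cf <- tidy(res)
  sim_lnvar <- cf[cf$feature == "LnVar" & cf$term == "SIM", ]
  expect_true(sim_lnvar$significant)
  expect_lt(sim_lnvar$estimate, 0)
  # no effect was simulated for MRY or for heterosis on LnVar
  expect_false(cf$significant[cf$feature == "LnVar" & cf$term == "MRY"])
  expect_false(cf$significant[cf$feature == "LnVar" & cf$term == "cross"])
  # SIM is significant on LnVar only
  expect_false(any(cf$significant[cf$term == "SIM" &
                                  cf$feature != "LnVar"]))
  # intercept is the HOL baseline: close to the standardised HOL group mean
  sub <- dplyr::inner_join(features, classes, by = "animal_id")
  y_std <- as.numeric(minmax_standardize(sub$LnVar))
  hol_mean <- mean(y_std[sub$breed == "HOL"])
  int <- cf$estimate[cf$feature == "LnVar" & cf$term == "intercept"]
  expect_equal(int, hol_mean, tolerance = 0.15)
})

test_that("an all-null simulation produces about alpha-level flagging", {
  set.seed(57)
  n <- 4000
  classes <- tibble::tibble(
    animal_id = sprintf("A%05d", 1:n),
    class = sample(c("purebred", "crossbred"), n, TRUE),
    breed = sample(c("HOL", "SIM", "MON", "MRY"), n, TRUE))
  classes$breed[classes$class == "crossbred" & classes$breed == "HOL"] <- "SIM"
  feature_names <- feature_catalog()$name
  features <- tibble::tibble(animal_id = classes$animal_id,
                             aDMY = rnorm(n, 25, 3))
  for (f in feature_names) features[[f]] <- rnorm(n)
  res <- suppressMessages(run_breed_analysis(features, classes))
  cf <- tidy(res)
  tests <- cf[!cf$term %in% c("intercept", "aDMY"), ]
  # 160 tests at alpha = 0.00125: expect ~0.2 false positives
  expect_lte(sum(tests$significant), 3)
})

test_that("the herd model recovers a SEL50 effect and respects hol_only", {
  set.seed(58)
  n_herds <- 40
  herds <- tibble::tibble(
    herd_id = sprintf("H%03d", 1:n_herds),
    label = rep(c("SEL50", "SEL99"), each = n_herds / 2))
  cows_per <- 50
  n <- n_herds * cows_per
  herd_of <- rep(herds$herd_id, each = cows_per)
  sel50 <- rep(herds$label, each = cows_per) == "SEL50"
  features <- tibble::tibble(
    animal_id = sprintf("A%05d", 1:n), herd_id = herd_of,
    aDMY = rnorm(n, 25, 3) - 2 * sel50,
    PertMinDaysRec = rnorm(n, 12, 3) - 3 * sel50,   # shorter recovery in SEL50
    LnVar = rnorm(n, 1, 0.5))
  res <- run_herd_analysis(features, herds)
  cf <- tidy(res)
  rec <- cf[cf$feature == "PertMinDaysRec" & cf$term == "SEL", ]
  expect_true(rec$significant)
  expect_lt(rec$estimate, 0)
  expect_false(cf$significant[cf$feature == "LnVar" & cf$term == "SEL"])

  # identical groups: nothing beyond chance
  features_null <- dplyr::mutate(features,
                                 PertMinDaysRec = rnorm(n, 12, 3))
  res0 <- run_herd_analysis(features_null, herds)
  expect_equal(sum(tidy(res0)$significant[tidy(res0)$term == "SEL"]), 0)

  # hol_only drops all non-purebred-HOL rows
  classes <- tibble::tibble(animal_id = features$animal_id,
                            class = rep_len(c("purebred", "crossbred"), n),
                            breed = rep_len(c("HOL", "SIM"), n))
  res_hol <- run_herd_analysis(features, herds, classes = classes,
                               hol_only = TRUE)
  expect_equal(res_hol$n, n / 2)
  expect_error(run_herd_analysis(features[sel50, ], herds),
               "SEL50 and SEL99")
})

test_that("the significance summary computes 8-of-11 as 72.7%", {
  cat4 <- feature_catalog()$name[feature_catalog()$category == 4]
  cf <- tibble::tibble(feature = cat4, term = "MRY",
                       significant = c(rep(TRUE, 8), rep(FALSE, 3)))
  s <- significance_summary(cf)
  row <- s[s$category == "4", ]
  expect_equal(row$n_significant, 8)
  expect_equal(row$n_features, 11)
  expect_equal(round(row$percentage, 1), 72.7)
  tot <- s[s$category == "Total", ]
  expect_equal(tot$percentage, 100 * 8 / 11)
})

test_that("tidiers expose coefficients and fit summaries", {
  set.seed(59)
  design <- tibble::tibble(x = rnorm(50))
  fit <- fit_linear(design, rnorm(50))
  expect_named(tidy(fit), c("term", "estimate", "std_error", "statistic",
                            "p_value"))
  g <- glance(fit)
  expect_equal(g$n, 50)
  expect_equal(g$p, 2)
})
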