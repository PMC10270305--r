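#' Default breed palette for the simulator
#'
#' Mean daily-yield targets (kg) per breed used to scale the Wood curve of
#' simulated cows. Values are plausibility anchors for Dutch automated-
#' milking herds: Holstein-Friesian highest (~27 kg), Groninger Whiteheaded
#' lowest (~15 kg), the remaining breeds in between.
#'
#' @return A tibble with columns `breed` and `mean_dmy`.
#' @export
breed_palette <- function() {
  tibble::tibble(
    breed = c("HOL", "MRY", "JER", "MON", "SIM", "DFR",
              "BSW", "GRO", "SRB", "NRF", "BBL", "AYR"),
    mean_dmy = c(27.2, 20.4, 18.1, 20.4, 22.3, 21.0,
                 21.8, 14.9, 23.0, 24.6, 21.0, 22.0))
}

#' Simulation configuration
#'
#' Assembles the configuration for [simulate_population()] /
#' [simulate_lactation()]. Defaults describe a population of automated-
#' milking herds of 50-300 cows: Wood-shaped mean curves with breed-specific
#' scale, day-to-day AR(1) noise, sporadic multi-day perturbations with a
#' linear development phase and an exponential recovery phase, and sporadic
#' missing days.
#'
#' @param seed Integer seed; mandatory, the population is a pure function of
#'   the configuration including the seed.
#' @param n_herds Number of herds.
#' @param herd_size_range Cows per herd, inclusive range.
#' @param p_herd_low_hol Share of herds simulated as low-Holstein (mixed
#'   breeds); the rest are near-pure Holstein herds.
#' @param high_hol_purity In a high-Holstein herd, probability that a cow is
#'   purebred HOL (the rest are HOL crossbreds).
#' @param low_hol_hol_share In a low-Holstein herd, probability that a cow is
#'   purebred HOL; the remainder split evenly between purebred non-HOL and
#'   HOL-crossbred cows.
#' @param breeds Breed palette tibble (`breed`, `mean_dmy`).
#' @param breed_weights Named sampling weights for the non-HOL breeds.
#' @param p_carrier_hol,p_carrier_other Probability that a purebred carries a
#'   7/8 + 1/8 composition instead of 8/8 (HOL purebreds vs all others; kept
#'   low for HOL so near-pure Holstein herds stay above 99% HOL genes).
#' @param wood_b,wood_c Population-mean Wood shape parameters.
#' @param cv_scale Lognormal coefficient of variation of the per-cow scale
#'   parameter `a`.
#' @param sd_b,sd_c Between-cow standard deviations of `b` and `c`.
#' @param sigma Marginal standard deviation of the AR(1) daily noise (kg)
#'   for a cow at the Holstein reference production level; each cow's noise
#'   sd scales proportionally with her expected mean yield, reflecting the
#'   mean-variance scaling that motivates the aDMY covariate downstream.
#' @param rho Lag-1 autocorrelation of the daily noise.
#' @param lambda Expected number of perturbations per lactation.
#' @param lambda_multiplier Optional named vector of per-breed multipliers on
#'   `lambda`; a cow's rate scales with its breed composition
#'   (`lambda * sum(fraction_b * multiplier_b)`).
#' @param depth_range Range of the multiplicative floor at the deepest day
#'   (fraction of expected yield remaining, in (0,1)).
#' @param dur_min Minimum perturbation duration in days.
#' @param dur_mean_extra Mean additional days beyond `dur_min` (geometric).
#' @param dev_frac Fraction of the duration spent in the development phase.
#' @param missing_rate Per-day probability that a record is missing.
#' @param len_range Lactation length range in days.
#' @param afc_mean,afc_sd Age at first calving, days.
#' @param calving_years Inclusive calendar-year range for first calvings.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_herds = 10,
                       herd_size_range = c(50, 300),
                       p_herd_low_hol = 0.5,
                       high_hol_purity = 0.995,
                       low_hol_hol_share = 0.25,
                       breeds = breed_palette(),
                       breed_weights = c(SIM = 6, MON = 3, BSW = 2.6,
                                         SRB = 1.9, NRF = 1.3, MRY = 2,
                                         JER = 1, DFR = 0.3, GRO = 0.15,
                                         BBL = 0.4, AYR = 0.05),
                       p_carrier_hol = 0.05, p_carrier_other = 0.3,
                       wood_b = 0.2, wood_c = 0.003,
                       cv_scale = 0.1, sd_b = 0.02, sd_c = 4e-4,
                       sigma = 1.8, rho = 0.3,
                       lambda = 3, lambda_multiplier = NULL,
                       depth_range = c(0.5, 0.95),
                       dur_min = 5, dur_mean_extra = 7,
                       dev_frac = 0.4,
                       missing_rate = 0.005,
                       len_range = c(305, 340),
                       afc_mean = 760, afc_sd = 60,
                       calving_years = c(2015, 2020)) {
  if (missing(seed)) abort("sim_config requires a seed")
  stopifnot(depth_range[1] > 0, depth_range[2] < 1, lambda >= 0,
            sigma >= 0, missing_rate >= 0, dur_min >= 1)
  structure(as.list(environment()), class = "sim_config")
}

# mean of dim^b * exp(-c dim) over days 1..len: converts a mean-DMY target
# into the Wood scale parameter a.
wood_scale_for_mean <- function(mean_dmy, b, c, len = 305) {
  d <- seq_len(len)
  mean_dmy / mean(d^b * exp(-c * d))
}

# classify an injected perturbation from its (noise-free) profile: the
# profile is the yield-to-expected ratio, so the detection rule applies
# directly: "none" if it never drops below the threshold, "major" if it has
# >= min_len successive days below it, else "minor".
truth_profile_class <- function(duration, dev_days, depth,
                                major_threshold = 0.85, min_len = 5) {
  rec <- duration - dev_days
  f <- c(1 - (1 - depth) * seq_len(dev_days) / dev_days,
         if (rec > 0) 1 - (1 - depth) * exp(-3 * seq_len(rec) / rec))
  below <- f < major_threshold
  if (!any(below)) return("none")
  if (max(rle(below)$lengths[rle(below)$values]) >= min_len) "major" else "minor"
}

# multiplicative perturbation profile over `dur` days: linear decline to
# `depth` over the development phase, exponential return towards 1 over the
# recovery phase (strictly below 1 throughout, so every episode day has a
# positive deficit and the deepest day is unique).
perturbation_profile <- function(dur, depth, dev_frac = 0.4) {
  dev <- max(1L, min(dur - 1L, as.integer(round(dev_frac * dur))))
  rec <- dur - dev
  f_dev <- 1 - (1 - depth) * seq_len(dev) / dev
  f_rec <- if (rec > 0) 1 - (1 - depth) * exp(-3 * seq_len(rec) / rec) else numeric(0)
  list(profile = c(f_dev, f_rec), dev_days = dev)
}

# Core single-lactation generator working in plain vectors (no tibbles):
# called tens of thousands of times by simulate_population(). `sigma` is the
# cow's own marginal noise sd (already scaled to her production level).
sim_lactation_core <- function(cfg, a, b, cc, lambda, sigma = cfg$sigma) {
  len <- if (cfg$len_range[1] == cfg$len_range[2]) cfg$len_range[1] else
    sample(seq(cfg$len_range[1], cfg$len_range[2]), 1)
  dims <- seq_len(len)
  base <- a * dims^b * exp(-cc * dims)

  f <- rep(1, len)
  k <- rpois(1, lambda)
  occupied <- rep(FALSE, len)
  ps <- pe <- pd <- pdur <- pdev <- integer(k)
  pdepth <- ploss <- pdeep <- numeric(k)
  np <- 0L
  for (j in seq_len(k)) {
    dur <- cfg$dur_min + rgeom(1, 1 / (1 + cfg$dur_mean_extra))
    depth <- runif(1, cfg$depth_range[1], cfg$depth_range[2])
    last_start <- min(340, len) - dur + 1
    if (last_start < 11) next
    placed <- FALSE
    for (try in 1:30) {
      s <- if (last_start == 11) 11L else sample(11:last_start, 1)
      span <- max(1, s - 2):min(len, s + dur + 1)  # 2-day buffer between episodes
      if (!any(occupied[span])) { placed <- TRUE; break }
    }
    if (!placed) next
    occupied[s:(s + dur - 1)] <- TRUE
    pp <- perturbation_profile(dur, depth, cfg$dev_frac)
    idx <- s:(s + dur - 1)
    f[idx] <- f[idx] * pp$profile
    deficit <- base[idx] * (1 - pp$profile)
    np <- np + 1L
    ps[np] <- s; pe[np] <- s + dur - 1L; pd[np] <- s + pp$dev_days - 1L
    pdur[np] <- as.integer(dur); pdev[np] <- pp$dev_days
    pdepth[np] <- depth; ploss[np] <- sum(deficit)
    pdeep[np] <- deficit[[pp$dev_days]]
  }

  noise <- if (sigma > 0) {
    innov_sd <- sigma * sqrt(1 - cfg$rho^2)
    as.numeric(stats::filter(rnorm(len, 0, innov_sd), cfg$rho,
                             method = "recursive",
                             init = rnorm(1, 0, sigma)))
  } else rep(0, len)

  dmy <- pmax(base * f + noise, 0)
  keep <- rep(TRUE, len)
  if (cfg$missing_rate > 0) {
    keep <- runif(len) > cfg$missing_rate
    keep[1] <- TRUE
  }
  ix <- seq_len(np)
  list(dim = dims[keep], dmy = dmy[keep],
       p_start = ps[ix], p_end = pe[ix], p_deepest = pd[ix],
       p_duration = pdur[ix], p_dev = pdev[ix], p_depth = pdepth[ix],
       p_loss = ploss[ix], p_deep_deficit = pdeep[ix])
}

#' Simulate one lactation
#'
#' Generates a single first-parity lactation: Wood-curve base, injected
#' multiplicative perturbations (placed without overlap inside days 11-340),
#' additive AR(1) Gaussian noise, flooring at 0 kg, and random missing days
#' (day 1 always kept).
#'
#' @param cfg A [sim_config()].
#' @param wood Numeric `c(a, b, c)`; defaults to the HOL palette entry.
#' @param lambda Perturbation rate; defaults to `cfg$lambda`.
#' @param seed Optional seed for a reproducible single draw.
#' @return A list with `series` (tibble `dim`, `dmy`) and `truth` (Wood
#'   parameters, a perturbation tibble with `start_dim`, `end_dim`,
#'   `deepest_dim`, `duration`, `dev_days`, `depth`, `milk_loss`,
#'   `deepest_deficit`, plus `sigma` and `rho`).
#' @export
simulate_lactation <- function(cfg, wood = NULL, lambda = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(wood)) {
    a <- wood_scale_for_mean(cfg$breeds$mean_dmy[cfg$breeds$breed == "HOL"],
                             cfg$wood_b, cfg$wood_c)
    wood <- c(a = a, b = cfg$wood_b, c = cfg$wood_c)
  }
  lambda <- lambda %||% cfg$lambda
  # noise sd scales proportionally with the cow's mean production level,
  # relative to the HOL reference mean (the milk-yield scaling premise that
  # also motivates the aDMY covariate in the group comparisons)
  ref <- cfg$breeds$mean_dmy[cfg$breeds$breed == "HOL"]
  d305 <- seq_len(305)
  cow_mean <- wood[[1]] * mean(d305^wood[[2]] * exp(-wood[[3]] * d305))
  core <- sim_lactation_core(cfg, wood[[1]], wood[[2]], wood[[3]], lambda,
                             sigma = cfg$sigma * cow_mean / ref)
  list(series = tibble::tibble(dim = core$dim, dmy = core$dmy),
       truth = list(wood = wood,
                    perturbations = tibble::tibble(
                      start_dim = core$p_start, end_dim = core$p_end,
                      deepest_dim = core$p_deepest,
                      duration = core$p_duration, dev_days = core$p_dev,
                      depth = core$p_depth, milk_loss = core$p_loss,
                      deepest_deficit = core$p_deep_deficit),
                    sigma = cfg$sigma, rho = cfg$rho))
}

#' Simulate a population of herds
#'
#' Generates herds with a configurable Holstein-fraction mix (supporting
#' SEL50-like and SEL99-like pools), cows with breed compositions in
#' eighths (purebred 8/8 or 7/8 + 1/8; crossbred 4/8 HOL + 4/8 other),
#' breed-scaled Wood curves, and per-cow lactations via the same generator
#' as [simulate_lactation()]. A cow's perturbation rate is
#' `lambda * sum(fraction_b * multiplier_b)` over its breed composition.
#'
#' @param cfg A [sim_config()]; `cfg$seed` makes the output deterministic.
#' @return A list: `records` (milk-record tibble: `animal_id`, `herd_id`,
#'   `parity`, `calving_date`, `dim`, `dmy`), `animals` (long metadata:
#'   `animal_id`, `birth_date`, `first_calving_date`, `age_at_first_calving`,
#'   `breed_code`, `fraction`), `herds` (`herd_id`, `herd_size`,
#'   `mean_hol_fraction`), and `truth` (`cows` tibble with the generating
#'   parameters, `perturbations` tibble keyed by `animal_id`).
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  non_hol <- setdiff(cfg$breeds$breed, "HOL")
  bw <- cfg$breed_weights[non_hol]
  bw[is.na(bw)] <- 0  # breeds absent from breed_weights are not drawn
  if (sum(bw) <= 0) abort("breed_weights must give positive weight to a non-HOL breed")
  names(bw) <- non_hol
  mean_dmy <- setNames(cfg$breeds$mean_dmy, cfg$breeds$breed)
  mult <- setNames(rep(1, nrow(cfg$breeds)), cfg$breeds$breed)
  if (!is.null(cfg$lambda_multiplier)) {
    mult[names(cfg$lambda_multiplier)] <- cfg$lambda_multiplier
  }

  # herd- and cow-level attributes, vectorised
  sizes <- if (cfg$herd_size_range[1] == cfg$herd_size_range[2])
    rep(cfg$herd_size_range[1], cfg$n_herds) else
    sample(seq(cfg$herd_size_range[1], cfg$herd_size_range[2]),
           cfg$n_herds, replace = TRUE)
  herd_low <- runif(cfg$n_herds) < cfg$p_herd_low_hol
  n <- sum(sizes)
  herd_ids <- sprintf("H%04d", seq_len(cfg$n_herds))
  cow_herd <- rep(herd_ids, times = sizes)
  cow_low <- rep(herd_low, times = sizes)
  animal_id <- sprintf("A%06d", seq_len(n))

  u <- runif(n)
  kind <- character(n); main <- character(n)
  lo <- cow_low
  kind[lo & u < cfg$low_hol_hol_share] <- "pure"
  main[lo & u < cfg$low_hol_hol_share] <- "HOL"
  mid <- lo & u >= cfg$low_hol_hol_share &
    u < cfg$low_hol_hol_share + (1 - cfg$low_hol_hol_share) / 2
  kind[mid] <- "pure"
  kind[lo & kind == ""] <- "cross"
  kind[!lo & u < cfg$high_hol_purity] <- "pure"
  main[!lo & u < cfg$high_hol_purity] <- "HOL"
  kind[!lo & kind == ""] <- "cross"
  need_breed <- main == ""
  main[need_breed] <- sample(non_hol, sum(need_breed), replace = TRUE,
                             prob = bw)

  has_minor <- kind == "pure" & runif(n) <
    ifelse(main == "HOL", cfg$p_carrier_hol, cfg$p_carrier_other)
  other <- character(n)
  all_breeds <- cfg$breeds$breed
  other[has_minor] <- vapply(main[has_minor], function(m)
    sample(setdiff(all_breeds, m), 1), character(1))
  other[kind == "cross"] <- main[kind == "cross"]

  frac_main <- ifelse(kind == "cross", 0.5, ifelse(has_minor, 7 / 8, 1))
  main_code <- ifelse(kind == "cross", "HOL", main)
  other_code <- ifelse(kind == "cross", main, other)
  frac_other <- ifelse(kind == "cross", 0.5, ifelse(has_minor, 1 / 8, 0))

  hol_frac <- ifelse(main_code == "HOL", frac_main, 0) +
    ifelse(other_code == "HOL" & frac_other > 0, frac_other, 0)
  target_dmy <- frac_main * mean_dmy[main_code] +
    ifelse(frac_other > 0, frac_other * mean_dmy[ifelse(frac_other > 0, other_code, "HOL")], 0)
  lam <- cfg$lambda * (frac_main * mult[main_code] +
                       ifelse(frac_other > 0, frac_other * mult[ifelse(frac_other > 0, other_code, "HOL")], 0))

  a <- wood_scale_for_mean(target_dmy, cfg$wood_b, cfg$wood_c) *
    exp(rnorm(n, 0, cfg$cv_scale))
  b <- rnorm(n, cfg$wood_b, cfg$sd_b)
  cc <- pmax(rnorm(n, cfg$wood_c, cfg$sd_c), 1e-5)
  afc <- as.integer(round(rnorm(n, cfg$afc_mean, cfg$afc_sd)))
  n_days_span <- 365 * (cfg$calving_years[2] - cfg$calving_years[1] + 1)
  calving <- as.Date(sprintf("%d-01-01", cfg$calving_years[1])) +
    sample.int(n_days_span, n, replace = TRUE) - 1

  rec_dim <- vector("list", n); rec_dmy <- vector("list", n)
  p_animal <- vector("list", n); p_fields <- vector("list", n)
  n_pert <- integer(n)
  hol_ref <- mean_dmy[["HOL"]]
  for (i in seq_len(n)) {
    core <- sim_lactation_core(cfg, a[i], b[i], cc[i], lam[i],
                               sigma = cfg$sigma * target_dmy[i] / hol_ref)
    rec_dim[[i]] <- core$dim
    rec_dmy[[i]] <- core$dmy
    n_pert[i] <- length(core$p_start)
    if (n_pert[i] > 0) p_fields[[i]] <- core
  }

  n_per_cow <- lengths(rec_dim)
  records <- tibble::tibble(
    animal_id = rep(animal_id, times = n_per_cow),
    herd_id = rep(cow_herd, times = n_per_cow),
    parity = 1L,
    calving_date = rep(calving, times = n_per_cow),
    dim = unlist(rec_dim, use.names = FALSE),
    dmy = unlist(rec_dmy, use.names = FALSE))

  two_comp <- frac_other > 0
  animals <- tibble::tibble(
    animal_id = c(animal_id, animal_id[two_comp]),
    birth_date = c(calving - afc, (calving - afc)[two_comp]),
    first_calving_date = c(calving, calving[two_comp]),
    age_at_first_calving = c(afc, afc[two_comp]),
    breed_code = c(main_code, other_code[two_comp]),
    fraction = c(frac_main, frac_other[two_comp])) |>
    dplyr::arrange(.data$animal_id, dplyr::desc(.data$fraction))

  herds <- tibble::tibble(
    herd_id = herd_ids, herd_size = sizes,
    mean_hol_fraction = as.numeric(tapply(hol_frac, cow_herd, mean)[herd_ids]))

  pp <- purrr::compact(p_fields)
  with_p <- which(n_pert > 0)
  perturbations <- if (length(with_p) > 0) {
    tibble::tibble(
      animal_id = rep(animal_id[with_p], times = n_pert[with_p]),
      start_dim = unlist(lapply(pp, `[[`, "p_start")),
      end_dim = unlist(lapply(pp, `[[`, "p_end")),
      deepest_dim = unlist(lapply(pp, `[[`, "p_deepest")),
      duration = unlist(lapply(pp, `[[`, "p_duration")),
      dev_days = unlist(lapply(pp, `[[`, "p_dev")),
      depth = unlist(lapply(pp, `[[`, "p_depth")),
      milk_loss = unlist(lapply(pp, `[[`, "p_loss")),
      deepest_deficit = unlist(lapply(pp, `[[`, "p_deep_deficit")))
  } else {
    tibble::tibble(animal_id = character(), start_dim = integer(),
                   end_dim = integer(), deepest_dim = integer(),
                   duration = integer(), dev_days = integer(),
                   depth = numeric(), milk_loss = numeric(),
                   deepest_deficit = numeric())
  }

  cows <- tibble::tibble(
    animal_id = animal_id, herd_id = cow_herd, kind = kind,
    main_breed = ifelse(kind == "cross", main, main),
    hol_fraction = hol_frac, first_calving_date = calving,
    a = a, b = b, c = cc, lambda = as.numeric(lam),
    sigma = as.numeric(cfg$sigma * target_dmy / hol_ref),
    rho = cfg$rho, n_perturbations = n_pert)

  list(records = records, animals = animals, herds = herds,
       truth = list(cows = cows, perturbations = perturbations))
}

#' Category-5 feature values implied by the simulation ground truth
#'
#' Computes the perturbation features analytically from the injected
#' perturbation records (the zero-noise expectation), applying the same
#' qualification and severity rules as [detect_perturbations()] to the
#' injected depth profile: episodes that never drop below the 85% threshold
#' do not count; episodes with at least `min_len` successive days below it
#' are major, the rest minor. Development/recovery days and milk losses come
#' from the injected profile.
#'
#' @param perturbations Truth perturbation tibble (from
#'   [simulate_population()]`$truth$perturbations` or a single lactation's
#'   `truth$perturbations` with an `animal_id` column added).
#' @param animal_ids Animals to report (rows of zeros for animals without
#'   perturbations); defaults to those present in `perturbations`.
#' @param major_threshold Qualification/severity threshold (default 0.85).
#' @param min_len Successive days below the threshold required for a major
#'   episode (default 5).
#' @return A tibble with one row per animal and the 11 category-5 feature
#'   columns.
#' @export
truth_feature_oracle <- function(perturbations, animal_ids = NULL,
                                 major_threshold = 0.85, min_len = 5) {
  cls <- vapply(seq_len(nrow(perturbations)), function(i) {
    truth_profile_class(perturbations$duration[[i]],
                        perturbations$dev_days[[i]],
                        perturbations$depth[[i]],
                        major_threshold, min_len)
  }, character(1))
  p <- dplyr::mutate(perturbations, severity = cls,
                     rec_days = .data$duration - .data$dev_days)
  p <- p[p$severity != "none", , drop = FALSE]
  ids <- animal_ids %||% sort(unique(p$animal_id))
  empty <- p[0, , drop = FALSE]
  by_id <- split(p, factor(p$animal_id, levels = ids))
  purrr::map(ids, function(id) {
    dplyr::bind_cols(tibble::tibble(animal_id = id),
                     perturbation_features(by_id[[id]] %||% empty))
  }) |> dplyr::bind_rows()
}
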