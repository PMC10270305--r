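# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# noise-free Wood-curve lactation
make_wood_series <- function(a = 20, b = 0.2, c = 0.003, dims = 1:305,
                             animal_id = NULL) {
  out <- tibble::tibble(dim = as.integer(dims),
                        dmy = a * dims^b * exp(-c * dims))
  if (!is.null(animal_id)) out <- dplyr::mutate(out, animal_id = animal_id,
                                                .before = 1)
  out
}

# series lying exactly on a quartic in dim (coefficients on the raw scale)
make_quartic_series <- function(coefs, dims = 11:340) {
  stopifnot(length(coefs) == 5)
  dmy <- coefs[1] + coefs[2] * dims + coefs[3] * dims^2 +
    coefs[4] * dims^3 + coefs[5] * dims^4
  tibble::tibble(dim = as.integer(dims), dmy = dmy)
}

# flat series with rectangular dips multiplied in; returns series plus the
# constant expected level
make_flat_series_with_dips <- function(level = 30, dims = 11:340,
                                       dips = list()) {
  dmy <- rep(level, length(dims))
  for (d in dips) {
    idx <- which(dims >= d$start & dims <= d$start + d$len - 1)
    dmy[idx] <- level * d$ratio
  }
  tibble::tibble(dim = as.integer(dims), dmy = dmy)
}

# residual object around a constant expected curve
flat_residuals <- function(series, level = 30) {
  curve_residuals(series$dim, series$dmy, rep(level, nrow(series)))
}

# long-format metadata for one animal given eighths per breed
make_meta <- function(animal_id, eighths, birth = as.Date("2013-01-05"),
                      calving = as.Date("2015-02-01")) {
  tibble::tibble(animal_id = animal_id, birth_date = birth,
                 first_calving_date = calving,
                 age_at_first_calving = as.integer(calving - birth),
                 breed_code = names(eighths),
                 fraction = unname(eighths) / 8)
}
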