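#' Classify animals as purebred, crossbred or other
#'
#' An animal is *purebred* when at least 7/8 of its genes come from a single
#' known breed, and *crossbred* when it is exactly 50% Holstein-Friesian and
#' 50% of one other known breed. Everything else (including 7/8 `UNK`) is
#' *other* and excluded from the breed comparison. `main_breed` is the breed
#' with the largest fraction (ties broken alphabetically).
#'
#' @param meta Long-format animal metadata: columns `animal_id`,
#'   `breed_code`, `fraction` (see [read_animal_meta()]). Fractions must sum
#'   to 1 per animal (tolerance 1e-9).
#' @return A tibble with one row per animal: `animal_id`, `class`
#'   (`"purebred"`, `"crossbred"`, `"other"`), `breed` (the defining breed:
#'   the purebred's breed or the crossbred's non-HOL half; `NA` for other)
#'   and `main_breed`.
#' @export
classify_animals <- function(meta) {
  sums <- meta |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::summarise(total = sum(.data$fraction), .groups = "drop")
  bad <- sums$animal_id[abs(sums$total - 1) > 1e-9]
  if (length(bad) > 0) {
    abort(paste0("breed fractions do not sum to 1 for: ",
                 paste(head(bad, 5), collapse = ", "),
                 if (length(bad) > 5) " ..." else ""))
  }
  ord <- dplyr::arrange(meta, .data$animal_id, dplyr::desc(.data$fraction),
                        .data$breed_code)
  ord$.known_half <- ord$breed_code != "UNK" & ord$breed_code != "HOL" &
    abs(ord$fraction - 0.5) <= 1e-9
  per <- ord |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::summarise(
      top_breed = .data$breed_code[[1]],
      top_frac = .data$fraction[[1]],
      top_known = .data$breed_code[[1]] != "UNK",
      hol = sum(.data$fraction[.data$breed_code == "HOL"]),
      half_other = dplyr::first(.data$breed_code[.data$.known_half],
                                default = NA_character_),
      .groups = "drop")
  pure <- per$top_frac >= 7 / 8 - 1e-9 & per$top_known
  cross <- !pure & abs(per$hol - 0.5) <= 1e-9 & !is.na(per$half_other)
  tibble::tibble(
    animal_id = per$animal_id,
    class = ifelse(pure, "purebred", ifelse(cross, "crossbred", "other")),
    breed = ifelse(pure, per$top_breed,
                   ifelse(cross, per$half_other, NA_character_)),
    main_breed = per$top_breed)
}

#' Stratified uniform down-sampling
#'
#' Draws a representative sample by repeated sorting: in round *k* the
#' remaining pool is sorted by the *k*-th trait (ascending, stable, ties
#' broken by id), one unit is taken every `n/per_round` positions
#' (0-based indices `round(i * n / per_round)`, `i = 0 .. per_round - 1`,
#' collisions resolved by the next free position, wrapping), and the
#' selected units are removed before the next round. The scheme covers the
#' full range of every sorted trait and avoids clusters of similar animals.
#'
#' @param pool A tibble with an id column and the trait columns.
#' @param traits Character vector of trait column names, one sorting round
#'   each (the reference procedure uses 4).
#' @param per_round Number of units selected per round.
#' @param id_col Name of the id column (default `"animal_id"`).
#' @return Character vector of `length(traits) * per_round` selected ids, in
#'   selection order; no duplicates.
#' @export
stratified_uniform_sample <- function(pool, traits, per_round,
                                      id_col = "animal_id") {
  stopifnot(all(traits %in% names(pool)), id_col %in% names(pool))
  if (nrow(pool) < length(traits) * per_round) {
    abort(paste0("pool too small: ", nrow(pool), " < ",
                 length(traits), " rounds x ", per_round))
  }
  remaining <- pool
  selected <- character(0)
  for (trait in traits) {
    ord <- order(remaining[[trait]], remaining[[id_col]], method = "radix")
    remaining <- remaining[ord, , drop = FALSE]
    n_k <- nrow(remaining)
    idx0 <- pmin(pmax(round((0:(per_round - 1)) * (n_k / per_round)), 0),
                 n_k - 1)
    taken <- logical(n_k)
    pick <- integer(per_round)
    for (i in seq_len(per_round)) {
      j <- idx0[[i]] + 1L
      while (taken[[j]]) j <- if (j == n_k) 1L else j + 1L
      taken[[j]] <- TRUE
      pick[[i]] <- j
    }
    selected <- c(selected, remaining[[id_col]][pick])
    remaining <- remaining[!taken, , drop = FALSE]
  }
  selected
}

#' Build the breed-comparison cohort (Subset A)
#'
#' Keeps purebred and crossbred animals, down-samples the (typically heavily
#' over-represented) purebred Holstein-Friesians with
#' [stratified_uniform_sample()] to `hol_sample` animals, and drops breeds
#' represented by fewer than `min_group` purebred + crossbred animals
#' combined.
#'
#' @param animals A per-animal tibble containing `animal_id`, `class` and
#'   `breed` (from [classify_animals()]) plus the four sampling traits.
#' @param min_group Minimum combined animals per non-HOL breed (default 10).
#' @param hol_sample Target number of purebred HOL animals (default 22100);
#'   applied only when more are available.
#' @param traits Sorting traits for the HOL down-sampling, in round order.
#' @return The filtered animal tibble (no `"other"`-class rows).
#' @export
build_subset_A <- function(animals, min_group = 10, hol_sample = 22100,
                           traits = c("age_at_first_calving", "aDMY",
                                      "calving_date", "max_herd_mates")) {
  out <- dplyr::filter(animals, .data$class %in% c("purebred", "crossbred"))
  hol <- dplyr::filter(out, .data$class == "purebred", .data$breed == "HOL")
  if (nrow(hol) > hol_sample) {
    per_round <- hol_sample %/% length(traits)
    keep_ids <- stratified_uniform_sample(hol, traits, per_round)
    out <- dplyr::filter(out, .data$breed != "HOL" |
                         .data$class != "purebred" |
                         .data$animal_id %in% keep_ids)
  }
  counts <- out |>
    dplyr::filter(.data$breed != "HOL") |>
    dplyr::count(.data$breed)
  drop <- counts$breed[counts$n < min_group]
  if (length(drop) > 0) {
    inform(paste0("dropping under-represented breed(s): ",
                  paste(drop, collapse = ", ")))
    out <- dplyr::filter(out, !(.data$breed %in% drop))
  }
  out
}

#' Label and select herds for the herd comparison (Subset B)
#'
#' Herds with 50-300 cows are labelled `SEL50` when their mean
#' Holstein-Friesian gene fraction is below 0.50 and `SEL99` when it is at
#' least 0.99; all other herds are excluded (reason `"size"` or
#' `"mid-range HOL"`). All SEL50 herds are kept; the SEL99 herds are
#' down-sampled to `n_sel99` with [stratified_uniform_sample()] over
#' herd-level traits when more are available.
#'
#' @param herds A herd tibble with `herd_id`, `herd_size`,
#'   `mean_hol_fraction`, plus the sampling traits for the SEL99
#'   down-sampling.
#' @param n_sel99 Target number of SEL99 herds (default 180).
#' @param traits Sorting traits for the SEL99 down-sampling.
#' @param size_range Eligible herd sizes, inclusive (default 50-300).
#' @return The herd tibble with added columns `label` (`"SEL50"`, `"SEL99"`,
#'   `"excluded"`), `reason` (for exclusions) and `selected` (logical).
#' @export
build_subset_B <- function(herds, n_sel99 = 180,
                           traits = c("mean_afc", "mean_dmy", "n_animals",
                                      "max_animals_year"),
                           size_range = c(50, 300)) {
  out <- dplyr::mutate(herds,
    label = dplyr::case_when(
      .data$herd_size < size_range[1] | .data$herd_size > size_range[2] ~ "excluded",
      .data$mean_hol_fraction < 0.50 ~ "SEL50",
      .data$mean_hol_fraction >= 0.99 ~ "SEL99",
      TRUE ~ "excluded"),
    reason = dplyr::case_when(
      .data$label != "excluded" ~ NA_character_,
      .data$herd_size < size_range[1] | .data$herd_size > size_range[2] ~ "size",
      TRUE ~ "mid-range HOL"))
  sel99 <- dplyr::filter(out, .data$label == "SEL99")
  keep99 <- sel99$herd_id
  if (nrow(sel99) > n_sel99) {
    per_round <- n_sel99 %/% length(traits)
    keep99 <- stratified_uniform_sample(sel99, traits, per_round,
                                        id_col = "herd_id")
  }
  dplyr::mutate(out, selected = (.data$label == "SEL50") |
                  (.data$label == "SEL99" & .data$herd_id %in% keep99))
}

#' Herd-level sampling traits
#'
#' Computes, per herd, the traits used to down-sample SEL99 herds: mean age
#' at first calving, mean daily yield, total number of animals, and the
#' maximum number of animals calving in a single calendar year.
#'
#' @param records Milk-record tibble with `animal_id`, `herd_id`,
#'   `calving_date`, `dmy`.
#' @param animals Optional per-animal metadata with `age_at_first_calving`
#'   (one row per animal; long metadata is deduplicated on `animal_id`).
#' @return A tibble keyed by `herd_id` with columns `mean_afc`, `mean_dmy`,
#'   `n_animals`, `max_animals_year`.
#' @export
herd_traits <- function(records, animals = NULL) {
  per_cow <- records |>
    dplyr::group_by(.data$herd_id, .data$animal_id) |>
    dplyr::summarise(aDMY = mean(.data$dmy),
                     calving_year = format(.data$calving_date[[1]], "%Y"),
                     .groups = "drop")
  if (!is.null(animals)) {
    afc <- dplyr::distinct(animals, .data$animal_id,
                           .data$age_at_first_calving)
    per_cow <- dplyr::left_join(per_cow, afc, by = "animal_id")
  } else {
    per_cow$age_at_first_calving <- NA_real_
  }
  per_cow |>
    dplyr::group_by(.data$herd_id) |>
    dplyr::summarise(
      mean_afc = mean(.data$age_at_first_calving),
      mean_dmy = mean(.data$aDMY),
      n_animals = dplyr::n(),
      max_animals_year = max(table(.data$calving_year)),
      .groups = "drop")
}
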