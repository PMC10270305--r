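#' Read a daily-milk-yield table
#'
#' Reads a CSV of per-day milk records. The canonical layout has columns
#' `animal_id, herd_id, parity, calving_date, dim, dmy_kg` (dates ISO-8601,
#' `dim` = days in milk with the day of calving as day 0). Column names can be
#' remapped through `schema`. Rows whose `dmy` or `dim` fail to parse are
#' reported, counted, and returned as an attribute rather than silently
#' dropped.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Named character vector mapping canonical names to file column
#'   names, e.g. `c(dmy = "milk_kg")`. Canonical names: `animal_id`,
#'   `herd_id`, `parity`, `calving_date`, `dim`, `dmy`. By default `dmy_kg`
#'   is accepted for `dmy`.
#' @return A tibble with columns `animal_id`, `herd_id`, `parity`,
#'   `calving_date`, `dim`, `dmy` (kg/day). Attribute `problems` holds a
#'   tibble of malformed rows (possibly empty).
#' @export
read_dmy_table <- function(path, schema = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  map <- c(animal_id = "animal_id", herd_id = "herd_id", parity = "parity",
           calving_date = "calving_date", dim = "dim", dmy = "dmy")
  if (!"dmy" %in% names(raw) && "dmy_kg" %in% names(raw)) map[["dmy"]] <- "dmy_kg"
  if (!is.null(schema)) map[names(schema)] <- schema

  for (col in c("animal_id", "herd_id", "dim", "dmy")) {
    if (!map[[col]] %in% names(raw)) {
      abort(paste0("column ", col, " not found (looked for '", map[[col]], "')"))
    }
  }

  out <- tibble::tibble(
    animal_id = as.character(raw[[map[["animal_id"]]]]),
    herd_id = as.character(raw[[map[["herd_id"]]]]),
    parity = if (map[["parity"]] %in% names(raw))
      suppressWarnings(as.integer(raw[[map[["parity"]]]])) else 1L,
    calving_date = if (map[["calving_date"]] %in% names(raw))
      as.Date(raw[[map[["calving_date"]]]]) else as.Date(NA),
    dim = suppressWarnings(as.integer(raw[[map[["dim"]]]])),
    dmy = suppressWarnings(as.numeric(raw[[map[["dmy"]]]]))
  )

  bad <- is.na(out$dim) | is.na(out$dmy)
  problems <- dplyr::mutate(raw[bad, , drop = FALSE], .row = which(bad),
                            .before = 1)
  if (any(bad)) {
    inform(paste0(sum(bad), " malformed row(s) dropped (non-numeric dim/dmy); ",
                  "see attr(x, 'problems')"))
  }
  n_zero <- sum(out$dmy[!bad] == 0)
  if (n_zero > 0) inform(paste0(n_zero, " zero-yield record(s) retained"))
  out <- out[!bad, , drop = FALSE]
  attr(out, "problems") <- tibble::as_tibble(problems)
  out
}

#' Read animal metadata
#'
#' Long-format CSV with one row per animal-breed component:
#' `animal_id, birth_date, first_calving_date, breed_code, fraction_eighths`.
#' Breed fractions are recorded in eighths (0-8) and must sum to 8 per animal.
#'
#' @param path Path to the metadata CSV.
#' @return A tibble with one row per animal-breed component, columns
#'   `animal_id`, `birth_date`, `first_calving_date`, `age_at_first_calving`
#'   (days), `breed_code`, `fraction` (in \[0,1\]).
#' @export
read_animal_meta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    animal_id = readr::col_character(),
    birth_date = readr::col_date(),
    first_calving_date = readr::col_date(),
    breed_code = readr::col_character(),
    fraction_eighths = readr::col_integer()
  ), progress = FALSE)
  dplyr::mutate(raw,
    age_at_first_calving = as.integer(.data$first_calving_date - .data$birth_date),
    fraction = .data$fraction_eighths / 8,
    fraction_eighths = NULL
  )
}

#' Write a daily-milk-yield table
#'
#' Writes the canonical CSV layout (`dmy` stored as `dmy_kg`); the round trip
#' through [read_dmy_table()] reproduces `animal_id`, `dim` and `dmy` exactly.
#'
#' @param records A milk-record tibble as returned by [read_dmy_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmy_table <- function(records, path) {
  out <- dplyr::rename(records, dmy_kg = "dmy")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Assemble per-animal lactation series
#'
#' Orders records by animal and days in milk, drops duplicate
#' `(animal_id, dim)` rows (keeping the first occurrence) and, when metadata
#' is supplied, flags animals missing from it. The result is the tidy
#' "lactation series" table the rest of the pipeline consumes: one group of
#' rows per animal, `dim` strictly increasing within animal.
#'
#' @param records Milk-record tibble (see [read_dmy_table()]).
#' @param meta Optional animal metadata (see [read_animal_meta()]).
#' @return The records tibble, sorted, deduplicated, with a logical
#'   `meta_missing` column when `meta` is given. Attribute `n_duplicates`
#'   counts dropped duplicate rows.
#' @export
assemble_lactations <- function(records, meta = NULL) {
  if (nrow(records) == 0) abort("no records supplied")
  out <- dplyr::arrange(records, .data$animal_id, .data$dim)
  dup <- duplicated(out[, c("animal_id", "dim")])
  if (any(dup)) {
    inform(paste0(sum(dup), " duplicate (animal, dim) row(s) dropped, first kept"))
    out <- out[!dup, , drop = FALSE]
  }
  if (!is.null(meta)) {
    known <- unique(meta$animal_id)
    out$meta_missing <- !(out$animal_id %in% known)
    if (any(out$meta_missing)) {
      inform(paste0(length(unique(out$animal_id[out$meta_missing])),
                    " animal(s) have no metadata; flagged meta_missing"))
    }
  }
  attr(out, "n_duplicates") <- sum(dup)
  out
}

#' Eligibility of lactation series
#'
#' Applies the record-level eligibility rules to each animal's first-parity
#' series: at least `min_days` recorded daily values, first record within
#' `max_start_dim` days of calving, no run of more than `max_gap` consecutive
#' missing days between the first and last record, and calving year at least
#' `min_calving_year`. Trailing truncation (dry-off or culling) is not
#' treated as a gap. Zero-yield days count as data.
#'
#' @param records Milk-record tibble with columns `animal_id`, `dim`, `dmy`
#'   and (for the calving-year rule) `calving_date`.
#' @param min_days Minimum number of recorded days (default 100).
#' @param max_start_dim Latest allowed first `dim` (default 5).
#' @param max_gap Longest allowed run of consecutive missing days (default 5).
#' @param min_calving_year Earliest allowed calving year (default 2010).
#' @return A tibble with one row per animal: `animal_id`, `pass`, `reasons`
#'   (comma-separated codes among `empty`, `min_days`, `start_dim`, `gap`,
#'   `calving_year`), `n_days`, `first_dim`, `max_gap_run`, `calving_year`.
#' @seealso [filter_eligible()]
#' @export
eligibility_check <- function(records, min_days = 100, max_start_dim = 5,
                              max_gap = 5, min_calving_year = 2010) {
  has_date <- "calving_date" %in% names(records)
  if (nrow(records) == 0) {
    return(tibble::tibble(animal_id = character(), pass = logical(),
                          reasons = character(), n_days = integer(),
                          first_dim = integer(), max_gap_run = integer(),
                          calving_year = integer()))
  }
  per <- records |>
    dplyr::arrange(.data$animal_id, .data$dim) |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::summarise(
      n_days = dplyr::n_distinct(.data$dim),
      first_dim = min(.data$dim),
      max_gap_run = {
        d <- unique(.data$dim)
        if (length(d) > 1) max(diff(d) - 1L) else 0L
      },
      calving_year = if (has_date)
        as.integer(format(.data$calving_date[[1]], "%Y")) else NA_integer_,
      .groups = "drop")
  fails <- cbind(
    min_days = per$n_days < min_days,
    start_dim = per$first_dim > max_start_dim,
    gap = per$max_gap_run > max_gap,
    calving_year = !is.na(per$calving_year) &
      per$calving_year < min_calving_year)
  reasons <- apply(fails, 1, function(f)
    paste(colnames(fails)[f], collapse = ","))
  dplyr::bind_cols(
    tibble::tibble(animal_id = per$animal_id,
                   pass = rowSums(fails) == 0, reasons = reasons),
    per[, c("n_days", "first_dim", "max_gap_run", "calving_year")])
}

#' Keep only eligible lactations
#'
#' @inheritParams eligibility_check
#' @return The subset of `records` belonging to animals that pass
#'   [eligibility_check()].
#' @export
filter_eligible <- function(records, min_days = 100, max_start_dim = 5,
                            max_gap = 5, min_calving_year = 2010) {
  elig <- eligibility_check(records, min_days, max_start_dim, max_gap,
                            min_calving_year)
  keep <- elig$animal_id[elig$pass]
  dplyr::filter(records, .data$animal_id %in% keep)
}

#' Breed codes recognised by the package
#'
#' The twelve dairy breed codes used in the breed comparison plus `UNK` for
#' unknown/other: Holstein-Friesian (HOL), Meuse-Rhine-Yssel (MRY), Jersey
#' (JER), Montbeliarde (MON), Simmental Fleckvieh (SIM), Dutch Friesian
#' (DFR), Brown Swiss (BSW), Groninger Whiteheaded (GRO), Swedish Red (SRB),
#' Norwegian Red (NRF), Belgian Blue (BBL), Ayrshire (AYR).
#'
#' @return Character vector of breed codes.
#' @export
breed_codes <- function() {
  c("HOL", "MRY", "JER", "MON", "SIM", "DFR", "BSW", "GRO",
    "SRB", "NRF", "BBL", "AYR", "UNK")
}
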