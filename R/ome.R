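#' Load an oral morphine equivalent (OME) conversion table
#'
#' The packaged default transcribes published equianalgesic conversion
#' ratios (oral morphine is the reference substance, factor 1): each row
#' maps an ATC prefix and administration route to mg OME per mg of
#' substance. Transdermal patches are a special case: their strength is a
#' delivery rate in micrograms per hour, so rows tagged
#' `mg_per_mg_delivered` convert the mass actually delivered per day
#' (`rate * 24 h / 1000`). Methadone's dose-dependent potency is represented
#' by a single configurable factor.
#'
#' @param path Path to a CSV with columns `atc_prefix`, `substance`,
#'   `route`, `factor`, `factor_units`; `NULL` loads the packaged table.
#' @return A validated conversion tibble.
#' @export
#' @examples
#' head(load_ome_table())
load_ome_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ome_table.csv", package = "rxvar")
  }
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           atc_prefix = readr::col_character(),
                           substance = readr::col_character(),
                           route = readr::col_character(),
                           factor = readr::col_double(),
                           factor_units = readr::col_character()
                         ))
  if (any(is.na(tab$factor)) || any(tab$factor <= 0)) {
    abort("conversion table load error: factors must be positive")
  }
  key <- paste(toupper(tab$atc_prefix), tolower(tab$route))
  if (anyDuplicated(key)) {
    abort(paste0("conversion table load error: duplicate (atc_prefix, route) key: ",
                 paste(unique(key[duplicated(key)]), collapse = ", ")))
  }
  bad_units <- setdiff(unique(tab$factor_units),
                       c("mg_per_mg", "mg_per_mg_delivered"))
  if (length(bad_units) > 0) {
    abort(paste0("conversion table load error: unknown factor_units: ",
                 paste(bad_units, collapse = ", ")))
  }
  tab
}

#' Convert prescriptions to oral morphine equivalents
#'
#' Looks each prescription up in the conversion table by the longest ATC
#' prefix matching its code within its route, and computes the total and
#' daily OME. For `mg_per_mg` rows, `total_ome = strength_mg_per_unit *
#' units_per_day * days_supplied * factor`; for transdermal
#' `mg_per_mg_delivered` rows the strength is a rate in micrograms/hour and
#' `daily_ome = strength * 24 / 1000 * factor`. Prescriptions with no
#' matching entry are flagged `convertible = FALSE` (their OME is `NA`) and
#' logged; rows with non-positive strength, units or days are logged as data
#' errors and dropped. The fraction of prescriptions that could be converted
#' is reported as `coverage`.
#'
#' @param prescriptions Opioid-selected prescription tibble with `rx_id`,
#'   `atc`, `route`, `strength_mg_per_unit`, `units_per_day`,
#'   `days_supplied`.
#' @param table Conversion table from [load_ome_table()].
#' @return A list with `ome` (the input plus `ome_factor`, `convertible`,
#'   `total_ome`, `daily_ome`), `log`, and `coverage` (fraction of retained
#'   prescriptions that are convertible).
#' @export
#' @examples
#' rx <- tibble::tibble(rx_id = "1", atc = "N02AA01", route = "oral",
#'                      strength_mg_per_unit = 30, units_per_day = 2,
#'                      days_supplied = 10)
#' compute_ome(rx)$ome$total_ome  # 600 mg OME
compute_ome <- function(prescriptions, table = load_ome_table()) {
  rx <- prescriptions
  bad <- (!is.na(rx$strength_mg_per_unit) & rx$strength_mg_per_unit <= 0) |
    (!is.na(rx$units_per_day) & rx$units_per_day <= 0) |
    (!is.na(rx$days_supplied) & rx$days_supplied <= 0)
  log <- log_rows(rx$rx_id[bad], "prescription", "nonpositive_quantity",
                  "strength, units per day or days supplied not positive")
  rx <- rx[!bad, , drop = FALSE]

  # longest-prefix match within route
  matched <- rx |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::inner_join(
      dplyr::mutate(table, route = tolower(.data$route)),
      by = "route", relationship = "many-to-many"
    ) |>
    dplyr::filter(stringr::str_starts(.data$atc, .data$atc_prefix)) |>
    dplyr::group_by(.data$.row) |>
    dplyr::slice_max(nchar(.data$atc_prefix), n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(".row", "factor", "factor_units")

  rx <- rx |>
    dplyr::mutate(.row = dplyr::row_number(),
                  route = tolower(.data$route)) |>
    dplyr::left_join(matched, by = ".row") |>
    dplyr::mutate(
      convertible = !is.na(.data$factor) &
        !is.na(.data$strength_mg_per_unit) & !is.na(.data$units_per_day) &
        !is.na(.data$days_supplied),
      daily_ome = dplyr::case_when(
        !.data$convertible ~ NA_real_,
        .data$factor_units == "mg_per_mg_delivered" ~
          .data$strength_mg_per_unit * 24 / 1000 * .data$factor,
        TRUE ~ .data$strength_mg_per_unit * .data$units_per_day * .data$factor
      ),
      total_ome = .data$daily_ome * .data$days_supplied
    ) |>
    dplyr::rename(ome_factor = "factor") |>
    dplyr::select(-".row", -"factor_units")

  log <- dplyr::bind_rows(
    log,
    log_rows(rx$rx_id[!rx$convertible], "prescription", "not_convertible",
             "no (ATC, route) conversion entry or missing dose fields")
  )
  list(
    ome = rx,
    log = log,
    coverage = if (nrow(rx) > 0) mean(rx$convertible) else NA_real_
  )
}
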