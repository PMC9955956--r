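#' Filter practices on data-quality criteria
#'
#' Retains practices meeting all five registration-quality criteria, each
#' threshold inclusive ("at least"): data covering >= 46 weeks, >= 85% of
#' prescriptions with a valid ATC code, >= 75% of contacts with a valid ICPC
#' code, >= 500 registered patients, and >= 80% of patients registered for
#' the full year.
#'
#' @param quality A tibble with one row per practice: `practice_id`,
#'   `weeks_of_data`, `pct_valid_atc`, `pct_valid_icpc`, `n_registered`,
#'   `pct_full_year`.
#' @return A list with `included` (the retained rows) and `log` (an
#'   exclusion log tibble with `entity_id`, `entity_kind`, `rule_id`,
#'   `detail`; one row per failed rule).
#' @export
#' @examples
#' q <- tibble::tibble(practice_id = c("a", "b"), weeks_of_data = c(52, 40),
#'                     pct_valid_atc = 90, pct_valid_icpc = 80,
#'                     n_registered = 1000, pct_full_year = 90)
#' filter_practices(q)$included$practice_id
filter_practices <- function(quality) {
  if (anyDuplicated(quality$practice_id)) {
    abort("duplicate practice ids in quality table")
  }
  rules <- list(
    min_weeks = list(
      fail = quality$weeks_of_data < 46,
      detail = "data cover fewer than 46 weeks"
    ),
    min_valid_atc = list(
      fail = quality$pct_valid_atc < 85,
      detail = "fewer than 85% of prescriptions have a valid ATC code"
    ),
    min_valid_icpc = list(
      fail = quality$pct_valid_icpc < 75,
      detail = "fewer than 75% of contacts have a valid ICPC code"
    ),
    min_registered = list(
      fail = quality$n_registered < 500,
      detail = "fewer than 500 registered patients"
    ),
    min_full_year = list(
      fail = quality$pct_full_year < 80,
      detail = "fewer than 80% of patients registered the full year"
    )
  )
  log <- purrr::imap(rules, function(r, id) {
    fail <- r$fail %in% TRUE | is.na(r$fail)
    log_rows(quality$practice_id[fail], "practice", id, r$detail)
  }) |> dplyr::bind_rows()
  excluded <- unique(log$entity_id)
  list(
    included = quality[!quality$practice_id %in% excluded, , drop = FALSE],
    log = log
  )
}

#' Filter patients on inclusion criteria
#'
#' Retains patients at least 20 years old (age at 1 January, via the 5-year
#' age band), registered with their practice for the entire year, and
#' without an active cancer diagnosis in the year of analysis. Rows with
#' missing values in any of these fields are excluded with `rule_id =
#' "missing_data"` rather than failing the run.
#'
#' @param patients Patient tibble with `patient_id`, `age_band`,
#'   `registered_full_year`, `cancer_active`.
#' @return A list with `included` (retained patient rows) and `log`.
#' @export
filter_patients <- function(patients) {
  lower <- suppressWarnings(age_band_lower(patients$age_band))
  miss <- is.na(lower) | is.na(patients$registered_full_year) |
    is.na(patients$cancer_active)
  under <- !miss & lower < 20
  part_year <- !miss & !patients$registered_full_year
  cancer <- !miss & patients$cancer_active
  log <- dplyr::bind_rows(
    log_rows(patients$patient_id[miss], "patient", "missing_data",
             "missing age band, registration or cancer status"),
    log_rows(patients$patient_id[under], "patient", "under_20",
             "younger than 20 on 1 January"),
    log_rows(patients$patient_id[part_year], "patient", "not_full_year",
             "not registered for the entire year"),
    log_rows(patients$patient_id[cancer], "patient", "active_cancer",
             "cancer diagnosis active in the year of analysis")
  )
  keep <- !(miss | under | part_year | cancer)
  list(included = patients[keep, , drop = FALSE], log = log)
}

#' Default list of codeine ATC codes to exclude
#'
#' Codeine (plain and in combination analgesics) is excluded from the
#' opioid selection because it is predominantly used for cough. The
#' substance-level exclusion is expressed as ATC codes and is configurable.
#'
#' @return Character vector of ATC codes.
#' @export
default_codeine_atc <- function() {
  c("R05DA04", "N02AA59", "N02AA79")
}

#' Select opioid prescriptions
#'
#' Keeps prescriptions whose ATC code starts with `N02A` (opioids) and,
#' optionally, `N07BC` (drugs used in opioid dependence; turning the flag
#' off reproduces the sensitivity analysis without that group). Codeine
#' codes are dropped. Malformed ATC codes (not 7 alphanumeric characters
#' after trimming) are logged as invalid and dropped. Every dropped row is
#' logged, so included and excluded rows partition the input.
#'
#' @param prescriptions Prescription tibble with `rx_id` and `atc`.
#' @param include_n07bc Keep ATC group N07BC? Default `TRUE`.
#' @param codeine_atc ATC codes treated as codeine, see
#'   [default_codeine_atc()].
#' @return A list with `opioids` (selected rows, `atc` trimmed) and `log`.
#' @export
#' @examples
#' rx <- tibble::tibble(rx_id = c("1", "2"), atc = c("N02AA01", "R05DA04"))
#' select_opioids(rx)$opioids$rx_id
select_opioids <- function(prescriptions, include_n07bc = TRUE,
                           codeine_atc = default_codeine_atc()) {
  atc <- stringr::str_trim(as.character(prescriptions$atc))
  malformed <- is.na(atc) | !stringr::str_detect(atc, "^[A-Za-z0-9]{7}$")
  atc_up <- toupper(atc)
  codeine <- !malformed & atc_up %in% toupper(codeine_atc)
  n07bc <- !malformed & !codeine & stringr::str_starts(atc_up, "N07BC")
  opioid <- !malformed & !codeine &
    (stringr::str_starts(atc_up, "N02A") | (n07bc & include_n07bc))
  non_opioid <- !malformed & !codeine & !opioid & !n07bc
  log <- dplyr::bind_rows(
    log_rows(prescriptions$rx_id[malformed], "prescription", "invalid_atc",
             "ATC code is not 7 alphanumeric characters"),
    log_rows(prescriptions$rx_id[codeine], "prescription",
             "codeine_excluded", "codeine is predominantly used for cough"),
    log_rows(prescriptions$rx_id[n07bc & !include_n07bc], "prescription",
             "n07bc_excluded", "ATC group N07BC excluded by configuration"),
    log_rows(prescriptions$rx_id[non_opioid], "prescription", "non_opioid",
             "ATC code outside N02A/N07BC")
  )
  kept <- prescriptions[opioid, , drop = FALSE]
  kept$atc <- atc_up[opioid]
  list(opioids = kept, log = log)
}
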