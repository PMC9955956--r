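#' Build opioid exposure episodes for a calendar year
#'
#' Each prescription covers the half-open day interval
#' `[start, start + days_supplied)`. Intervals are clipped to the calendar
#' year (OME pro-rated by the fraction of the interval falling inside the
#' year), and maximal runs of intervals separated by gaps of at most
#' `gap_tolerance` days are merged into episodes. Days covered by more than
#' one prescription count once toward episode length, while the OME of all
#' member prescriptions accumulates, so dose adds up but time does not. In
#' reports `end_date` is the last covered day (inclusive) and
#' `length = end_date - start_date + 1`; bridged gap days count toward the
#' length. Episodes never extend outside the year, so chronic use starting
#' in the last three months of a year is, by construction, not identifiable.
#'
#' @param prescriptions OME-annotated opioid prescriptions (see
#'   [compute_ome()]): `patient_id`, `start_date`, `days_supplied`,
#'   `total_ome`, and optionally `convertible`.
#' @param year Calendar year to clip to.
#' @param gap_tolerance Maximum gap (days) between consecutive covered runs
#'   that is still merged; 0 means strictly consecutive coverage.
#' @param noncovertible One of `"exclude"` (default: prescriptions without
#'   an OME value are dropped entirely) or `"coverage_only"` (they extend
#'   coverage days but contribute 0 mg OME).
#' @return A list with `episodes` (tibble: `patient_id`, `episode`,
#'   `start_date`, `end_date`, `length`, `total_ome`, `mean_daily_ome`) and
#'   `log` (rejected rows).
#' @export
#' @examples
#' rx <- tibble::tibble(
#'   patient_id = "a", start_date = as.Date(c("2019-01-01", "2019-02-20")),
#'   days_supplied = 50, total_ome = 3000
#' )
#' build_episodes(rx, 2019)$episodes
build_episodes <- function(prescriptions, year, gap_tolerance = 0,
                           noncovertible = c("exclude", "coverage_only")) {
  noncovertible <- match.arg(noncovertible)
  rx <- prescriptions
  if (!"convertible" %in% names(rx)) rx$convertible <- !is.na(rx$total_ome)
  if (!"rx_id" %in% names(rx)) rx$rx_id <- as.character(seq_len(nrow(rx)))
  bad <- is.na(rx$days_supplied) | rx$days_supplied <= 0
  log <- log_rows(rx$rx_id[bad], "prescription", "nonpositive_days",
                  "days supplied missing or not positive")
  rx <- rx[!bad, , drop = FALSE]
  if (noncovertible == "exclude") {
    log <- dplyr::bind_rows(
      log,
      log_rows(rx$rx_id[!rx$convertible], "prescription",
               "not_convertible", "excluded from episode construction")
    )
    rx <- rx[rx$convertible, , drop = FALSE]
  } else {
    rx$total_ome[!rx$convertible] <- 0
  }

  jan1 <- as.Date(paste0(year, "-01-01"))
  ylen <- year_length(year)
  if (nrow(rx) == 0) {
    return(list(episodes = empty_episodes(), log = log))
  }

  clipped <- rx |>
    dplyr::mutate(
      start_day = as.integer(.data$start_date - jan1) + 1L,
      end_excl = .data$start_day + as.integer(.data$days_supplied),
      cs = pmax(.data$start_day, 1L),
      ce = pmin(.data$end_excl, ylen + 1L)
    ) |>
    dplyr::filter(.data$ce > .data$cs)
  if (nrow(clipped) == 0) {
    return(list(episodes = empty_episodes(), log = log))
  }
  ep <- clipped |>
    dplyr::mutate(
      ome_clipped = .data$total_ome * (.data$ce - .data$cs) /
        (.data$end_excl - .data$start_day)
    ) |>
    dplyr::arrange(.data$patient_id, .data$cs, .data$ce) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(
      run_end = cummax(.data$ce),
      prev_end = dplyr::lag(.data$run_end),
      new_episode = is.na(.data$prev_end) |
        .data$cs - .data$prev_end > gap_tolerance,
      episode = cumsum(.data$new_episode)
    ) |>
    dplyr::group_by(.data$patient_id, .data$episode) |>
    dplyr::summarise(
      start_day = min(.data$cs),
      end_day = max(.data$ce) - 1L,
      total_ome = sum(.data$ome_clipped),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      start_date = jan1 + .data$start_day - 1L,
      end_date = jan1 + .data$end_day - 1L,
      length = .data$end_day - .data$start_day + 1L,
      mean_daily_ome = .data$total_ome / .data$length
    ) |>
    dplyr::select("patient_id", "episode", "start_date", "end_date",
                  "length", "total_ome", "mean_daily_ome")
  list(episodes = ep, log = log)
}

empty_episodes <- function() {
  tibble::tibble(
    patient_id = character(), episode = integer(),
    start_date = as.Date(character()), end_date = as.Date(character()),
    length = integer(), total_ome = numeric(), mean_daily_ome = numeric()
  )
}

OUTCOME_CLASSES <- c("none", "chronic_lt90", "chronic_ge90")

#' Classify patient-years from exposure episodes
#'
#' A patient-year is `chronic_ge90` if any episode lasts at least
#' `min_days` consecutive days with a mean daily dose of at least
#' `dose_threshold` mg OME (both thresholds inclusive); otherwise
#' `chronic_lt90` if any episode lasts at least `min_days`; otherwise
#' `none`. The precedence makes the classes mutually exclusive: a patient
#' meeting both definitions in one year is classified as chronic high-dose
#' only.
#'
#' @param episodes Episode tibble from [build_episodes()].
#' @param min_days Minimum episode length for chronic use (days).
#' @param dose_threshold Mean daily dose separating high-dose use (mg
#'   OME/day).
#' @return A tibble `patient_id`, `class` (factor `none`, `chronic_lt90`,
#'   `chronic_ge90`) with one row per patient present in `episodes`.
#' @export
classify_patient_year <- function(episodes, min_days = 90,
                                  dose_threshold = 90) {
  episodes |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      chronic = any(.data$length >= min_days),
      highdose = any(.data$length >= min_days &
                       .data$mean_daily_ome >= dose_threshold),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      class = factor(
        dplyr::case_when(
          .data$highdose ~ "chronic_ge90",
          .data$chronic ~ "chronic_lt90",
          TRUE ~ "none"
        ),
        levels = OUTCOME_CLASSES
      )
    ) |>
    dplyr::select("patient_id", "class")
}

#' Classify a whole cohort
#'
#' End-to-end patient-year classification: selects opioid prescriptions,
#' converts them to OME, builds exposure episodes and classifies every
#' patient, including those without any opioid prescription (class
#' `none`).
#'
#' @param patients Included patient tibble (`patient_id`, `practice_id`).
#' @param prescriptions Raw prescription tibble.
#' @param year Calendar year.
#' @param gap_tolerance Passed to [build_episodes()].
#' @param include_n07bc Passed to [select_opioids()].
#' @param ome_table Passed to [compute_ome()].
#' @param ... Further arguments to [build_episodes()].
#' @return A tibble `patient_id`, `practice_id`, `year`, `class` with one
#'   row per patient in `patients`.
#' @export
classify_cohort <- function(patients, prescriptions, year,
                            gap_tolerance = 0, include_n07bc = TRUE,
                            ome_table = load_ome_table(), ...) {
  unknown <- setdiff(unique(prescriptions$patient_id), patients$patient_id)
  if (length(unknown) > 0) {
    abort(paste0("prescriptions reference unknown patients: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  sel <- select_opioids(prescriptions, include_n07bc = include_n07bc)
  ome <- compute_ome(sel$opioids, table = ome_table)
  eps <- build_episodes(ome$ome, year = year,
                        gap_tolerance = gap_tolerance, ...)
  classes <- classify_patient_year(eps$episodes)
  patients |>
    dplyr::select("patient_id", "practice_id") |>
    dplyr::left_join(classes, by = "patient_id") |>
    dplyr::mutate(
      year = year,
      class = forcats_replace_na(.data$class)
    )
}

# replace NA class with "none" keeping factor levels (no forcats dependency)
forcats_replace_na <- function(x) {
  x <- factor(x, levels = OUTCOME_CLASSES)
  x[is.na(x)] <- "none"
  x
}
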