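#' Cohort descriptives in the customary table layout
#'
#' Totals, practice-size summaries, outcome counts, and sex, age-group and
#' chronic-disease-count distributions of an included cohort. Every
#' percentage uses the included-patient denominator; the numeric columns
#' carry full precision and `formatted` applies half-up rounding at render
#' time only.
#'
#' @param patients Included patient tibble.
#' @param classes Patient-year classes from [classify_cohort()] (may be the
#'   same tibble if it carries a `class` column).
#' @param practices Practice tibble (used for the practice count).
#' @return A tibble: `section`, `statistic`, `n`, `denominator`, `pct`,
#'   `formatted`.
#' @export
descriptives <- function(patients, classes, practices) {
  if (!"class" %in% names(patients)) {
    patients <- dplyr::left_join(
      patients, dplyr::select(classes, "patient_id", "class"),
      by = "patient_id"
    )
  }
  n_pat <- nrow(patients)
  sizes <- if (n_pat > 0) {
    dplyr::count(patients, .data$practice_id)$n
  } else {
    integer()
  }
  row <- function(section, statistic, n = NA_real_, denom = NA_real_,
                  digits = 1, value = NULL) {
    pct <- if (!is.na(denom) && denom > 0) 100 * n / denom else NA_real_
    formatted <- if (!is.null(value)) {
      format(value, big.mark = " ", trim = TRUE)
    } else if (!is.na(pct)) {
      fmt_count_pct(n, denom, digits)
    } else {
      format(n, big.mark = " ", trim = TRUE)
    }
    tibble::tibble(section = section, statistic = statistic,
                   n = as.numeric(n), denominator = as.numeric(denom),
                   pct = pct, formatted = formatted)
  }
  counts <- function(section, statistic, flag, digits = 1) {
    row(section, statistic, sum(flag, na.rm = TRUE), n_pat, digits)
  }
  lower <- age_band_lower(patients$age_band)
  dplyr::bind_rows(
    row("totals", "patients", n_pat),
    row("totals", "practices", nrow(practices)),
    row("practice_size", "mean", value = if (length(sizes)) round(mean(sizes)) else 0),
    row("practice_size", "min", value = if (length(sizes)) min(sizes) else 0),
    row("practice_size", "max", value = if (length(sizes)) max(sizes) else 0),
    counts("opioid_prescriptions", "chronic_lt90",
           patients$class == "chronic_lt90", digits = 2),
    counts("opioid_prescriptions", "chronic_ge90",
           patients$class == "chronic_ge90", digits = 2),
    counts("sex", "male", patients$sex == "male"),
    counts("age", "20-39", lower >= 20 & lower < 40),
    counts("age", "40-59", lower >= 40 & lower < 60),
    counts("age", "60-79", lower >= 60 & lower < 80),
    counts("age", "80+", lower >= 80),
    dplyr::bind_rows(lapply(DISEASE_LEVELS, function(l) {
      counts("n_chronic_diseases", l, patients$n_chronic_diseases == l)
    }))
  )
}

# Every printed percentage must equal numerator/denominator of the same
# table: the self-consistency audit re-derives each one.
audit_descriptives <- function(desc) {
  has_pct <- !is.na(desc$pct)
  recomputed <- 100 * desc$n[has_pct] / desc$denominator[has_pct]
  if (any(abs(recomputed - desc$pct[has_pct]) > 1e-9)) {
    abort("descriptives failed the percentage self-consistency audit")
  }
  invisible(TRUE)
}

summarise_exclusions <- function(log) {
  if (nrow(log) == 0) {
    return(tibble::tibble(entity_kind = character(), rule_id = character(),
                          n = integer()))
  }
  dplyr::count(log, .data$entity_kind, .data$rule_id, name = "n")
}

#' Run the full practice-variation study
#'
#' Orchestrates the pipeline per calendar year: cohort (simulated from
#' `config`, or supplied), practice-quality and patient inclusion filters,
#' opioid selection, OME conversion, episode classification, case-mix
#' standardization per outcome, variation ratios, overdispersion-adjusted
#' funnel analysis, and outlier profiling for the chronic high-dose
#' outcome. All randomness derives from `config$seed` (per-year seeds are
#' offset by the year), so a run is reproducible end to end.
#'
#' @param config A [cohort_config()] used to simulate cohorts when `cohort`
#'   is `NULL`.
#' @param years Years to analyse; default the config year.
#' @param cohort Optional pre-built cohort (a `rxvar_cohort` or a list with
#'   `practices`, `patients`, `prescriptions`) analysed for a single year.
#' @param practice_quality Optional practice data-quality table for
#'   [filter_practices()]; when `NULL` all practices pass.
#' @param include_n07bc Include ATC group N07BC (turn off for the
#'   sensitivity analysis).
#' @param gap_tolerance Episode gap tolerance in days.
#' @param winsor_fraction Winsor fraction for the overdispersion estimate.
#' @param funnel_levels Control-limit levels for the funnel curves.
#' @param outlier_level Level at which practices are flagged as outliers.
#' @param outcomes Outcome classes to analyse.
#' @param ome_table Conversion table, see [load_ome_table()].
#' @return An object of class `rxvar_report`: per-year results
#'   (`descriptives`, `variation`, `outlier_counts`, `funnels`, `profile`,
#'   `exclusions`, `coverage`, tables of practice outcomes) plus a
#'   `manifest` recording seed, configuration hash and conventions.
#' @export
run_study <- function(config = cohort_config(), years = NULL, cohort = NULL,
                      practice_quality = NULL, include_n07bc = TRUE,
                      gap_tolerance = 0, winsor_fraction = 0.10,
                      funnel_levels = c(0.95, 0.998), outlier_level = 0.95,
                      outcomes = c("chronic_lt90", "chronic_ge90"),
                      ome_table = load_ome_table()) {
  config <- validate_cohort_config(config)
  if (is.null(years)) years <- config$year
  if (!is.null(cohort) && length(years) > 1) {
    abort("a supplied cohort can only be analysed for a single year")
  }
  year_results <- lapply(years, function(y) {
    coh <- cohort
    if (is.null(coh)) {
      cfg <- config
      cfg$year <- y
      cfg$seed <- (config$seed + 131 * (y - years[1])) %% 2147483647
      coh <- simulate_cohort(cfg)
    }
    run_study_year(coh, year = y, practice_quality = practice_quality,
                   include_n07bc = include_n07bc,
                   gap_tolerance = gap_tolerance,
                   winsor_fraction = winsor_fraction,
                   funnel_levels = funnel_levels,
                   outlier_level = outlier_level, outcomes = outcomes,
                   ome_table = ome_table)
  })
  names(year_results) <- as.character(years)
  structure(
    list(
      years = year_results,
      manifest = list(
        seed = config$seed,
        config_hash = rlang::hash(config),
        years = years,
        include_n07bc = include_n07bc,
        gap_tolerance = gap_tolerance,
        winsor_fraction = winsor_fraction,
        outlier_level = outlier_level,
        quantile_convention = QUANTILE_CONVENTION,
        package_version = as.character(utils::packageVersion("rxvar")),
        r_version = R.version.string
      )
    ),
    class = "rxvar_report"
  )
}

run_study_year <- function(coh, year, practice_quality, include_n07bc,
                           gap_tolerance, winsor_fraction, funnel_levels,
                           outlier_level, outcomes, ome_table) {
  practices <- coh$practices
  patients <- coh$patients
  prescriptions <- coh$prescriptions

  logs <- list()
  if (!is.null(practice_quality)) {
    fp <- filter_practices(practice_quality)
    logs$practices <- fp$log
    keep <- fp$included$practice_id
    practices <- practices[practices$practice_id %in% keep, , drop = FALSE]
    patients <- patients[patients$practice_id %in% keep, , drop = FALSE]
  }
  fpat <- filter_patients(patients)
  logs$patients <- fpat$log
  patients <- fpat$included
  prescriptions <- prescriptions[
    prescriptions$patient_id %in% patients$patient_id, , drop = FALSE
  ]

  sel <- select_opioids(prescriptions, include_n07bc = include_n07bc)
  logs$opioid_selection <- sel$log
  ome <- compute_ome(sel$opioids, table = ome_table)
  logs$ome <- ome$log
  eps <- build_episodes(ome$ome, year = year, gap_tolerance = gap_tolerance)
  logs$episodes <- eps$log
  class_tbl <- classify_patient_year(eps$episodes)
  cohort_classes <- patients |>
    dplyr::select("patient_id", "practice_id") |>
    dplyr::left_join(class_tbl, by = "patient_id") |>
    dplyr::mutate(year = year, class = forcats_replace_na(.data$class))
  model_data <- dplyr::left_join(
    patients, dplyr::select(cohort_classes, "patient_id", "class"),
    by = "patient_id"
  )

  per_outcome <- lapply(outcomes, function(oc) {
    model <- fit_case_mix_model(model_data, outcome = oc)
    out_tbl <- expected_counts(model, model_data)
    view <- standardized_view(out_tbl)
    funnel <- flag_practices(view$analyzed, level = outlier_level,
                             levels = funnel_levels,
                             winsor_fraction = winsor_fraction)
    list(model = model, outcomes = out_tbl, view = view, funnel = funnel)
  })
  names(per_outcome) <- outcomes

  variation_input <- dplyr::bind_rows(lapply(outcomes, function(oc) {
    v <- per_outcome[[oc]]$view$analyzed
    dplyr::bind_rows(
      tibble::tibble(year = year, outcome = oc, adjusted = FALSE,
                     practice_id = v$practice_id,
                     proportion = v$raw_proportion),
      tibble::tibble(year = year, outcome = oc, adjusted = TRUE,
                     practice_id = v$practice_id,
                     proportion = v$standardized_proportion)
    )
  }))
  variation <- variation_table(variation_input)

  outlier_tbl <- dplyr::bind_rows(lapply(outcomes, function(oc) {
    dplyr::mutate(outlier_counts(per_outcome[[oc]]$funnel),
                  year = year, outcome = oc, .before = 1)
  }))

  profile <- NULL
  if ("chronic_ge90" %in% outcomes &&
      all(c("pct_low_income", "pct_high_income", "urbanicity_addr_km2") %in%
            names(practices))) {
    groups <- assign_outlier_groups(per_outcome$chronic_ge90$funnel,
                                    per_outcome$chronic_ge90$view$zero_outcome)
    profile <- profile_groups(
      groups, practices,
      outcomes_lt90 = per_outcome$chronic_lt90$outcomes,
      outcomes_ge90 = per_outcome$chronic_ge90$outcomes
    )
  }

  desc <- descriptives(patients, cohort_classes, practices)
  audit_descriptives(desc)

  list(
    year = year,
    descriptives = desc,
    classes = cohort_classes,
    ome_coverage = ome$coverage,
    n_opioid_prescriptions = nrow(ome$ome),
    models = lapply(per_outcome, `[[`, "model"),
    practice_outcomes = lapply(per_outcome, `[[`, "outcomes"),
    zero_outcome = lapply(per_outcome, function(x) x$view$zero_outcome),
    variation = variation,
    outlier_counts = outlier_tbl,
    funnels = lapply(per_outcome, `[[`, "funnel"),
    profile = profile,
    exclusions = summarise_exclusions(dplyr::bind_rows(logs))
  )
}

#' @export
print.rxvar_report <- function(x, ...) {
  cat("Practice-variation study report (seed ", x$manifest$seed, ")\n",
      sep = "")
  for (y in names(x$years)) {
    yr <- x$years[[y]]
    cat("\nYear ", y, ": ", sep = "")
    n <- yr$descriptives$n[yr$descriptives$statistic == "patients"]
    np <- yr$descriptives$n[yr$descriptives$statistic == "practices"]
    cat(format(n, big.mark = " "), "patients in", np, "practices\n")
    print(yr$variation)
  }
  invisible(x)
}
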