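#' Assign practices to outlier-profiling groups
#'
#' Groups practices for the interpretation step: practices without any
#' patient with the outcome (`no_outcome`; they were never plotted on the
#' funnel), and low and high outliers on the funnel plot. Practices in
#' control are excluded from profiling.
#'
#' @param funnel A [flag_practices()] result (typically for the chronic
#'   high-dose outcome).
#' @param zero_outcome Zero-outcome practice tibble from
#'   [standardized_view()] (or a vector of practice ids).
#' @return A tibble `practice_id`, `group` (factor `no_outcome`,
#'   `low_outlier`, `high_outlier`).
#' @export
assign_outlier_groups <- function(funnel, zero_outcome) {
  zero_ids <- if (is.data.frame(zero_outcome)) zero_outcome$practice_id
              else as.character(zero_outcome)
  pts <- funnel$points
  groups <- dplyr::bind_rows(
    tibble::tibble(practice_id = zero_ids, group = "no_outcome"),
    tibble::tibble(
      practice_id = pts$practice_id[pts$status == "low_outlier"],
      group = "low_outlier"
    ),
    tibble::tibble(
      practice_id = pts$practice_id[pts$status == "high_outlier"],
      group = "high_outlier"
    )
  )
  if (anyDuplicated(groups$practice_id)) {
    abort("a practice cannot be both zero-outcome and plotted on the funnel")
  }
  groups$group <- factor(groups$group,
                         levels = c("no_outcome", "low_outlier",
                                    "high_outlier"))
  groups
}

#' Profile outlier groups on practice characteristics
#'
#' Summarises each group of practices on practice size, outcome
#' proportions, neighbourhood income shares and urbanicity. Both means and
#' medians with 25th-75th percentiles (package quantile convention) are
#' emitted; the customary report view shows medians and IQRs. Missing
#' covariate values are excluded per field, with the number missing
#' reported.
#'
#' @param groups Output of [assign_outlier_groups()].
#' @param practices Practice covariate tibble (`practice_id`, `list_size`,
#'   `pct_low_income`, `pct_high_income`, `urbanicity_addr_km2`).
#' @param outcomes_lt90,outcomes_ge90 Optional [expected_counts()] tables
#'   supplying standardized outcome proportions per practice (reported as
#'   percentages).
#' @return A tibble: `group`, `metric`, `n`, `n_missing`, `mean`, `median`,
#'   `q25`, `q75`.
#' @export
profile_groups <- function(groups, practices,
                           outcomes_lt90 = NULL, outcomes_ge90 = NULL) {
  wide <- groups |>
    dplyr::left_join(
      dplyr::select(practices, "practice_id", "list_size",
                    "pct_low_income", "pct_high_income",
                    "urbanicity_addr_km2"),
      by = "practice_id"
    )
  if (!is.null(outcomes_lt90)) {
    wide <- dplyr::left_join(
      wide,
      dplyr::transmute(outcomes_lt90, practice_id = .data$practice_id,
                       pct_chronic_lt90 = 100 * .data$standardized_proportion),
      by = "practice_id"
    )
  }
  if (!is.null(outcomes_ge90)) {
    wide <- dplyr::left_join(
      wide,
      dplyr::transmute(outcomes_ge90, practice_id = .data$practice_id,
                       pct_chronic_ge90 = 100 * .data$standardized_proportion),
      by = "practice_id"
    )
  }
  metrics <- setdiff(names(wide), c("practice_id", "group"))
  wide |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric",
                        values_to = "value") |>
    dplyr::group_by(.data$group, .data$metric) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      n_missing = sum(is.na(.data$value)),
      mean = if (any(!is.na(.data$value))) mean(.data$value, na.rm = TRUE)
             else NA_real_,
      median = if (any(!is.na(.data$value)))
        rx_quantile(.data$value[!is.na(.data$value)], 0.5) else NA_real_,
      q25 = if (any(!is.na(.data$value)))
        rx_quantile(.data$value[!is.na(.data$value)], 0.25) else NA_real_,
      q75 = if (any(!is.na(.data$value)))
        rx_quantile(.data$value[!is.na(.data$value)], 0.75) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(metric = factor(.data$metric, levels = metrics)) |>
    dplyr::arrange(.data$group, .data$metric)
}
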