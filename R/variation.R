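#' Percentile ratio of practice proportions
#'
#' Ratio of the high to the low percentile (default 95th/5th) of a vector
#' of practice-level proportions. Percentiles use the package quantile
#' convention (linear interpolation between order statistics, see
#' [rx_quantile()]); the convention is stamped into the output. Both the
#' ratio and the two percentiles are returned, mirroring the bracketed
#' proportions of published variation tables.
#'
#' @param values Positive practice proportions (zero-outcome practices must
#'   already be excluded).
#' @param hi,lo Percentiles in (0, 100).
#' @return One-row tibble: `p_hi`, `p_lo`, `ratio`, `n`, `convention`.
#' @export
#' @examples
#' percentile_ratio(1:100)  # 95.05 / 5.95
percentile_ratio <- function(values, hi = 95, lo = 5) {
  if (length(values) == 0 || any(is.na(values)) || any(values <= 0)) {
    abort("`values` must be positive and complete (exclude zero-outcome practices first)")
  }
  if (length(values) < 20) {
    warn("fewer than 20 practices: percentile ratio is unstable")
  }
  q <- rx_quantile(values, c(hi, lo) / 100)
  tibble::tibble(
    p_hi = q[1], p_lo = q[2], ratio = q[1] / q[2],
    n = length(values), convention = QUANTILE_CONVENTION
  )
}

#' Top-k / bottom-k mean ratio
#'
#' Mean of the `k` largest practice proportions divided by the mean of the
#' `k` smallest (default `k = 10`).
#'
#' @inheritParams percentile_ratio
#' @param k Number of practices in each tail; requires `2k <= n`.
#' @return One-row tibble: `mean_top`, `mean_bottom`, `ratio`, `k`, `n`.
#' @export
#' @examples
#' topk_ratio(1:20)  # 15.5 / 5.5
topk_ratio <- function(values, k = 10) {
  if (length(values) == 0 || any(is.na(values)) || any(values <= 0)) {
    abort("`values` must be positive and complete")
  }
  if (2 * k > length(values)) {
    abort(paste0("`k` = ", k, " requires at least ", 2 * k,
                 " practices; got ", length(values)))
  }
  s <- sort(values)
  top <- mean(tail(s, k))
  bottom <- mean(head(s, k))
  tibble::tibble(mean_top = top, mean_bottom = bottom, ratio = top / bottom,
                 k = k, n = length(values))
}

#' Variation summary table
#'
#' Computes both variation statistics (95%/5% percentile ratio and mean
#' top-10/bottom-10 ratio) for every outcome-by-adjustment combination in a
#' long table of practice proportions, mirroring the published layout where
#' each ratio is shown with the two proportions it is based on.
#'
#' @param proportions Long tibble with columns `outcome`, `adjusted`
#'   (logical), `practice_id`, `proportion` (positive), and optionally
#'   `year`.
#' @param hi,lo Percentiles for [percentile_ratio()].
#' @param k Tail size for [topk_ratio()].
#' @return A tibble with one row per outcome-adjustment (and year)
#'   combination: percentiles, tail means and both ratios.
#' @export
variation_table <- function(proportions, hi = 95, lo = 5, k = 10) {
  grouping <- intersect(c("year", "outcome", "adjusted"), names(proportions))
  proportions |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::group_modify(function(d, key) {
      pr <- percentile_ratio(d$proportion, hi = hi, lo = lo)
      if (nrow(d) >= 2 * k) {
        tk <- topk_ratio(d$proportion, k = k)
      } else {
        warn(paste0("fewer than ", 2 * k, " practices: top/bottom-", k,
                    " ratio not computed"))
        tk <- tibble::tibble(mean_top = NA_real_, mean_bottom = NA_real_,
                             ratio = NA_real_)
      }
      tibble::tibble(
        n_practices = nrow(d),
        p95 = pr$p_hi, p5 = pr$p_lo, ratio_95_5 = pr$ratio,
        mean_top10 = tk$mean_top, mean_bottom10 = tk$mean_bottom,
        ratio_top10_bottom10 = tk$ratio,
        convention = QUANTILE_CONVENTION
      )
    }) |>
    dplyr::ungroup()
}
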