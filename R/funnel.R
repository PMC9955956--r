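#' Practice z-score at the Poisson null
#'
#' Standardized deviation of the observed from the expected outcome count,
#' `z = (O - E) / sqrt(E)`, using the count-data variance at the null
#' (observed count with mean and variance `E`). These scores underlie the
#' winsorized overdispersion estimate.
#'
#' @param observed Observed counts.
#' @param expected Expected counts (> 0).
#' @return Numeric vector of z-scores.
#' @export
#' @examples
#' practice_z(110, 100)  # 1
practice_z <- function(observed, expected) {
  if (any(is.na(expected)) || any(expected <= 0)) {
    abort("`expected` must be positive")
  }
  (observed - expected) / sqrt(expected)
}

#' Winsorized overdispersion factor
#'
#' Estimates the multiplicative overdispersion factor phi of a set of
#' practice z-scores by winsorizing the scores at their `winsor_fraction`
#' and `1 - winsor_fraction` quantiles (package quantile convention) and
#' taking the mean of the squared winsorized scores. Overdispersion is
#' deemed present — and control limits are widened by `sqrt(phi)` — only
#' when phi exceeds `1 + 2 * sqrt(2 / n)`; otherwise limits use phi = 1.
#' Winsorizing protects the estimate from the very outliers the funnel plot
#' is meant to flag.
#'
#' @param z Numeric vector of practice z-scores (length >= 10).
#' @param winsor_fraction Fraction winsorized in each tail (default 0.10).
#' @return A list: `phi`, `triggered`, `threshold`, `n`, `winsor_fraction`.
#' @export
#' @examples
#' overdispersion_phi(rep(0, 12))$phi  # 0
overdispersion_phi <- function(z, winsor_fraction = 0.10) {
  n <- length(z)
  if (n < 10) {
    abort("overdispersion estimation needs at least 10 practices")
  }
  if (winsor_fraction < 0 || winsor_fraction >= 0.5) {
    abort("`winsor_fraction` must be in [0, 0.5)")
  }
  q <- rx_quantile(z, c(winsor_fraction, 1 - winsor_fraction))
  zw <- pmin(pmax(z, q[1]), q[2])
  phi <- mean(zw^2)
  threshold <- 1 + 2 * sqrt(2 / n)
  list(phi = phi, triggered = phi > threshold, threshold = threshold,
       n = n, winsor_fraction = winsor_fraction)
}

#' Funnel control limits for the O/E ratio
#'
#' Normal-approximation control limits around the target O/E = 1:
#' `1 +/- q * sqrt(phi / E)` where `q` is the two-sided standard-normal
#' quantile of the level (1.959964 for 95%, 3.090232 for 99.8%). The lower
#' limit is floored at 0. Limits tighten as the expected count grows and
#' widen by `sqrt(phi)` under overdispersion.
#'
#' @param expected Grid of expected counts (> 0).
#' @param phi Overdispersion factor (>= 0); 1 means no adjustment.
#' @param level Coverage level, e.g. 0.95 or 0.998.
#' @return A tibble: `level`, `expected`, `lower`, `upper`.
#' @export
#' @examples
#' control_limits(100, 1, 0.95)  # 0.8040 / 1.1960
control_limits <- function(expected, phi = 1, level = 0.95) {
  if (any(expected <= 0)) abort("`expected` must be positive")
  if (phi < 0) abort("`phi` must be non-negative")
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1)")
  q <- qnorm(1 - (1 - level) / 2)
  half <- q * sqrt(phi / expected)
  tibble::tibble(
    level = level, expected = expected,
    lower = pmax(0, 1 - half), upper = 1 + half
  )
}

#' Flag outlier practices on a funnel plot
#'
#' Builds the funnel-plot analysis for a set of analyzed practices
#' (observed count >= 1): estimates the winsorized overdispersion factor
#' from the practice z-scores, widens the control limits by `sqrt(phi)`
#' when the overdispersion trigger fires (and adjustment is enabled), and
#' classifies each practice as `in_control`, `low_outlier` or
#' `high_outlier` by comparing its O/E ratio with the limits at its
#' expected count. A practice exactly on a limit is in control: outliers
#' must lie strictly outside.
#'
#' @param outcomes A [expected_counts()] table restricted to analyzed
#'   practices (see [standardized_view()]).
#' @param level Flagging level (default 0.95).
#' @param levels Levels for the reported limit curves.
#' @param winsor_fraction Passed to [overdispersion_phi()].
#' @param overdispersion Apply the adjustment when triggered? Set `FALSE`
#'   to force phi = 1.
#' @return An object of class `rxvar_funnel`: `points` (per-practice
#'   status), `limits` (limit curves over an expected-count grid), `phi`,
#'   `phi_used`, `triggered`, `adjusted_for_od`, `level`,
#'   `winsor_fraction`, `outcome`.
#' @export
flag_practices <- function(outcomes, level = 0.95, levels = c(0.95, 0.998),
                           winsor_fraction = 0.10, overdispersion = TRUE) {
  if (any(outcomes$observed < 1)) {
    abort("`outcomes` must contain analyzed practices only (observed >= 1); use standardized_view()")
  }
  z <- practice_z(outcomes$observed, outcomes$expected)
  od <- overdispersion_phi(z, winsor_fraction = winsor_fraction)
  adjusted <- overdispersion && od$triggered
  phi_used <- if (adjusted) od$phi else 1
  lim_at <- control_limits(outcomes$expected, phi = phi_used, level = level)
  status <- factor(
    dplyr::case_when(
      outcomes$observed / outcomes$expected > lim_at$upper ~ "high_outlier",
      outcomes$observed / outcomes$expected < lim_at$lower ~ "low_outlier",
      TRUE ~ "in_control"
    ),
    levels = c("in_control", "low_outlier", "high_outlier")
  )
  grid <- exp(seq(log(max(min(outcomes$expected) * 0.8, 1e-3)),
                  log(max(outcomes$expected) * 1.1), length.out = 200))
  limits <- dplyr::bind_rows(
    lapply(levels, function(l) control_limits(grid, phi = phi_used, level = l))
  )
  structure(
    list(
      points = dplyr::mutate(
        dplyr::select(outcomes, "practice_id", "n_patients", "observed",
                      "expected", "oe_ratio"),
        status = status
      ),
      limits = limits,
      phi = od$phi, phi_used = phi_used, triggered = od$triggered,
      adjusted_for_od = adjusted, trigger_threshold = od$threshold,
      level = level, winsor_fraction = winsor_fraction,
      outcome = attr(outcomes, "outcome")
    ),
    class = "rxvar_funnel"
  )
}

#' @export
print.rxvar_funnel <- function(x, ...) {
  cat("Funnel analysis", if (!is.null(x$outcome)) paste0("for `", x$outcome, "`"),
      "\n")
  cat(sprintf("  %d practices; phi = %.3f (trigger > %.3f): %s\n",
              nrow(x$points), x$phi, x$trigger_threshold,
              if (x$adjusted_for_od) "limits adjusted for overdispersion"
              else "no adjustment applied"))
  print(outlier_counts(x))
  invisible(x)
}

#' Outlier counts in the published table layout
#'
#' Counts and percentages of practices outside, above and below the
#' flagging-level control limits. Percentages use the analyzed-practice
#' denominator (practices with at least one outcome).
#'
#' @param funnel A [flag_practices()] result.
#' @return A tibble: `category`, `n`, `pct`.
#' @export
outlier_counts <- function(funnel) {
  st <- funnel$points$status
  n_analyzed <- length(st)
  counts <- c(
    outside = sum(st != "in_control"),
    above = sum(st == "high_outlier"),
    below = sum(st == "low_outlier")
  )
  tibble::tibble(
    category = paste0("outliers_", names(counts), "_",
                      format(100 * funnel$level), "pct_limits"),
    n = unname(as.integer(counts)),
    n_analyzed = n_analyzed,
    pct = unname(100 * counts / n_analyzed)
  )
}

#' Funnel plot
#'
#' Scatter of the practice O/E ratios against their expected counts with
#' the control-limit curves, a dashed target line at O/E = 1, and outlier
#' status mapped to colour.
#'
#' @param object A `rxvar_funnel`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot rxvar_funnel
autoplot.rxvar_funnel <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$expected, y = .data$oe_ratio)) +
    ggplot2::geom_line(
      data = object$limits,
      ggplot2::aes(y = .data$lower, group = .data$level,
                   linetype = factor(.data$level)),
      colour = "grey40"
    ) +
    ggplot2::geom_line(
      data = object$limits,
      ggplot2::aes(y = .data$upper, group = .data$level,
                   linetype = factor(.data$level)),
      colour = "grey40"
    ) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$status), alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(
      in_control = "grey30", low_outlier = "#2166ac", high_outlier = "#b2182b"
    )) +
    ggplot2::labs(
      x = "Expected number of patients with the outcome",
      y = "Observed / expected ratio",
      linetype = "Control limit",
      colour = NULL,
      title = if (!is.null(object$outcome)) {
        paste0("Funnel plot: ", object$outcome,
               if (object$adjusted_for_od) " (overdispersion-adjusted)" else "")
      } else {
        NULL
      }
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
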