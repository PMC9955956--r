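#' Fit the case-mix adjustment model
#'
#' Logistic regression (maximum likelihood via iteratively reweighted least
#' squares, deviance tolerance 1e-8, at most 25 iterations) of a binary
#' outcome indicator — 1 for the target class, 0 otherwise — on categorical
#' age band, sex and chronic-disease count. The fitted probabilities are
#' the case-mix expected outcome probabilities used for indirect
#' standardization. With `covariates = NULL` an intercept-only model is
#' fitted, so every patient's prediction equals the overall proportion and
#' standardized proportions reduce to raw proportions.
#'
#' @param data Patient-level tibble containing a `class` column (see
#'   [classify_cohort()]) and the covariate columns.
#' @param outcome Target class: `"chronic_lt90"` or `"chronic_ge90"`.
#' @param covariates Character vector of covariate column names; `NULL` for
#'   intercept-only.
#' @return An object of class `case_mix_model` wrapping the `glm` fit, with
#'   `converged` and `separation` diagnostics.
#' @export
fit_case_mix_model <- function(data,
                               outcome = c("chronic_lt90", "chronic_ge90"),
                               covariates = c("age_band", "sex",
                                              "n_chronic_diseases")) {
  outcome <- match.arg(outcome)
  y <- as.integer(data$class == outcome)
  if (sum(y) == 0 || sum(y) == length(y)) {
    abort(paste0("cannot fit case-mix model for `", outcome,
                 "`: need at least one event and one non-event"))
  }
  df <- data[, covariates, drop = FALSE]
  df$.y <- y
  for (v in covariates) {
    if (is.factor(df[[v]]) && any(table(df[[v]]) == 0)) {
      warn(paste0("covariate `", v, "` has empty levels; they are dropped ",
                  "from the model"))
      df[[v]] <- droplevels(df[[v]])
    }
    if (length(unique(df[[v]])) < 2) {
      warn(paste0("covariate `", v, "` is constant; dropped from the model"))
      covariates <- setdiff(covariates, v)
    }
  }
  form <- if (length(covariates) == 0) {
    .y ~ 1
  } else {
    stats::reformulate(covariates, response = ".y")
  }
  fit <- glm(form, family = binomial(), data = df,
             control = glm.control(epsilon = 1e-8, maxit = 25))
  separation <- any(abs(coef(fit)) > 15, na.rm = TRUE)
  if (!fit$converged || separation) {
    warn(paste0("case-mix model for `", outcome, "` flagged: ",
                if (!fit$converged) "did not converge; " else "",
                if (separation) "possible complete separation" else ""))
  }
  structure(
    list(fit = fit, outcome = outcome, covariates = covariates,
         converged = fit$converged, separation = separation,
         n_obs = length(y), overall = mean(y)),
    class = "case_mix_model"
  )
}

#' @export
print.case_mix_model <- function(x, ...) {
  cat("Case-mix model for outcome `", x$outcome, "`\n", sep = "")
  cat("  n =", x$n_obs, " events =", round(x$overall * x$n_obs),
      sprintf("(%.3f%%)", 100 * x$overall), "\n")
  cat("  covariates:",
      if (length(x$covariates)) paste(x$covariates, collapse = ", ")
      else "(intercept only)", "\n")
  cat("  converged:", x$converged,
      if (x$separation) " [separation flagged]" else "", "\n")
  invisible(x)
}

#' @export
predict.case_mix_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    unname(stats::fitted(object$fit))
  } else {
    unname(predict(object$fit, newdata = newdata, type = "response"))
  }
}

#' Tidy a case-mix model
#'
#' @param x A `case_mix_model`.
#' @param ... Passed to the `glm` tidier.
#' @return A tibble of coefficients (log-odds scale) with standard errors.
#' @export
#' @method tidy case_mix_model
tidy.case_mix_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "z value"],
    p.value = s[, "Pr(>|z|)"]
  )
}

#' Glance at a case-mix model
#'
#' @param x A `case_mix_model`.
#' @param ... Unused.
#' @return One-row tibble with fit summaries.
#' @export
#' @method glance case_mix_model
glance.case_mix_model <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome,
    n_obs = x$n_obs,
    n_events = as.integer(round(x$overall * x$n_obs)),
    overall_proportion = x$overall,
    null.deviance = x$fit$null.deviance,
    deviance = x$fit$deviance,
    AIC = stats::AIC(x$fit),
    converged = x$converged,
    separation = x$separation
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-practice observed and expected outcome counts
#'
#' For each practice, sums the model-predicted probabilities of its
#' patients into the expected count `E`, counts observed outcomes `O`, and
#' derives the observed/expected ratio and the indirectly standardized
#' proportion `(O/E) * overall proportion`. Because the logistic model
#' contains an intercept, the score equations of the maximum-likelihood fit
#' make expected counts sum to observed counts over all practices.
#'
#' @param model A fitted [fit_case_mix_model()].
#' @param data The same patient-level tibble used for fitting (must contain
#'   `practice_id`, `class` and the model covariates).
#' @return A tibble of class `practice_outcomes`: `practice_id`,
#'   `n_patients`, `observed`, `expected`, `oe_ratio`, `raw_proportion`,
#'   `standardized_proportion`, with the outcome and overall proportion as
#'   attributes.
#' @export
expected_counts <- function(model, data) {
  p <- predict(model, newdata = data)
  y <- as.integer(data$class == model$outcome)
  overall <- mean(y)
  out <- tibble::tibble(practice_id = data$practice_id, p = p, y = y) |>
    dplyr::group_by(.data$practice_id) |>
    dplyr::summarise(
      n_patients = dplyr::n(),
      observed = sum(.data$y),
      expected = sum(.data$p),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      oe_ratio = .data$observed / .data$expected,
      raw_proportion = .data$observed / .data$n_patients,
      standardized_proportion = .data$oe_ratio * overall
    )
  attr(out, "outcome") <- model$outcome
  attr(out, "overall_proportion") <- overall
  class(out) <- c("practice_outcomes", class(out))
  out
}

#' Split practices by outcome occurrence
#'
#' To avoid standardized proportions of zero, only practices with at least
#' one patient with the outcome enter the variation analysis; practices
#' without any outcome are reported separately.
#'
#' @param outcomes A [expected_counts()] table.
#' @param include_zero If `TRUE`, zero-outcome practices are kept in the
#'   analyzed set (for diagnostics only).
#' @return A list with `analyzed`, `zero_outcome` (both tibbles) and
#'   `n_zero`.
#' @export
standardized_view <- function(outcomes, include_zero = FALSE) {
  zero <- outcomes[outcomes$observed == 0, , drop = FALSE]
  analyzed <- if (include_zero) outcomes else
    outcomes[outcomes$observed >= 1, , drop = FALSE]
  list(analyzed = analyzed, zero_outcome = zero, n_zero = nrow(zero))
}
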