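sim_class_data <- function(cfg, seed_offset = 0) {
  cfg$seed <- cfg$seed + seed_offset
  pr <- simulate_practices(cfg)
  pat <- simulate_patients(pr, cfg)
  gt <- simulate_true_classes(pat, pr, cfg)
  list(
    practices = pr,
    data = dplyr::mutate(
      dplyr::left_join(pat, dplyr::select(gt, patient_id, true_class),
                       by = "patient_id"),
      class = true_class
    )
  )
}

test_that("an intercept-only model predicts the overall proportion", {
  d <- sim_class_data(small_config())$data
  m <- fit_case_mix_model(d, outcome = "chronic_lt90", covariates = NULL)
  p <- predict(m, newdata = d)
  expect_equal(unique(round(p, 12)),
               round(mean(d$class == "chronic_lt90"), 12))
  out <- expected_counts(m, d)
  expect_equal(out$standardized_proportion, out$raw_proportion,
               tolerance = 1e-12)
})

test_that("flipping the outcome indicator negates all coefficients", {
  d <- sim_class_data(small_config())$data
  m <- fit_case_mix_model(d, outcome = "chronic_lt90")
  flipped <- dplyr::mutate(
    d, class = factor(ifelse(class == "chronic_lt90", "none",
                             "chronic_lt90"),
                      levels = rxvar:::OUTCOME_CLASSES)
  )
  m2 <- fit_case_mix_model(flipped, outcome = "chronic_lt90")
  expect_equal(coef(m2$fit), -coef(m$fit), tolerance = 1e-6)
})

test_that("the fit recovers known generating coefficients within 3 SE", {
  cfg <- cohort_config(n_practices = 4, practice_size_log_mean = log(50000),
                       practice_size_log_sd = 0, size_range = c(100, 60000),
                       tau_practice = 0, seed = 88)
  d <- sim_class_data(cfg)$data
  d$class <- factor(ifelse(d$class == "none", "none", "chronic_lt90"),
                    levels = rxvar:::OUTCOME_CLASSES)  # any chronic use
  m <- fit_case_mix_model(d, outcome = "chronic_lt90")
  td <- tidy(m)
  eff <- cfg$covariate_effects
  truth <- c(
    "(Intercept)" = cfg$base_logit_chronic,
    setNames(eff$age_band[-1], paste0("age_band", names(eff$age_band)[-1])),
    sexmale = eff$sex_male,
    setNames(eff$n_chronic_diseases[-1],
             paste0("n_chronic_diseases",
                    names(eff$n_chronic_diseases)[-1]))
  )
  td <- td[td$term %in% names(truth), ]
  z <- abs(td$estimate - truth[td$term]) / td$std.error
  expect_lt(max(z), 3)
  expect_true(m$converged)
  expect_false(m$separation)
  g <- glance(m)
  expect_equal(g$n_obs, nrow(d))
})

test_that("degenerate outcomes and empty levels are caught", {
  d <- sim_class_data(small_config())$data
  d$class <- factor("none", levels = rxvar:::OUTCOME_CLASSES)
  expect_error(fit_case_mix_model(d, "chronic_lt90"), "non-event")
  d2 <- sim_class_data(small_config())$data
  d2 <- d2[d2$age_band != "90+", ]
  expect_warning(fit_case_mix_model(d2, "chronic_lt90"), "empty levels")
})

test_that("expected counts calibrate: sum(E) equals sum(O)", {
  d <- sim_class_data(small_config())$data
  for (oc in c("chronic_lt90", "chronic_ge90")) {
    m <- fit_case_mix_model(d, outcome = oc)
    out <- expected_counts(m, d)
    expect_lt(abs(sum(out$expected) - sum(out$observed)) /
                sum(out$observed), 1e-6)
    expect_true(all(out$expected > 0))
    expect_equal(out$standardized_proportion,
                 out$oe_ratio * attr(out, "overall_proportion"),
                 tolerance = 1e-12)
  }
})

test_that("expected counts scale with size under a homogeneous case mix", {
  d <- sim_class_data(small_config())$data
  d$age_band <- factor("50-54", levels = levels(d$age_band))
  d$sex <- "female"
  d$n_chronic_diseases <- factor("1", levels = rxvar:::DISEASE_LEVELS)
  m <- suppressWarnings(fit_case_mix_model(d, outcome = "chronic_lt90"))
  out <- expected_counts(m, d)
  expect_equal(out$expected / out$n_patients,
               rep(mean(d$class == "chronic_lt90"), nrow(out)),
               tolerance = 1e-9)
  # with a single practice holding all patients, O/E is exactly 1
  d1 <- dplyr::mutate(d, practice_id = "only")
  m1 <- suppressWarnings(fit_case_mix_model(d1, outcome = "chronic_lt90"))
  out1 <- expected_counts(m1, d1)
  expect_equal(out1$oe_ratio, 1, tolerance = 1e-9)
})

test_that("standardized proportions are invariant to reference relabeling", {
  d <- sim_class_data(small_config())$data
  m <- fit_case_mix_model(d, outcome = "chronic_lt90")
  out <- expected_counts(m, d)
  d2 <- dplyr::mutate(d, age_band = stats::relevel(droplevels(age_band),
                                                   ref = "60-64"))
  m2 <- fit_case_mix_model(d2, outcome = "chronic_lt90")
  out2 <- expected_counts(m2, d2)
  expect_equal(out$standardized_proportion, out2$standardized_proportion,
               tolerance = 1e-8)
})

test_that("standardized_view splits analyzed and zero-outcome practices", {
  out <- tibble::tibble(
    practice_id = c("a", "b", "c"), n_patients = c(10, 10, 10),
    observed = c(0, 1, 5), expected = c(1, 2, 3)
  )
  v <- standardized_view(out)
  expect_equal(nrow(v$analyzed), 2L)
  expect_equal(v$n_zero, 1L)
  expect_equal(v$zero_outcome$practice_id, "a")
  all_in <- standardized_view(dplyr::mutate(out, observed = c(2, 1, 5)))
  expect_equal(all_in$n_zero, 0L)
})
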