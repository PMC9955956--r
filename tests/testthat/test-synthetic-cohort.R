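test_that("configuration validation names the offending field", {
  expect_error(cohort_config(n_practices = 1), "n_practices")
  expect_error(cohort_config(tau_practice = -0.1), "tau_practice")
  expect_error(cohort_config(p_male = 1.5), "p_male")
  w <- default_age_band_weights()
  w[1] <- w[1] + 1e-6
  expect_error(cohort_config(age_band_weights = w), "age_band_weights")
})

test_that("generation is deterministic given the seed and substreamed", {
  cfg <- small_config()
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$practices, b$practices)
  expect_identical(a$patients, b$patients)
  expect_identical(a$prescriptions, b$prescriptions)
  expect_identical(a$ground_truth, b$ground_truth)
  # practice draws do not depend on how many patients are generated later
  p1 <- simulate_practices(cfg)
  invisible(simulate_patients(p1, cfg))
  p2 <- simulate_practices(cfg)
  expect_identical(p1, p2)
})

test_that("zero practice variance collapses all true prescribing logits", {
  cfg <- small_config(tau_practice = 0)
  pr <- simulate_practices(cfg)
  expect_true(all(pr$u_practice == 0))
  pat <- simulate_patients(pr, cfg)
  gt <- simulate_true_classes(pat, pr, cfg)
  expect_equal(length(unique(gt$practice_true_logit)), 1L)
})

test_that("practice sizes hit their configured mean", {
  cfg <- cohort_config(n_practices = 361, seed = 5)
  pr <- simulate_practices(cfg)
  expect_true(all(pr$list_size >= 500 & pr$list_size <= 13000))
  expect_lt(abs(mean(pr$list_size) - 2838) / 2838, 0.05)
})

test_that("patient margins converge to the configured weights", {
  cfg <- cohort_config(n_practices = 30, practice_size_log_mean = log(10000),
                       practice_size_log_sd = 0, seed = 9)
  pr <- simulate_practices(cfg)
  pat <- simulate_patients(pr, cfg)
  n <- nrow(pat)
  # 20-39 share: target 30.6% within 3 Monte-Carlo SEs
  share <- mean(age_band_lower(pat$age_band) < 40)
  se <- sqrt(0.306 * (1 - 0.306) / n)
  expect_lt(abs(share - 0.306), 3 * se)
  sex_se <- sqrt(0.493 * 0.507 / n)
  expect_lt(abs(mean(pat$sex == "male") - 0.493), 3 * sex_se)
})

test_that("degenerate patient distributions are honoured", {
  w <- setNames(rep(0, 15), names(default_age_band_weights()))
  w["50-54"] <- 1
  cfg <- small_config(age_band_weights = w, p_cancer = 0)
  pat <- simulate_patients(simulate_practices(cfg), cfg)
  expect_true(all(pat$age_band == "50-54"))
  expect_false(any(pat$cancer_active))
})

test_that("realized class frequencies match the logistic-model expectation", {
  cfg <- cohort_config(n_practices = 50, practice_size_log_mean = log(5000),
                       practice_size_log_sd = 0, seed = 31)
  pr <- simulate_practices(cfg)
  pat <- simulate_patients(pr, cfg)
  probs <- rxvar:::true_class_probabilities(pat, pr, cfg)
  gt <- simulate_true_classes(pat, pr, cfg)
  p_exp <- mean(probs$p_chronic)
  p_obs <- mean(gt$true_class != "none")
  se <- sqrt(p_exp * (1 - p_exp) / nrow(pat))
  expect_lt(abs(p_obs - p_exp), 3 * se)
  p_hd_exp <- p_exp * mean(probs$p_highdose_given_chronic)
  p_hd_obs <- mean(gt$true_class == "chronic_ge90")
  se_hd <- sqrt(p_hd_exp * (1 - p_hd_exp) / nrow(pat))
  expect_lt(abs(p_hd_obs - p_hd_exp), 3 * se_hd)
})

test_that("rare-outcome practice rates spread as the lognormal closed form", {
  # for a rare outcome with random intercept sd tau, the 95th/5th percentile
  # ratio of true practice rates approaches exp(2 * 1.645 * tau)
  cfg <- cohort_config(n_practices = 20000, tau_practice = 0.6, seed = 77)
  pr <- simulate_practices(cfg)
  p <- plogis(cfg$base_logit_chronic + pr$u_practice)
  q <- rx_quantile(p, c(0.95, 0.05))
  expect_lt(abs(q[1] / q[2] - exp(3.29 * 0.6)) / exp(3.29 * 0.6), 0.05)
})

test_that("impossible outcomes generate no outcome prescriptions", {
  cfg <- small_config(base_logit_chronic = -Inf, p_short_course = 0,
                      noise_fraction = 0)
  coh <- simulate_cohort(cfg)
  expect_true(all(coh$ground_truth$true_class == "none"))
  expect_equal(nrow(coh$prescriptions), 0L)
})

test_that("every generated patient appears exactly once in the ground truth", {
  coh <- simulate_cohort(small_config())
  expect_setequal(coh$ground_truth$patient_id, coh$patients$patient_id)
  expect_equal(anyDuplicated(coh$ground_truth$patient_id), 0L)
})

test_that("cohorts round-trip through CSV files", {
  coh <- simulate_cohort(small_config(n_practices = 4))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_setequal(
    list.files(dir),
    c("practices.csv", "patients.csv", "prescriptions.csv",
      "ground_truth.csv")
  )
  rx <- readr::read_csv(file.path(dir, "prescriptions.csv"),
                        show_col_types = FALSE)
  expect_equal(nrow(rx), nrow(coh$prescriptions))
  expect_s3_class(rx$start_date, "Date")
})
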