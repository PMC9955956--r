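test_that("abutting prescriptions merge into one episode", {
  rx <- make_rx("a", start_day = c(1, 51), days_supplied = c(50, 50),
                daily_ome = 40)
  eps <- build_episodes(rx, 2019)$episodes
  expect_equal(nrow(eps), 1L)
  expect_equal(eps$length, 100L)
  expect_equal(eps$total_ome, 4000)
  expect_equal(eps$mean_daily_ome, 40)
})

test_that("a gap beyond the tolerance splits episodes", {
  rx <- make_rx("a", start_day = c(1, 81), days_supplied = c(50, 50),
                daily_ome = 40)
  split <- build_episodes(rx, 2019, gap_tolerance = 0)$episodes
  expect_equal(nrow(split), 2L)
  expect_equal(split$length, c(50L, 50L))
  merged <- build_episodes(rx, 2019, gap_tolerance = 30)$episodes
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$length, 130L)  # bridged gap days count toward length
})

test_that("overlap days count once for duration while OME accumulates", {
  rx <- make_rx("a", start_day = c(1, 1), days_supplied = c(30, 30),
                daily_ome = c(30, 60))
  eps <- build_episodes(rx, 2019)$episodes
  expect_equal(eps$length, 30L)
  expect_equal(eps$total_ome, 30 * 30 + 60 * 30)
  expect_equal(eps$mean_daily_ome, 90)
})

test_that("episodes are clipped to the calendar year with pro-rated OME", {
  rx <- make_rx("a", start_day = 336, days_supplied = 60, daily_ome = 50)
  eps <- build_episodes(rx, 2019)$episodes
  expect_equal(eps$end_date, as.Date("2019-12-31"))
  expect_equal(eps$length, 30L)
  expect_equal(eps$total_ome, 50 * 60 * (30 / 60))
  before <- make_rx("b", start_day = -20, days_supplied = 10, daily_ome = 10)
  expect_equal(nrow(build_episodes(before, 2019)$episodes), 0L)
})

test_that("non-positive days supplied are rejected with a log entry", {
  rx <- dplyr::bind_rows(
    make_rx("a", 1, 30, 10),
    make_rx("b", 1, 0, 10)
  )
  res <- build_episodes(rx, 2019)
  expect_equal(unique(res$episodes$patient_id), "a")
  expect_equal(res$log$rule_id, "nonpositive_days")
})

test_that("non-convertible prescriptions follow the configured policy", {
  rx <- make_rx("a", start_day = c(1, 31), days_supplied = c(30, 30),
                daily_ome = 40)
  rx$convertible <- c(TRUE, FALSE)
  rx$total_ome[2] <- NA
  excl <- build_episodes(rx, 2019, noncovertible = "exclude")$episodes
  expect_equal(excl$length, 30L)
  cov <- build_episodes(rx, 2019, noncovertible = "coverage_only")$episodes
  expect_equal(cov$length, 60L)
  expect_equal(cov$total_ome, 1200)
})

test_that("interval merge equals the day-array brute force on random input", {
  set.seed(2024)
  rx <- random_patient_rx(1000)
  got <- build_episodes(rx, 2019)$episodes |>
    dplyr::mutate(
      start_day = as.integer(start_date - as.Date("2019-01-01")) + 1L,
      end_day = as.integer(end_date - as.Date("2019-01-01")) + 1L
    ) |>
    dplyr::arrange(patient_id, start_day)
  want <- oracle_episodes(rx, 2019) |>
    dplyr::arrange(patient_id, start_day)
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$patient_id, want$patient_id)
  expect_equal(got$start_day, want$start_day)
  expect_equal(got$end_day, want$end_day)
  expect_equal(got$length, want$length)
  expect_equal(got$total_ome, want$total_ome, tolerance = 1e-10)
})

test_that("interval merge equals the brute force under a gap tolerance", {
  set.seed(2025)
  rx <- random_patient_rx(300)
  for (tol in c(3, 14)) {
    got <- build_episodes(rx, 2019, gap_tolerance = tol)$episodes
    want <- oracle_episodes(rx, 2019, gap_tolerance = tol)
    expect_equal(nrow(got), nrow(want))
    expect_equal(sort(got$length), sort(want$length))
    expect_equal(sum(got$total_ome), sum(want$total_ome), tolerance = 1e-10)
  }
})

test_that("duration and dose thresholds classify inclusively with precedence", {
  # 90 days at mean exactly 90 mg OME/day: high-dose (inclusive boundary)
  at_bound <- build_episodes(
    make_rx("a", 1, 90, daily_ome = 90), 2019
  )$episodes
  expect_equal(at_bound$total_ome, 8100)
  expect_equal(classify_patient_year(at_bound)$class,
               factor("chronic_ge90", levels = rxvar:::OUTCOME_CLASSES))
  # 89 days at a high dose is not chronic at all
  short <- build_episodes(make_rx("b", 1, 89, daily_ome = 200),
                          2019)$episodes
  expect_equal(as.character(classify_patient_year(short)$class), "none")
  # chronic low-dose and chronic high-dose episodes in one year: high-dose wins
  both <- build_episodes(dplyr::bind_rows(
    make_rx("c", 1, 120, daily_ome = 30),
    make_rx("c", 200, 95, daily_ome = 120)
  ), 2019)$episodes
  expect_equal(nrow(both), 2L)
  expect_equal(as.character(classify_patient_year(both)$class),
               "chronic_ge90")
  # 90 days just under the dose threshold
  under <- build_episodes(make_rx("d", 1, 90, daily_ome = 89.99),
                          2019)$episodes
  expect_equal(as.character(classify_patient_year(under)$class),
               "chronic_lt90")
})

test_that("adding a prescription never demotes a patient-year class", {
  set.seed(7)
  ord <- function(x) match(x, rxvar:::OUTCOME_CLASSES)
  for (i in 1:60) {
    base <- random_patient_rx(1, max_rx = 4)
    cls <- function(rx) {
      eps <- build_episodes(rx, 2019)$episodes
      if (nrow(eps) == 0) "none" else
        as.character(classify_patient_year(eps)$class)
    }
    before <- cls(base)
    # duration direction: adding any prescription cannot undo chronic use
    extra <- make_rx(base$patient_id[1], sample(1:300, 1), sample(1:60, 1),
                     runif(1, 5, 200))
    extra$rx_id <- "extra"
    after <- cls(dplyr::bind_rows(base, extra))
    if (before != "none") expect_gte(ord(after), 2)
    # dose direction: an addition at or above the high-dose threshold
    # cannot demote high-dose use
    if (before == "chronic_ge90") {
      rich <- make_rx(base$patient_id[1], sample(1:300, 1), sample(1:60, 1),
                      runif(1, 90, 300))
      rich$rx_id <- "rich"
      expect_equal(cls(dplyr::bind_rows(base, rich)), "chronic_ge90")
    }
  }
})

test_that("classify_cohort covers every patient and validates references", {
  patients <- tibble::tibble(patient_id = c("a", "b", "c"),
                             practice_id = "p1")
  rx <- tibble::tibble(
    rx_id = "1", patient_id = "a", atc = "N02AA01",
    start_date = as.Date("2019-01-01"), days_supplied = 120,
    strength_mg_per_unit = 10, units_per_day = 3, route = "oral"
  )
  cls <- classify_cohort(patients, rx, year = 2019)
  expect_equal(nrow(cls), 3L)
  got <- setNames(as.character(cls$class), cls$patient_id)
  expect_equal(got[["a"]], "chronic_lt90")
  expect_equal(got[["b"]], "none")
  bad <- dplyr::mutate(rx, patient_id = "ghost")
  expect_error(classify_cohort(patients, bad, 2019), "unknown patients")
  none <- classify_cohort(patients, rx[0, ], 2019)
  expect_true(all(none$class == "none"))
})

test_that("the classifier recovers generator ground truth exactly", {
  cfg <- small_config(noise_fraction = 0)
  coh <- simulate_cohort(cfg)
  cls <- classify_cohort(coh$patients, coh$prescriptions, cfg$year)
  joined <- dplyr::inner_join(cls, coh$ground_truth, by = "patient_id")
  expect_equal(as.character(joined$class), as.character(joined$true_class))
  # noise records (codeine, NSAIDs, missing strength) do not disturb recovery
  noisy <- simulate_cohort(small_config(noise_fraction = 0.05))
  cls2 <- classify_cohort(noisy$patients, noisy$prescriptions, cfg$year)
  j2 <- dplyr::inner_join(cls2, noisy$ground_truth, by = "patient_id")
  expect_equal(as.character(j2$class), as.character(j2$true_class))
})
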