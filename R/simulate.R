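#' Simulate general practices
#'
#' Draws the practice frame of a synthetic cohort: list sizes from a
#' truncated log-normal (heavy right tail, as observed practice-size ranges
#' show), a practice-level random intercept `u_practice` on the logit scale,
#' and neighbourhood covariates (low/high income percentages, urbanicity in
#' addresses/km2) linearly coupled to the random intercept with Gaussian
#' noise. Runs are deterministic given `config$seed`; each generator stage
#' uses its own substream, so changing the number of patients never perturbs
#' the practice draws.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per practice: `practice_id`, `list_size`,
#'   `u_practice`, `pct_low_income`, `pct_high_income`,
#'   `urbanicity_addr_km2`.
#' @export
#' @examples
#' simulate_practices(cohort_config(n_practices = 5, seed = 1))
simulate_practices <- function(config) {
  config <- validate_cohort_config(config)
  n <- as.integer(config$n_practices)
  with_substream(config$seed, "practices", {
    sizes <- numeric(0)
    while (length(sizes) < n) {
      draw <- exp(rnorm(2L * n, config$practice_size_log_mean,
                        config$practice_size_log_sd))
      draw <- draw[draw >= config$size_range[1] & draw <= config$size_range[2]]
      sizes <- c(sizes, draw)
    }
    sizes <- round(sizes[seq_len(n)])
    u <- rnorm(n, 0, config$tau_practice)
    low <- pmin(pmax(34 + config$ses_effect * u + rnorm(n, 0, 4), 1), 99)
    high <- pmin(pmax(24 - 0.6 * config$ses_effect * u + rnorm(n, 0, 3), 1), 99)
    urb <- round(exp(log(1242) + config$urban_effect * u + rnorm(n, 0, 0.5)))
    tibble::tibble(
      practice_id = sprintf("p%04d", seq_len(n)),
      list_size = as.integer(sizes),
      u_practice = u,
      pct_low_income = low,
      pct_high_income = high,
      urbanicity_addr_km2 = urb
    )
  })
}

#' Simulate registered patients
#'
#' Fills each practice with its list-size many patients, drawing 5-year age
#' band, sex, chronic-disease count, active-cancer flag and full-year
#' registration independently from the configured marginal distributions.
#'
#' @param practices Output of [simulate_practices()].
#' @param config The same [cohort_config()].
#' @return A tibble with one row per patient: `patient_id`, `practice_id`,
#'   `age_band`, `sex`, `n_chronic_diseases`, `cancer_active`,
#'   `registered_full_year`.
#' @export
simulate_patients <- function(practices, config) {
  config <- validate_cohort_config(config)
  if (!is.data.frame(practices) || nrow(practices) == 0) {
    abort("`practices` must be a non-empty practice table")
  }
  n <- sum(practices$list_size)
  with_substream(config$seed, "patients", {
    pid <- rep(practices$practice_id, practices$list_size)
    tibble::tibble(
      patient_id = paste0(pid, "-", sprintf("%06d", sequence(practices$list_size))),
      practice_id = pid,
      age_band = factor(
        sample(AGE_BANDS_ADULT, n, replace = TRUE,
               prob = config$age_band_weights[AGE_BANDS_ADULT]),
        levels = AGE_BANDS_ADULT
      ),
      sex = ifelse(runif(n) < config$p_male, "male", "female"),
      n_chronic_diseases = factor(
        sample(DISEASE_LEVELS, n, replace = TRUE,
               prob = config$chronic_disease_weights[DISEASE_LEVELS]),
        levels = DISEASE_LEVELS
      ),
      cancer_active = runif(n) < config$p_cancer,
      registered_full_year = runif(n) < config$p_full_year
    )
  })
}

# Per-patient outcome probabilities under the generative logistic model.
true_class_probabilities <- function(patients, practices, config) {
  eff <- config$covariate_effects
  u <- setNames(practices$u_practice, practices$practice_id)
  eta <- config$base_logit_chronic +
    eff$age_band[as.character(patients$age_band)] +
    eff$sex_male * (patients$sex == "male") +
    eff$n_chronic_diseases[as.character(patients$n_chronic_diseases)] +
    u[patients$practice_id]
  tibble::tibble(
    patient_id = patients$patient_id,
    practice_id = patients$practice_id,
    p_chronic = plogis(unname(eta)),
    p_highdose_given_chronic =
      plogis(config$base_logit_highdose_given_chronic),
    practice_true_logit = config$base_logit_chronic +
      unname(u[patients$practice_id])
  )
}

#' Draw ground-truth outcome classes
#'
#' Assigns each patient a true class (`none`, `chronic_lt90`,
#' `chronic_ge90`) from the generative model: chronic use follows a logistic
#' model in age band, sex and chronic-disease count with the practice random
#' intercept; being high-dose given chronic use is a fixed conditional
#' probability independent of the practice effect, so practice-level rates of
#' both outcomes scale with `exp(u_practice)` for rare outcomes.
#'
#' @inheritParams simulate_patients
#' @param patients Output of [simulate_patients()].
#' @return A ground-truth tibble: `patient_id`, `practice_id`, `true_class`,
#'   `practice_true_logit`.
#' @export
simulate_true_classes <- function(patients, practices, config) {
  config <- validate_cohort_config(config)
  probs <- true_class_probabilities(patients, practices, config)
  with_substream(config$seed, "classes", {
    chronic <- runif(nrow(probs)) < probs$p_chronic
    hd <- runif(nrow(probs)) < probs$p_highdose_given_chronic
    tibble::tibble(
      patient_id = probs$patient_id,
      practice_id = probs$practice_id,
      true_class = factor(
        dplyr::case_when(
          chronic & hd ~ "chronic_ge90",
          chronic ~ "chronic_lt90",
          TRUE ~ "none"
        ),
        levels = c("none", "chronic_lt90", "chronic_ge90")
      ),
      practice_true_logit = probs$practice_true_logit
    )
  })
}

year_length <- function(year) {
  as.integer(as.Date(paste0(year + 1, "-01-01")) -
               as.Date(paste0(year, "-01-01")))
}

# Generator drug palette: oral opioids with their OME factors, used to vary
# ATC codes while controlling the daily OME exactly.
GEN_DRUGS <- tibble::tibble(
  drug = c("morphine", "oxycodone", "tramadol"),
  atc = c("N02AA01", "N02AA05", "N02AX02"),
  strength = c(10, 5, 50),
  factor = c(1, 1.5, 0.1)
)

#' Simulate prescription streams
#'
#' Realises each patient's true class as dispensing records. Chronic
#' patients receive chained prescriptions (default 30 days supplied each,
#' abutting with zero gaps) covering one 90-365 day episode at a constant
#' daily dose drawn strictly below `90 * (1 - highdose_margin)` mg OME
#' (chronic <90) or strictly above `90 * (1 + highdose_margin)` (chronic
#' high-dose). Patients of class `none` receive nothing or, with probability
#' `p_short_course`, one short (<90 day) course. A configurable fraction of
#' noise records (codeine, a non-opioid NSAID, opioid rows with missing
#' strength) is injected on top; with `noise_fraction = 0` and matching gap
#' tolerance the episode classifier recovers the ground truth exactly.
#'
#' @inheritParams simulate_patients
#' @param classes Optional precomputed [simulate_true_classes()] output; when
#'   `NULL` the classes are drawn (from the dedicated class substream, so the
#'   result is identical either way).
#' @return A list with `prescriptions` (tibble: `rx_id`, `patient_id`,
#'   `atc`, `start_date`, `days_supplied`, `strength_mg_per_unit`,
#'   `units_per_day`, `route`) and `ground_truth`.
#' @export
simulate_prescriptions <- function(patients, practices, config,
                                   classes = NULL) {
  config <- validate_cohort_config(config)
  if (is.null(classes)) {
    classes <- simulate_true_classes(patients, practices, config)
  }
  ylen <- year_length(config$year)
  jan1 <- as.Date(paste0(config$year, "-01-01"))
  margin <- config$highdose_margin
  chunk <- config$rx_chunk_days

  with_substream(config$seed, "prescriptions", {
    out <- classes[classes$true_class != "none", ]
    n_out <- nrow(out)
    episodes <- NULL
    if (n_out > 0) {
      len <- pmin(90L + stats::rgeom(n_out, 1 / 60), 270L)
      start <- floor(runif(n_out) * (ylen - len + 1)) + 1L
      hd <- out$true_class == "chronic_ge90"
      daily <- ifelse(hd,
                      runif(n_out, 90 * (1 + margin), 250),
                      runif(n_out, 10, 90 * (1 - margin)))
      drug_i <- sample(1:2, n_out, replace = TRUE)  # morphine / oxycodone
      episodes <- tibble::tibble(
        patient_id = out$patient_id,
        ep_len = as.integer(len), ep_start = as.integer(start),
        daily_ome = daily,
        atc = GEN_DRUGS$atc[drug_i],
        strength = GEN_DRUGS$strength[drug_i],
        ome_factor = GEN_DRUGS$factor[drug_i],
        n_chunks = as.integer(ceiling(len / chunk))
      )
    }

    none_ids <- classes$patient_id[classes$true_class == "none"]
    short_ids <- none_ids[runif(length(none_ids)) < config$p_short_course]
    n_short <- length(short_ids)
    shorts <- NULL
    if (n_short > 0) {
      len <- sample(3:28, n_short, replace = TRUE)
      drug_i <- sample(1:3, n_short, replace = TRUE)
      shorts <- tibble::tibble(
        patient_id = short_ids,
        start_day = floor(runif(n_short) * (ylen - len + 1)) + 1L,
        days_supplied = as.integer(len),
        daily_ome = runif(n_short, 5, 60),
        atc = GEN_DRUGS$atc[drug_i],
        strength = GEN_DRUGS$strength[drug_i],
        ome_factor = GEN_DRUGS$factor[drug_i]
      )
    }

    rx <- list()
    if (!is.null(episodes)) {
      chained <- tidyr::uncount(episodes, weights = .data$n_chunks,
                                .id = "chunk_i")
      chained <- dplyr::mutate(
        chained,
        start_day = .data$ep_start + (.data$chunk_i - 1L) * chunk,
        days_supplied = pmin(chunk, .data$ep_len - (.data$chunk_i - 1L) * chunk)
      )
      rx$episodes <- dplyr::transmute(
        chained,
        patient_id = .data$patient_id, atc = .data$atc,
        start_day = as.integer(.data$start_day),
        days_supplied = as.integer(.data$days_supplied),
        strength_mg_per_unit = .data$strength,
        units_per_day = .data$daily_ome / (.data$strength * .data$ome_factor)
      )
    }
    if (!is.null(shorts)) {
      rx$shorts <- dplyr::transmute(
        shorts,
        patient_id = .data$patient_id, atc = .data$atc,
        start_day = as.integer(.data$start_day),
        days_supplied = .data$days_supplied,
        strength_mg_per_unit = .data$strength,
        units_per_day = .data$daily_ome / (.data$strength * .data$ome_factor)
      )
    }
    genuine <- dplyr::bind_rows(rx)
    if (nrow(genuine) == 0) {
      genuine <- tibble::tibble(
        patient_id = character(), atc = character(), start_day = integer(),
        days_supplied = integer(), strength_mg_per_unit = numeric(),
        units_per_day = numeric()
      )
    }
    n_noise <- round(config$noise_fraction * nrow(genuine))
    if (n_noise > 0) {
      noise_type <- sample(c("codeine", "non_opioid", "missing_strength"),
                           n_noise, replace = TRUE)
      len <- sample(5:14, n_noise, replace = TRUE)
      noise <- tibble::tibble(
        patient_id = sample(classes$patient_id, n_noise, replace = TRUE),
        atc = dplyr::case_when(
          noise_type == "codeine" ~ "R05DA04",
          noise_type == "non_opioid" ~ "M01AE01",
          TRUE ~ "N02AA05"
        ),
        start_day = floor(runif(n_noise) * (ylen - len + 1)) + 1L,
        days_supplied = as.integer(len),
        strength_mg_per_unit = dplyr::case_when(
          noise_type == "codeine" ~ 30,
          noise_type == "non_opioid" ~ 400,
          TRUE ~ NA_real_
        ),
        units_per_day = 3
      )
      genuine <- dplyr::bind_rows(genuine, noise)
    }
    prescriptions <- genuine |>
      dplyr::arrange(.data$patient_id, .data$start_day, .data$atc) |>
      dplyr::mutate(
        rx_id = sprintf("rx%07d", dplyr::row_number()),
        start_date = jan1 + .data$start_day - 1L,
        route = "oral"
      ) |>
      dplyr::select("rx_id", "patient_id", "atc", "start_date",
                    "days_supplied", "strength_mg_per_unit", "units_per_day",
                    "route")
    list(prescriptions = prescriptions, ground_truth = classes)
  })
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper chaining [simulate_practices()],
#' [simulate_patients()] and [simulate_prescriptions()].
#'
#' @inheritParams simulate_practices
#' @return A list of class `rxvar_cohort` with elements `practices`,
#'   `patients`, `prescriptions`, `ground_truth` and `config`.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_config(n_practices = 5, seed = 42))
#' names(coh)
simulate_cohort <- function(config = cohort_config()) {
  config <- validate_cohort_config(config)
  practices <- simulate_practices(config)
  patients <- simulate_patients(practices, config)
  rx <- simulate_prescriptions(patients, practices, config)
  structure(
    list(practices = practices, patients = patients,
         prescriptions = rx$prescriptions, ground_truth = rx$ground_truth,
         config = config),
    class = "rxvar_cohort"
  )
}

#' Write a synthetic cohort to CSV files
#'
#' Writes `practices.csv`, `patients.csv`, `prescriptions.csv` and
#' `ground_truth.csv` into `dir` (created if needed). Dates are ISO-8601.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(
    dplyr::select(cohort$practices, "practice_id", "list_size",
                  "pct_low_income", "pct_high_income", "urbanicity_addr_km2"),
    file.path(dir, "practices.csv")
  )
  readr::write_csv(cohort$patients, file.path(dir, "patients.csv"))
  readr::write_csv(cohort$prescriptions, file.path(dir, "prescriptions.csv"))
  readr::write_csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}
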