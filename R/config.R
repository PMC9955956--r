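#' Synthetic cohort configuration
#'
#' Parameters of the synthetic primary-care cohort generator. The defaults
#' emulate a 2019-like Dutch general-practice population: 361 practices with
#' a truncated log-normal list-size distribution averaging about 2 838 adult
#' patients, the 2019 age/sex/chronic-disease case mix, and outcome rates of
#' about 1.43% chronic (<90 mg OME/day) and 0.16% chronic high-dose
#' (>=90 mg OME/day) opioid prescribing. Between-practice variation comes
#' from a practice-level random intercept on the logit scale
#' (`tau_practice`), to which practice socioeconomic status and urbanicity
#' covariates are coupled.
#'
#' @param n_practices Number of practices (>= 2).
#' @param practice_size_log_mean,practice_size_log_sd Log-normal parameters
#'   of practice list size.
#' @param size_range Truncation bounds for list size (patients).
#' @param age_band_weights Named probability vector over 5-year age bands
#'   `20-24` ... `90+` (must sum to 1).
#' @param p_male Probability of male sex.
#' @param chronic_disease_weights Named probability vector over chronic
#'   disease counts `0,1,2,3,4+` (must sum to 1).
#' @param p_cancer Probability of an active cancer diagnosis in the year.
#' @param p_full_year Probability of full-year registration.
#' @param base_logit_chronic Intercept (log-odds) of any chronic opioid use
#'   for the reference patient (age 20-24, female, 0 chronic diseases) in a
#'   practice with zero random effect.
#' @param base_logit_highdose_given_chronic Log-odds that a chronic user is
#'   high-dose (>=90 mg OME/day); independent of the practice effect.
#' @param covariate_effects List with elements `age_band` (named log-odds
#'   increments per band), `sex_male` (scalar) and `n_chronic_diseases`
#'   (named increments per level); reference levels carry 0.
#' @param tau_practice SD of the practice random intercept (logit scale,
#'   >= 0).
#' @param ses_effect Change in percentage of low-income residents per unit
#'   of practice random effect (couples SES to prescribing).
#' @param urban_effect Change in log urbanicity (addresses/km2) per unit of
#'   practice random effect.
#' @param year Calendar year the prescriptions fall in.
#' @param highdose_margin Relative margin keeping generated daily doses away
#'   from the 90 mg OME/day boundary (doses are drawn below
#'   `90*(1-margin)` or above `90*(1+margin)`), so boundary behaviour is
#'   tested explicitly rather than accidentally.
#' @param rx_chunk_days Days supplied per chained prescription within an
#'   episode.
#' @param p_short_course Probability that a patient without chronic use
#'   receives a short (<90 day) opioid course.
#' @param noise_fraction Fraction of additional noise prescriptions (codeine,
#'   non-opioid ATC, missing strength) injected relative to the number of
#'   genuine opioid prescriptions.
#' @param seed Integer seed; expanded internally into independent substreams
#'   for practices, patients, classes and prescriptions.
#'
#' @return A validated list of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_practices = 20, seed = 1)
#' cfg$tau_practice
cohort_config <- function(n_practices = 361,
                          practice_size_log_mean = 7.803,
                          practice_size_log_sd = 0.55,
                          size_range = c(500, 13000),
                          age_band_weights = default_age_band_weights(),
                          p_male = 0.493,
                          chronic_disease_weights = c(
                            "0" = 0.408, "1" = 0.242, "2" = 0.141,
                            "3" = 0.084, "4+" = 0.125
                          ),
                          p_cancer = 0.03,
                          p_full_year = 0.95,
                          base_logit_chronic = -5.816,
                          base_logit_highdose_given_chronic = -2.190,
                          covariate_effects = default_covariate_effects(),
                          tau_practice = 0.6,
                          ses_effect = 8,
                          urban_effect = 0.5,
                          year = 2019,
                          highdose_margin = 0.10,
                          rx_chunk_days = 30,
                          p_short_course = 0.06,
                          noise_fraction = 0.02,
                          seed = 20190101) {
  cfg <- list(
    n_practices = n_practices,
    practice_size_log_mean = practice_size_log_mean,
    practice_size_log_sd = practice_size_log_sd,
    size_range = size_range,
    age_band_weights = age_band_weights,
    p_male = p_male,
    chronic_disease_weights = chronic_disease_weights,
    p_cancer = p_cancer,
    p_full_year = p_full_year,
    base_logit_chronic = base_logit_chronic,
    base_logit_highdose_given_chronic = base_logit_highdose_given_chronic,
    covariate_effects = covariate_effects,
    tau_practice = tau_practice,
    ses_effect = ses_effect,
    urban_effect = urban_effect,
    year = year,
    highdose_margin = highdose_margin,
    rx_chunk_days = rx_chunk_days,
    p_short_course = p_short_course,
    noise_fraction = noise_fraction,
    seed = seed
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

#' @rdname cohort_config
#' @export
default_age_band_weights <- function() {
  # 2019-like margins: 20-39 30.6%, 40-59 36.8%, 60-79 27.2%, 80+ 5.4%,
  # spread over 5-year bands with a tapering tail above 80.
  w <- c(
    rep(0.306 / 4, 4), rep(0.368 / 4, 4), rep(0.272 / 4, 4),
    0.030, 0.016, 0.008
  )
  setNames(w, AGE_BANDS_ADULT)
}

#' @rdname cohort_config
#' @export
default_covariate_effects <- function() {
  list(
    age_band = setNames(
      c(0, 0.15, 0.30, 0.45, 0.60, 0.75, 0.90, 1.00,
        1.10, 1.20, 1.30, 1.40, 1.50, 1.55, 1.60),
      AGE_BANDS_ADULT
    ),
    sex_male = -0.10,
    n_chronic_diseases = setNames(c(0, 0.5, 0.9, 1.2, 1.5), DISEASE_LEVELS)
  )
}

config_error <- function(field, msg) {
  abort(paste0("configuration error in field `", field, "`: ", msg),
        class = "rxvar_config_error")
}

check_prob_vector <- function(x, field, levels) {
  if (!is.numeric(x) || length(x) != length(levels) ||
      !setequal(names(x), levels)) {
    config_error(field, paste0("must be a named probability vector over ",
                               paste(levels, collapse = ", ")))
  }
  if (any(x < 0)) config_error(field, "probabilities must be non-negative")
  if (abs(sum(x) - 1) > 1e-9) config_error(field, "must sum to 1 (tol 1e-9)")
  invisible(x)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    config_error(field, "must be a probability in [0, 1]")
  }
  invisible(x)
}

validate_cohort_config <- function(cfg) {
  if (!is.numeric(cfg$n_practices) || cfg$n_practices < 2) {
    config_error("n_practices", "must be at least 2")
  }
  if (!is.numeric(cfg$practice_size_log_sd) || cfg$practice_size_log_sd < 0) {
    config_error("practice_size_log_sd", "must be non-negative")
  }
  if (length(cfg$size_range) != 2 || cfg$size_range[1] < 1 ||
      diff(cfg$size_range) < 0) {
    config_error("size_range", "must be increasing bounds with minimum >= 1")
  }
  check_prob_vector(cfg$age_band_weights, "age_band_weights", AGE_BANDS_ADULT)
  check_prob_vector(cfg$chronic_disease_weights, "chronic_disease_weights",
                    DISEASE_LEVELS)
  check_prob(cfg$p_male, "p_male")
  check_prob(cfg$p_cancer, "p_cancer")
  check_prob(cfg$p_full_year, "p_full_year")
  check_prob(cfg$p_short_course, "p_short_course")
  if (!is.numeric(cfg$tau_practice) || cfg$tau_practice < 0) {
    config_error("tau_practice", "must be non-negative")
  }
  eff <- cfg$covariate_effects
  if (!is.list(eff) ||
      !all(c("age_band", "sex_male", "n_chronic_diseases") %in% names(eff))) {
    config_error("covariate_effects",
                 "must list `age_band`, `sex_male`, `n_chronic_diseases`")
  }
  if (!setequal(names(eff$age_band), AGE_BANDS_ADULT)) {
    config_error("covariate_effects$age_band",
                 "must name every adult 5-year band")
  }
  if (!setequal(names(eff$n_chronic_diseases), DISEASE_LEVELS)) {
    config_error("covariate_effects$n_chronic_diseases",
                 "must name levels 0, 1, 2, 3, 4+")
  }
  if (cfg$highdose_margin < 0 || cfg$highdose_margin >= 1) {
    config_error("highdose_margin", "must be in [0, 1)")
  }
  if (cfg$noise_fraction < 0) {
    config_error("noise_fraction", "must be non-negative")
  }
  if (cfg$rx_chunk_days < 1) {
    config_error("rx_chunk_days", "must be at least 1 day")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed)) {
    config_error("seed", "must be a single integer")
  }
  cfg
}
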