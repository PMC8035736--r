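# Generator configuration -----------------------------------------------

# Default per-condition simulation parameters. Onset probabilities are set so
# that, under the reference assessment method, the simulated prevalence
# ranking mirrors what large claims-based cancer cohorts report: peptic ulcer
# and chronic pulmonary disease most common, haemodynamic and neurological
# conditions rare. Claim rates are claims/person-year after onset.
default_condition_params <- function() {
  data.frame(
    condition = charlson_conditions(),
    onset_prob = c(
      0.015, 0.030, 0.030, 0.060, 0.160, 0.025, 0.190,
      0.095, 0.080, 0.040, 0.015, 0.020, 0.020
    ),
    outpatient_rate = rep(4, 13),
    inpatient_rate = rep(0.3, 13),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic claims generator
#'
#' Builds and validates the parameter set that drives [generate_cohort()].
#' Defaults describe a cohort resembling a national-sample cancer cohort:
#' index diagnoses in one calendar year, claims history from
#' `enrollment_start_year`, administrative censoring at `study_end_date`,
#' age at index normally distributed with mean 57.4 and SD 15.4 years, and
#' deaths generated from competing exponential cause-specific hazards in
#' which the non-cancer hazard depends on the patient's true CCI category
#' and sex.
#'
#' @param n_patients Number of patients to simulate.
#' @param male_fraction Proportion of male patients.
#' @param age_mean,age_sd Mean and SD (years) of age at index diagnosis;
#'   draws are truncated to 18--100 years.
#' @param index_year Calendar year of the index cancer diagnosis.
#' @param enrollment_start_year First calendar year of enrollment (claims
#'   history begins 1 January of this year for every patient).
#' @param study_end_date Administrative censoring date (`Date` or ISO string).
#' @param conditions Data frame with columns `condition`, `onset_prob`,
#'   `outpatient_rate`, `inpatient_rate`, one row per Charlson condition.
#' @param onset_buffer_days Minimum number of days by which a true
#'   condition's onset precedes the index date (onset is uniform between
#'   enrollment start and `index_date - onset_buffer_days`). The default 0
#'   allows onsets arbitrarily close to the index; validation scenarios use
#'   a positive buffer so that rule-out windows are satisfiable for every
#'   true condition.
#' @param upcoding_rate Spurious single-claim diagnosis codes per
#'   patient-year (each an isolated claim with a random Charlson code).
#' @param upcoding_index_boost Multiplier on the up-coding intensity during
#'   the 90 days before the index date, emulating the burst of
#'   administrative coding around a cancer workup.
#' @param true_log_hr Named numeric, log hazard ratios of non-cancer death
#'   for true CCI categories `mild`, `moderate`, `severe` versus category 0.
#' @param sex_log_hr Log hazard ratio of non-cancer death for male vs female.
#' @param baseline_hazard Non-cancer death hazard (events/person-year) for a
#'   female patient with CCI 0.
#' @param cancer_death_hazard Cancer death hazard (events/person-year),
#'   independent of comorbidity; cancer deaths are split between the index
#'   cancer and other cancers.
#' @param inpatient_frailty_mode If `TRUE`, condition-related inpatient
#'   claims are emitted only for a frail subpopulation that also carries an
#'   extra non-cancer mortality hazard, so that hospitalization marks
#'   disease severity.
#' @param frailty_prob Probability that a patient is frail (used only when
#'   `inpatient_frailty_mode` is `TRUE`).
#' @param frailty_log_hr Extra non-cancer log hazard for frail patients.
#' @param rng_seed Integer seed; the generated database is a deterministic
#'   function of the configuration including this seed.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_patients = 2979,
                             male_fraction = 0.508,
                             age_mean = 57.4,
                             age_sd = 15.4,
                             index_year = 2006,
                             enrollment_start_year = 2002,
                             study_end_date = "2015-12-31",
                             conditions = default_condition_params(),
                             onset_buffer_days = 0,
                             upcoding_rate = 0.6,
                             upcoding_index_boost = 6,
                             true_log_hr = c(mild = 0.3, moderate = 0.7, severe = 1.6),
                             sex_log_hr = 0.4,
                             baseline_hazard = 0.009,
                             cancer_death_hazard = 0.032,
                             inpatient_frailty_mode = FALSE,
                             frailty_prob = 0.3,
                             frailty_log_hr = 0.8,
                             rng_seed = 1L) {
  cfg <- list(
    n_patients = n_patients, male_fraction = male_fraction,
    age_mean = age_mean, age_sd = age_sd, index_year = as.integer(index_year),
    enrollment_start_year = as.integer(enrollment_start_year),
    study_end_date = as.Date(study_end_date),
    conditions = as.data.frame(conditions),
    onset_buffer_days = onset_buffer_days,
    upcoding_rate = upcoding_rate, upcoding_index_boost = upcoding_index_boost,
    true_log_hr = true_log_hr, sex_log_hr = sex_log_hr,
    baseline_hazard = baseline_hazard,
    cancer_death_hazard = cancer_death_hazard,
    inpatient_frailty_mode = isTRUE(inpatient_frailty_mode),
    frailty_prob = frailty_prob, frailty_log_hr = frailty_log_hr,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid generator config: field `%s` %s", field, why),
         call. = FALSE)
  }
  chk_prop <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
      fail(field, "must be a proportion in [0, 1]")
    }
  }
  chk_rate <- function(x, field) {
    if (!is.numeric(x) || any(is.na(x)) || any(x < 0)) {
      fail(field, "must be a non-negative rate")
    }
  }
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1 ||
      is.na(cfg$n_patients) || cfg$n_patients < 1) {
    fail("n_patients", "must be >= 1")
  }
  chk_prop(cfg$male_fraction, "male_fraction")
  if (!is.numeric(cfg$age_sd) || cfg$age_sd <= 0) fail("age_sd", "must be > 0")
  if (!is.numeric(cfg$age_mean) || cfg$age_mean <= 0) {
    fail("age_mean", "must be > 0")
  }
  if (is.na(cfg$study_end_date)) fail("study_end_date", "must be a date")
  if (cfg$study_end_date <= as.Date(sprintf("%d-12-31", cfg$index_year))) {
    fail("study_end_date", "must fall after the index year")
  }
  if (cfg$enrollment_start_year >= cfg$index_year) {
    fail("enrollment_start_year", "must precede index_year")
  }
  cond <- cfg$conditions
  need <- c("condition", "onset_prob", "outpatient_rate", "inpatient_rate")
  if (!all(need %in% names(cond))) {
    fail("conditions", paste("must have columns", paste(need, collapse = ", ")))
  }
  if (!setequal(cond$condition, charlson_conditions()) ||
      anyDuplicated(cond$condition) > 0) {
    fail("conditions", "must list each of the 13 Charlson conditions once")
  }
  if (any(cond$onset_prob < 0 | cond$onset_prob > 1)) {
    fail("conditions$onset_prob", "must be proportions in [0, 1]")
  }
  chk_rate(cond$outpatient_rate, "conditions$outpatient_rate")
  chk_rate(cond$inpatient_rate, "conditions$inpatient_rate")
  chk_rate(cfg$onset_buffer_days, "onset_buffer_days")
  chk_rate(cfg$upcoding_rate, "upcoding_rate")
  chk_rate(cfg$upcoding_index_boost, "upcoding_index_boost")
  if (!is.numeric(cfg$true_log_hr) ||
      !setequal(names(cfg$true_log_hr), c("mild", "moderate", "severe"))) {
    fail("true_log_hr", "must be named numeric over mild, moderate, severe")
  }
  if (!is.numeric(cfg$sex_log_hr) || length(cfg$sex_log_hr) != 1) {
    fail("sex_log_hr", "must be a single number")
  }
  chk_rate(cfg$baseline_hazard, "baseline_hazard")
  chk_rate(cfg$cancer_death_hazard, "cancer_death_hazard")
  chk_prop(cfg$frailty_prob, "frailty_prob")
  if (!is.numeric(cfg$frailty_log_hr) || length(cfg$frailty_log_hr) != 1) {
    fail("frailty_log_hr", "must be a single number")
  }
  if (is.na(cfg$rng_seed)) fail("rng_seed", "must be an integer")
  invisible(cfg)
}

#' Read a generator configuration from YAML
#'
#' The YAML file may set any subset of the [generator_config()] arguments;
#' unknown keys are rejected. Per-condition parameters are given under a
#' `conditions` mapping of condition id to `onset_prob`, `outpatient_rate`,
#' `inpatient_rate` (unspecified conditions keep their defaults).
#'
#' @param path Path to a YAML file.
#' @return A validated `generator_config`.
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(generator_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$conditions)) {
    cond <- default_condition_params()
    for (id in names(raw$conditions)) {
      if (!id %in% cond$condition) {
        stop("unknown condition in config: ", id)
      }
      for (fld in names(raw$conditions[[id]])) {
        if (!fld %in% c("onset_prob", "outpatient_rate", "inpatient_rate")) {
          stop("unknown condition field in config: ", fld)
        }
        cond[cond$condition == id, fld] <- raw$conditions[[id]][[fld]]
      }
    }
    raw$conditions <- cond
  }
  if (!is.null(raw$true_log_hr)) {
    raw$true_log_hr <- unlist(raw$true_log_hr)
  }
  do.call(generator_config, raw)
}
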