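# Synthetic claims generator --------------------------------------------

DAYS_PER_YEAR <- 365.25

# Observed split of cancer deaths between the index cancer and other primary
# cancers in population cancer cohorts (~5:1).
INDEX_CANCER_DEATH_SHARE <- 686 / (686 + 135)

# Random full ICD-10 codes for a set of normalized prefixes: prefix plus one
# random trailing digit, so every emitted code prefix-matches its source.
random_codes_from_prefixes <- function(prefixes, n) {
  if (n == 0L) return(character(0))
  paste0(sample(prefixes, n, replace = TRUE),
         sample(0:9, n, replace = TRUE))
}

#' Generate a synthetic claims database with known truth
#'
#' Simulates an administrative-claims cancer cohort: each patient receives
#' one index malignancy claim (random C00--C97 code) on a uniformly drawn
#' date in `index_year`; true comorbid conditions are assigned per condition
#' with the configured onset probabilities; a condition present from a
#' uniformly sampled onset date emits outpatient and inpatient claims as
#' independent homogeneous Poisson processes carrying that condition's
#' ICD-10 codes; spurious "up-coded" diagnoses appear as isolated single
#' claims with intensity `upcoding_rate`, boosted by
#' `upcoding_index_boost` in the 90 days before the index date; deaths are
#' drawn from competing exponential cause-specific hazards in which the
#' non-cancer hazard is `baseline_hazard` scaled by the true CCI-category
#' and sex log hazard ratios; survivors are censored administratively at
#' `study_end_date`.
#'
#' The output is a deterministic function of the configuration (including
#' `rng_seed`) and includes a truth table with each patient's true
#' condition set, true CCI score/category and index date.
#'
#' @param config A [generator_config()].
#' @return A `claims_db` with a `truth` table.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "generator_config")) {
    config <- do.call(generator_config, as.list(config))
  }
  validate_generator_config(config)
  set.seed(config$rng_seed)
  n <- as.integer(config$n_patients)
  conds <- charlson_conditions()
  pid <- sprintf("P%06d", seq_len(n))
  sex <- ifelse(runif(n) < config$male_fraction, "male", "female")

  jan1 <- as.Date(sprintf("%d-01-01", config$index_year))
  dec31 <- as.Date(sprintf("%d-12-31", config$index_year))
  index_date <- jan1 + sample.int(as.integer(dec31 - jan1) + 1L, n,
                                  replace = TRUE) - 1L

  age <- rnorm(n, config$age_mean, config$age_sd)
  while (any(bad <- age < 18 | age > 100)) {
    age[bad] <- rnorm(sum(bad), config$age_mean, config$age_sd)
  }
  birth_date <- index_date - round(age * DAYS_PER_YEAR)
  enroll_start <- rep(as.Date(sprintf("%d-01-01", config$enrollment_start_year)), n)

  # True comorbidity flags and the CCI category that drives mortality.
  cp <- config$conditions[match(conds, config$conditions$condition), ]
  flags <- matrix(runif(n * 13) < rep(cp$onset_prob, each = n),
                  nrow = n, dimnames = list(NULL, conds))
  truth_cci <- cci_from_flag_matrix(flags)
  frail <- if (config$inpatient_frailty_mode) {
    runif(n) < config$frailty_prob
  } else {
    rep(FALSE, n)
  }

  # Competing exponential cause-specific hazards on time since index.
  cat_lp <- c(zero = 0, config$true_log_hr)[as.character(truth_cci$category)]
  lp <- unname(cat_lp) + config$sex_log_hr * (sex == "male") +
    config$frailty_log_hr * frail
  h_nc <- config$baseline_hazard * exp(lp)
  t_nc <- if (all(h_nc > 0)) rexp(n, h_nc) else
    ifelse(h_nc > 0, rexp(n, pmax(h_nc, 1e-300)), Inf)
  t_ca <- if (config$cancer_death_hazard > 0) {
    rexp(n, config$cancer_death_hazard)
  } else {
    rep(Inf, n)
  }
  t_admin <- as.numeric(config$study_end_date - index_date) / DAYS_PER_YEAR
  t_min <- pmin(t_nc, t_ca)
  dead <- t_min < t_admin
  death_day <- pmin(pmax(1, round(t_min * DAYS_PER_YEAR)),
                    as.numeric(config$study_end_date - index_date))
  death_date <- as.Date(ifelse(dead, index_date + death_day, NA),
                        origin = "1970-01-01")
  is_cancer_death <- dead & (t_ca <= t_nc)
  cause_split <- runif(n) < INDEX_CANCER_DEATH_SHARE
  death_cause <- rep(NA_character_, n)
  death_cause[dead & !is_cancer_death] <- "non_cancer"
  death_cause[is_cancer_death & cause_split] <- "index_cancer"
  death_cause[is_cancer_death & !cause_split] <- "other_cancer"
  enrollment_end <- as.Date(ifelse(dead, death_date, config$study_end_date),
                            origin = "1970-01-01")

  patients <- data.frame(
    patient_id = pid, sex = sex, birth_date = birth_date,
    enrollment_start = enroll_start, enrollment_end = enrollment_end,
    death_date = death_date, death_cause = death_cause,
    stringsAsFactors = FALSE
  )

  claim_parts <- list(
    # Index malignancy claim (inpatient, on the index date).
    data.table::data.table(
      patient_id = pid, claim_type = "inpatient", service_date = index_date,
      icd10_codes = random_codes_from_prefixes(cancer_prefixes(), n)
    )
  )

  # Recurrent condition claims: homogeneous Poisson streams from a uniform
  # onset in (enrollment_start, index_date) until end of enrollment.
  tab <- quan_code_table()
  pos <- which(flags, arr.ind = TRUE)
  if (nrow(pos) > 0) {
    i <- pos[, 1]
    j <- pos[, 2]
    onset_span <- pmax(as.numeric(index_date[i] - enroll_start[i]) -
                         config$onset_buffer_days, 1)
    onset <- enroll_start[i] + floor(runif(length(i)) * onset_span)
    stream_days <- as.numeric(enrollment_end[i] - onset)
    stream_years <- pmax(stream_days, 0) / DAYS_PER_YEAR
    in_rate <- cp$inpatient_rate[j]
    if (config$inpatient_frailty_mode) in_rate <- in_rate * frail[i]
    for (stream in c("outpatient", "inpatient")) {
      rate <- if (stream == "outpatient") cp$outpatient_rate[j] else in_rate
      n_claims <- rpois(length(i), rate * stream_years)
      keep <- which(n_claims > 0)
      if (length(keep) == 0) next
      rows <- rep(keep, n_claims[keep])
      dates <- onset[rows] + floor(runif(length(rows)) * (stream_days[rows] + 1))
      codes <- character(length(rows))
      for (cid in unique(conds[j[rows]])) {
        sel <- conds[j[rows]] == cid
        codes[sel] <- random_codes_from_prefixes(
          tab$prefix[tab$condition == cid], sum(sel))
      }
      claim_parts[[length(claim_parts) + 1L]] <- data.table::data.table(
        patient_id = pid[i[rows]], claim_type = stream,
        service_date = dates, icd10_codes = codes
      )
    }
  }

  # Up-coding: isolated single claims with random Charlson codes; intensity
  # boosted in the 90 days before the index date.
  if (config$upcoding_rate > 0) {
    win_start <- pmax(enroll_start, index_date - 90L)
    win_days <- as.numeric(index_date - win_start)
    total_days <- as.numeric(enrollment_end - enroll_start) + 1
    base_days <- total_days - win_days
    pre_days <- as.numeric(win_start - enroll_start)
    n_base <- rpois(n, config$upcoding_rate * base_days / DAYS_PER_YEAR)
    n_boost <- rpois(n, config$upcoding_rate * config$upcoding_index_boost *
                       win_days / DAYS_PER_YEAR)
    rows <- rep(seq_len(n), n_base)
    if (length(rows) > 0) {
      off <- floor(runif(length(rows)) * base_days[rows])
      shift <- off >= pre_days[rows]
      dates <- enroll_start[rows] + off + shift * win_days[rows]
      claim_parts[[length(claim_parts) + 1L]] <- data.table::data.table(
        patient_id = pid[rows],
        claim_type = ifelse(runif(length(rows)) < 0.8,
                            "outpatient", "inpatient"),
        service_date = dates,
        icd10_codes = random_codes_from_prefixes(tab$prefix, length(rows))
      )
    }
    rows <- rep(seq_len(n), n_boost)
    if (length(rows) > 0) {
      dates <- win_start[rows] + floor(runif(length(rows)) * win_days[rows])
      claim_parts[[length(claim_parts) + 1L]] <- data.table::data.table(
        patient_id = pid[rows],
        claim_type = ifelse(runif(length(rows)) < 0.8,
                            "outpatient", "inpatient"),
        service_date = dates,
        icd10_codes = random_codes_from_prefixes(tab$prefix, length(rows))
      )
    }
  }

  claims <- data.table::rbindlist(claim_parts)
  data.table::setorder(claims, patient_id, service_date, claim_type, icd10_codes)

  true_conditions <- vapply(seq_len(n), function(k) {
    paste(conds[flags[k, ]], collapse = ";")
  }, character(1))
  truth <- data.frame(
    patient_id = pid, index_date = index_date,
    true_conditions = true_conditions,
    true_cci_score = truth_cci$score,
    true_cci_category = as.character(truth_cci$category),
    stringsAsFactors = FALSE
  )

  claims_db(patients, as.data.frame(claims), truth)
}
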