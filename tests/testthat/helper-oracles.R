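# Independent brute-force oracles used to validate the implementation.

# Rule-out confirmation by scanning all claim-date pairs.
confirm_oracle <- function(dates, washout) {
  if (washout == 0) return(length(dates) >= 1)
  if (length(dates) < 2) return(FALSE)
  for (a in seq_along(dates)) {
    for (b in seq_along(dates)) {
      if (abs(as.numeric(dates[a] - dates[b])) > washout) return(TRUE)
    }
  }
  FALSE
}

# Charlson score by independent summation: hierarchy and weight map are
# restated here rather than taken from the package.
oracle_weights <- c(
  myocardial_infarction = 1, congestive_heart_failure = 1,
  peripheral_vascular = 1, cerebrovascular = 1, chronic_pulmonary = 1,
  rheumatic = 1, peptic_ulcer = 1, liver_mild = 1,
  diabetes_uncomplicated = 1, diabetes_complicated = 2,
  hemiplegia_paraplegia = 2, renal = 2, liver_moderate_severe = 3
)

cci_oracle <- function(flags) {
  f <- flags[names(oracle_weights)]
  if (f[["liver_moderate_severe"]]) f[["liver_mild"]] <- FALSE
  if (f[["diabetes_complicated"]]) f[["diabetes_uncomplicated"]] <- FALSE
  sum(oracle_weights[f])
}

# Efron log partial likelihood with delayed entry, evaluated directly from
# the risk-set definition: at event age t the risk set is
# {i : entry_i < t <= exit_i}.
efron_logpl <- function(beta, entry, exit, event, X) {
  eta <- as.vector(X %*% beta)
  w <- exp(eta)
  ll <- 0
  for (t in sort(unique(exit[event == 1]))) {
    D <- which(event == 1 & exit == t)
    R <- which(entry < t & exit >= t)
    d <- length(D)
    sum_d <- sum(w[D])
    sum_r <- sum(w[R])
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum_r - (l / d) * sum_d)
    }
  }
  ll
}

# Compact builders for hand-made fixtures ---------------------------------

d <- function(x) as.Date(x)

make_patient <- function(patient_id, sex = "female",
                         birth_date = "1950-01-01",
                         enrollment_start = "2002-01-01",
                         enrollment_end = "2015-12-31",
                         death_date = NA, death_cause = NA) {
  data.frame(patient_id = patient_id, sex = sex,
             birth_date = d(birth_date),
             enrollment_start = d(enrollment_start),
             enrollment_end = d(enrollment_end),
             death_date = d(death_date),
             death_cause = as.character(death_cause),
             stringsAsFactors = FALSE)
}

make_claim <- function(patient_id, service_date, codes,
                       claim_type = "outpatient") {
  data.frame(patient_id = patient_id, claim_type = claim_type,
             service_date = d(service_date),
             icd10_codes = paste(codes, collapse = ";"),
             stringsAsFactors = FALSE)
}

empty_flags <- function() {
  stats::setNames(rep(FALSE, 13), charlson_conditions())
}

# Small noise-free configuration with dense, early-onset claim streams, for
# truth-recovery checks.
dense_config <- function(n = 400, seed = 11, ...) {
  cond <- default_condition_params <- comorbiscope:::default_condition_params()
  cond$onset_prob <- rep(0.12, 13)
  cond$outpatient_rate <- rep(15, 13)
  cond$inpatient_rate <- rep(0, 13)
  generator_config(n_patients = n, conditions = cond,
                   onset_buffer_days = 365, upcoding_rate = 0,
                   baseline_hazard = 0.02, cancer_death_hazard = 0.02,
                   rng_seed = seed, ...)
}
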