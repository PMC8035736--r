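# Index-case selection, survival records, left-truncated Cox fits

test_that("index cases require first cancer in target year and 3-year enrollment", {
  patients <- rbind(
    make_patient("P1", birth_date = "1946-03-01"),
    make_patient("P2"),
    make_patient("P3", enrollment_start = "2004-06-01")
  )
  claims <- rbind(
    make_claim("P1", "2006-03-01", "C16", "inpatient"),
    make_claim("P2", "2004-05-01", "C18", "inpatient"),  # prior history
    make_claim("P2", "2006-02-01", "C18", "inpatient"),
    make_claim("P3", "2006-03-01", "C34", "inpatient")   # enrolled < 3 y
  )
  db <- claims_db(patients, claims)
  cases <- identify_index_cases(db, 2006)
  expect_equal(cases$patient_id, "P1")
  expect_equal(cases$index_date, d("2006-03-01"))
  expect_equal(cases$age_at_index, 60, tolerance = 0.01)
  att <- summarize_attrition(db, 2006)
  expect_equal(unname(att), c(3L, 2L, 1L, 1L))
  expect_true(all(diff(att) <= 0))
})

test_that("survival records encode delayed entry and cause-specific censoring", {
  mk <- function(id, death_date = NA, cause = NA) {
    make_patient(id, birth_date = "1946-01-01", death_date = death_date,
                 death_cause = cause,
                 enrollment_end = if (is.na(death_date)) "2015-12-31"
                 else death_date)
  }
  patients <- rbind(
    mk("P1", "2009-07-02", "non_cancer"),   # ~3.5 y after index
    mk("P2", "2007-03-15", "index_cancer"),
    mk("P3")
  )
  cases <- data.frame(patient_id = c("P1", "P2", "P3"),
                      index_date = d("2006-01-01"))
  cci <- data.frame(patient_id = c("P1", "P2", "P3"),
                    cci_category = c("mild", "zero", "zero"))
  db <- claims_db(patients, make_claim("P1", "2006-01-01", "C16")[0, ])
  recs <- build_survival_records(db, cases, cci, "2015-12-31")
  expect_equal(recs$entry_age, rep(60, 3), tolerance = 0.01)
  expect_equal(recs$event, c(1L, 0L, 0L))
  expect_equal(recs$exit_age[1], 63.5, tolerance = 0.01)
  expect_equal(recs$exit_age[2], 61.2, tolerance = 0.01)
  expect_equal(recs$exit_age[3], 70, tolerance = 0.01)
  expect_true(all(recs$exit_age > recs$entry_age))

  bad <- patients
  bad$death_date[1] <- d("2005-12-01")
  bad$enrollment_end[1] <- d("2005-12-01")
  bad_db <- claims_db(bad, make_claim("P1", "2005-06-01", "K251")[0, ])
  expect_error(build_survival_records(bad_db, cases, cci, "2015-12-31"),
               "death on or before")
})

test_that("the fitted log partial likelihood matches the brute-force evaluator", {
  set.seed(31)
  n <- 30
  recs <- data.frame(
    patient_id = sprintf("P%02d", 1:n),
    entry_age = runif(n, 50, 70),
    sex = sample(c("male", "female"), n, replace = TRUE),
    cci_category = sample(c("zero", "mild"), n, replace = TRUE)
  )
  recs$exit_age <- recs$entry_age + rexp(n, 0.25)
  recs$event <- rbinom(n, 1, 0.7)
  recs$event[1] <- 1L
  fit <- fit_left_truncated_cox(recs)
  X <- cbind(recs$cci_category == "mild", recs$sex == "male")
  beta <- fit$coefficients$coef
  expect_equal(fit$loglik,
               efron_logpl(beta, recs$entry_age, recs$exit_age, recs$event, X),
               tolerance = 1e-6)
  # hazard ratios and Wald intervals are consistent transformations
  expect_equal(fit$coefficients$hr, exp(beta))
  expect_true(all(fit$coefficients$ci_low <= fit$coefficients$hr))
  expect_true(all(fit$coefficients$ci_high >= fit$coefficients$hr))
})

test_that("two-group exponential data recover a true hazard ratio of 2", {
  set.seed(77)
  n <- 5000
  grp <- rep(c("zero", "mild"), each = n / 2)
  rate <- ifelse(grp == "mild", 0.10, 0.05)
  recs <- data.frame(
    patient_id = sprintf("P%04d", 1:n),
    entry_age = 50,
    sex = "female",
    cci_category = grp
  )
  tt <- rexp(n, rate)
  cens <- runif(n, 5, 15)
  recs$exit_age <- 50 + pmin(tt, cens)
  recs$event <- as.integer(tt <= cens)
  fit <- fit_left_truncated_cox(recs, adjust_sex = FALSE)
  est <- fit$coefficients[fit$coefficients$term == "cci_categorymild", ]
  expect_lt(abs(est$coef - log(2)), 3 * est$se)
})

test_that("coefficients are translation-invariant in age", {
  set.seed(5)
  n <- 400
  recs <- data.frame(
    patient_id = sprintf("P%03d", 1:n),
    entry_age = runif(n, 40, 70),
    sex = sample(c("male", "female"), n, replace = TRUE),
    cci_category = sample(c("zero", "mild", "moderate"), n, replace = TRUE)
  )
  recs$exit_age <- recs$entry_age + rexp(n, 0.1)
  recs$event <- rbinom(n, 1, 0.6)
  f1 <- fit_left_truncated_cox(recs)
  shifted <- recs
  shifted$entry_age <- shifted$entry_age + 7
  shifted$exit_age <- shifted$exit_age + 7
  f2 <- fit_left_truncated_cox(shifted)
  expect_equal(f1$coefficients$coef, f2$coefficients$coef, tolerance = 1e-8)
})

test_that("degenerate designs raise explicit diagnostics", {
  recs <- data.frame(
    patient_id = c("P1", "P2", "P3"),
    entry_age = c(50, 80, 81),
    exit_age = c(60, 85, 86),
    event = c(1L, 0L, 0L),
    sex = "female",
    cci_category = c("zero", "mild", "mild")
  )
  # the only event's risk set contains just itself: monotone likelihood
  expect_warning(fit_left_truncated_cox(recs, adjust_sex = FALSE),
                 "undefined|converge")
  none <- recs
  none$event <- 0L
  expect_error(fit_left_truncated_cox(none), "no events")
})

test_that("hr_table emits one model per method with mild/moderate/severe rows", {
  db <- generate_cohort(generator_config(n_patients = 500, rng_seed = 21,
                                         baseline_hazard = 0.02))
  methods <- enumerate_methods()[c(3, 12, 27), ]
  ht <- hr_table(db, methods, 2006, "2015-12-31")
  expect_equal(nrow(ht), 9)
  expect_equal(ht$category, rep(c("mild", "moderate", "severe"), 3))
  expect_true(all(is.na(ht$hr) | ht$hr > 0))
  expect_true(all(is.na(ht$hr) | (ht$ci_low <= ht$hr & ht$hr <= ht$ci_high)))
})
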