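# Assessment methods, windows, rule-out confirmation, ascertainment

test_that("all 27 assessment methods are enumerated once, in fixed order", {
  m <- enumerate_methods()
  expect_equal(nrow(m), 27)
  expect_equal(anyDuplicated(m$label), 0)
  expect_equal(length(unique(m$washout)), 3)
  expect_equal(length(unique(m$lookback)), 3)
  expect_equal(length(unique(m$claim_types)), 3)
  # the reference method: 30-day washout, 2-year lookback, either claim type
  expect_true("30:2y:either" %in% m$label)
  # nesting order: washout, then lookback, then claim type
  expect_equal(m$washout, rep(c(0, 30, 90), each = 9))
  expect_equal(m$lookback[1:9], rep(1:3, each = 3))
})

test_that("the lookback window is half-open and the claim-type filter applies", {
  idx <- d("2006-06-01")
  cl <- rbind(
    make_claim("P1", idx, "K251"),                       # on index date
    make_claim("P1", idx - 100, "K251", "outpatient"),
    make_claim("P1", idx - 400, "K251", "inpatient")
  )
  m1 <- assessment_method(0, 1, "either")
  kept <- eligible_claims(cl, idx, m1)
  expect_equal(as.numeric(idx - kept$service_date), 100)

  m_in <- assessment_method(0, 1, "inpatient_only")
  expect_equal(nrow(eligible_claims(cl, idx, m_in)), 0)

  # claim 400 days before index: excluded at 1-year, included at 2-year
  expect_false((idx - 400) %in% eligible_claims(cl, idx, m1)$service_date)
  m2 <- assessment_method(0, 2, "either")
  expect_true((idx - 400) %in% eligible_claims(cl, idx, m2)$service_date)
})

test_that("rule-out confirmation follows the washout window rule", {
  idx <- d("2006-06-01")
  expect_true(confirm_condition(c(idx - 100, idx - 50), 30))   # gap 50 > 30
  expect_false(confirm_condition(c(idx - 40, idx - 20), 30))   # gap 20 <= 30
  expect_true(confirm_condition(idx - 10, 0))
  expect_true(confirm_condition(idx - 10, "none"))
  expect_false(confirm_condition(idx - 10, 30))
  expect_true(confirm_condition(c(idx - 120, idx - 25), 90))
  expect_false(confirm_condition(c(idx - 80, idx - 10), 90))
  expect_false(confirm_condition(as.Date(character(0)), 0))
})

test_that("confirmation matches a brute-force all-pairs scan on random instances", {
  set.seed(2024)
  base <- d("2006-06-01")
  for (k in 1:1000) {
    n <- sample(0:12, 1)
    dates <- base - sample(1:1095, n, replace = TRUE)
    w <- sample(c(0, 30, 90), 1)
    expect_identical(confirm_condition(dates, w), confirm_oracle(dates, w))
  }
})

test_that("single up-coded claims are ruled out; dense streams always confirm", {
  p <- make_patient("P1")
  idx <- d("2006-06-01")
  db1 <- claims_db(p, make_claim("P1", idx - 50, "K25"))
  expect_false(ascertain(db1, "P1", idx,
                         assessment_method(30, 2, "either"))[["peptic_ulcer"]])
  expect_true(ascertain(db1, "P1", idx,
                        assessment_method(0, 2, "either"))[["peptic_ulcer"]])
  expect_error(ascertain(db1, "P9", idx, assessment_method(0, 2, "either")),
               "unknown patient")

  # monthly chronic pulmonary claims over 2 years: confirmed under every
  # method that can see outpatient claims
  monthly <- do.call(rbind, lapply(seq(30, 720, by = 30), function(k) {
    make_claim("P1", idx - k, "J449", "outpatient")
  }))
  db2 <- claims_db(p, monthly)
  m <- enumerate_methods()
  for (k in seq_len(nrow(m))) {
    f <- ascertain(db2, "P1", idx, m[k, ])
    expect_equal(f[["chronic_pulmonary"]],
                 m$claim_types[k] != "inpatient_only",
                 info = m$label[k])
  }
})

test_that("claims 2.5 years old are seen only by the 3-year lookback", {
  idx <- d("2006-06-01")
  cl <- rbind(
    make_claim("P1", idx - 913, "I219"),  # ~2.5 y before index
    make_claim("P1", idx - 950, "I22")
  )
  db <- claims_db(make_patient("P1"), cl)
  for (lb in 1:3) {
    f <- ascertain(db, "P1", idx, assessment_method(30, lb, "either"))
    expect_equal(f[["myocardial_infarction"]], lb == 3, info = lb)
  }
})

test_that("the vectorized ascertainment agrees with the per-patient path", {
  db <- generate_cohort(generator_config(n_patients = 40, rng_seed = 8))
  idx <- db$truth[, c("patient_id", "index_date")]
  for (lab in c("none:1y:inpatient_only", "30:2y:either",
                "90:3y:outpatient_only")) {
    m <- enumerate_methods()
    m <- m[m$label == lab, ]
    flags <- ascertain_all(db, idx, m)
    for (k in c(1, 7, 23)) {
      expect_identical(flags[k, ],
                       ascertain(db, idx$patient_id[k], idx$index_date[k], m),
                       info = lab)
    }
  }
})

test_that("flags are monotone in washout, lookback, and claim type", {
  for (seed in 1:3) {
    db <- generate_cohort(generator_config(n_patients = 300, rng_seed = seed))
    idx <- db$truth[, c("patient_id", "index_date")]
    cc <- comorbiscope:::condition_claim_table(db)
    f <- function(w, lb, ct) ascertain_all(db, idx, assessment_method(w, lb, ct), cc)
    expect_true(all(f(90, 2, "either") <= f(30, 2, "either")))
    expect_true(all(f(30, 2, "either") <= f(0, 2, "either")))
    expect_true(all(f(30, 1, "either") <= f(30, 2, "either")))
    expect_true(all(f(30, 2, "either") <= f(30, 3, "either")))
    expect_true(all((f(30, 2, "inpatient_only") | f(30, 2, "outpatient_only"))
                    <= f(30, 2, "either")))
  }
})

test_that("with no up-coding and dense early streams, flags recover the truth", {
  db <- generate_cohort(dense_config(n = 400, seed = 11))
  idx <- db$truth[, c("patient_id", "index_date")]
  flags <- ascertain_all(db, idx, assessment_method(30, 3, "either"))
  conds <- charlson_conditions()
  truth <- matrix(FALSE, nrow(idx), 13, dimnames = list(idx$patient_id, conds))
  lists <- strsplit(db$truth$true_conditions, ";", fixed = TRUE)
  truth[cbind(rep(seq_len(nrow(idx)), lengths(lists)),
              match(unlist(lists), conds))] <- TRUE
  expect_identical(flags, truth)
})

test_that("prevalence, multiplicity, and claim-type shares behave", {
  db <- generate_cohort(generator_config(n_patients = 250, rng_seed = 13))
  idx <- db$truth[, c("patient_id", "index_date")]
  prev <- prevalence_table(db, idx)
  expect_equal(nrow(prev), 27 * 13)
  expect_true(all(prev$prevalence >= 0 & prev$prevalence <= 100))
  # widest method dominates the narrowest for every condition
  wide <- prev[prev$washout == 0 & prev$lookback == 3 &
                 prev$claim_types == "either", ]
  narrow <- prev[prev$washout == 90 & prev$lookback == 1 &
                   prev$claim_types == "inpatient_only", ]
  expect_true(all(wide$prevalence >=
                    narrow$prevalence[match(wide$condition, narrow$condition)]))
  expect_error(prevalence_table(db, idx[0, ]), "empty cohort")

  flags <- ascertain_all(db, idx, assessment_method(30, 2, "either"))
  bins <- multiplicity_distribution(flags)
  expect_equal(sum(bins), nrow(idx))
  expect_true(all(bins >= 0))
  zero <- multiplicity_distribution(flags & FALSE)
  expect_equal(unname(zero), c(nrow(idx), 0L, 0L, 0L))

  bd <- claim_type_breakdown(db, idx, 30, 2)
  sums <- tapply(bd$share, bd$condition, sum)
  expect_true(all(is.na(sums) | abs(sums - 100) < 1e-9))
})

test_that("a mixed inpatient/outpatient pair confirms only via the union stream", {
  idx <- d("2006-06-01")
  cl <- rbind(
    make_claim("P1", idx - 80, "K251", "inpatient"),
    make_claim("P1", idx - 20, "K252", "outpatient")
  )
  db <- claims_db(make_patient("P1"), cl)
  idx_df <- data.frame(patient_id = "P1", index_date = idx)
  expect_true(ascertain(db, "P1", idx,
                        assessment_method(30, 2, "either"))[["peptic_ulcer"]])
  expect_false(ascertain(db, "P1", idx,
                         assessment_method(30, 2, "inpatient_only"))[["peptic_ulcer"]])
  expect_false(ascertain(db, "P1", idx,
                         assessment_method(30, 2, "outpatient_only"))[["peptic_ulcer"]])
  bd <- claim_type_breakdown(db, idx_df, 30, 2)
  pud <- bd[bd$condition == "peptic_ulcer", ]
  expect_equal(pud$share[pud$bucket == "cross_type"], 100)
})
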