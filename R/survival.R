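# Cohort construction and left-truncated Cox modelling ------------------

#' Identify index cancer cases
#'
#' An index case is a patient whose first-ever malignancy claim (any ICD-10
#' code in C00--C97) falls in `target_year`; that claim's service date is
#' the index date. Patients with a malignancy claim before `target_year`
#' (prior cancer history) are excluded, as are patients whose enrollment
#' started less than `min_enrollment_years` years before the index date, so
#' that every lookback window is fully observable.
#'
#' @param db A `claims_db`.
#' @param target_year Calendar year of index diagnoses.
#' @param min_enrollment_years Required continuous enrollment before index.
#' @return Data frame: `patient_id`, `index_date`, `age_at_index` (years).
#' @export
identify_index_cases <- function(db, target_year, min_enrollment_years = 3) {
  cl <- db$claims
  codes <- strsplit(cl$icd10_codes, ";", fixed = TRUE)
  nl <- lengths(codes)
  cancer_hit <- is_cancer_code(normalize_code(unlist(codes)))
  dt <- data.table::data.table(
    patient_id = rep(cl$patient_id, nl)[cancer_hit],
    service_date = rep(cl$service_date, nl)[cancer_hit]
  )
  if (nrow(dt) == 0) {
    return(data.frame(patient_id = character(0),
                      index_date = as.Date(character(0)),
                      age_at_index = numeric(0)))
  }
  first <- dt[, list(index_date = min(service_date)), by = "patient_id"]
  in_year <- as.integer(format(first$index_date, "%Y")) == target_year
  first <- first[in_year]
  p <- db$patients
  es <- p$enrollment_start[match(first$patient_id, p$patient_id)]
  ok <- es <= first$index_date - round(min_enrollment_years * DAYS_PER_YEAR)
  first <- first[ok]
  bd <- p$birth_date[match(first$patient_id, p$patient_id)]
  out <- data.frame(
    patient_id = first$patient_id,
    index_date = first$index_date,
    age_at_index = as.numeric(first$index_date - bd) / DAYS_PER_YEAR,
    stringsAsFactors = FALSE
  )
  out[order(out$patient_id), , drop = FALSE]
}

#' Build left-truncated survival records
#'
#' One record per index case on the age timescale: entry at the age at
#' index (delayed entry / left truncation), exit at death or administrative
#' censoring, event = death from a non-cancer cause. Deaths from the index
#' cancer or another cancer are censored at the death age (cause-specific
#' hazard convention).
#'
#' @param db A `claims_db`.
#' @param cases Index cases from [identify_index_cases()].
#' @param cci Data frame with `patient_id` and `cci_category` for every
#'   case.
#' @param study_end_date Administrative censoring date.
#' @return Data frame: `patient_id`, `entry_age`, `exit_age`, `event`
#'   (0/1), `sex`, `cci_category`.
#' @export
build_survival_records <- function(db, cases, cci, study_end_date) {
  study_end_date <- as.Date(study_end_date)
  p <- db$patients
  i <- match(cases$patient_id, p$patient_id)
  if (anyNA(i)) stop("cases reference unknown patients")
  j <- match(cases$patient_id, cci$patient_id)
  if (anyNA(j)) stop("every index case needs a CCI result")
  if (is.null(cci$cci_category)) cci$cci_category <- cci$category
  death <- p$death_date[i]
  if (any(!is.na(death) & death <= cases$index_date)) {
    stop("death on or before the index date")
  }
  exit_date <- pmin(ifelse(is.na(death), study_end_date, death),
                    as.numeric(study_end_date))
  exit_date <- as.Date(exit_date, origin = "1970-01-01")
  event <- as.integer(!is.na(death) & death <= study_end_date &
                        p$death_cause[i] == "non_cancer")
  bd <- p$birth_date[i]
  out <- data.frame(
    patient_id = cases$patient_id,
    entry_age = as.numeric(cases$index_date - bd) / DAYS_PER_YEAR,
    exit_age = as.numeric(exit_date - bd) / DAYS_PER_YEAR,
    event = event,
    sex = p$sex[i],
    cci_category = factor(as.character(cci$cci_category[j]),
                          levels = cci_levels()),
    stringsAsFactors = FALSE
  )
  if (any(out$exit_age <= out$entry_age)) {
    stop("exit age must exceed entry age for every record")
  }
  out
}

#' Fit a sex-adjusted left-truncated Cox model
#'
#' Maximizes the delayed-entry Cox partial likelihood on the age timescale
#' (risk set at each event age t: records with `entry_age < t <= exit_age`),
#' with Efron handling of tied event ages, via [survival::coxph()]. CCI
#' category zero is the reference group. Wald 95% confidence intervals are
#' reported as `exp(coef +- 1.96 se)`.
#'
#' @param records Survival records from [build_survival_records()].
#' @param adjust_sex Include sex as an adjustment covariate (default).
#' @return Object of class `ltcox_fit`: `coefficients` (data frame with
#'   `term`, `coef`, `se`, `hr`, `ci_low`, `ci_high`), `loglik` (log
#'   partial likelihood at the solution), `n`, `n_events`, `diagnostics`
#'   (character; empty when the fit is clean).
#' @export
fit_left_truncated_cox <- function(records, adjust_sex = TRUE) {
  if (nrow(records) == 0) stop("no records")
  if (sum(records$event) == 0) stop("no events: cannot fit a Cox model")
  records$cci_category <- droplevels(
    factor(as.character(records$cci_category), levels = cci_levels())
  )
  terms <- character(0)
  if (nlevels(records$cci_category) > 1) terms <- "cci_category"
  if (adjust_sex && length(unique(records$sex)) > 1) {
    records$sex <- factor(records$sex, levels = c("female", "male"))
    terms <- c(terms, "sex")
  }
  if (length(terms) == 0) stop("no covariate varies; nothing to estimate")
  fml <- stats::as.formula(
    paste("survival::Surv(entry_age, exit_age, event) ~",
          paste(terms, collapse = " + "))
  )
  diagnostics <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = records, ties = "efron"),
    warning = function(w) {
      diagnostics <<- c(diagnostics, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  undefined <- is.na(cf) | abs(cf) > 15 | se > 50
  if (any(undefined)) {
    diagnostics <- c(diagnostics, paste(
      "coefficient effectively undefined (monotone likelihood or empty",
      "risk sets):", paste(names(cf)[undefined], collapse = ", ")))
  }
  if (length(diagnostics) > 0) {
    warning("left-truncated Cox fit diagnostics: ",
            paste(diagnostics, collapse = " | "))
  }
  out <- list(
    coefficients = data.frame(
      term = names(cf), coef = unname(cf), se = unname(se),
      hr = exp(unname(cf)),
      ci_low = exp(unname(cf) - 1.96 * unname(se)),
      ci_high = exp(unname(cf) + 1.96 * unname(se)),
      row.names = NULL, stringsAsFactors = FALSE
    ),
    loglik = fit$loglik[length(fit$loglik)],
    n = nrow(records),
    n_events = sum(records$event),
    diagnostics = diagnostics,
    fit = fit
  )
  class(out) <- "ltcox_fit"
  out
}

#' @export
print.ltcox_fit <- function(x, ...) {
  cat(sprintf("<ltcox_fit> n = %d, events = %d, log PL = %.3f\n",
              x$n, x$n_events, x$loglik))
  print(x$coefficients, digits = 3)
  if (length(x$diagnostics) > 0) {
    cat("diagnostics:", paste(x$diagnostics, collapse = " | "), "\n")
  }
  invisible(x)
}

#' Hazard-ratio table across assessment methods
#'
#' Runs the full pipeline per assessment method — ascertain condition
#' flags, apply the severity hierarchy, score the CCI, build survival
#' records and fit the sex-adjusted left-truncated Cox model — and collects
#' the non-cancer mortality hazard ratios for CCI categories mild (1--2),
#' moderate (3--4) and severe (>= 5) versus the CCI 0 reference.
#'
#' @param db A `claims_db`.
#' @param methods Data frame of methods (default: all 27).
#' @param target_year Index diagnosis year.
#' @param study_end_date Administrative censoring date.
#' @param min_enrollment_years Enrollment requirement before index.
#' @return Data frame with one row per method x category: `washout`,
#'   `lookback`, `claim_types`, `category`, `hr`, `ci_low`, `ci_high`,
#'   `n_events`, `diagnostic` (`NA` when clean). Per-method failures are
#'   reported in `diagnostic` without aborting the remaining methods.
#' @export
hr_table <- function(db, methods = enumerate_methods(), target_year,
                     study_end_date, min_enrollment_years = 3) {
  cases <- identify_index_cases(db, target_year, min_enrollment_years)
  if (nrow(cases) == 0) stop("no index cases in target year")
  index_dates <- cases[, c("patient_id", "index_date")]
  cond_claims <- condition_claim_table(db)
  cats <- c("mild", "moderate", "severe")
  out <- lapply(seq_len(nrow(methods)), function(k) {
    m <- methods[k, ]
    base <- data.frame(washout = m$washout, lookback = m$lookback,
                       claim_types = m$claim_types, category = cats,
                       hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                       n_events = NA_integer_, diagnostic = NA_character_,
                       stringsAsFactors = FALSE)
    res <- tryCatch({
      flags <- ascertain_all(db, index_dates, m, cond_claims)
      cci <- cci_from_flag_matrix(flags)
      cci$patient_id <- rownames(flags)
      recs <- build_survival_records(db, cases, cci, study_end_date)
      fit <- suppressWarnings(fit_left_truncated_cox(recs))
      cf <- fit$coefficients
      for (cat in cats) {
        row <- match(paste0("cci_category", cat), cf$term)
        if (!is.na(row)) {
          base[base$category == cat,
               c("hr", "ci_low", "ci_high")] <- cf[row, c("hr", "ci_low",
                                                          "ci_high")]
        }
      }
      base$n_events <- fit$n_events
      if (length(fit$diagnostics) > 0) {
        base$diagnostic <- paste(fit$diagnostics, collapse = " | ")
      }
      base
    }, error = function(e) {
      base$diagnostic <- conditionMessage(e)
      base
    })
    res
  })
  do.call(rbind, out)
}
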