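# Comorbidity ascertainment under parametrized assessment methods --------

#' Define a comorbidity assessment method
#'
#' An assessment method is the combination of a washout (rule-out) window, a
#' lookback period, and the claim types searched. With no washout a single
#' claim carrying a condition's code confirms the condition; with a washout
#' of W days, two claims strictly more than W days apart are required,
#' screening out isolated "up-coded" diagnoses.
#'
#' @param washout Washout window in days: 0 (none), 30 or 90.
#' @param lookback Lookback period in years before the index date: 1, 2 or 3.
#' @param claim_types `"inpatient_only"`, `"outpatient_only"` or `"either"`.
#' @return A list of class `assessment_method`.
#' @export
assessment_method <- function(washout, lookback, claim_types) {
  if (identical(washout, "none")) washout <- 0
  washout <- as.numeric(washout)
  lookback <- as.numeric(lookback)
  if (!washout %in% c(0, 30, 90)) stop("washout must be 0 (none), 30 or 90")
  if (!lookback %in% 1:3) stop("lookback must be 1, 2 or 3 years")
  claim_types <- match.arg(claim_types,
                           c("inpatient_only", "outpatient_only", "either"))
  structure(list(washout = washout, lookback = lookback,
                 claim_types = claim_types,
                 label = sprintf("%s:%dy:%s",
                                 if (washout == 0) "none" else washout,
                                 lookback, claim_types)),
            class = "assessment_method")
}

#' Enumerate all 27 assessment methods
#'
#' The full factorial of washout window (none/30/90 days), lookback period
#' (1/2/3 years) and claim type (inpatient only / outpatient only / either),
#' in that nesting order.
#'
#' @return Data frame with columns `washout`, `lookback`, `claim_types`,
#'   `label`; exactly 27 distinct rows.
#' @export
enumerate_methods <- function() {
  grid <- expand.grid(
    claim_types = c("inpatient_only", "outpatient_only", "either"),
    lookback = 1:3,
    washout = c(0, 30, 90),
    stringsAsFactors = FALSE
  )[, c("washout", "lookback", "claim_types")]
  grid$label <- sprintf("%s:%dy:%s",
                        ifelse(grid$washout == 0, "none", grid$washout),
                        grid$lookback, grid$claim_types)
  rownames(grid) <- NULL
  grid
}

as_method <- function(m) {
  if (inherits(m, "assessment_method")) return(m)
  assessment_method(m$washout, m$lookback, m$claim_types)
}

#' Claims eligible for ascertainment under a method
#'
#' Keeps claims whose service date falls in the half-open lookback window
#' `[index_date - lookback * 365.25 days, index_date)` — the index date
#' itself is excluded — and whose claim type is permitted by the method.
#'
#' @param claims Data frame of one patient's claims.
#' @param index_date Index (cancer diagnosis) date.
#' @param method An [assessment_method()].
#' @return The eligible subset of `claims`.
#' @export
eligible_claims <- function(claims, index_date, method) {
  method <- as_method(method)
  win_start <- index_date - round(method$lookback * DAYS_PER_YEAR)
  keep <- claims$service_date >= win_start & claims$service_date < index_date
  if (method$claim_types != "either") {
    keep <- keep & claims$claim_type == sub("_only", "", method$claim_types)
  }
  claims[keep, , drop = FALSE]
}

#' Rule-out confirmation of a condition from claim dates
#'
#' @param claim_dates Dates of the in-window claims carrying the condition's
#'   codes.
#' @param washout Washout window: 0 (or `"none"`), 30 or 90 days.
#' @return `TRUE` if the condition is confirmed: at least one claim when the
#'   washout is disabled, otherwise two claims strictly more than `washout`
#'   days apart.
#' @export
#' @examples
#' d <- as.Date("2006-06-01")
#' confirm_condition(c(d - 100, d - 50), 30)  # TRUE: gap 50 > 30
#' confirm_condition(c(d - 40, d - 20), 30)   # FALSE: gap 20 <= 30
confirm_condition <- function(claim_dates, washout) {
  if (identical(washout, "none")) washout <- 0
  if (length(claim_dates) == 0) return(FALSE)
  if (washout == 0) return(TRUE)
  as.numeric(max(claim_dates) - min(claim_dates)) > washout
}

# Long table of condition-bearing diagnosis codes, one row per (claim, code)
# that maps to a Charlson condition. Computed once per database and reused
# across methods.
condition_claim_table <- function(db) {
  cl <- db$claims
  codes <- strsplit(cl$icd10_codes, ";", fixed = TRUE)
  nl <- lengths(codes)
  dt <- data.table::data.table(
    patient_id = rep(cl$patient_id, nl),
    claim_type = rep(cl$claim_type, nl),
    service_date = rep(cl$service_date, nl),
    condition = condition_of_code(normalize_code(unlist(codes)))
  )
  dt[!is.na(dt$condition)]
}

check_index_dates <- function(index_dates) {
  if (!is.data.frame(index_dates) ||
      !all(c("patient_id", "index_date") %in% names(index_dates))) {
    stop("`index_dates` must be a data frame with patient_id and index_date")
  }
  if (anyDuplicated(index_dates$patient_id) > 0) {
    stop("duplicated patient_id in index_dates")
  }
  index_dates
}

#' Ascertain condition flags for every patient under one method
#'
#' Vectorized form of [ascertain()]: applies the lookback window, claim-type
#' filter and rule-out confirmation to all patients at once. Under
#' `claim_types = "either"` the confirming claim pair may mix inpatient and
#' outpatient claims.
#'
#' @param db A `claims_db`.
#' @param index_dates Data frame with `patient_id`, `index_date`; one row
#'   per cohort member.
#' @param method An [assessment_method()] (or a row of
#'   [enumerate_methods()]).
#' @param cond_claims Optional precomputed result of the internal
#'   condition-code expansion, to amortize work across methods.
#' @return Logical matrix, one row per `index_dates` row (rownames =
#'   patient id), one column per Charlson condition.
#' @export
ascertain_all <- function(db, index_dates, method, cond_claims = NULL) {
  method <- as_method(method)
  check_index_dates(index_dates)
  if (is.null(cond_claims)) cond_claims <- condition_claim_table(db)
  conds <- charlson_conditions()
  flags <- matrix(FALSE, nrow = nrow(index_dates), ncol = length(conds),
                  dimnames = list(index_dates$patient_id, conds))
  idx <- data.table::data.table(patient_id = index_dates$patient_id,
                                index_date = index_dates$index_date)
  dt <- merge(cond_claims, idx, by = "patient_id")
  if (nrow(dt) == 0) return(flags)
  win_start <- dt$index_date - round(method$lookback * DAYS_PER_YEAR)
  keep <- dt$service_date >= win_start & dt$service_date < dt$index_date
  if (method$claim_types != "either") {
    keep <- keep & dt$claim_type == sub("_only", "", method$claim_types)
  }
  dt <- dt[keep]
  if (nrow(dt) == 0) return(flags)
  agg <- dt[, list(n = .N,
                   span = as.numeric(max(service_date) - min(service_date))),
            by = c("patient_id", "condition")]
  ok <- if (method$washout == 0) agg$n >= 1 else agg$span > method$washout
  agg <- agg[ok]
  flags[cbind(match(agg$patient_id, index_dates$patient_id),
              match(agg$condition, conds))] <- TRUE
  flags
}

#' Ascertain condition flags for a single patient
#'
#' Composes [eligible_claims()] and [confirm_condition()] per condition.
#'
#' @param db A `claims_db`.
#' @param patient_id Patient identifier (must exist in the database).
#' @param index_date The patient's index date.
#' @param method An [assessment_method()].
#' @return Named logical vector over the 13 Charlson conditions.
#' @export
ascertain <- function(db, patient_id, index_date, method) {
  method <- as_method(method)
  if (!patient_id %in% db$patients$patient_id) {
    stop("unknown patient: ", patient_id)
  }
  cl <- db$claims[db$claims$patient_id == patient_id, , drop = FALSE]
  cl <- eligible_claims(cl, index_date, method)
  conds <- charlson_conditions()
  flags <- setNames(rep(FALSE, length(conds)), conds)
  if (nrow(cl) == 0) return(flags)
  codes <- strsplit(cl$icd10_codes, ";", fixed = TRUE)
  nl <- lengths(codes)
  hit <- condition_of_code(normalize_code(unlist(codes)))
  dates <- rep(cl$service_date, nl)
  for (cid in conds) {
    flags[[cid]] <- confirm_condition(dates[!is.na(hit) & hit == cid],
                                      method$washout)
  }
  flags
}

#' Prevalence of each condition under each assessment method
#'
#' @param db A `claims_db`.
#' @param index_dates Cohort index dates (see [ascertain_all()]).
#' @param methods Data frame of methods, e.g. [enumerate_methods()].
#' @return Long data frame: `washout`, `lookback`, `claim_types`,
#'   `condition`, `prevalence` (percent of the cohort flagged).
#' @export
prevalence_table <- function(db, index_dates, methods = enumerate_methods()) {
  check_index_dates(index_dates)
  if (nrow(index_dates) == 0) stop("empty cohort")
  cond_claims <- condition_claim_table(db)
  out <- lapply(seq_len(nrow(methods)), function(k) {
    m <- methods[k, ]
    flags <- ascertain_all(db, index_dates, m, cond_claims)
    data.frame(washout = m$washout, lookback = m$lookback,
               claim_types = m$claim_types,
               condition = colnames(flags),
               prevalence = 100 * colMeans(flags),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Distribution of the number of comorbid conditions
#'
#' @param flags Logical flag matrix from [ascertain_all()].
#' @return Named integer vector of patient counts in bins `0`, `1`, `2`,
#'   `3+`; sums to the cohort size.
#' @export
multiplicity_distribution <- function(flags) {
  k <- rowSums(check_flags(flags))
  bins <- cut(k, c(-0.5, 0.5, 1.5, 2.5, Inf), labels = c("0", "1", "2", "3+"))
  setNames(as.integer(table(bins)), levels(bins))
}

#' Claim-type composition of each ascertained condition
#'
#' Among patients confirmed for a condition using either claim type, asks
#' which single-stream methods (same washout and lookback) would also have
#' confirmed it: the inpatient stream only, the outpatient stream only,
#' both, or neither alone (the confirming pair mixes claim types and exists
#' only in the union stream).
#'
#' @param db A `claims_db`.
#' @param index_dates Cohort index dates.
#' @param washout,lookback Washout window (days) and lookback (years) held
#'   fixed across the three claim-type variants.
#' @return Long data frame: `condition`, `bucket` (`inpatient_only`,
#'   `outpatient_only`, `both`, `cross_type`), `n`, `share` (percent of the
#'   either-confirmed patients for that condition; shares sum to 100 within
#'   condition).
#' @export
claim_type_breakdown <- function(db, index_dates, washout = 30, lookback = 2) {
  check_index_dates(index_dates)
  cond_claims <- condition_claim_table(db)
  f_either <- ascertain_all(db, index_dates,
                            assessment_method(washout, lookback, "either"),
                            cond_claims)
  f_in <- ascertain_all(db, index_dates,
                        assessment_method(washout, lookback, "inpatient_only"),
                        cond_claims)
  f_out <- ascertain_all(db, index_dates,
                         assessment_method(washout, lookback, "outpatient_only"),
                         cond_claims)
  buckets <- c("inpatient_only", "outpatient_only", "both", "cross_type")
  out <- lapply(charlson_conditions(), function(cid) {
    e <- f_either[, cid]
    bucket <- ifelse(f_in[, cid] & f_out[, cid], "both",
                     ifelse(f_in[, cid], "inpatient_only",
                            ifelse(f_out[, cid], "outpatient_only",
                                   "cross_type")))
    n <- vapply(buckets, function(b) sum(e & bucket == b), integer(1))
    denom <- sum(e)
    data.frame(condition = cid, bucket = buckets, n = as.integer(n),
               share = if (denom > 0) 100 * n / denom else rep(NA_real_, 4),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
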