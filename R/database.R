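# Claims database container and on-disk format --------------------------

#' Construct a claims database
#'
#' Bundles a patients table, a claims table and (optionally) a simulation
#' truth table into a validated `claims_db` object, the container consumed
#' by every downstream stage.
#'
#' @param patients Data frame with columns `patient_id`, `sex`
#'   (`"male"`/`"female"`), `birth_date`, `enrollment_start`,
#'   `enrollment_end` (`Date`), `death_date` (`Date`, `NA` if alive) and
#'   `death_cause` (`"index_cancer"`, `"other_cancer"`, `"non_cancer"`, or
#'   `NA`).
#' @param claims Data frame with columns `patient_id`, `claim_type`
#'   (`"inpatient"`/`"outpatient"`), `service_date` (`Date`) and
#'   `icd10_codes` (one or more ICD-10 codes separated by `";"`).
#' @param truth Optional data frame with columns `patient_id`, `index_date`,
#'   `true_conditions` (`";"`-separated, possibly empty), `true_cci_score`,
#'   `true_cci_category`.
#' @return A `claims_db` object.
#' @export
claims_db <- function(patients, claims, truth = NULL) {
  db <- structure(
    list(patients = as.data.frame(patients),
         claims = as.data.frame(claims),
         truth = if (is.null(truth)) NULL else as.data.frame(truth)),
    class = "claims_db"
  )
  validate_claims_db(db)
  db
}

#' Validate claims database invariants
#'
#' Checks referential integrity (every claim and truth row points at an
#' existing patient), date ordering (enrollment spans are non-empty, deaths
#' fall inside enrollment, claims fall inside the patient's enrollment),
#' cause-of-death consistency, and non-empty diagnosis code lists. Called by
#' [claims_db()] and [read_claims_db()].
#'
#' @param db A `claims_db` object.
#' @return The database, invisibly; errors describe the offending rows.
#' @export
validate_claims_db <- function(db) {
  p <- db$patients
  cl <- db$claims
  need_p <- c("patient_id", "sex", "birth_date", "enrollment_start",
              "enrollment_end", "death_date", "death_cause")
  need_c <- c("patient_id", "claim_type", "service_date", "icd10_codes")
  if (!all(need_p %in% names(p))) {
    stop("patients table missing columns: ",
         paste(setdiff(need_p, names(p)), collapse = ", "))
  }
  if (!all(need_c %in% names(cl))) {
    stop("claims table missing columns: ",
         paste(setdiff(need_c, names(cl)), collapse = ", "))
  }
  if (anyDuplicated(p$patient_id) > 0) stop("duplicated patient_id")
  if (!all(p$sex %in% c("male", "female"))) stop("sex must be male/female")
  bad <- which(!(p$enrollment_start < p$enrollment_end))
  if (length(bad) > 0) {
    stop("patients rows with empty enrollment span: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  dead <- !is.na(p$death_date)
  if (!identical(dead, !is.na(p$death_cause))) {
    stop("death_cause must be present exactly when death_date is present")
  }
  if (any(!p$death_cause[dead] %in%
          c("index_cancer", "other_cancer", "non_cancer"))) {
    stop("unknown death_cause value")
  }
  bad <- which(dead & (p$death_date < p$enrollment_start |
                         p$death_date > p$enrollment_end))
  if (length(bad) > 0) {
    stop("death_date outside enrollment for patients rows: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (nrow(cl) > 0) {
    orphan <- which(!cl$patient_id %in% p$patient_id)
    if (length(orphan) > 0) {
      stop("claims rows referencing unknown patient_id: ",
           paste(utils::head(orphan, 5), collapse = ", "))
    }
    if (!all(cl$claim_type %in% c("inpatient", "outpatient"))) {
      stop("claim_type must be inpatient/outpatient")
    }
    if (any(is.na(cl$icd10_codes) | !nzchar(cl$icd10_codes))) {
      stop("claims with empty icd10_codes")
    }
    es <- p$enrollment_start[match(cl$patient_id, p$patient_id)]
    ee <- p$enrollment_end[match(cl$patient_id, p$patient_id)]
    bad <- which(cl$service_date < es | cl$service_date > ee)
    if (length(bad) > 0) {
      stop("claims outside the patient's enrollment: rows ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  if (!is.null(db$truth)) {
    orphan <- which(!db$truth$patient_id %in% p$patient_id)
    if (length(orphan) > 0) {
      stop("truth rows referencing unknown patient_id: ",
           paste(utils::head(orphan, 5), collapse = ", "))
    }
  }
  invisible(db)
}

#' @export
print.claims_db <- function(x, ...) {
  cat(sprintf("<claims_db> %d patients, %d claims%s\n",
              nrow(x$patients), nrow(x$claims),
              if (is.null(x$truth)) "" else
                sprintf(", truth for %d patients", nrow(x$truth))))
  deaths <- table(factor(x$patients$death_cause,
                         c("index_cancer", "other_cancer", "non_cancer")))
  cat(sprintf("  deaths: %d index-cancer, %d other-cancer, %d non-cancer\n",
              deaths[1], deaths[2], deaths[3]))
  invisible(x)
}

#' Write a claims database to a directory
#'
#' Writes `patients.csv`, `claims.csv` and (when present) `truth.csv` as
#' UTF-8 CSV with ISO-8601 dates. [read_claims_db()] inverts the operation
#' exactly, truth table included.
#'
#' @param db A `claims_db`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_claims_db <- function(db, dir) {
  validate_claims_db(db)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(db$patients, file.path(dir, "patients.csv"))
  data.table::fwrite(db$claims, file.path(dir, "claims.csv"))
  if (!is.null(db$truth)) {
    data.table::fwrite(db$truth, file.path(dir, "truth.csv"))
  }
  invisible(dir)
}

#' Read a claims database from a directory
#'
#' @param dir Directory containing `patients.csv`, `claims.csv` and
#'   optionally `truth.csv` as written by [write_claims_db()].
#' @return A validated `claims_db`.
#' @export
read_claims_db <- function(dir) {
  pf <- file.path(dir, "patients.csv")
  cf <- file.path(dir, "claims.csv")
  if (!file.exists(pf)) stop("missing patients.csv in ", dir)
  if (!file.exists(cf)) stop("missing claims.csv in ", dir)
  patients <- as.data.frame(data.table::fread(
    pf,
    colClasses = list(character = c("patient_id", "sex", "death_cause"),
                      Date = c("birth_date", "enrollment_start",
                               "enrollment_end", "death_date")),
    na.strings = ""
  ))
  claims <- as.data.frame(data.table::fread(
    cf,
    colClasses = list(character = c("patient_id", "claim_type", "icd10_codes"),
                      Date = "service_date"),
    na.strings = NULL
  ))
  tf <- file.path(dir, "truth.csv")
  truth <- NULL
  if (file.exists(tf)) {
    truth <- as.data.frame(data.table::fread(
      tf,
      colClasses = list(character = c("patient_id", "true_conditions",
                                      "true_cci_category"),
                        Date = "index_date",
                        integer = "true_cci_score"),
      na.strings = NULL
    ))
  }
  claims_db(patients, claims, truth)
}
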