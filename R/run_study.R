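# End-to-end study orchestration ----------------------------------------

#' Cohort attrition summary
#'
#' Telescoping inclusion counts for the index-case definition: patients
#' with any malignancy claim in the target year; of those, patients whose
#' first-ever malignancy claim falls in the target year (no prior cancer
#' history); of those, patients meeting the pre-index enrollment
#' requirement.
#'
#' @param db A `claims_db`.
#' @param target_year Index diagnosis year.
#' @param min_enrollment_years Enrollment requirement before index.
#' @return Named integer vector: `initial`, `no_prior_history`,
#'   `enrollment_ok`, `final` (equal to `enrollment_ok`).
#' @export
summarize_attrition <- function(db, target_year, min_enrollment_years = 3) {
  cl <- db$claims
  codes <- strsplit(cl$icd10_codes, ";", fixed = TRUE)
  nl <- lengths(codes)
  cancer_hit <- is_cancer_code(normalize_code(unlist(codes)))
  dt <- data.table::data.table(
    patient_id = rep(cl$patient_id, nl)[cancer_hit],
    service_date = rep(cl$service_date, nl)[cancer_hit]
  )
  if (nrow(dt) == 0) {
    z <- c(initial = 0L, no_prior_history = 0L, enrollment_ok = 0L, final = 0L)
    return(z)
  }
  yr <- as.integer(format(dt$service_date, "%Y"))
  initial_ids <- unique(dt$patient_id[yr == target_year])
  first <- dt[, list(index_date = min(service_date)), by = "patient_id"]
  first <- first[as.integer(format(first$index_date, "%Y")) == target_year]
  p <- db$patients
  es <- p$enrollment_start[match(first$patient_id, p$patient_id)]
  ok <- es <= first$index_date - round(min_enrollment_years * DAYS_PER_YEAR)
  c(initial = length(initial_ids),
    no_prior_history = nrow(first),
    enrollment_ok = sum(ok),
    final = sum(ok))
}

#' Recovery of true comorbidity flags per assessment method
#'
#' Compares ascertained flags with the generator truth, pooled over all
#' (patient, condition) pairs in the cohort: sensitivity = flagged among
#' truly present, positive predictive value = truly present among flagged.
#' Only available for databases carrying a truth table.
#'
#' @param db A `claims_db` with truth.
#' @param index_dates Cohort index dates.
#' @param methods Data frame of methods.
#' @return Data frame: `washout`, `lookback`, `claim_types`, `sensitivity`,
#'   `ppv` (proportions in `[0, 1]`, `NA` when undefined).
#' @export
truth_recovery <- function(db, index_dates, methods = enumerate_methods()) {
  if (is.null(db$truth)) stop("database has no truth table")
  check_index_dates(index_dates)
  conds <- charlson_conditions()
  tr <- db$truth[match(index_dates$patient_id, db$truth$patient_id), ]
  true_flags <- matrix(FALSE, nrow(index_dates), length(conds),
                       dimnames = list(index_dates$patient_id, conds))
  cond_lists <- strsplit(tr$true_conditions, ";", fixed = TRUE)
  nl <- lengths(cond_lists)
  true_flags[cbind(rep(seq_len(nrow(tr)), nl),
                   match(unlist(cond_lists), conds))] <- TRUE
  cond_claims <- condition_claim_table(db)
  out <- lapply(seq_len(nrow(methods)), function(k) {
    m <- methods[k, ]
    flags <- ascertain_all(db, index_dates, m, cond_claims)
    tp <- sum(flags & true_flags)
    data.frame(
      washout = m$washout, lookback = m$lookback, claim_types = m$claim_types,
      sensitivity = if (sum(true_flags) > 0) tp / sum(true_flags) else NA_real_,
      ppv = if (sum(flags) > 0) tp / sum(flags) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

config_hash <- function(config) {
  canon <- config
  canon$study_end_date <- as.character(canon$study_end_date)
  canon$conditions <- as.list(canon$conditions)
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(canon, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full method-comparison study
#'
#' Orchestrates simulate -> ascertain -> score -> fit across all 27
#' assessment methods and writes the comparison surfaces: per-method
#' condition prevalence, comorbidity-count distributions, the claim-type
#' composition of each condition at the reference washout/lookback, the
#' hazard-ratio table, truth recovery, the generated database itself, and a
#' JSON run manifest (configuration hash, seed, row counts, wall times).
#' Re-running with the same configuration and seed reproduces identical
#' CSV output.
#'
#' @param config A [generator_config()], or the path to a YAML file for
#'   [read_generator_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding the configuration's `rng_seed`.
#' @return The manifest, invisibly.
#' @export
run_study <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- read_generator_config(config)
  if (!is.null(seed)) config$rng_seed <- as.integer(seed)
  validate_generator_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    stages[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }

  db <- tick("simulate", generate_cohort(config))
  write_claims_db(db, file.path(out_dir, "db"))
  message(sprintf("[simulate] %d patients, %d claims",
                  nrow(db$patients), nrow(db$claims)))

  attrition <- summarize_attrition(db, config$index_year)
  cases <- tick("index_cases",
                identify_index_cases(db, config$index_year))
  message(sprintf("[cohort] attrition %s -> %d index cases",
                  paste(attrition, collapse = " / "), nrow(cases)))
  index_dates <- cases[, c("patient_id", "index_date")]
  methods <- enumerate_methods()

  prev <- tick("prevalence", prevalence_table(db, index_dates, methods))
  data.table::fwrite(prev, file.path(out_dir, "prevalence.csv"))

  mult <- tick("multiplicity", {
    cond_claims <- condition_claim_table(db)
    do.call(rbind, lapply(seq_len(nrow(methods)), function(k) {
      m <- methods[k, ]
      bins <- multiplicity_distribution(
        ascertain_all(db, index_dates, m, cond_claims))
      data.frame(washout = m$washout, lookback = m$lookback,
                 claim_types = m$claim_types,
                 n_conditions = names(bins), n_patients = unname(bins),
                 stringsAsFactors = FALSE)
    }))
  })
  data.table::fwrite(mult, file.path(out_dir, "multiplicity.csv"))

  breakdown <- tick("claim_type_breakdown",
                    claim_type_breakdown(db, index_dates, 30, 2))
  data.table::fwrite(breakdown, file.path(out_dir, "claim_type_breakdown.csv"))

  hr <- tick("hr_table",
             hr_table(db, methods, config$index_year, config$study_end_date))
  data.table::fwrite(hr, file.path(out_dir, "hr_table.csv"))

  recov <- tick("truth_recovery", truth_recovery(db, index_dates, methods))
  data.table::fwrite(recov, file.path(out_dir, "truth_recovery.csv"))

  files <- c("prevalence.csv", "multiplicity.csv", "claim_type_breakdown.csv",
             "hr_table.csv", "truth_recovery.csv")
  manifest <- list(
    config_hash = config_hash(config),
    seed = config$rng_seed,
    package_version = as.character(packageVersion("comorbiscope")),
    n_patients = nrow(db$patients),
    n_claims = nrow(db$claims),
    attrition = as.list(attrition),
    n_index_cases = nrow(cases),
    n_methods = nrow(methods),
    output_files = files,
    wall_time_s = stages
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
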