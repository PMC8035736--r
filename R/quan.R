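#' @import data.table
#' @importFrom stats rbinom rexp rnorm rpois runif setNames qbinom
#' @importFrom utils packageVersion
NULL

# Cache for the coding table; populated lazily so the installed extdata file
# remains the single source of truth.
.quan_env <- new.env(parent = emptyenv())

#' The 13 Charlson conditions handled by this package
#'
#' The Charlson index originally covers 19 conditions. Claims-based cancer
#' cohort studies drop the two malignancy conditions (every subject has
#' cancer by design) and, in databases where dementia and AIDS/HIV codes are
#' masked for confidentiality, those two as well, leaving the 13 conditions
#' returned here.
#'
#' @return Character vector of 13 condition identifiers, in fixed order.
#' @export
charlson_conditions <- function() {
  c(
    "myocardial_infarction", "congestive_heart_failure", "peripheral_vascular",
    "cerebrovascular", "chronic_pulmonary", "rheumatic", "peptic_ulcer",
    "liver_mild", "diabetes_uncomplicated", "diabetes_complicated",
    "hemiplegia_paraplegia", "renal", "liver_moderate_severe"
  )
}

#' ICD-10 coding table for the Charlson conditions
#'
#' Returns the packaged coding algorithm (after Quan et al. 2005) mapping
#' normalized ICD-10 prefixes to the 13 in-scope Charlson conditions, with
#' the Charlson et al. 1987 weights. The table ships as a plain tab-separated
#' file under `inst/extdata` so it can be audited or substituted.
#'
#' @return A `data.frame` with columns `condition`, `prefix`, `weight`.
#' @export
quan_code_table <- function() {
  load_quan_table()
  as.data.frame(.quan_env$table)
}

load_quan_table <- function() {
  if (!is.null(.quan_env$table)) {
    return(invisible(NULL))
  }
  path <- system.file("extdata", "quan_icd10_charlson.tsv",
                      package = "comorbiscope", mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(identical(names(tab), c("condition", "prefix", "weight")))
  stopifnot(setequal(unique(tab$condition), charlson_conditions()))
  if (anyDuplicated(tab$prefix) > 0) {
    stop("duplicated prefix in coding table")
  }
  # Disjointness across conditions: no prefix of one condition may be a
  # leading substring of a prefix belonging to a different condition,
  # otherwise a single code could map to two conditions.
  pre <- tab$prefix
  cond <- tab$condition
  for (i in seq_along(pre)) {
    hits <- startsWith(pre, pre[[i]]) & cond != cond[[i]]
    if (any(hits)) {
      stop(sprintf("coding table not disjoint: prefix %s (%s) overlaps %s",
                   pre[[i]], cond[[i]], paste(pre[hits], collapse = ", ")))
    }
  }
  weights <- tapply(tab$weight, tab$condition, unique)
  if (!all(lengths(weights) == 1L) || !all(unlist(weights) %in% 1:3)) {
    stop("each condition must have a single weight in {1, 2, 3}")
  }
  .quan_env$table <- tab
  .quan_env$prefix_to_condition <- setNames(tab$condition, tab$prefix)
  .quan_env$weights <- vapply(weights, identity, numeric(1))[charlson_conditions()]
  .quan_env$prefix3 <- setNames(tab$condition, tab$prefix)[nchar(tab$prefix) == 3]
  .quan_env$prefix4 <- setNames(tab$condition, tab$prefix)[nchar(tab$prefix) == 4]
  invisible(NULL)
}

# Exclusion prefixes: malignancy / metastatic tumour codes are never counted
# as comorbidity in a cancer cohort, and dementia + AIDS/HIV codes are masked
# in the source data this pipeline emulates.
cancer_prefixes <- function() {
  num <- c(0:26, 30:34, 37:41, 43, 45:58, 60:76, 77:80, 81:85, 88, 90:97)
  sprintf("C%02d", num)
}

masked_prefixes <- function() {
  c("F00", "F01", "F02", "F03", "F051", "G30", "G311", "B20", "B22", "B24")
}

#' Normalize a raw ICD-10 code
#'
#' Trims whitespace, uppercases, and removes the decimal point, so that
#' `"k25.1"` becomes `"K251"`. Idempotent.
#'
#' @param raw Character vector of raw ICD-10 codes.
#' @return Character vector of normalized codes.
#' @export
#' @examples
#' normalize_code(c("k25.1", "I21", "  e11.2 "))
normalize_code <- function(raw) {
  if (!is.character(raw)) {
    stop("`raw` must be a character vector of ICD-10 codes")
  }
  out <- gsub(".", "", toupper(trimws(raw)), fixed = TRUE)
  if (any(!nzchar(out))) {
    stop("empty ICD-10 code after trimming")
  }
  out
}

#' Is a normalized code a malignancy code?
#'
#' Matches the malignant-neoplasm ranges C00--C26, C30--C34, C37--C41, C43,
#' C45--C58, C60--C76, C77--C80 (metastatic), C81--C85, C88, C90--C97.
#'
#' @param code Character vector of normalized codes.
#' @return Logical vector.
#' @export
is_cancer_code <- function(code) {
  substr(code, 1, 3) %in% cancer_prefixes()
}

#' Is a normalized code a masked dementia or AIDS/HIV code?
#'
#' Dementia (F00--F03, F05.1, G30, G31.1) and AIDS/HIV (B20, B22, B24) are
#' masked in the claims source this package emulates and never ascertained.
#'
#' @param code Character vector of normalized codes.
#' @return Logical vector.
#' @export
is_masked_code <- function(code) {
  mp <- masked_prefixes()
  substr(code, 1, 3) %in% mp | substr(code, 1, 4) %in% mp
}

# Vectorized code -> condition mapping; NA_character_ where the code maps to
# no condition (unknown, malignancy, or masked).
condition_of_code <- function(code) {
  load_quan_table()
  hit <- .quan_env$prefix4[substr(code, 1, 4)]
  miss <- is.na(hit)
  if (any(miss)) {
    hit[miss] <- .quan_env$prefix3[substr(code[miss], 1, 3)]
  }
  hit[is_cancer_code(code) | is_masked_code(code)] <- NA_character_
  unname(hit)
}

#' Map a normalized ICD-10 code to Charlson conditions
#'
#' Prefix match against the packaged coding table. Malignancy codes and
#' masked dementia/AIDS codes always map to the empty set, as do unknown
#' codes. Because the prefix sets are pairwise disjoint the result has at
#' most one element.
#'
#' @param code A single normalized ICD-10 code (see [normalize_code()]).
#' @return Character vector of condition ids (length 0 or 1).
#' @export
#' @examples
#' conditions_for_code("K251")   # peptic_ulcer
#' conditions_for_code("C169")   # character(0): malignancy, excluded
conditions_for_code <- function(code) {
  stopifnot(is.character(code), length(code) == 1L)
  hit <- condition_of_code(code)
  if (is.na(hit)) character(0) else hit
}

#' Charlson 1987 weight of a condition
#'
#' @param condition_id Character vector of condition identifiers.
#' @return Integer vector of weights (1, 2 or 3 for the in-scope conditions).
#' @export
#' @examples
#' weight_of("renal")                  # 2
#' weight_of("liver_moderate_severe")  # 3
weight_of <- function(condition_id) {
  load_quan_table()
  unknown <- setdiff(condition_id, charlson_conditions())
  if (length(unknown) > 0) {
    stop("unknown condition id: ", paste(unknown, collapse = ", "))
  }
  as.integer(.quan_env$weights[condition_id])
}
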