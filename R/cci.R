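# Charlson index scoring -------------------------------------------------

cci_levels <- function() c("zero", "mild", "moderate", "severe")

#' Apply the severity hierarchy to condition flags
#'
#' When both the mild and the moderate/severe form of a condition pair are
#' flagged (liver disease; diabetes), only the severe form contributes to the
#' score: moderate/severe liver disease suppresses mild liver disease and
#' complicated diabetes suppresses uncomplicated diabetes. The operation is
#' idempotent and leaves all other flags unchanged.
#'
#' @param flags Named logical vector over the 13 conditions, or a logical
#'   matrix with those column names (one row per patient).
#' @return Object of the same shape with the hierarchy applied.
#' @export
apply_hierarchy <- function(flags) {
  flags <- check_flags(flags)
  if (is.matrix(flags)) {
    flags[, "liver_mild"] <- flags[, "liver_mild"] &
      !flags[, "liver_moderate_severe"]
    flags[, "diabetes_uncomplicated"] <- flags[, "diabetes_uncomplicated"] &
      !flags[, "diabetes_complicated"]
  } else {
    flags[["liver_mild"]] <- flags[["liver_mild"]] &&
      !flags[["liver_moderate_severe"]]
    flags[["diabetes_uncomplicated"]] <- flags[["diabetes_uncomplicated"]] &&
      !flags[["diabetes_complicated"]]
  }
  flags
}

check_flags <- function(flags) {
  conds <- charlson_conditions()
  if (is.matrix(flags)) {
    if (!setequal(colnames(flags), conds)) {
      stop("flags matrix must have one column per Charlson condition")
    }
    return(flags[, conds, drop = FALSE])
  }
  if (!is.logical(flags) || !setequal(names(flags), conds)) {
    stop("flags must be a named logical vector over the 13 Charlson conditions")
  }
  flags[conds]
}

#' Map a Charlson score to its risk category
#'
#' Categories follow the conventional grouping 0, 1--2 (mild), 3--4
#' (moderate), >= 5 (severe).
#'
#' @param score Non-negative integer vector of Charlson scores.
#' @return Factor with levels `zero`, `mild`, `moderate`, `severe`.
#' @export
cci_category <- function(score) {
  if (any(score < 0 | score != floor(score))) {
    stop("scores must be non-negative integers")
  }
  idx <- findInterval(score, c(0, 1, 3, 5))
  factor(cci_levels()[idx], levels = cci_levels())
}

#' Charlson comorbidity score and category
#'
#' Sums the Charlson 1987 weights over the flagged conditions. Flags are
#' expected to be hierarchy-resolved (see [apply_hierarchy()]); with the
#' hierarchy applied the maximum attainable score over the 13 in-scope
#' conditions is 16.
#'
#' @param flags Named logical vector over the 13 conditions.
#' @return List with integer `score` and factor `category`.
#' @export
#' @examples
#' f <- setNames(rep(FALSE, 13), charlson_conditions())
#' f[c("myocardial_infarction", "renal")] <- TRUE
#' cci_score(f)  # score 3, moderate
cci_score <- function(flags) {
  flags <- check_flags(flags)
  w <- weight_of(charlson_conditions())
  score <- as.integer(sum(w[flags]))
  list(score = score, category = cci_category(score))
}

# Vectorized scoring for a patients x conditions flag matrix; applies the
# hierarchy first. Returns data.frame(score, category).
cci_from_flag_matrix <- function(flags) {
  flags <- apply_hierarchy(check_flags(flags))
  w <- weight_of(charlson_conditions())
  score <- as.integer(flags %*% w)
  data.frame(score = score, category = cci_category(score))
}
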