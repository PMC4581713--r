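#' Covariate schema for synthetic screening cohorts
#'
#' A covariate schema lists the categorical risk factors of the cohort: for
#' each variable its ordered level labels, the designated reference level
#' (always the first level, matching the reference categories of the risk
#' models), and the population marginal probability of each level.
#'
#' @param variables a named list; each element is a list with components
#'   `levels` (character), `probs` (numeric, same length, sums to 1).  The
#'   first level is the reference.
#' @return an object of class `covariate_schema`.
#' @export
covariate_schema <- function(variables) {
  stopifnot(is.list(variables), length(variables) >= 1L,
            !is.null(names(variables)), all(nzchar(names(variables))))
  for (nm in names(variables)) {
    v <- variables[[nm]]
    if (is.null(v$levels) || is.null(v$probs) ||
        length(v$levels) != length(v$probs) || length(v$levels) < 2L)
      stop("schema variable '", nm, "': needs matching levels and probs")
    if (anyDuplicated(v$levels))
      stop("schema variable '", nm, "': duplicated level labels")
    if (any(v$probs < 0) || abs(sum(v$probs) - 1) > 1e-12)
      stop("schema variable '", nm,
           "': probabilities must be nonnegative and sum to 1")
    variables[[nm]]$reference <- v$levels[[1L]]
  }
  structure(list(variables = variables), class = "covariate_schema")
}

#' Default covariate schema
#'
#' Marginal level frequencies pooled over cases and non-cases of the Singapore
#' Breast Cancer Screening Programme cohort (n = 24,161): age band, ethnicity,
#' age at menarche, age at first live birth, number of affected first-degree
#' relatives, past breast biopsy, body-mass index, and mean breast dense area.
#' The first level of each variable is the risk-model reference category.
#'
#' Variables recorded in the source cohort but absent from the risk models
#' (education, parity, HRT use, age at menopause) are not generated.
#'
#' @return a `covariate_schema`.
#' @export
#' @examples
#' sch <- default_covariate_schema()
#' names(sch$variables)
default_covariate_schema <- function() {
  counts <- list(
    age_band    = c("50-54" = 7338, "55-59" = 8930, "60-64" = 7893),
    ethnicity   = c("Chinese" = 20545, "Indian" = 1123, "Malay" = 1182,
                    "Others" = 1311),
    menarche    = c(">=14" = 15717, "12-13" = 7670, "<12" = 774),
    first_birth = c("<20" = 4125, "20-24" = 9064,
                    "25-29/nulliparous" = 8270, ">=30" = 2702),
    relatives   = c("None" = 23550, ">=1" = 611),
    biopsy      = c("No" = 22881, "Yes" = 1280),
    bmi         = c("<20" = 2604, "20-<24" = 8744, "24-<28" = 8532,
                    ">=28" = 4281),
    dense_area  = c("<=10" = 4793, "11-20" = 8867, "21-30" = 5488,
                    "31-40" = 2863, "41-50" = 1268, "51-60" = 882)
  )
  covariate_schema(lapply(counts, function(ct)
    list(levels = names(ct), probs = unname(ct) / sum(ct))))
}

#' Hazard specification for outcome simulation
#'
#' Holds the multiplicative structure of the proportional-hazards generator:
#' a log hazard ratio for every non-reference covariate level (reference = 0),
#' the constant baseline event rate for the all-reference profile, the
#' recruitment window over which entry dates are drawn uniformly, and the
#' administrative censoring date.
#'
#' @param log_hr named list (one element per schema variable) of named numeric
#'   vectors giving the log hazard ratio of each non-reference level.
#' @param baseline_rate events per person-year for the all-reference profile
#'   (`NULL` until calibrated, see [calibrate_baseline_rate()]).
#' @param recruitment_start,recruitment_end,censor_date `Date` scalars.
#' @return an object of class `hazard_spec`.
#' @export
hazard_spec <- function(log_hr,
                        baseline_rate = NULL,
                        recruitment_start = as.Date("1994-10-01"),
                        recruitment_end = as.Date("1997-02-28"),
                        censor_date = as.Date("2011-12-31")) {
  stopifnot(is.list(log_hr), !is.null(names(log_hr)))
  for (nm in names(log_hr)) {
    b <- log_hr[[nm]]
    if (!is.numeric(b) || is.null(names(b)) || any(!is.finite(b)))
      stop("log_hr for '", nm, "' must be a named finite numeric vector")
  }
  if (!is.null(baseline_rate)) {
    stopifnot(is.numeric(baseline_rate), length(baseline_rate) == 1L,
              is.finite(baseline_rate), baseline_rate > 0)
  }
  stopifnot(inherits(recruitment_start, "Date"),
            inherits(recruitment_end, "Date"),
            inherits(censor_date, "Date"),
            recruitment_start < recruitment_end,
            censor_date > recruitment_end)
  structure(list(log_hr = log_hr,
                 baseline_rate = baseline_rate,
                 recruitment_start = recruitment_start,
                 recruitment_end = recruitment_end,
                 censor_date = censor_date),
            class = "hazard_spec")
}

#' Default hazard specification
#'
#' Log hazard ratios are taken from the fully adjusted proportional-hazards
#' model of the source cohort (Gail variables + BMI + dense area): e.g. HR
#' 1.17 for age 55-59, 3.37 for BMI >= 28, 3.27 for dense area 51-60 cm^2.
#' Recruitment runs October 1994 through February 1997 with administrative
#' censoring on 31 December 2011.  The baseline rate is left uncalibrated;
#' [calibrate_baseline_rate()] pins it to an expected event count.
#'
#' @param baseline_rate optional events per person-year for the all-reference
#'   profile.
#' @return a `hazard_spec`.
#' @export
default_hazard_spec <- function(baseline_rate = NULL) {
  hr <- list(
    age_band    = c("55-59" = 1.17, "60-64" = 0.98),
    ethnicity   = c("Indian" = 1.10, "Malay" = 0.71, "Others" = 1.05),
    menarche    = c("12-13" = 1.14, "<12" = 1.72),
    first_birth = c("20-24" = 1.14, "25-29/nulliparous" = 1.63, ">=30" = 1.97),
    relatives   = c(">=1" = 1.78),
    biopsy      = c("Yes" = 1.66),
    bmi         = c("20-<24" = 2.19, "24-<28" = 2.66, ">=28" = 3.37),
    dense_area  = c("11-20" = 1.60, "21-30" = 2.20, "31-40" = 2.33,
                    "41-50" = 2.12, "51-60" = 3.27)
  )
  hazard_spec(log_hr = lapply(hr, log), baseline_rate = baseline_rate)
}

# Per-subject log relative hazard exp(beta' x) for a covariate table.
# Reference levels contribute 0; a level missing from the spec is an error.
linear_hazard <- function(covariates, spec, schema) {
  lp <- numeric(nrow(covariates))
  for (nm in names(schema$variables)) {
    v <- schema$variables[[nm]]
    beta <- setNames(numeric(length(v$levels)), v$levels)
    extra <- spec$log_hr[[nm]]
    if (!is.null(extra)) {
      unknown <- setdiff(names(extra), v$levels)
      if (length(unknown))
        stop("hazard spec for '", nm, "' has unknown level(s): ",
             paste(unknown, collapse = ", "))
      beta[names(extra)] <- extra
    }
    non_ref <- setdiff(v$levels[-1L], names(extra %||% character()))
    if (length(non_ref))
      stop("hazard spec for '", nm, "' is missing level(s): ",
           paste(non_ref, collapse = ", "))
    lp <- lp + beta[as.character(covariates[[nm]])]
  }
  unname(lp)
}
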