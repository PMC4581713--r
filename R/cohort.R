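#' Sample covariates for a synthetic screening cohort
#'
#' Draws `n` subjects with each categorical variable sampled independently
#' from its schema marginal.  Real-data correlations between risk factors
#' (e.g. the negative BMI-density confounding) are deliberately not
#' reproduced: no joint distribution is available, only marginals.
#'
#' @param n number of subjects.
#' @param schema a [covariate_schema()].
#' @param seed integer seed; the draw is deterministic given `(n, schema, seed)`.
#' @return a `data.frame` with `subject_id` and one factor column per schema
#'   variable (levels in schema order, reference first).
#' @export
#' @examples
#' cov <- sample_covariates(100, default_covariate_schema(), seed = 1)
#' table(cov$biopsy)
sample_covariates <- function(n, schema, seed) {
  stopifnot(inherits(schema, "covariate_schema"), n >= 1)
  n <- as.integer(n)
  with_seed(seed, {
    cols <- lapply(schema$variables, function(v) {
      idx <- sample.int(length(v$levels), n, replace = TRUE, prob = v$probs)
      factor(v$levels[idx], levels = v$levels)
    })
    cbind(data.frame(subject_id = seq_len(n)), as.data.frame(cols))
  })
}

#' Simulate survival outcomes under a proportional-hazards generator
#'
#' Event times follow an exponential law with per-subject rate
#' `lambda0 * exp(beta' x)` (constant baseline hazard; the survival function
#' is `S(t|x) = exp(-e^{beta'x} * lambda0 * t)`).  Entry dates are uniform
#' over the recruitment window; follow-up is administratively censored at the
#' censoring date.  Times are recorded in whole days (event times rounded up),
#' which produces the tied event days typical of registry data.
#'
#' @param covariates covariate table from [sample_covariates()].
#' @param spec a [hazard_spec()] with a calibrated `baseline_rate`
#'   (events per person-year).
#' @param schema the schema the covariates were drawn from.
#' @param seed integer seed.
#' @return a cohort `data.frame`: the covariate columns plus `entry_date`,
#'   `time` (days), `event` (0/1), and `label_10y` (event within 3,652 days).
#' @export
simulate_outcomes <- function(covariates, spec, schema, seed) {
  stopifnot(inherits(spec, "hazard_spec"), inherits(schema, "covariate_schema"))
  if (is.null(spec$baseline_rate))
    stop("hazard_spec has no baseline_rate; calibrate it first")
  n <- nrow(covariates)
  rel <- exp(linear_hazard(covariates, spec, schema))
  rate_day <- spec$baseline_rate / DAYS_PER_YEAR
  with_seed(seed, {
    entry_offset <- floor(runif(
      n, 0, as.numeric(spec$recruitment_end - spec$recruitment_start) + 1))
    entry <- spec$recruitment_start + entry_offset
    cens <- as.numeric(spec$censor_date - entry)   # days of potential follow-up
    t_event <- rexp(n, rate = rate_day * rel)
    event <- as.integer(t_event <= cens)
    time <- ifelse(event == 1L, pmax(1, ceiling(t_event)), cens)
    out <- covariates
    out$entry_date <- entry
    out$time <- as.numeric(time)
    out$event <- event
    out$label_10y <- derive_label_10y(out$time, out$event)
    out
  })
}

#' 10-year case label
#'
#' Deterministic function of follow-up: 1 if the subject had an event within
#' 3,652 days of entry, else 0.  All subjects have at least 10 years of
#' potential follow-up under the default calendar, so the label is never
#' censored before the horizon.
#'
#' @param time follow-up in days.
#' @param event 0/1 event indicator.
#' @return integer 0/1 vector.
#' @export
derive_label_10y <- function(time, event) {
  as.integer(event == 1L & time <= DAYS_10Y)
}

#' Calibrate the baseline event rate to an expected event count
#'
#' Root-finds the constant baseline rate `lambda0` (events per person-year for
#' the all-reference profile) such that the expected number of events in a
#' cohort of size `n` equals `target_events`.  The expectation is taken over
#' the covariate mixture and the uniform entry dates by a large fixed-seed
#' Monte-Carlo draw of relative hazards, using the closed-form exponential
#' probability `1 - exp(-lambda0 * r_i * C_i)` per draw (no event simulation
#' is needed).
#'
#' @param schema a [covariate_schema()].
#' @param spec a [hazard_spec()] (its `baseline_rate` is ignored).
#' @param n cohort size the target refers to.
#' @param target_events expected number of events (must be `< n`).
#' @param seed integer seed for the Monte-Carlo mixture draw.
#' @param mc_n Monte-Carlo sample size for the expectation.
#' @return `lambda0` in events per person-year.
#' @export
#' @examples
#' lam <- calibrate_baseline_rate(default_covariate_schema(),
#'                                default_hazard_spec(),
#'                                n = 24161, target_events = 680, seed = 1)
calibrate_baseline_rate <- function(schema, spec, n, target_events, seed,
                                    mc_n = 200000L) {
  stopifnot(target_events >= 0, target_events < n)
  if (target_events == 0) return(0)
  cov <- sample_covariates(mc_n, schema, seed = derive_seed(seed, "calibration"))
  rel <- exp(linear_hazard(cov, spec, schema))
  cens <- with_seed(derive_seed(seed, "calibration/entry"), {
    off <- floor(runif(mc_n, 0,
      as.numeric(spec$recruitment_end - spec$recruitment_start) + 1))
    as.numeric(spec$censor_date - (spec$recruitment_start + off))
  })
  expected_frac <- function(lam_year) {
    mean(1 - exp(-(lam_year / DAYS_PER_YEAR) * rel * cens))
  }
  target_frac <- target_events / n
  upper <- 1
  while (expected_frac(upper) < target_frac) {
    upper <- upper * 10
    if (upper > 1e6) stop("calibration target unattainable")
  }
  uniroot(function(l) expected_frac(l) - target_frac,
          lower = 0, upper = upper, tol = 1e-12)$root
}

#' Simulate a complete cohort
#'
#' Convenience wrapper: samples covariates and outcomes with substream seeds
#' derived from one master seed.
#'
#' @inheritParams sample_covariates
#' @inheritParams simulate_outcomes
#' @return a cohort `data.frame` (see [simulate_outcomes()]).
#' @export
simulate_cohort <- function(n, schema, spec, seed) {
  cov <- sample_covariates(n, schema, seed = derive_seed(seed, "covariates"))
  simulate_outcomes(cov, spec, schema, seed = derive_seed(seed, "outcomes"))
}

#' Write / read a cohort table as CSV
#'
#' Dates are written ISO-8601; categorical columns are re-leveled against the
#' schema on read.
#'
#' @param cohort a cohort `data.frame`.
#' @param path file path.
#' @param schema schema used to restore factor levels on read.
#' @return `read_cohort` returns the cohort `data.frame`; `write_cohort`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  if (inherits(out$entry_date, "Date"))
    out$entry_date <- format(out$entry_date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, schema = default_covariate_schema()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in names(schema$variables)) {
    if (!nm %in% names(df)) stop("cohort file missing column '", nm, "'")
    v <- schema$variables[[nm]]
    bad <- setdiff(unique(df[[nm]]), v$levels)
    if (length(bad))
      stop("cohort column '", nm, "' has non-schema level(s): ",
           paste(bad, collapse = ", "))
    df[[nm]] <- factor(df[[nm]], levels = v$levels)
  }
  if ("entry_date" %in% names(df)) df$entry_date <- as.Date(df$entry_date)
  df
}
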