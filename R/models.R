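#' Specification of a nested risk model
#'
#' Three nested models are supported, each adding one block:
#' `"gail_bmi"` (Gail variables, ethnicity, BMI), `"gail_bmi_density"`
#' (+ mammographic density categories), `"gail_bmi_density_grs"`
#' (+ continuous genetic risk score).  Density defaults to the dense-area
#' encoding; a percent-density variable of the same categorical form can be
#' swapped in via `density_var`.
#'
#' @param name one of `"gail_bmi"`, `"gail_bmi_density"`,
#'   `"gail_bmi_density_grs"`.
#' @param density_var name of the density variable in the cohort/schema.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(name = c("gail_bmi", "gail_bmi_density",
                                "gail_bmi_density_grs"),
                       density_var = "dense_area") {
  name <- match.arg(name)
  gail_block <- c("age_band", "ethnicity", "menarche", "first_birth",
                  "relatives", "biopsy", "bmi")
  vars <- gail_block
  if (name != "gail_bmi") vars <- c(vars, density_var)
  structure(list(name = name,
                 variables = vars,
                 density_var = density_var,
                 with_grs = name == "gail_bmi_density_grs"),
            class = "model_spec")
}

#' Encode the regression design matrix for a model
#'
#' One 0/1 dummy column per non-reference level of each categorical variable
#' (reference = first factor level), plus an untransformed continuous `grs`
#' column when the model includes the genetic risk score.  Column names are
#' `variable=level`.
#'
#' @param cohort cohort `data.frame` with factor covariate columns.
#' @param spec a [model_spec()].
#' @param grs numeric score vector (required iff `spec$with_grs`).
#' @return numeric matrix with attribute `continuous` naming the continuous
#'   columns.
#' @export
encode_design <- function(cohort, spec, grs = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  cols <- list()
  for (v in spec$variables) {
    if (!v %in% names(cohort)) stop("cohort is missing variable '", v, "'")
    x <- cohort[[v]]
    if (!is.factor(x)) stop("cohort variable '", v, "' must be a factor")
    if (anyNA(x)) stop("cohort variable '", v, "' has missing values")
    for (lev in levels(x)[-1L]) {
      cols[[paste0(v, "=", lev)]] <- as.numeric(x == lev)
    }
  }
  continuous <- character()
  if (spec$with_grs) {
    if (is.null(grs)) stop("model includes GRS but no scores were supplied")
    if (length(grs) != nrow(cohort))
      stop("grs length does not match cohort size")
    cols[["grs"]] <- as.numeric(grs)
    continuous <- "grs"
  }
  X <- do.call(cbind, cols)
  rownames(X) <- NULL
  attr(X, "continuous") <- continuous
  X
}

#' Fit a proportional-hazards model
#'
#' Maximizes the Cox partial likelihood with the Efron approximation for tied
#' event times (day-resolution follow-up generates ties).  The optimizer is
#' `survival::coxph.fit`; convergence, separation and constant-column checks,
#' and the reference profile used later for baseline-hazard extraction, are
#' handled here.  The reference profile is the reference category (0) for all
#' dummy columns and the cohort mean for continuous columns.
#'
#' @param design matrix from [encode_design()].
#' @param time follow-up times (days).
#' @param event 0/1 event indicators.
#' @return an object of class `ph_fit`: `coefficients`, `var` (covariance),
#'   `se`, `loglik` (null and fitted log partial likelihood), `iter`,
#'   `n`, `nevent`, `reference_profile`, and `H0_10y` (NA until
#'   [cumulative_baseline_hazard_10y()] is run).
#' @export
fit_ph <- function(design, time, event) {
  event <- as.integer(event)
  stopifnot(length(time) == length(event), all(event %in% c(0L, 1L)),
            all(time > 0))
  if (sum(event) < 2L) stop("need at least 2 events to fit")
  if (is.null(dim(design))) design <- as.matrix(design)
  if (nrow(design) != length(time)) stop("design/outcome length mismatch")
  storage.mode(design) <- "double"
  continuous <- attr(design, "continuous") %||% character()
  if (ncol(design) > 0L) {
    const <- apply(design, 2L, function(x) diff(range(x)) == 0)
    if (any(const))
      stop("constant design column(s): ",
           paste(colnames(design)[const], collapse = ", "))
  }
  y <- survival::Surv(time, event)
  if (ncol(design) == 0L) {
    fit <- list(coefficients = numeric(0), var = matrix(0, 0, 0),
                loglik = c(NA_real_, NA_real_), iter = 0L)
  } else {
    fit <- survival::coxph.fit(design, y, strata = NULL, offset = NULL,
                               init = NULL,
                               control = survival::coxph.control(),
                               weights = NULL, method = "efron",
                               rownames = NULL)
    beta <- fit$coefficients
    se <- sqrt(diag(as.matrix(fit$var)))
    if (any(!is.finite(beta)) || any(!is.finite(se)) || any(se > 20))
      stop("proportional-hazards fit failed (non-convergence or separation); ",
           "coefficients: ", paste(signif(beta, 3), collapse = ", "))
  }
  ref <- setNames(numeric(ncol(design)), colnames(design))
  for (cc in continuous) ref[cc] <- mean(design[, cc])
  structure(list(
    coefficients = setNames(as.numeric(fit$coefficients), colnames(design)),
    var = as.matrix(fit$var),
    se = setNames(if (ncol(design)) sqrt(diag(as.matrix(fit$var)))
                  else numeric(0), colnames(design)),
    loglik = fit$loglik,
    iter = fit$iter,
    n = length(time),
    nevent = sum(event),
    reference_profile = ref,
    continuous = continuous,
    H0_10y = NA_real_
  ), class = "ph_fit")
}

#' @export
print.ph_fit <- function(x, ...) {
  cat("Proportional-hazards fit:", length(x$coefficients), "coefficients,",
      x$n, "subjects,", x$nevent, "events\n")
  if (length(x$coefficients)) print(hr_table(x), digits = 3)
  if (!is.na(x$H0_10y))
    cat("10-year cumulative baseline hazard:", signif(x$H0_10y, 4), "\n")
  invisible(x)
}

#' Hazard-ratio summary table of a fit
#'
#' @param fit a `ph_fit`.
#' @param level confidence level for the Wald intervals.
#' @return data.frame with `term`, `hr`, `lo`, `hi`, `p`.
#' @export
hr_table <- function(fit, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  b <- fit$coefficients
  se <- fit$se
  data.frame(term = names(b),
             hr = exp(b),
             lo = exp(b - z * se),
             hi = exp(b + z * se),
             p = 2 * stats::pnorm(-abs(b / se)),
             row.names = NULL)
}

# Nelson-Aalen (Efron-corrected) cumulative baseline hazard step function,
# evaluated at the largest event time <= `at`, for the x = 0 profile.
baseline_cumhaz_at <- function(lp, time, event, at) {
  w <- exp(lp)
  ev_times <- time[event == 1L]
  if (!length(ev_times)) return(0)
  dt <- sort(unique(ev_times))
  o <- order(time)
  tt <- time[o]; ww <- w[o]
  # risk-set weight sum at each distinct event time: sum of w over time >= t
  cum_from <- rev(cumsum(rev(ww)))
  idx <- findInterval(dt, tt, left.open = TRUE) + 1L  # first index with tt >= t
  R <- cum_from[idx]
  S <- as.numeric(tapply(w[event == 1L], factor(ev_times, levels = dt), sum))
  d <- as.integer(table(factor(ev_times, levels = dt)))
  inc <- vapply(seq_along(dt), function(k) {
    l <- seq_len(d[k]) - 1L
    sum(1 / (R[k] - (l / d[k]) * S[k]))
  }, numeric(1))
  keep <- dt <= at
  if (!any(keep)) return(0)
  sum(inc[keep])
}

#' 10-year cumulative baseline hazard
#'
#' Cox models leave the baseline hazard unestimated; the absolute-risk scale
#' is recovered by evaluating the Nelson-Aalen cumulative-hazard estimator
#' (with the Efron tie correction matching the fit) at the reference
#' covariate profile `x-bar` (reference category for categoricals, cohort
#' mean for the continuous GRS), taking the survival estimate
#' `S^NA(t | x-bar) = exp(-H(t | x-bar))` at the largest event time at or
#' before 3,652 days, and setting
#' `H0(10y) = -log(S^NA(10y | x-bar)) / exp(beta' x-bar)`.
#' For categorical-only models `exp(beta' x-bar) = 1` and this reduces to the
#' Nelson-Aalen cumulative hazard itself.
#'
#' @param fit a `ph_fit`.
#' @param time,event the follow-up data the model was fitted to.
#' @param design the design matrix the model was fitted to.
#' @param at horizon in days (default 3,652 = 10 years).
#' @return nonnegative scalar `H0`; zero with a warning if no events precede
#'   the horizon.
#' @export
cumulative_baseline_hazard_10y <- function(fit, time, event, design,
                                           at = DAYS_10Y) {
  stopifnot(inherits(fit, "ph_fit"))
  event <- as.integer(event)
  lp <- if (length(fit$coefficients))
    drop(as.matrix(design) %*% fit$coefficients) else numeric(length(time))
  lp_ref <- sum(fit$coefficients * fit$reference_profile)
  h_at_zero <- baseline_cumhaz_at(lp, time, event, at)
  if (h_at_zero == 0) {
    warning("no events at or before the horizon; H0 = 0")
    return(0)
  }
  s_na_ref <- exp(-h_at_zero * exp(lp_ref))   # S^NA(t | x-bar)
  -log(s_na_ref) / exp(lp_ref)
}

#' Individual 10-year absolute risk
#'
#' `r_i = 1 - S(10 | x_i) = 1 - exp(-exp(beta' x_i) * H0(10y))`: the
#' probability of diagnosis within ten years of entry given the subject's
#' covariates, under the fitted proportional-hazards model.
#'
#' @param fit a `ph_fit` whose `H0_10y` has been set (see
#'   [cumulative_baseline_hazard_10y()]).
#' @param design design matrix of the subjects to score (same columns as the
#'   fit).
#' @return numeric vector of risks in `[0, 1]`.
#' @export
absolute_risk_10y <- function(fit, design) {
  stopifnot(inherits(fit, "ph_fit"))
  if (is.na(fit$H0_10y))
    stop("fit has no H0_10y; run cumulative_baseline_hazard_10y() first")
  lp <- if (length(fit$coefficients))
    drop(as.matrix(design) %*% fit$coefficients) else
      numeric(nrow(as.matrix(design)))
  1 - exp(-exp(lp) * fit$H0_10y)
}

# Convenience: fit + baseline in one call.
fit_ph_with_baseline <- function(design, time, event) {
  fit <- fit_ph(design, time, event)
  fit$H0_10y <- cumulative_baseline_hazard_10y(fit, time, event, design)
  fit
}

#' Schoenfeld-residual check of the proportional-hazards assumption
#'
#' Tests each covariate (and globally) for a time-varying effect by
#' correlating scaled Schoenfeld residuals with event time, via
#' `survival::cox.zph` on a refitted `coxph` object with identical
#' coefficients.
#'
#' @param fit a `ph_fit` (used for validation of convergence).
#' @param design,time,event the fitted data.
#' @param transform time transform passed to `survival::cox.zph`.
#' @return data.frame with `term`, `chisq`, `df`, `p`; last row is the global
#'   test.
#' @export
schoenfeld_ph_check <- function(fit, design, time, event, transform = "km") {
  stopifnot(inherits(fit, "ph_fit"), length(fit$coefficients) >= 1L)
  X <- as.matrix(design)
  cox <- survival::coxph(survival::Surv(time, as.integer(event)) ~ X,
                         ties = "efron")
  zph <- survival::cox.zph(cox, transform = transform)
  tab <- as.data.frame(zph$table)
  data.frame(term = sub("^X", "", rownames(tab)),
             chisq = tab$chisq, df = tab$df, p = tab$p, row.names = NULL)
}
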