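#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' Probability that a random case scores higher than a random non-case, with
#' half credit for ties; computed from ranks, so it is exact and O(n log n).
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 case labels.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve on a fixed false-positive grid
#'
#' True-positive rate interpolated at each requested false-positive rate;
#' used for pointwise averaging of ROC curves over genotype replicates.
#'
#' @param scores,labels as in [roc_auc()].
#' @param fpr_grid increasing vector of false-positive rates in `[0, 1]`.
#' @return data.frame with `fpr`, `tpr`.
#' @export
roc_curve_points <- function(scores, labels, fpr_grid = seq(0, 1, by = 0.01)) {
  labels <- as.integer(labels)
  o <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[o] == 1L) / sum(labels == 1L)
  fp <- cumsum(labels[o] == 0L) / sum(labels == 0L)
  tpr <- stats::approx(c(0, fp, 1), c(0, tp, 1), xout = fpr_grid,
                       method = "linear", ties = max)$y
  data.frame(fpr = fpr_grid, tpr = tpr)
}

# Stratified fold assignment: shuffles within each class so every fold keeps
# (up to rounding) the class ratio; guarantees events in every training set.
stratified_folds <- function(labels, k, seed) {
  n <- length(labels)
  fold <- integer(n)
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' Cross-validated out-of-fold 10-year risks for one model
#'
#' Splits the cohort into `k` folds stratified by event status, fits the
#' model on each training set, extracts the training-set 10-year cumulative
#' baseline hazard, and scores the held-out subjects by 10-year absolute
#' risk.  Returns the pooled out-of-fold risk vector (one risk per subject).
#'
#' @param cohort cohort `data.frame`.
#' @param spec a [model_spec()].
#' @param grs numeric score vector when the model includes the GRS.
#' @param k_folds number of folds.
#' @param seed integer seed for the fold split.
#' @return numeric vector of out-of-fold risks, in cohort order.
#' @export
cv_risks <- function(cohort, spec, grs = NULL, k_folds = 10L, seed = 1L) {
  stopifnot(k_folds >= 2L)
  design <- encode_design(cohort, spec, grs = grs)
  fold <- stratified_folds(cohort$event, k_folds, seed)
  # stratification guarantees events in every training fold unless events are
  # scarcer than folds; refold with a shifted seed before giving up
  tries <- 0L
  while (any(tapply(cohort$event, fold, sum) == sum(cohort$event)) ||
         min(table(factor(fold, levels = seq_len(k_folds)))) == 0L) {
    tries <- tries + 1L
    if (tries > 5L) stop("could not form ", k_folds, " usable folds")
    message("refolding (try ", tries, "): empty or event-free fold")
    fold <- stratified_folds(cohort$event, k_folds, seed + tries)
  }
  risks <- numeric(nrow(cohort))
  for (f in seq_len(k_folds)) {
    tr <- fold != f
    Xtr <- design[tr, , drop = FALSE]
    attr(Xtr, "continuous") <- attr(design, "continuous")
    fit <- fit_ph(Xtr, cohort$time[tr], cohort$event[tr])
    fit$H0_10y <- cumulative_baseline_hazard_10y(
      fit, cohort$time[tr], cohort$event[tr], Xtr)
    risks[!tr] <- absolute_risk_10y(fit, design[!tr, , drop = FALSE])
  }
  risks
}

#' Cross-validated AUC averaged over virtual genotype datasets
#'
#' For each genotype replicate (when the model includes the GRS): simulate
#' genotypes conditional on case status, compute the GRS, run k-fold
#' cross-validation, and compute the pooled out-of-fold AUC against the
#' 10-year case labels.  The AUC is reported as the mean with a 2.5/97.5
#' percentile interval across replicates.  For models without the GRS the
#' replicate dimension collapses to a single cross-validation pass.
#'
#' @param cohort cohort `data.frame`.
#' @param panel a [snp_panel()] (ignored for GRS-free models).
#' @param spec a [model_spec()].
#' @param n_replicates number of virtual genotype datasets.
#' @param k_folds CV folds.
#' @param seed master seed (folds and genotypes use derived substreams).
#' @param fpr_grid grid for the averaged ROC curve.
#' @return list with `model`, `auc_mean`, `auc_lo`, `auc_hi`,
#'   `auc_replicates`, `roc` (data.frame `fpr`, `tpr_mean`, `tpr_lo`,
#'   `tpr_hi`), `n_replicates`, `k_folds`.
#' @export
cv_averaged_auc <- function(cohort, panel, spec, n_replicates = 20L,
                            k_folds = 10L, seed = 1L,
                            fpr_grid = seq(0, 1, by = 0.01)) {
  stopifnot(n_replicates >= 1L)
  labels <- cohort$label_10y
  fold_seed <- derive_seed(seed, paste0("cv/", spec$name))
  if (!spec$with_grs) {
    risks <- cv_risks(cohort, spec, k_folds = k_folds, seed = fold_seed)
    aucs <- roc_auc(risks, labels)
    rocs <- list(roc_curve_points(risks, labels, fpr_grid))
  } else {
    aucs <- numeric(n_replicates)
    rocs <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      g <- simulate_genotypes(panel, cohort$event,
                              seed = derive_seed(seed, paste0("genotypes/rep", r)))
      grs <- genetic_risk_score(g, panel)
      risks <- cv_risks(cohort, spec, grs = grs, k_folds = k_folds,
                        seed = fold_seed)
      aucs[r] <- roc_auc(risks, labels)
      rocs[[r]] <- roc_curve_points(risks, labels, fpr_grid)
    }
  }
  tpr <- sapply(rocs, `[[`, "tpr")
  tpr <- matrix(tpr, nrow = length(fpr_grid))
  list(model = spec$name,
       auc_mean = mean(aucs),
       auc_lo = unname(quantile(aucs, 0.025, type = 7)),
       auc_hi = unname(quantile(aucs, 0.975, type = 7)),
       auc_replicates = aucs,
       roc = data.frame(fpr = fpr_grid,
                        tpr_mean = rowMeans(tpr),
                        tpr_lo = apply(tpr, 1, quantile, 0.025),
                        tpr_hi = apply(tpr, 1, quantile, 0.975)),
       n_replicates = length(aucs),
       k_folds = k_folds)
}

#' Gonen-Heller concordance probability
#'
#' Censoring-robust discrimination measure computed from the fitted linear
#' predictors alone:
#' `K = 2/(n(n-1)) * sum_{i<j} 1 / (1 + exp(-|beta'(x_i - x_j)|))`,
#' with exchangeable pairs (equal predictors) contributing 1/2.  An optional
#' percentile interval is obtained by a nonparametric bootstrap over
#' subjects.
#'
#' @param fit a `ph_fit`.
#' @param design design matrix of the fitted cohort.
#' @param n_boot bootstrap resamples for the interval (0 = point estimate
#'   only).
#' @param seed seed for the bootstrap.
#' @return list with `estimate`, `lo`, `hi` (NA when `n_boot = 0`), `n_boot`.
#' @export
concordance_probability <- function(fit, design, n_boot = 200L, seed = 1L) {
  stopifnot(inherits(fit, "ph_fit"))
  X <- as.matrix(design)
  if (nrow(X) < 2L) stop("need at least 2 subjects")
  lp <- if (length(fit$coefficients)) drop(X %*% fit$coefficients)
        else numeric(nrow(X))
  if (diff(range(lp)) == 0) {
    warning("all linear predictors identical; concordance = 0.5")
    return(list(estimate = 0.5, lo = NA_real_, hi = NA_real_, n_boot = 0L))
  }
  est <- gonen_heller_cpp(lp)
  lo <- hi <- NA_real_
  if (n_boot > 0L) {
    boots <- with_seed(derive_seed(seed, "concordance/boot"), {
      vapply(seq_len(n_boot), function(b) {
        gonen_heller_cpp(lp[sample.int(length(lp), replace = TRUE)])
      }, numeric(1))
    })
    lo <- unname(quantile(boots, 0.025))
    hi <- unname(quantile(boots, 0.975))
  }
  list(estimate = est, lo = lo, hi = hi, n_boot = as.integer(n_boot))
}

#' Predictive values at absolute-risk thresholds
#'
#' For each threshold `tau`: `PPV = #(case & risk >= tau) / #(risk >= tau)`
#' and `NPV = #(non-case & risk < tau) / #(risk < tau)`.  An empty group
#' yields `NA` (undefined), never zero.
#'
#' @param risks predicted 10-year absolute risks.
#' @param labels 0/1 10-year case labels.
#' @param thresholds risk thresholds in (0, 1); the defaults are the a-priori
#'   screening thresholds 1 to 10 percent.
#' @return data.frame with `threshold`, `n_above`, `ppv`, `n_below`, `npv`.
#' @export
#' @examples
#' predictive_values(c(0.005, 0.02, 0.03, 0.04), c(0, 0, 1, 1),
#'                   thresholds = 0.025)
predictive_values <- function(risks, labels,
                              thresholds = c(0.010, 0.015, 0.020, 0.025,
                                             0.030, 0.050, 0.100)) {
  labels <- as.integer(labels)
  stopifnot(length(risks) == length(labels),
            all(thresholds > 0 & thresholds < 1))
  out <- lapply(thresholds, function(tau) {
    above <- risks >= tau
    n_above <- sum(above)
    n_below <- sum(!above)
    data.frame(
      threshold = tau,
      n_above = n_above,
      ppv = if (n_above > 0) sum(labels[above] == 1L) / n_above else NA_real_,
      n_below = n_below,
      npv = if (n_below > 0) sum(labels[!above] == 0L) / n_below else NA_real_)
  })
  do.call(rbind, out)
}

#' Binned risk distributions by case status
#'
#' Histogram of predicted risks per class (cases vs non-cases) per model,
#' normalized to probabilities within class; the plot-ready analog of the
#' predicted-risk density figures.
#'
#' @param risks_by_model named list of risk vectors (one per model).
#' @param labels 0/1 case labels shared by all models.
#' @param breaks histogram breaks (default: 40 equal bins over the pooled
#'   range).
#' @return tidy data.frame with `model`, `class`, `bin_mid`, `prob`.
#' @export
risk_distribution_summary <- function(risks_by_model, labels, breaks = NULL) {
  stopifnot(is.list(risks_by_model), length(risks_by_model) >= 1L)
  labels <- as.integer(labels)
  if (is.null(breaks)) {
    rng <- range(unlist(risks_by_model))
    breaks <- seq(rng[1], rng[2], length.out = 41L)
  }
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  out <- list()
  for (m in names(risks_by_model)) {
    r <- risks_by_model[[m]]
    for (cls in c(0L, 1L)) {
      h <- hist(r[labels == cls], breaks = breaks, plot = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        model = m,
        class = if (cls == 1L) "case" else "non-case",
        bin_mid = mids,
        prob = h$counts / max(1L, sum(h$counts)))
    }
  }
  do.call(rbind, out)
}
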