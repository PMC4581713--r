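#' Default run configuration
#'
#' The defaults reproduce the study profile: 24,161 women, an expected
#' 680 incident cases (106 in-situ + 574 invasive), the shipped synthetic
#' 75-SNP panel, 1,000 virtual genotype datasets, 10-fold cross-validation,
#' and the seven a-priori absolute-risk thresholds (1 to 10 percent).  Any field can
#' be overridden programmatically or through a YAML profile
#' ([load_run_config()]).
#'
#' @param ... named overrides of default fields.
#' @return a `run_config` list.
#' @export
default_run_config <- function(...) {
  insitu_cases <- 106L
  invasive_cases <- 574L
  cfg <- list(
    n_subjects = 24161L,
    insitu_cases = insitu_cases,
    invasive_cases = invasive_cases,
    target_events = insitu_cases + invasive_cases,
    panel = "default",
    n_replicates = 1000L,
    k_folds = 10L,
    thresholds = c(0.010, 0.015, 0.020, 0.025, 0.030, 0.050, 0.100),
    n_boot = 200L,
    calibration_mc = 200000L,
    seed = 1L,
    out_dir = "brcarisk_run"
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (!is.null(dots$insitu_cases) || !is.null(dots$invasive_cases)) {
    if (is.null(dots$target_events))
      cfg$target_events <- cfg$insitu_cases + cfg$invasive_cases
  }
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 10,
            cfg$target_events > 0, cfg$target_events < cfg$n_subjects,
            cfg$n_replicates >= 1, cfg$k_folds >= 2,
            all(cfg$thresholds > 0 & cfg$thresholds < 1),
            cfg$n_boot >= 0, cfg$seed == as.integer(cfg$seed))
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a YAML profile (e.g. the shipped
#' `inst/extdata/paper_profile.yaml`) and merges it over the defaults.
#'
#' @param path YAML file.
#' @param ... further overrides applied after the file.
#' @return a `run_config`.
#' @export
load_run_config <- function(path, ...) {
  prof <- yaml::read_yaml(path)
  cfg <- do.call(default_run_config, prof)
  dots <- list(...)
  if (length(dots)) cfg <- do.call(default_run_config, c(prof, dots))
  cfg
}

resolve_panel <- function(panel) {
  if (inherits(panel, "snp_panel")) return(panel)
  if (identical(panel, "default")) return(default_snp_panel())
  read_snp_panel(panel)
}

#' Validate pipeline input files
#'
#' Schema, range and uniqueness checks with row-level diagnostics for a SNP
#' panel TSV and (optionally) a cohort CSV.
#'
#' @param panel_file path to a panel TSV.
#' @param cohort_file optional path to a cohort CSV.
#' @param schema schema for cohort level checks.
#' @return list with `ok` (logical), `n_snps`, and `messages` (character).
#' @export
validate_inputs <- function(panel_file, cohort_file = NULL,
                            schema = default_covariate_schema()) {
  msgs <- character()
  n_snps <- NA_integer_
  df <- tryCatch(utils::read.delim(panel_file, stringsAsFactors = FALSE),
                 error = function(e) e)
  if (inherits(df, "error")) {
    msgs <- c(msgs, paste0("panel: parse error: ", conditionMessage(df)))
  } else {
    req <- c("snp_id", "risk_allele_freq", "odds_ratio")
    miss <- setdiff(req, names(df))
    if (length(miss)) {
      msgs <- c(msgs, paste0("panel: missing column(s): ",
                             paste(miss, collapse = ", ")))
    } else {
      dup <- which(duplicated(df$snp_id))
      if (length(dup))
        msgs <- c(msgs, paste0("panel row ", dup + 1L,
                               ": duplicate snp_id '", df$snp_id[dup], "'"))
      bad_p <- which(!is.finite(df$risk_allele_freq) |
                       df$risk_allele_freq <= 0 | df$risk_allele_freq >= 1)
      if (length(bad_p))
        msgs <- c(msgs, paste0("panel row ", bad_p + 1L,
                               ": frequency out of range (must be in (0,1))"))
      bad_or <- which(!is.finite(df$odds_ratio) | df$odds_ratio <= 0)
      if (length(bad_or))
        msgs <- c(msgs, paste0("panel row ", bad_or + 1L,
                               ": odds ratio out of range (must be > 0)"))
      if (!length(msgs)) n_snps <- nrow(df)
    }
  }
  if (!is.null(cohort_file)) {
    co <- tryCatch(read_cohort(cohort_file, schema), error = function(e) e)
    if (inherits(co, "error")) {
      msgs <- c(msgs, paste0("cohort: ", conditionMessage(co)))
    } else {
      if (any(co$time <= 0))
        msgs <- c(msgs, paste0("cohort row ", which(co$time <= 0) + 1L,
                               ": nonpositive follow-up time"))
      if (any(!co$event %in% c(0L, 1L)))
        msgs <- c(msgs, "cohort: event must be 0/1")
      else if (any(co$label_10y != derive_label_10y(co$time, co$event)))
        msgs <- c(msgs, "cohort: label_10y inconsistent with (time, event)")
    }
  }
  list(ok = length(msgs) == 0L, n_snps = n_snps, messages = msgs)
}

# Distribution of baseline characteristics by case status (table 1 analog).
cohort_distribution_table <- function(cohort, schema, grs = NULL) {
  rows <- list()
  status <- factor(ifelse(cohort$event == 1L, "case", "non-case"),
                   levels = c("case", "non-case"))
  add_var <- function(name, f) {
    tab <- table(f, status)
    for (lev in rownames(tab)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        variable = name, level = lev,
        cases = as.integer(tab[lev, "case"]),
        noncases = as.integer(tab[lev, "non-case"]),
        cases_pct = 100 * tab[lev, "case"] / sum(tab[, "case"]),
        noncases_pct = 100 * tab[lev, "non-case"] / sum(tab[, "non-case"]))
    }
  }
  for (nm in names(schema$variables)) add_var(nm, cohort[[nm]])
  if (!is.null(grs))
    add_var("grs_quintile", factor(grs_quintiles(grs), levels = 1:5))
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Calibrates the baseline rate, simulates the cohort, simulates genotype
#' replicates, fits the three nested models, and evaluates them; writes the
#' artifact set to `config$out_dir`:
#' `table1_analog.csv` (cohort distributions by case status),
#' `table2_analog.csv` (hazard ratios per model),
#' `table3_analog.csv` (concordance probabilities),
#' `table4_analog.csv` (PPV/NPV by threshold),
#' `roc_curves.csv` + `roc_curves.png`,
#' `risk_distributions.csv` + `risk_distributions.png`, and
#' `manifest.json` (config, seeds, event counts, timings).
#'
#' @param config a `run_config` (see [default_run_config()]).
#' @return invisibly, a list with the cohort, fits, evaluation results and
#'   the manifest.
#' @export
run_pipeline <- function(config = default_run_config()) {
  config <- validate_run_config(unclass(config))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t_start <- Sys.time()
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- Sys.time()
    res <- expr
    timings[[stage]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
    res
  }
  seed <- as.integer(config$seed)
  schema <- default_covariate_schema()
  panel <- resolve_panel(config$panel)

  spec0 <- default_hazard_spec()
  lambda0 <- clock("calibrate", calibrate_baseline_rate(
    schema, spec0, n = config$n_subjects,
    target_events = config$target_events,
    seed = derive_seed(seed, "calibration"),
    mc_n = config$calibration_mc))
  hspec <- default_hazard_spec(baseline_rate = lambda0)

  cohort <- clock("cohort", simulate_cohort(
    config$n_subjects, schema, hspec, seed = derive_seed(seed, "cohort")))

  reps <- clock("genotypes", simulate_genotype_datasets(
    panel, cohort$event, n_replicates = config$n_replicates,
    seed = derive_seed(seed, "genotypes")))

  specs <- list(gail_bmi = model_spec("gail_bmi"),
                gail_bmi_density = model_spec("gail_bmi_density"),
                gail_bmi_density_grs = model_spec("gail_bmi_density_grs"))

  fits <- clock("fit", {
    f1 <- local({
      X <- encode_design(cohort, specs$gail_bmi)
      fit_ph_with_baseline(X, cohort$time, cohort$event)
    })
    f2 <- local({
      X <- encode_design(cohort, specs$gail_bmi_density)
      fit_ph_with_baseline(X, cohort$time, cohort$event)
    })
    f3_reps <- lapply(reps, function(r) {
      X <- encode_design(cohort, specs$gail_bmi_density_grs, grs = r$grs)
      fit_ph_with_baseline(X, cohort$time, cohort$event)
    })
    list(f1 = f1, f2 = f2, f3_reps = f3_reps)
  })

  # table 1 analog (GRS quintiles from the first replicate)
  tab1 <- cohort_distribution_table(cohort, schema, grs = reps[[1L]]$grs)
  utils::write.csv(tab1, file.path(config$out_dir, "table1_analog.csv"),
                   row.names = FALSE)

  # table 2 analog: HR = exp(coefficient); model 3 coefficients averaged
  # over genotype replicates.
  tab2 <- local({
    t1 <- cbind(model = "gail_bmi", hr_table(fits$f1))
    t2 <- cbind(model = "gail_bmi_density", hr_table(fits$f2))
    beta <- rowMeans(sapply(fits$f3_reps, `[[`, "coefficients"))
    se <- rowMeans(sapply(fits$f3_reps, `[[`, "se"))
    z <- qnorm(0.975)
    t3 <- data.frame(model = "gail_bmi_density_grs", term = names(beta),
                     hr = exp(beta), lo = exp(beta - z * se),
                     hi = exp(beta + z * se),
                     p = 2 * stats::pnorm(-abs(beta / se)))
    rbind(t1, t2, t3)
  })
  utils::write.csv(tab2, file.path(config$out_dir, "table2_analog.csv"),
                   row.names = FALSE)

  evals <- clock("evaluate", lapply(specs, function(sp)
    cv_averaged_auc(cohort, panel, sp, n_replicates = config$n_replicates,
                    k_folds = config$k_folds, seed = seed)))

  # table 3 analog: concordance probabilities
  tab3 <- clock("concordance", local({
    X1 <- encode_design(cohort, specs$gail_bmi)
    X2 <- encode_design(cohort, specs$gail_bmi_density)
    c1 <- concordance_probability(fits$f1, X1, n_boot = config$n_boot,
                                  seed = seed)
    c2 <- concordance_probability(fits$f2, X2, n_boot = config$n_boot,
                                  seed = seed)
    k3 <- vapply(seq_along(reps), function(r) {
      X3 <- encode_design(cohort, specs$gail_bmi_density_grs,
                          grs = reps[[r]]$grs)
      concordance_probability(fits$f3_reps[[r]], X3, n_boot = 0L)$estimate
    }, numeric(1))
    data.frame(
      model = names(specs),
      concordance = c(c1$estimate, c2$estimate, mean(k3)),
      lo = c(c1$lo, c2$lo,
             if (length(k3) >= 2) unname(quantile(k3, 0.025)) else NA_real_),
      hi = c(c1$hi, c2$hi,
             if (length(k3) >= 2) unname(quantile(k3, 0.975)) else NA_real_))
  }))
  utils::write.csv(tab3, file.path(config$out_dir, "table3_analog.csv"),
                   row.names = FALSE)

  # full-data risks; model 3 PPV/NPV averaged over replicates
  risks1 <- local({
    X <- encode_design(cohort, specs$gail_bmi)
    absolute_risk_10y(fits$f1, X)
  })
  risks2 <- local({
    X <- encode_design(cohort, specs$gail_bmi_density)
    absolute_risk_10y(fits$f2, X)
  })
  risks3_reps <- lapply(seq_along(reps), function(r) {
    X <- encode_design(cohort, specs$gail_bmi_density_grs,
                       grs = reps[[r]]$grs)
    absolute_risk_10y(fits$f3_reps[[r]], X)
  })
  labels <- cohort$label_10y
  tab4 <- local({
    pv1 <- cbind(model = "gail_bmi",
                 predictive_values(risks1, labels, config$thresholds))
    pv2 <- cbind(model = "gail_bmi_density",
                 predictive_values(risks2, labels, config$thresholds))
    pv3_list <- lapply(risks3_reps, predictive_values, labels = labels,
                       thresholds = config$thresholds)
    pv3 <- pv3_list[[1L]]
    pv3$ppv <- rowMeans(sapply(pv3_list, `[[`, "ppv"))
    pv3$npv <- rowMeans(sapply(pv3_list, `[[`, "npv"))
    pv3$n_above <- rowMeans(sapply(pv3_list, `[[`, "n_above"))
    pv3$n_below <- rowMeans(sapply(pv3_list, `[[`, "n_below"))
    rbind(pv1, pv2, cbind(model = "gail_bmi_density_grs", pv3))
  })
  utils::write.csv(tab4, file.path(config$out_dir, "table4_analog.csv"),
                   row.names = FALSE)

  roc_df <- do.call(rbind, lapply(evals, function(e)
    cbind(model = e$model, e$roc)))
  utils::write.csv(roc_df, file.path(config$out_dir, "roc_curves.csv"),
                   row.names = FALSE)

  dist_df <- risk_distribution_summary(
    list(gail_bmi = risks1, gail_bmi_density = risks2,
         gail_bmi_density_grs = risks3_reps[[1L]]), labels)
  utils::write.csv(dist_df,
                   file.path(config$out_dir, "risk_distributions.csv"),
                   row.names = FALSE)

  plot_pipeline_figures(roc_df, dist_df, evals, config$out_dir)

  manifest <- list(
    package = "brcarisk",
    version = as.character(utils::packageVersion("brcarisk")),
    r_version = R.version.string,
    created = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config)[setdiff(names(config), "out_dir")],
    seeds = list(
      master = seed,
      calibration = derive_seed(seed, "calibration"),
      cohort = derive_seed(seed, "cohort"),
      genotypes = derive_seed(seed, "genotypes")),
    baseline_rate_per_year = lambda0,
    n_events = sum(cohort$event),
    n_cases_10y = sum(cohort$label_10y),
    auc = lapply(evals, function(e)
      list(mean = e$auc_mean, lo = e$auc_lo, hi = e$auc_hi)),
    timings_sec = timings
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, fits = fits, evals = evals,
                 tables = list(tab1 = tab1, tab2 = tab2, tab3 = tab3,
                               tab4 = tab4),
                 manifest = manifest))
}

# ROC and risk-distribution figures (ggplot2); kept out of the artifact
# byte-identity contract.
plot_pipeline_figures <- function(roc_df, dist_df, evals, out_dir) {
  auc_lab <- vapply(evals, function(e)
    sprintf("%s (AUC %.2f)", e$model, e$auc_mean), character(1))
  roc_df$model <- factor(roc_df$model, levels = names(evals),
                         labels = auc_lab)
  p1 <- ggplot2::ggplot(roc_df,
          ggplot2::aes(x = fpr, y = tpr_mean,
                       colour = model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", colour = NULL,
                  title = "Cross-validated ROC, averaged over genotype replicates") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
  ggplot2::ggsave(file.path(out_dir, "roc_curves.png"), p1,
                  width = 6, height = 5, dpi = 150)
  p2 <- ggplot2::ggplot(dist_df,
          ggplot2::aes(x = bin_mid, y = prob,
                       colour = class)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~model, ncol = 1) +
    ggplot2::scale_colour_manual(values = c(case = "red", `non-case` = "black")) +
    ggplot2::labs(x = "Predicted 10-year absolute risk",
                  y = "Within-class probability", colour = NULL,
                  title = "Predicted-risk distributions by case status") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
  ggplot2::ggsave(file.path(out_dir, "risk_distributions.png"), p2,
                  width = 6, height = 7, dpi = 150)
  invisible(NULL)
}
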