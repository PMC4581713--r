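# Shared fixtures, built once per test run and memoized.  The full-scale
# cohort mirrors the study conditions: 24,161 women, baseline rate calibrated
# to an expected 680 events, covariate marginals and hazard ratios at their
# defaults.

.fx <- new.env(parent = emptyenv())

fx_memo <- function(key, value) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(value)
  .fx[[key]]
}

fx_schema <- function() fx_memo("schema", default_covariate_schema())

fx_lambda0 <- function() {
  fx_memo("lambda0", calibrate_baseline_rate(
    fx_schema(), default_hazard_spec(), n = 24161, target_events = 680,
    seed = 920))
}

fx_hspec <- function() default_hazard_spec(baseline_rate = fx_lambda0())

# Full-scale default cohort (24,161 women).
fx_cohort <- function(seed = 101) {
  fx_memo(paste0("cohort", seed),
          simulate_cohort(24161, fx_schema(), fx_hspec(), seed = seed))
}

fx_panel <- function() fx_memo("panel", default_snp_panel())

# A small cohort for cheap unit tests.
fx_small_cohort <- function(seed = 77, n = 4000) {
  fx_memo(paste0("small", seed), local({
    lam <- calibrate_baseline_rate(fx_schema(), default_hazard_spec(),
                                   n = n, target_events = round(680 * n / 24161),
                                   seed = 921, mc_n = 50000L)
    simulate_cohort(n, fx_schema(),
                    default_hazard_spec(baseline_rate = lam), seed = seed)
  }))
}

# Full-model fits over 20 genotype replicates on the default cohort: the
# common input for the GRS hazard-ratio, concordance, predictive-value and
# quintile checks.
fx_full_model_run <- function(n_replicates = 20L, seed = 301L) {
  fx_memo("full_run", local({
    cohort <- fx_cohort()
    panel <- fx_panel()
    sp1 <- model_spec("gail_bmi")
    sp3 <- model_spec("gail_bmi_density_grs")
    X1 <- encode_design(cohort, sp1)
    f1 <- fit_ph(X1, cohort$time, cohort$event)
    f1$H0_10y <- cumulative_baseline_hazard_10y(f1, cohort$time, cohort$event, X1)
    risks1 <- absolute_risk_10y(f1, X1)
    reps <- lapply(seq_len(n_replicates), function(r) {
      g <- simulate_genotypes(panel, cohort$event,
                              seed = derive_seed(seed, paste0("genotypes/rep", r)))
      grs <- genetic_risk_score(g, panel)
      X3 <- encode_design(cohort, sp3, grs = grs)
      f3 <- fit_ph(X3, cohort$time, cohort$event)
      f3$H0_10y <- cumulative_baseline_hazard_10y(f3, cohort$time,
                                                  cohort$event, X3)
      list(grs = grs,
           fit = f3,
           risks = absolute_risk_10y(f3, X3),
           concordance = concordance_probability(f3, X3, n_boot = 0L)$estimate)
    })
    list(cohort = cohort, panel = panel, fit1 = f1, risks1 = risks1,
         reps = reps)
  }))
}
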