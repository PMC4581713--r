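test_that("Mann-Whitney AUC handles separation, ties and the null", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)  # 3 of 4 pairs concordant
  expect_equal(roc_auc(c(1, 1), c(0, 1)), 0.5)  # tie gets half credit
  set.seed(601)
  s <- rnorm(10000)
  l <- rbinom(10000, 1, 0.5)
  expect_lt(abs(roc_auc(s, l) - 0.5), 0.02)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("AUC matches an independent implementation on random data", {
  set.seed(602)
  for (i in 1:5) {
    s <- round(rnorm(300), 2)            # rounding forces ties
    l <- rbinom(300, 1, 0.3)
    ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(s, l), ref, tolerance = 1e-12)
  }
})

test_that("cross-validated AUC is deterministic and stable in fold count", {
  cohort <- fx_cohort()
  panel <- fx_panel()
  sp1 <- model_spec("gail_bmi")
  e1 <- cv_averaged_auc(cohort, panel, sp1, n_replicates = 1, k_folds = 10,
                        seed = 5)
  e1b <- cv_averaged_auc(cohort, panel, sp1, n_replicates = 1, k_folds = 10,
                         seed = 5)
  expect_equal(e1$auc_mean, e1b$auc_mean, tolerance = 1e-12)

  e2 <- cv_averaged_auc(cohort, panel, sp1, n_replicates = 1, k_folds = 2,
                        seed = 5)
  expect_lt(abs(e1$auc_mean - e2$auc_mean), 0.02)
})

test_that("an informative panel outscores uninformative genotypes", {
  panel <- fx_panel()
  null_panel <- snp_panel(transform(as.data.frame(panel), odds_ratio = 1))
  sp3 <- model_spec("gail_bmi_density_grs")
  gaps <- vapply(1:5, function(s) {
    cohort <- simulate_cohort(6000, fx_schema(), fx_hspec(), seed = 700 + s)
    auc_inf <- mean(vapply(1:3, function(r) {
      g <- simulate_genotypes(panel, cohort$event,
                              seed = derive_seed(s, paste0("inf", r)))
      roc_auc(cv_risks(cohort, sp3, grs = genetic_risk_score(g, panel),
                       k_folds = 5, seed = s),
              cohort$label_10y)
    }, numeric(1)))
    auc_null <- mean(vapply(1:3, function(r) {
      # genotypes drawn with no case-control tilt, scored with the same weights
      g <- simulate_genotypes(null_panel, cohort$event,
                              seed = derive_seed(s, paste0("null", r)))
      roc_auc(cv_risks(cohort, sp3, grs = genetic_risk_score(g, panel),
                       k_folds = 5, seed = s),
              cohort$label_10y)
    }, numeric(1)))
    auc_inf - auc_null
  }, numeric(1))
  expect_gt(mean(gaps), 0)
  expect_gt(sum(gaps > 0), 3)
})

test_that("Gonen-Heller estimator agrees with a brute-force pair loop", {
  set.seed(603)
  for (n in c(2, 17, 50)) {
    X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.5))
    beta <- c(0.8, -0.5)
    fit <- structure(list(coefficients = setNames(beta, colnames(X))),
                     class = "ph_fit")
    lp <- drop(X %*% beta)
    brute <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- lp[i] - lp[j]
        brute <- brute + if (d == 0) 0.5 else 1 / (1 + exp(-abs(d)))
      }
    }
    brute <- brute / choose(n, 2)
    est <- concordance_probability(fit, X, n_boot = 0)$estimate
    expect_equal(est, brute, tolerance = 1e-12)
  }

  # exchangeable pair and a flat predictor both give exactly 0.5
  fit0 <- structure(list(coefficients = c(a = 0, b = 0)), class = "ph_fit")
  expect_warning(k0 <- concordance_probability(
    fit0, cbind(a = rnorm(10), b = rnorm(10)), n_boot = 0), "identical")
  expect_equal(k0$estimate, 0.5)

  # bootstrap interval brackets the estimate and is seed-stable
  set.seed(604)
  X <- cbind(a = rnorm(200))
  fit <- structure(list(coefficients = c(a = 1)), class = "ph_fit")
  k1 <- concordance_probability(fit, X, n_boot = 50, seed = 2)
  k2 <- concordance_probability(fit, X, n_boot = 50, seed = 2)
  expect_identical(k1, k2)
  expect_true(k1$lo <= k1$estimate && k1$estimate <= k1$hi)
})

test_that("predictive values count tail classifications correctly", {
  # perfect split
  pv <- predictive_values(c(0.001, 0.002, 0.9, 0.95), c(0, 0, 1, 1),
                          thresholds = 0.5)
  expect_equal(pv$ppv, 1)
  expect_equal(pv$npv, 1)
  # degenerate: everyone above threshold
  pv2 <- predictive_values(rep(0.02, 10), rep(c(0, 1), 5), thresholds = 0.01)
  expect_equal(pv2$ppv, 0.5)          # prevalence
  expect_true(is.na(pv2$npv))
  # hand count
  pv3 <- predictive_values(c(0.005, 0.02, 0.03, 0.04), c(0, 0, 1, 1),
                           thresholds = 0.025)
  expect_equal(pv3$ppv, 1)
  expect_equal(pv3$npv, 1)  # both subjects below threshold are non-cases
  expect_error(predictive_values(1:3 / 10, c(0, 1, 1), thresholds = 2))
})

test_that("PPV is nondecreasing in the threshold while groups stay large", {
  run <- fx_full_model_run()
  pv <- predictive_values(run$risks1, run$cohort$label_10y)
  ok <- which(pv$n_above >= 50)
  expect_true(all(diff(pv$ppv[ok]) > -1e-12))
})

test_that("risk distributions summarize by class and normalize", {
  run <- fx_full_model_run()
  labels <- run$cohort$label_10y
  d <- risk_distribution_summary(
    list(gail_bmi = run$risks1, full = run$reps[[1]]$risks), labels)
  sums <- tapply(d$prob, interaction(d$model, d$class), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # discrimination gap: case/non-case mean-risk separation grows with GRS
  gap1 <- mean(run$risks1[labels == 1]) - mean(run$risks1[labels == 0])
  gap3 <- mean(vapply(run$reps, function(r)
    mean(r$risks[labels == 1]) - mean(r$risks[labels == 0]), numeric(1)))
  expect_gt(gap3, gap1)
})
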