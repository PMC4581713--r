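test_that("design encoding produces one dummy per non-reference level", {
  cohort <- fx_small_cohort()
  X1 <- encode_design(cohort, model_spec("gail_bmi"))
  expect_equal(ncol(X1), 15)  # 2+3+2+3+1+1+3
  X2 <- encode_design(cohort, model_spec("gail_bmi_density"))
  expect_equal(ncol(X2), 20)
  grs <- rnorm(nrow(cohort))
  X3 <- encode_design(cohort, model_spec("gail_bmi_density_grs"), grs = grs)
  expect_equal(ncol(X3), 21)
  expect_identical(attr(X3, "continuous"), "grs")
  expect_equal(X3[, "grs"], grs)

  # an all-reference subject encodes to a zero row
  ref <- cohort[1, ]
  for (nm in names(fx_schema()$variables))
    ref[[nm]] <- factor(fx_schema()$variables[[nm]]$levels[1],
                        levels = fx_schema()$variables[[nm]]$levels)
  expect_equal(sum(encode_design(ref, model_spec("gail_bmi_density"))), 0)

  # one deviation from reference -> exactly one nonzero dummy
  one <- ref
  one$bmi <- factor(">=28", levels = levels(cohort$bmi))
  row <- encode_design(one, model_spec("gail_bmi"))
  expect_equal(sum(row != 0), 1)
  expect_equal(unname(row[1, "bmi=>=28"]), 1)

  bad <- cohort
  bad$bmi[1] <- NA
  expect_error(encode_design(bad, model_spec("gail_bmi")), "missing values")
  expect_error(encode_design(cohort, model_spec("gail_bmi_density_grs")),
               "no scores")
})

test_that("partial-likelihood fit recovers generating hazard ratios", {
  set.seed(501)
  n <- 5000
  x <- rbinom(n, 1, 0.5)
  z <- rbinom(n, 1, 0.3)              # independent of the hazard
  tt <- rexp(n, 0.05 * 2^x)
  cens <- runif(n, 5, 15)
  event <- as.integer(tt <= cens)
  time <- pmin(tt, cens)
  X <- cbind(x = x, z = z)
  fit <- fit_ph(X, time, event)
  expect_lt(abs(fit$coefficients[["x"]] - log(2)), 3 * fit$se[["x"]])
  expect_lt(abs(fit$coefficients[["z"]]), 3 * fit$se[["z"]])

  # permutation invariance
  p <- sample(n)
  fit2 <- fit_ph(X[p, ], time[p], event[p])
  expect_lt(max(abs(fit2$coefficients - fit$coefficients)), 1e-8)

  # preconditions
  expect_error(fit_ph(cbind(k = rep(1, n)), time, event), "constant")
  expect_error(fit_ph(X[1:5, ], rep(1, 5), rep(0L, 5)), "2 events")
})

test_that("fit agrees with survival::coxph on identical data", {
  cohort <- fx_small_cohort()
  X <- encode_design(cohort, model_spec("gail_bmi"))
  fit <- fit_ph(X, cohort$time, cohort$event)
  ref <- survival::coxph(
    survival::Surv(cohort$time, cohort$event) ~ X, ties = "efron")
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-8)
})

test_that("cumulative baseline hazard matches survival::basehaz and the
           exponential oracle", {
  cohort <- fx_small_cohort()
  X <- encode_design(cohort, model_spec("gail_bmi"))
  fit <- fit_ph(X, cohort$time, cohort$event)
  h0 <- cumulative_baseline_hazard_10y(fit, cohort$time, cohort$event, X)
  cox <- survival::coxph(survival::Surv(cohort$time, cohort$event) ~ X,
                         ties = "efron")
  bh <- survival::basehaz(cox, centered = FALSE)
  h_ref <- max(bh$hazard[bh$time <= 3652])
  expect_equal(h0, h_ref, tolerance = 1e-6)

  # single-profile exponential data: H0(10y) ~ 10 * lambda (years)
  set.seed(502)
  n <- 10000
  lam_year <- 0.03
  tt <- rexp(n, lam_year / 365.25)
  cens <- runif(n, 4000, 6200)
  event <- as.integer(tt <= cens)
  time <- pmin(ceiling(tt), cens)
  nullfit <- fit_ph(matrix(numeric(0), n, 0), time, event)
  h0e <- cumulative_baseline_hazard_10y(nullfit, time, event,
                                        matrix(numeric(0), n, 0))
  expect_lt(abs(h0e - 10 * lam_year) / (10 * lam_year), 0.05)

  # time-rescaling: doubling all follow-up times halves H0 at a fixed
  # horizon (exactly at 2t, approximately at t for constant hazard)
  h_t <- cumulative_baseline_hazard_10y(nullfit, time, event,
                                        matrix(numeric(0), n, 0), at = 1826)
  h_2x <- cumulative_baseline_hazard_10y(nullfit, 2 * time, event,
                                         matrix(numeric(0), n, 0), at = 3652)
  expect_equal(h_2x, h_t, tolerance = 1e-12)
  expect_lt(abs(h_2x - h0e / 2) / (h0e / 2), 0.1)

  # no events before the horizon
  expect_warning(
    h00 <- cumulative_baseline_hazard_10y(nullfit, rep(9000, n), rep(0L, n),
                                          matrix(numeric(0), n, 0)),
    "no events")
  expect_equal(h00, 0)
})

test_that("absolute risk follows 1 - exp(-exp(lp) * H0)", {
  cohort <- fx_small_cohort()
  X <- encode_design(cohort, model_spec("gail_bmi"))
  fit <- fit_ph(X, cohort$time, cohort$event)
  fit$H0_10y <- 0.0282
  r <- absolute_risk_10y(fit, X)
  ref_row <- X[1, , drop = FALSE] * 0
  expect_equal(absolute_risk_10y(fit, ref_row), 1 - exp(-0.0282))
  # monotone in the linear predictor
  lp <- drop(X %*% fit$coefficients)
  expect_identical(order(lp), order(r))
  fit$H0_10y <- 0
  expect_equal(absolute_risk_10y(fit, X), rep(0, nrow(X)))
})

test_that("model-3 risk is increasing in GRS, all else fixed", {
  run <- fx_full_model_run()
  fit <- run$reps[[1]]$fit
  cohort <- run$cohort
  grs_grid <- seq(3, 6.5, by = 0.25)
  X <- encode_design(cohort[rep(1, length(grs_grid)), ],
                     model_spec("gail_bmi_density_grs"), grs = grs_grid)
  r <- absolute_risk_10y(fit, X)
  expect_true(all(diff(r) > 0))
})

test_that("Schoenfeld residual test holds its size and detects violations", {
  # type-I error near nominal under exact proportional hazards
  n_reject <- 0L
  n_rep <- 200L
  set.seed(503)
  for (i in seq_len(n_rep)) {
    n <- 400
    x <- cbind(a = rbinom(n, 1, 0.5), b = rnorm(n))
    tt <- rexp(n, 0.1 * exp(0.4 * x[, "a"]))
    cens <- runif(n, 5, 20)
    event <- as.integer(tt <= cens)
    time <- pmin(tt, cens)
    fit <- fit_ph(x, time, event)
    tab <- schoenfeld_ph_check(fit, x, time, event)
    if (tab$p[tab$term == "GLOBAL"] < 0.05) n_reject <- n_reject + 1L
  }
  expect_lt(abs(n_reject / n_rep - 0.05), 0.03)

  # power: an effect that reverses sign over time is detected
  set.seed(504)
  hits <- 0L
  for (i in 1:10) {
    n <- 5000
    x <- rbinom(n, 1, 0.5)
    # piecewise hazard: HR e^1 before t = 5, e^-1 after
    t1 <- rexp(n, 0.08 * exp(1 * x))
    t2 <- 5 + rexp(n, 0.08 * exp(-1 * x))
    tt <- ifelse(t1 <= 5, t1, t2)
    cens <- runif(n, 8, 20)
    event <- as.integer(tt <= cens)
    time <- pmin(tt, cens)
    fit <- fit_ph(cbind(x = x), time, event)
    tab <- schoenfeld_ph_check(fit, cbind(x = x), time, event)
    if (tab$p[tab$term == "GLOBAL"] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 10, 0.8)
})

test_that("hazard-ratio table is the exponential of the coefficients", {
  cohort <- fx_small_cohort()
  X <- encode_design(cohort, model_spec("gail_bmi"))
  fit <- fit_ph(X, cohort$time, cohort$event)
  tab <- hr_table(fit)
  expect_equal(tab$hr, unname(exp(fit$coefficients)), tolerance = 1e-12)
  expect_true(all(tab$lo < tab$hr & tab$hr < tab$hi))
})
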