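# Coefficient refitting, cohort mean linear predictor, Breslow baseline
# survival, recalibration modes, SCORE diabetes adjustment.

test_that("refit recovers the generating coefficients within sampling error", {
  set.seed(101)
  spec <- make_two_term_spec(b_age = 0.5 / 10, b_sbp = -0.3 / 10,
                             mean_lp = 0.05 * 52.5 - 0.03 * 140)
  d <- as_cohort(simulate_from_spec(spec, 8000, lambda0 = 0.01))
  fit <- refit_coefficients(d, spec)
  truth <- c(0.05, -0.03)
  expect_equal(fit$coefficient, truth, tolerance = 3 * max(fit$se) / max(abs(truth)))
  for (i in 1:2)
    expect_lt(abs(fit$coefficient[i] - truth[i]), 3 * fit$se[i])
})

test_that("null data yield null coefficients within 3 SE", {
  set.seed(102)
  spec <- make_two_term_spec(b_age = 0, b_sbp = 0, mean_lp = 0)
  d <- as_cohort(simulate_from_spec(spec, 6000, lambda0 = 0.01))
  fit <- refit_coefficients(d, spec)
  expect_true(all(abs(fit$coefficient) < 3 * fit$se))
})

test_that("exponential single-binary-covariate fit approximates the log rate ratio", {
  set.seed(103)
  n <- 6000
  x <- rbinom(n, 1, 0.5)
  rate <- 0.05 * exp(0.7 * x)
  t_ev <- rexp(n, rate)
  d <- as_cohort(data.frame(
    id = seq_len(n), sex = "male", age = x,           # age column carries the flag
    sbp = runif(n, 100, 180),                         # null covariate

    followup_years = pmin(t_ev, 10), cvd_death = as.integer(t_ev <= 10),
    all_cause_death = as.integer(t_ev <= 10)))
  spec <- make_two_term_spec(b_age = 0, b_sbp = 0, mean_lp = 0)
  fit <- refit_coefficients(d, spec)
  b <- fit$coefficient[1]
  # closed-form exponential MLE of the log rate ratio
  py1 <- sum(d$followup_years[x == 1]); d1 <- sum(d$cvd_death[x == 1])
  py0 <- sum(d$followup_years[x == 0]); d0 <- sum(d$cvd_death[x == 0])
  mle <- log((d1 / py1) / (d0 / py0))
  expect_equal(b, mle, tolerance = 0.05)
  expect_equal(b, 0.7, tolerance = 0.1)
})

test_that("too few events or degenerate designs are refused", {
  spec <- make_two_term_spec()
  d <- as_cohort(simulate_from_spec(spec, 50, lambda0 = 0.001))
  expect_validation_error(refit_coefficients(d, spec, min_events = 30), "events")
})

test_that("cohort mean linear predictor is the mean of per-row predictors", {
  spec <- make_two_term_spec()
  d <- make_test_cohort(100)
  men <- d[d$sex == "male", ]
  expect_equal(mean_lp(d, spec),
               mean(vapply(seq_len(nrow(men)),
                           function(i) linear_predictor(men[i, ], spec), 0)))
  # identical rows: mean equals the single profile's predictor
  one <- d[rep(which(d$sex == "male")[1], 5), ]; one$id <- paste0("i", 1:5)
  expect_equal(mean_lp(one, spec), linear_predictor(one[1, ], spec))
  # zero-coefficient spec
  spec0 <- make_two_term_spec(b_age = 0, b_sbp = 0, mean_lp = 0)
  expect_equal(mean_lp(d, spec0), 0)
})

test_that("Breslow cumulative hazard agrees with survival::basehaz", {
  set.seed(104)
  spec <- make_two_term_spec()
  d <- simulate_from_spec(spec, 500, lambda0 = 0.01)
  lp <- linear_predictor(d, spec) - spec$mean_lp
  fit <- survival::coxph(survival::Surv(followup_years, cvd_death) ~
                           offset(lp), data = d)
  # survfit centers an offset-only model at the mean offset, so compare
  # against the Breslow estimate on mean-centered predictors
  bh <- survival::basehaz(fit, centered = FALSE)
  for (t in c(2, 4, 5.9)) {
    expect_equal(breslow_cumhaz(d$followup_years, d$cvd_death, lp - mean(lp), t),
                 max(bh$hazard[bh$time <= t]), tolerance = 1e-10)
  }
})

test_that("baseline survival reduces to KM under a null model and recovers known S0", {
  set.seed(105)
  spec0 <- make_two_term_spec(b_age = 0, b_sbp = 0, mean_lp = 0)
  d <- as_cohort(simulate_from_spec(spec0, 4000, lambda0 = 0.02))
  s0 <- baseline_survival_at(d, spec0, 5)
  km <- km_estimate(d$followup_years, d$cvd_death, 5)
  expect_equal(s0, km$survival, tolerance = 0.01)
  # with real covariate effects: recover the generating S0(5) = exp(-5*lambda0)
  # (spec mean LP set to the simulated population mean so the centered
  # baseline coincides with the generating one)
  set.seed(106)
  spec <- make_two_term_spec(mean_lp = 0.08 * 52.5 + 0.015 * 140)
  d2 <- as_cohort(simulate_from_spec(spec, 20000, lambda0 = 0.01))
  s0_hat <- baseline_survival_at(d2, spec, 5)
  expect_equal(s0_hat, exp(-0.05), tolerance = 0.01)
  # monotone in the horizon
  expect_gte(baseline_survival_at(d2, spec, 4), s0_hat)
  expect_validation_error(baseline_survival_at(d2, spec, 50), "exceeds")
})

test_that("mean-only recalibration is a fixed point on data from the spec itself", {
  set.seed(107)
  # mean LP set to the simulated population's true mean (age ~ U(40, 65),
  # sbp ~ U(100, 180)) so the spec's published mean is the cohort's own
  spec <- make_two_term_spec(s5 = exp(-0.05),
                             mean_lp = 0.08 * 52.5 + 0.015 * 140)
  d <- as_cohort(simulate_from_spec(spec, 20000, lambda0 = 0.01))
  rec <- recalibrate(d, spec, mode = "mean_only", h = 5)
  # coefficients untouched
  expect_equal(vapply(rec$terms, `[[`, 0, "coefficient"),
               vapply(spec$terms, `[[`, 0, "coefficient"))
  # mean LP and baseline survival reproduce the generating values
  expect_equal(rec$mean_lp, spec$mean_lp, tolerance = 0.02)
  expect_equal(rec$baseline_survival[["5"]], exp(-0.05), tolerance = 0.005)
  prov <- attr(rec, "provenance")
  expect_identical(prov$mode, "mean_only")
  expect_identical(prov$n, sum(d$sex == "male"))
  expect_silent(validate_model_spec(rec))
})

test_that("full self-recalibration leaves per-subject risks nearly unchanged", {
  set.seed(108)
  # event rate chosen to emulate the low-mortality setting the models are
  # used in (~2% five-year baseline risk)
  spec <- make_two_term_spec(s5 = exp(-0.02))
  d <- as_cohort(simulate_from_spec(spec, 20000, lambda0 = 0.004))
  rec <- recalibrate(d, spec, mode = "full", h = 5)
  r_orig <- cox_form_risk(d, spec, horizon = 5)
  r_rec <- cox_form_risk(d, rec, horizon = 5)
  expect_lt(median(abs(r_rec - r_orig)), 0.002)
  # modes agree exactly when the supplied coefficients equal the refit ones
  refit <- refit_coefficients(d, spec)
  spec_refit <- spec
  for (i in seq_along(spec_refit$terms))
    spec_refit$terms[[i]]$coefficient <- refit$coefficient[i]
  rec_mean <- recalibrate(d, spec_refit, mode = "mean_only", h = 5)
  expect_equal(rec$mean_lp, rec_mean$mean_lp, tolerance = 1e-8)
  expect_equal(rec$baseline_survival[["5"]], rec_mean$baseline_survival[["5"]],
               tolerance = 1e-8)
})

test_that("SCORE adjustment attaches the x3/x5 multiplier and changes only diabetic risk", {
  spec <- builtin_score_specs_synthetic()[["score_high_women_synthetic"]]
  adj <- adjust_score_spec(spec)
  expect_equal(adj$diabetes_multiplier, c(male = 3, female = 5))
  expect_warning(adjust_score_spec(spec, c(male = 0.5, female = 1)), "below 1")
  p <- data.frame(sex = "female", age = 55, total_cholesterol = 5, sbp = 140,
                  current_smoker = 0, diabetes = 0)
  p_dm <- transform(p, diabetes = 1)
  r0 <- weibull_score_risk(p, adj, 10, diabetes_adjust = TRUE)
  r1 <- weibull_score_risk(p_dm, adj, 10, diabetes_adjust = TRUE)
  expect_equal(r1, pmin(1, 5 * r0))
  # neutral multipliers change nothing
  neutral <- suppressWarnings(adjust_score_spec(spec, c(male = 1, female = 1)))
  expect_equal(weibull_score_risk(p_dm, neutral, 10, diabetes_adjust = TRUE),
               weibull_score_risk(p_dm, spec, 10, diabetes_adjust = FALSE))
  expect_validation_error(adjust_score_spec(make_two_term_spec()), "weibull")
})

test_that("recalibrate refuses weibull_score specs", {
  spec <- builtin_score_specs_synthetic()[[1L]]
  d <- as_cohort(make_test_cohort(40))
  expect_validation_error(recalibrate(d, spec), "adjust_score_spec")
})
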