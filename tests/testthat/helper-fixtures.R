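# Shared fixtures, built in code.

# minimal two-term proportional-hazards spec on age and sbp (identity
# transforms, canonical units) with a known baseline survival
make_two_term_spec <- function(sex = "male", b_age = 0.08, b_sbp = 0.015,
                               mean_lp = 0.08 * 52 + 0.015 * 126,
                               s5 = 0.96) {
  model_spec(
    model_id = "two-term-test", sex = sex, family = "cox_form",
    terms = list(risk_term("age", "identity", b_age),
                 risk_term("sbp", "identity", b_sbp)),
    mean_lp = mean_lp, baseline_survival = list("5" = s5),
    native_horizon = 5, thresholds = c(0.1, 0.2),
    categories = c("low", "intermediate", "high"))
}

# small cohort with all engine covariates; outcomes are arbitrary unless
# a generator config is used instead
make_test_cohort <- function(n = 50, seed = 7) {
  set.seed(seed)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  data.frame(
    id = sprintf("P%03d", seq_len(n)),
    sex = sex,
    age = runif(n, 40, 65),
    total_cholesterol = runif(n, 3, 7),
    hdl = runif(n, 0.7, 2),
    glucose = runif(n, 4, 9),
    sbp = runif(n, 100, 180),
    bp_treated = rbinom(n, 1, 0.2),
    current_smoker = rbinom(n, 1, 0.3),
    diabetes = rbinom(n, 1, 0.1),
    bmi = runif(n, 18, 32),
    followup_years = runif(n, 0.5, 6),
    cvd_death = rbinom(n, 1, 0.2)
  ) |>
    transform(all_cause_death = pmax(cvd_death, rbinom(n, 1, 0.1)))
}

# simulate survival data from a two-term spec so the spec is exactly true:
# S0(t) = exp(-lambda0 * t), T = -log(U)/(lambda0 * exp(L - Lbar))
simulate_from_spec <- function(spec, n, lambda0, censor_at = 6,
                               loss_rate = 0) {
  sex <- spec$sex
  d <- data.frame(
    id = seq_len(n), sex = sex,
    age = runif(n, 40, 65),
    sbp = runif(n, 100, 180))
  lp <- linear_predictor(d, spec)
  t_ev <- -log(runif(n)) / (lambda0 * exp(lp - spec$mean_lp))
  t_cen <- if (loss_rate > 0) pmin(rexp(n, loss_rate), censor_at) else censor_at
  d$followup_years <- pmin(t_ev, t_cen)
  d$cvd_death <- as.integer(t_ev <= t_cen)
  d$all_cause_death <- d$cvd_death
  d
}

expect_validation_error <- function(expr, pattern = NULL) {
  expect_error(expr, regexp = pattern, class = "riskrecal_validation_error")
}
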