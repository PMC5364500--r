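# Scoring engine: absolute CVD-mortality risk for a profile under a spec.
#
# Profiles/cohorts use canonical units: lipids and glucose in mmol/L, SBP
# in mmHg, BMI in kg/m^2, age in years. Equations expecting mg/dL declare
# that in spec$units and values are converted at the term boundary.

# mg/dL per mmol/L; cholesterol MW 386.65 g/mol / 10, glucose 180.16 / 10
.UNIT_FACTORS <- c(TC = 38.67, HDL = 38.67, glucose = 18.02)

#' Convert lipid/glucose concentrations between mmol/L and mg/dL
#'
#' @param value positive concentration(s) in the unit system opposite to
#'   `target`.
#' @param quantity `"TC"`, `"HDL"` or `"glucose"`.
#' @param target `"mg/dL"` or `"mmol/L"`.
#' @return converted value(s). Conversion factors: 38.67 mg/dL per mmol/L
#'   for cholesterol, 18.02 for glucose.
#' @export
#' @examples
#' convert_units(1, "TC", "mg/dL")     # 38.67
#' convert_units(5, "glucose", "mg/dL") # 90.1
convert_units <- function(value, quantity = c("TC", "HDL", "glucose"),
                          target = c("mg/dL", "mmol/L")) {
  quantity <- match.arg(quantity)
  target <- match.arg(target)
  if (any(value <= 0)) stop_validation("concentrations must be positive")
  f <- .UNIT_FACTORS[[quantity]]
  if (target == "mg/dL") value * f else value / f
}

# covariate name -> convert_units quantity, for spec$units handling
.QUANTITY_OF <- c(total_cholesterol = "TC", hdl = "HDL", glucose = "glucose")

#' @noRd
covariate_values <- function(data, covariate, units) {
  if (!covariate %in% names(data))
    stop_validation("profile is missing covariate '%s'", covariate)
  v <- as.numeric(data[[covariate]])
  unit <- units[[covariate]]
  if (!is.null(unit) && unit == "mg/dL" && covariate %in% names(.QUANTITY_OF))
    v <- convert_units(v, .QUANTITY_OF[[covariate]], "mg/dL")
  v
}

#' @noRd
transformed_value <- function(data, covariate, transform, units) {
  v <- covariate_values(data, covariate, units)
  if (transform == "log") {
    if (any(v <= 0, na.rm = TRUE))
      stop_validation("non-positive value for log-transformed covariate '%s'", covariate)
    v <- log(v)
  }
  v
}

#' @noRd
condition_indicator <- function(data, condition) {
  if (is.null(condition)) return(1)
  if (!"bp_treated" %in% names(data))
    stop_validation("profile is missing covariate 'bp_treated' required by a conditional term")
  trt <- as.numeric(data[["bp_treated"]]) != 0
  if (condition == "bp_treated") as.numeric(trt) else as.numeric(!trt)
}

#' Evaluate the linear predictor of a proportional-hazards risk equation
#'
#' Sums `coefficient * f(x)` over the spec's terms: log terms on
#' unit-converted values, band terms contribute the matching band's
#' coefficient, product terms multiply two transformed covariates, and
#' conditional terms (treated/untreated blood pressure) apply only when
#' their predicate holds.
#'
#' @param profile a one-row data.frame/list, or a whole cohort table
#'   (vectorized).
#' @param spec a `cox_form` [model_spec()].
#' @return numeric vector of linear predictors, one per row.
#' @export
linear_predictor <- function(profile, spec) {
  if (spec$family != "cox_form")
    stop_validation("linear_predictor requires a cox_form spec")
  data <- as.data.frame(profile)
  n <- nrow(data)
  lp <- numeric(n)
  for (term in spec$terms) {
    contrib <- switch(term$transform,
      identity = ,
      log = term$coefficient *
        transformed_value(data, term$covariate, term$transform, spec$units),
      bands = {
        v <- covariate_values(data, term$covariate, spec$units)
        b <- term$bands[order(term$bands$lo), , drop = FALSE]
        idx <- findInterval(v, b$lo)     # half-open [lo, hi)
        b$coefficient[idx]
      },
      product = {
        f1 <- term$factors[[1L]]
        f2 <- term$factors[[2L]]
        term$coefficient *
          transformed_value(data, f1$covariate, f1$transform, spec$units) *
          transformed_value(data, f2$covariate, f2$transform, spec$units)
      })
    lp <- lp + contrib * condition_indicator(data, term$condition)
  }
  lp
}

#' @noRd
baseline_survival_for <- function(spec, horizon, rescale) {
  key <- as.character(horizon)
  bs <- spec$baseline_survival
  avail <- as.numeric(names(bs))
  hit <- which(abs(avail - horizon) < 1e-9)
  if (length(hit)) return(as.numeric(bs[[hit[1L]]]))
  if (!rescale)
    stop_validation("spec '%s' has no baseline survival at horizon %s (set rescale = TRUE to use the constant-hazard-fraction rule)",
                    spec$model_id, key)
  native <- spec$native_horizon
  hit <- which(abs(avail - native) < 1e-9)
  if (!length(hit)) hit <- 1L
  rescale_baseline_survival(as.numeric(bs[[hit]]), avail[hit], horizon)
}

#' Absolute risk under a proportional-hazards risk equation
#'
#' Computes `risk = 1 - S0(h)^exp(L - Lbar)`, where `L` is the subject's
#' linear predictor, `Lbar` the spec's mean linear predictor and `S0(h)`
#' the baseline survival at the requested horizon; the result is clipped
#' to `[0, 1]`.
#'
#' @inheritParams linear_predictor
#' @param horizon prediction horizon in years; must be available in the
#'   spec's `baseline_survival` unless `rescale = TRUE`.
#' @param rescale allow [rescale_baseline_survival()] from the native
#'   horizon when `horizon` is absent from the spec.
#' @return numeric vector of risks in `[0, 1]`.
#' @export
cox_form_risk <- function(profile, spec, horizon = spec$native_horizon,
                          rescale = FALSE) {
  s0 <- baseline_survival_for(spec, horizon, rescale)
  lp <- linear_predictor(profile, spec)
  risk <- 1 - s0^exp(lp - spec$mean_lp)
  pmin(pmax(risk, 0), 1)
}

#' Absolute risk under a SCORE-style cause-specific Weibull equation
#'
#' Each cause (coronary and non-coronary CVD) has baseline survival
#' `S0(a) = exp(-exp(alpha) * (a - 20)^p)` in attained age `a`, and a
#' covariate shift `w = beta_tc*(TC - 6) + beta_sbp*(SBP - 120) +
#' beta_smoker*smoker` acting proportionally: `S(a) = S0(a)^exp(w)`.
#' The risk over a horizon `h` is `1 - S(a + h)/S(a)` per cause, summed
#' over the two causes and clipped to `[0, 1]`.
#'
#' @inheritParams linear_predictor
#' @param spec a `weibull_score` [model_spec()] (or any list with a
#'   `causes` element of that shape).
#' @param horizon horizon in years (>= 0).
#' @param diabetes_adjust apply the spec's diabetes multiplier (or the
#'   conventional x3 men / x5 women if the spec carries none).
#' @return numeric vector of risks in `[0, 1]`.
#' @export
weibull_score_risk <- function(profile, spec, horizon = 10,
                               diabetes_adjust = FALSE) {
  data <- as.data.frame(profile)
  for (nm in c("age", "total_cholesterol", "sbp", "current_smoker"))
    if (!nm %in% names(data))
      stop_validation("profile is missing covariate '%s'", nm)
  age <- as.numeric(data$age)
  if (any(age <= 20))
    stop_validation("weibull_score risk is undefined at age <= 20")
  if (horizon < 0) stop_validation("horizon must be >= 0")
  w <- 0
  total <- 0
  for (cause in spec$causes) {
    w <- cause$beta_tc * (as.numeric(data$total_cholesterol) - 6) +
      cause$beta_sbp * (as.numeric(data$sbp) - 120) +
      cause$beta_smoker * (as.numeric(data$current_smoker) != 0)
    s <- function(a) exp(-exp(cause$alpha) * (a - 20)^cause$p)^exp(w)
    total <- total + (1 - s(age + horizon) / s(age))
  }
  risk <- pmin(pmax(total, 0), 1)
  if (diabetes_adjust) {
    dm <- spec$diabetes_multiplier
    if (is.null(dm)) dm <- c(male = 3, female = 5)
    risk <- apply_diabetes_multiplier(risk, spec$sex, as.numeric(data$diabetes) != 0,
                                      multipliers = dm)
  }
  risk
}

#' Multiply predicted risk for diabetic subjects
#'
#' Diabetic subjects' predicted risk is scaled by a fixed factor (the
#' convention used here: x3 for men, x5 for women) and capped at 1;
#' non-diabetic risk is returned unchanged.
#'
#' @param risk risk(s) in `[0, 1]`.
#' @param sex `"male"` or `"female"` (scalar or vector).
#' @param diabetic logical/0-1 flag(s).
#' @param multipliers named vector `c(male=, female=)`.
#' @return adjusted risk(s), capped at 1.
#' @export
#' @examples
#' apply_diabetes_multiplier(0.02, "male", TRUE)  # 0.06
apply_diabetes_multiplier <- function(risk, sex, diabetic,
                                      multipliers = c(male = 3, female = 5)) {
  if (any(risk < 0 | risk > 1)) stop_validation("risk must lie in [0, 1]")
  m <- unname(multipliers[as.character(sex)])
  ifelse(as.logical(diabetic), pmin(1, m * risk), risk)
}

#' Rescale baseline survival to a different horizon
#'
#' Constant-hazard-fraction rule: `S0(h) = exp(log(S0(H)) * h / H)`, i.e.
#' the cumulative baseline hazard is assumed proportional to time. Used
#' e.g. to turn a 10-year baseline survival into a 5-year one. Cohort
#' recalibration ([baseline_survival_at()]) is the preferred alternative
#' when target-cohort data are available.
#'
#' @param s0_native baseline survival at the native horizon, in (0, 1).
#' @param native_h native horizon (years, > 0).
#' @param target_h target horizon (years, > 0).
#' @return baseline survival at `target_h`.
#' @export
#' @examples
#' rescale_baseline_survival(0.9604, 10, 5)  # 0.98
rescale_baseline_survival <- function(s0_native, native_h, target_h) {
  if (any(s0_native <= 0 | s0_native >= 1))
    stop_validation("s0_native must lie strictly in (0, 1)")
  if (native_h <= 0 || target_h <= 0)
    stop_validation("horizons must be positive")
  exp(log(s0_native) * target_h / native_h)
}

#' Score a whole cohort under one model spec
#'
#' Applies the spec's risk equation to every subject of the matching sex;
#' rows of the other sex get `NA` (score them with the paired spec).
#'
#' @param cohort a cohort table (see [as_cohort()]).
#' @param spec a [model_spec()].
#' @param horizon prediction horizon in years.
#' @param diabetes_adjust apply the diabetes multiplier
#'   (`weibull_score` family).
#' @param rescale allow baseline-survival rescaling (`cox_form` family).
#' @return numeric vector of length `nrow(cohort)`, named by subject id.
#' @export
score_cohort <- function(cohort, spec, horizon = spec$native_horizon,
                         diabetes_adjust = FALSE, rescale = FALSE) {
  data <- as.data.frame(cohort)
  out <- rep(NA_real_, nrow(data))
  sel <- data$sex == spec$sex
  if (any(sel)) {
    rows <- data[sel, , drop = FALSE]
    out[sel] <- tryCatch(
      if (spec$family == "cox_form") {
        cox_form_risk(rows, spec, horizon = horizon, rescale = rescale)
      } else {
        weibull_score_risk(rows, spec, horizon = horizon,
                           diabetes_adjust = diabetes_adjust)
      },
      riskrecal_validation_error = function(e) {
        stop_validation("scoring failed for model '%s' (subjects %s...): %s",
                        spec$model_id,
                        paste(head(data$id[sel], 3L), collapse = ", "),
                        conditionMessage(e))
      })
  }
  if (!is.null(data$id)) names(out) <- data$id
  out
}
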