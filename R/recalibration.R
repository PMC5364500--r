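# Recalibration: rebuild a risk equation's mean linear predictor and
# baseline survival from a target cohort (mean-only recalibration), or
# additionally refit the term coefficients by Cox partial likelihood
# (full recalibration), preserving the spec's covariate structure.

#' Design matrix realizing a spec's covariate structure
#'
#' One column per estimable quantity: plain/log/product/conditional
#' terms give their transformed (condition-masked) value; band terms
#' give one indicator column per non-referent band (the band with
#' coefficient 0 is the referent).
#'
#' @param cohort a `cohort_table` (rows of the spec's sex).
#' @param spec a `cox_form` [model_spec()].
#' @return numeric matrix; `attr(, "term_map")` maps columns back to
#'   term/band positions.
#' @keywords internal
#' @export
spec_design_matrix <- function(cohort, spec) {
  data <- as.data.frame(cohort)
  cols <- list()
  map <- list()
  for (ti in seq_along(spec$terms)) {
    term <- spec$terms[[ti]]
    cond <- condition_indicator(data, term$condition)
    if (term$transform == "bands") {
      b <- term$bands[order(term$bands$lo), , drop = FALSE]
      v <- covariate_values(data, term$covariate, spec$units)
      idx <- findInterval(v, b$lo)
      ref <- which(b$coefficient == 0)[1L]
      if (is.na(ref)) ref <- 1L
      for (bi in setdiff(seq_len(nrow(b)), ref)) {
        nm <- sprintf("%s_band[%s,%s)", term$covariate, b$lo[bi], b$hi[bi])
        cols[[nm]] <- as.numeric(idx == bi) * cond
        map[[nm]] <- list(term = ti, band = bi)
      }
    } else {
      x <- switch(term$transform,
        identity = ,
        log = transformed_value(data, term$covariate, term$transform, spec$units),
        product = {
          f1 <- term$factors[[1L]]; f2 <- term$factors[[2L]]
          transformed_value(data, f1$covariate, f1$transform, spec$units) *
            transformed_value(data, f2$covariate, f2$transform, spec$units)
        })
      nm <- paste0(
        if (term$transform == "product") {
          paste(vapply(term$factors, function(f)
            paste0(f$transform, "_", f$covariate), ""), collapse = "_x_")
        } else paste0(term$transform, "_", term$covariate),
        if (!is.null(term$condition)) paste0("_", term$condition) else "")
      cols[[nm]] <- x * cond
      map[[nm]] <- list(term = ti, band = NA_integer_)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  attr(X, "term_map") <- map
  X
}

#' Refit a spec's coefficients on a cohort (Cox partial likelihood)
#'
#' Fits a proportional-hazards model with exactly the spec's covariate
#' structure (same transforms, bands, interactions, treated/untreated
#' split) to the cohort's CVD-death outcome.
#'
#' @param cohort a `cohort_table`; only rows matching `spec$sex` are
#'   used.
#' @param spec a `cox_form` [model_spec()].
#' @param min_events minimum number of events required to attempt a fit.
#' @return data.frame with `column`, `coefficient`, `se`, plus the
#'   `coxph` fit in `attr(, "fit")`.
#' @export
refit_coefficients <- function(cohort, spec, min_events = 30) {
  if (spec$family != "cox_form")
    stop_validation("refit_coefficients requires a cox_form spec")
  data <- as.data.frame(cohort)
  data <- data[data$sex == spec$sex, , drop = FALSE]
  n_ev <- sum(as.numeric(data$cvd_death) %in% 1)
  if (n_ev < min_events)
    stop_validation("cohort has %d events for sex '%s'; %d required",
                    n_ev, spec$sex, min_events)
  X <- spec_design_matrix(data, spec)
  y <- survival::Surv(data$followup_years, as.numeric(data$cvd_death))
  fit <- tryCatch(
    survival::coxph(y ~ X),
    error = function(e) stop_numeric("Cox fit failed: %s", conditionMessage(e)),
    warning = function(w) stop_numeric("Cox fit did not converge cleanly: %s",
                                       conditionMessage(w)))
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(!is.finite(beta)) || any(abs(beta) > 50))
    stop_numeric("Cox fit shows separation or divergence (|coef| > 50)")
  out <- data.frame(column = colnames(X), coefficient = unname(beta),
                    se = unname(se))
  attr(out, "term_map") <- attr(X, "term_map")
  attr(out, "fit") <- fit
  out
}

#' @noRd
apply_refit_to_spec <- function(spec, refit) {
  map <- attr(refit, "term_map")
  for (i in seq_len(nrow(refit))) {
    m <- map[[refit$column[i]]]
    if (is.na(m$band)) {
      spec$terms[[m$term]]$coefficient <- refit$coefficient[i]
    } else {
      b <- spec$terms[[m$term]]$bands
      b <- b[order(b$lo), , drop = FALSE]
      b$coefficient[m$band] <- refit$coefficient[i]
      spec$terms[[m$term]]$bands <- b
    }
  }
  spec
}

#' Cohort mean linear predictor
#'
#' Mean over subjects (of the spec's sex) of the spec's linear
#' predictor — the quantity published as "Mean (Coefficient x Value)".
#'
#' @inheritParams refit_coefficients
#' @return scalar Lbar.
#' @export
mean_lp <- function(cohort, spec) {
  data <- as.data.frame(cohort)
  data <- data[data$sex == spec$sex, , drop = FALSE]
  if (!nrow(data)) stop_validation("no subjects of sex '%s'", spec$sex)
  mean(linear_predictor(data, spec))
}

#' Breslow cumulative baseline hazard
#'
#' `H0(t) = sum over event times u <= t of d_u / sum_{j at risk} exp(lp_j)`
#' (Breslow tie handling). The baseline refers to `lp = 0`; pass
#' centered linear predictors to obtain a centered baseline.
#'
#' @param times follow-up times.
#' @param events 0/1 event indicators.
#' @param lp per-subject linear predictors.
#' @param t evaluation time.
#' @return cumulative hazard at `t`.
#' @export
breslow_cumhaz <- function(times, events, lp, t) {
  stopifnot(length(times) == length(events), length(times) == length(lp))
  ev <- as.numeric(events) != 0
  ord <- order(times)
  ti <- times[ord]; ei <- ev[ord]; ri <- exp(lp[ord])
  # risk-set sums: subjects with time >= u
  rev_cum <- rev(cumsum(rev(ri)))
  ut <- unique(ti[ei & ti <= t])
  h0 <- 0
  for (u in ut) {
    at <- match(u, ti)               # first index with time == u (sorted)
    h0 <- h0 + sum(ei & ti == u) / rev_cum[at]
  }
  h0
}

#' Baseline survival at a horizon, centered at the cohort mean predictor
#'
#' Breslow estimate of the cumulative hazard, centered so that a subject
#' whose linear predictor equals the cohort mean `Lbar` has survival
#' `S0(h)`; this is the baseline the risk formula
#' `1 - S0(h)^exp(L - Lbar)` expects.
#'
#' @inheritParams refit_coefficients
#' @param h horizon in years; must not exceed the observed follow-up.
#' @param lp optional precomputed linear predictors (defaults to the
#'   spec's).
#' @return `S0(h)` in (0, 1].
#' @export
baseline_survival_at <- function(cohort, spec, h, lp = NULL) {
  data <- as.data.frame(cohort)
  data <- data[data$sex == spec$sex, , drop = FALSE]
  if (!nrow(data)) stop_validation("no subjects of sex '%s'", spec$sex)
  if (h > max(data$followup_years))
    stop_validation("horizon %g exceeds the observed follow-up (max %g)",
                    h, max(data$followup_years))
  if (is.null(lp)) lp <- linear_predictor(data, spec)
  lbar <- mean(lp)
  h0c <- breslow_cumhaz(data$followup_years, data$cvd_death, lp - lbar, h)
  exp(-h0c)
}

#' Recalibrate a risk equation to a cohort
#'
#' `mode = "mean_only"` keeps the original coefficients but replaces the
#' mean linear predictor and the baseline survival at `h` with values
#' estimated from the cohort; `mode = "full"` first refits all
#' coefficients by Cox partial likelihood and then recomputes both. The
#' result is a valid spec with `native_horizon = h` and provenance
#' metadata (mode, cohort size/hash, date) attached.
#'
#' @inheritParams refit_coefficients
#' @param mode `"mean_only"` or `"full"`.
#' @param h recalibration horizon in years.
#' @return a recalibrated `model_spec` with `attr(, "provenance")`.
#' @export
recalibrate <- function(cohort, spec, mode = c("mean_only", "full"), h = 5,
                        min_events = 30) {
  mode <- match.arg(mode)
  if (spec$family != "cox_form")
    stop_validation("recalibrate applies to cox_form specs; use adjust_score_spec for weibull_score")
  out <- spec
  refit <- NULL
  if (mode == "full") {
    refit <- refit_coefficients(cohort, spec, min_events = min_events)
    out <- apply_refit_to_spec(out, refit)
  }
  data <- as.data.frame(cohort)
  data <- data[data$sex == spec$sex, , drop = FALSE]
  lp <- linear_predictor(data, out)
  out$mean_lp <- mean(lp)
  s0 <- baseline_survival_at(data, out, h, lp = lp)
  out$baseline_survival <- setNames(list(s0), as.character(h))
  out$native_horizon <- h
  validate_model_spec(out)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(as.data.frame(cohort), tmp)
  attr(out, "provenance") <- list(
    mode = mode, horizon = h, n = nrow(data),
    n_events = sum(as.numeric(data$cvd_death) %in% 1),
    cohort_md5 = unname(tools::md5sum(tmp)),
    date = format(Sys.Date()),
    refit = refit)
  out
}

#' Attach a diabetes-multiplier rule to a SCORE-type spec
#'
#' The SCORE family carries no diabetes covariate; predicted risk for
#' diabetic subjects is instead multiplied by a fixed per-sex factor at
#' scoring time (here x3 for men, x5 for women by default).
#'
#' @param spec a `weibull_score` [model_spec()].
#' @param multipliers named vector `c(male=, female=)`.
#' @return the spec with `diabetes_multiplier` set.
#' @export
adjust_score_spec <- function(spec, multipliers = c(male = 3, female = 5)) {
  if (spec$family != "weibull_score")
    stop_validation("adjust_score_spec applies to weibull_score specs")
  if (any(multipliers < 1))
    warning("diabetes multiplier below 1 reduces risk for diabetic subjects")
  spec$diabetes_multiplier <- multipliers
  validate_model_spec(spec)
  spec
}
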