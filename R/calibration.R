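# Calibration: Kaplan-Meier-adjusted observed risk per predicted-risk
# group, decile formation with small-group collapsing, and the
# Greenwood-Nam-D'Agostino (GND) chi-square test.

#' Kaplan-Meier survival and Greenwood variance at a time point
#'
#' Product-limit estimate via [survival::survfit()]; the variance is the
#' Greenwood estimate of `Var(S(t))`. Beyond the last observed time the
#' last value is carried forward.
#'
#' @param times positive follow-up times.
#' @param events 0/1 event indicators.
#' @param t evaluation time (>= 0).
#' @return list with `survival` and `greenwood_var`.
#' @export
km_estimate <- function(times, events, t) {
  if (length(times) == 0L) stop_validation("km_estimate needs a non-empty sample")
  if (any(times <= 0)) stop_validation("times must be positive")
  if (t < 0) stop_validation("t must be >= 0")
  fit <- survival::survfit(survival::Surv(times, as.numeric(events) != 0) ~ 1)
  s <- summary(fit, times = t, extend = TRUE)
  v <- s$std.err^2
  if (!is.finite(v)) v <- 0   # S reached 0: Greenwood formula degenerates
  list(survival = as.numeric(s$surv), greenwood_var = as.numeric(v))
}

#' Form calibration risk groups by decile collapsing
#'
#' Subjects are split into `init_groups` quantile groups of predicted
#' risk (tied predictions stay together). Any group observing fewer than
#' `min_events` events by the horizon is merged into the adjacent
#' neighbour whose mean predicted risk is closer (edge groups merge
#' inward); the lowest-risk violating group is processed first, and
#' merging repeats until every group meets the minimum. Groups remain
#' contiguous in risk order.
#'
#' @param predicted per-subject predicted risks for the horizon.
#' @param times,events follow-up times (years) and 0/1 CVD-death
#'   indicators.
#' @param h evaluation horizon in years.
#' @param init_groups initial number of quantile groups (deciles).
#' @param min_events minimum observed events per final group.
#' @return object of class `"risk_groups"`: a data.frame with one row
#'   per group (`n`, `mean_predicted`, `km_observed`, `greenwood_var`,
#'   `observed_events`, `expected_events`) ordered by mean predicted
#'   risk, with group member indices in `attr(, "members")`.
#' @export
form_groups <- function(predicted, times, events, h, init_groups = 10,
                        min_events = 2) {
  stopifnot(length(predicted) == length(times),
            length(predicted) == length(events))
  ev <- as.numeric(events) != 0
  ev_h <- ev & times <= h
  if (sum(ev_h) < min_events)
    stop_validation("fewer than min_events = %d events observed by horizon %g",
                    min_events, h)
  breaks <- unique(quantile(predicted, probs = seq(0, 1, length.out = init_groups + 1)))
  grp <- if (length(breaks) < 2L) {
    rep(1L, length(predicted))
  } else {
    cut(predicted, breaks, include.lowest = TRUE, labels = FALSE)
  }
  members <- split(seq_along(predicted), grp)          # ascending risk order
  repeat {
    n_ev <- vapply(members, function(i) sum(ev_h[i]), 0)
    bad <- which(n_ev < min_events)
    if (!length(bad) || length(members) == 1L) break
    g <- bad[1L]
    G <- length(members)
    mp <- vapply(members, function(i) mean(predicted[i]), 0)
    nb <- if (g == 1L) 2L
          else if (g == G) G - 1L
          else if (abs(mp[g - 1L] - mp[g]) <= abs(mp[g + 1L] - mp[g])) g - 1L
          else g + 1L
    members[[min(g, nb)]] <- c(members[[min(g, nb)]], members[[max(g, nb)]])
    members[[max(g, nb)]] <- NULL
  }
  rows <- lapply(members, function(i) {
    km <- km_estimate(times[i], ev[i], h)
    data.frame(n = length(i),
               mean_predicted = mean(predicted[i]),
               km_observed = 1 - km$survival,
               greenwood_var = km$greenwood_var,
               observed_events = sum(ev_h[i]),
               expected_events = length(i) * mean(predicted[i]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "members") <- unname(members)
  attr(out, "horizon") <- h
  class(out) <- c("risk_groups", "data.frame")
  out
}

#' Greenwood-Nam-D'Agostino calibration test
#'
#' Compares Kaplan-Meier observed risk with mean predicted risk across
#' risk groups: `chi2 = sum_g (km_observed_g - mean_predicted_g)^2 /
#' greenwood_var_g`, referred to a chi-square distribution with `G - 1`
#' degrees of freedom. Groups with zero Kaplan-Meier variance are
#' excluded with a warning.
#'
#' @param groups a `"risk_groups"` object from [form_groups()] (any
#'   data.frame with columns `mean_predicted`, `km_observed`,
#'   `greenwood_var` works).
#' @param variance `"greenwood"` (default) uses the Kaplan-Meier
#'   Greenwood variance; `"binomial"` uses `p(1-p)/n` with
#'   `p = mean_predicted` (requires an `n` column).
#' @return object of class `"gnd_result"`: list with `chi2`, `groups`,
#'   `df`, `p_value`, `variance`.
#' @export
gnd_test <- function(groups, variance = c("greenwood", "binomial")) {
  variance <- match.arg(variance)
  g <- as.data.frame(groups)
  if (nrow(g) < 2L)
    stop_validation("gnd_test requires at least two risk groups")
  v <- if (variance == "greenwood") {
    g$greenwood_var
  } else {
    g$mean_predicted * (1 - g$mean_predicted) / g$n
  }
  use <- v > 0
  if (sum(use) < 2L)
    stop_validation("fewer than two groups with positive variance")
  if (any(!use))
    warning(sprintf("%d group(s) with zero variance excluded from the GND statistic",
                    sum(!use)))
  chi2 <- sum((g$km_observed[use] - g$mean_predicted[use])^2 / v[use])
  G <- sum(use)
  structure(list(chi2 = chi2, groups = G, df = G - 1L,
                 p_value = gnd_pvalue(chi2, G), variance = variance),
            class = "gnd_result")
}

#' GND p-value for a given statistic and group count
#'
#' Upper-tail chi-square probability with `n_groups - 1` degrees of
#' freedom (the test's degrees-of-freedom convention).
#'
#' @param chi2 test statistic (>= 0).
#' @param n_groups number of risk groups G.
#' @return p-value.
#' @export
#' @examples
#' gnd_pvalue(5.109, 5)  # 0.276
gnd_pvalue <- function(chi2, n_groups) {
  if (chi2 < 0) stop_validation("chi2 must be >= 0")
  if (n_groups < 2) stop_validation("n_groups must be >= 2")
  pchisq(chi2, df = n_groups - 1, lower.tail = FALSE)
}

#' @export
print.gnd_result <- function(x, ...) {
  cat(sprintf("Greenwood-Nam-D'Agostino: chi2 = %.3f on %d df (G = %d), P = %.3f [%s variance]\n",
              x$chi2, x$df, x$groups, x$p_value, x$variance))
  invisible(x)
}

#' Observed and expected event counts per calibration group
#'
#' Observed events are Kaplan-Meier adjusted (`n * km_observed`);
#' expected events are `n * mean_predicted`. Exported in risk order for
#' calibration plotting.
#'
#' @param groups a `"risk_groups"` object.
#' @return data.frame with `group`, `n`, `observed`, `expected`,
#'   `mean_predicted`, `km_observed`.
#' @export
calibration_chart_data <- function(groups) {
  g <- as.data.frame(groups)
  if (nrow(g) == 0L) stop_validation("no groups supplied")
  data.frame(group = seq_len(nrow(g)), n = g$n,
             observed = g$n * g$km_observed,
             expected = g$n * g$mean_predicted,
             mean_predicted = g$mean_predicted,
             km_observed = g$km_observed)
}
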