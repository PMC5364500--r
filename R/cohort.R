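# Cohort data model, CSV I/O, eligibility filtering and descriptive
# summaries.

COHORT_REQUIRED <- c("id", "sex", "age", "followup_years", "cvd_death",
                     "all_cause_death")
COHORT_RISK_FACTORS <- c("age", "total_cholesterol", "hdl", "glucose", "sbp",
                         "bp_treated", "current_smoker", "diabetes", "bmi")
COHORT_FLAG_COLS <- c("bp_treated", "current_smoker", "diabetes", "cvd_death",
                      "all_cause_death", "hypertension", "lost_followup",
                      "prior_cvd", "cancer", "ckd", "missing_model_inputs")

#' Coerce and validate a cohort table
#'
#' A cohort table holds one row per subject: an identifier, sex, the
#' risk-factor profile (canonical units: mmol/L, mmHg, kg/m^2, years),
#' follow-up time in years and death indicators, plus optional
#' eligibility flags (`lost_followup`, `prior_cvd`, `cancer`, `ckd`,
#' `missing_model_inputs`) and an optional `hypertension` flag.
#'
#' Validated invariants: unique ids, positive follow-up, sex in
#' male/female, 0/1 flags, and `cvd_death` implying `all_cause_death`.
#'
#' @param x a data.frame.
#' @return the table with class `"cohort_table"`.
#' @export
as_cohort <- function(x) {
  x <- as.data.frame(x)
  missing_cols <- setdiff(COHORT_REQUIRED, names(x))
  if (length(missing_cols))
    stop_validation("cohort is missing mandatory column(s): %s",
                    paste(missing_cols, collapse = ", "))
  if (anyDuplicated(x$id))
    stop_validation("duplicate subject ids: %s",
                    paste(head(unique(x$id[duplicated(x$id)]), 5L), collapse = ", "))
  if (!all(x$sex %in% VALID_SEX))
    stop_validation("sex must be 'male' or 'female'")
  for (col in intersect(COHORT_FLAG_COLS, names(x))) {
    v <- x[[col]]
    if (is.logical(v)) x[[col]] <- as.integer(v)
    else if (!all(is.na(v) | v %in% c(0, 1)))
      stop_validation("column '%s' must be a 0/1 flag", col)
  }
  bad <- which(!is.na(x$followup_years) & x$followup_years <= 0)
  if (length(bad))
    stop_validation("followup_years must be positive (rows %s)",
                    paste(head(bad, 5L), collapse = ", "))
  bad <- which(x$cvd_death == 1 & x$all_cause_death == 0)
  if (length(bad))
    stop_validation("cvd_death implies all_cause_death; violated at rows %s",
                    paste(head(bad, 5L), collapse = ", "))
  class(x) <- c("cohort_table", "data.frame")
  x
}

#' Read / write a cohort CSV
#'
#' The CSV uses the documented column names; missing values are empty
#' cells; lines starting with `#` (the units annotation written by
#' `write_cohort`) are ignored on read.
#'
#' @param path file path.
#' @return `read_cohort`: a validated `cohort_table`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_validation("cohort file not found: %s", path)
  x <- tryCatch(
    read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop_validation("could not parse %s: %s", path,
                                        conditionMessage(e)))
  tryCatch(as_cohort(x), riskrecal_validation_error = function(e)
    stop_validation("%s: %s", path, conditionMessage(e)))
}

#' @rdname read_cohort
#' @param cohort a `cohort_table`.
#' @param units_comment write a leading `#` comment line documenting units.
#' @export
write_cohort <- function(cohort, path, units_comment = TRUE) {
  cohort <- as_cohort(cohort)
  if (units_comment) {
    writeLines(paste("# units: lipids/glucose mmol/L, sbp mmHg, bmi kg/m2,",
                     "age/followup years; flags 0/1"), path)
    suppressWarnings(write.table(cohort, path, sep = ",", row.names = FALSE,
                                 append = TRUE, quote = FALSE))
  } else {
    write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Apply the eligibility cascade and record a flow ledger
#'
#' Exclusions are applied sequentially — age below range, age above
#' range, lost to follow-up, prevalent disease (prior CVD, cancer or
#' chronic kidney disease), missing model inputs — and the count removed
#' at each step is recorded, so `initial - sum(excluded) = final`.
#' Flag columns that are absent are treated as all-zero.
#'
#' @param cohort a `cohort_table` (may carry the optional flag columns).
#' @param age_range inclusive eligible age range in years.
#' @return list with `cohort` (the eligible subset) and `ledger` (a
#'   data.frame of step, excluded, remaining).
#' @export
eligibility_filter <- function(cohort, age_range = c(40, 65)) {
  x <- as.data.frame(cohort)
  flag <- function(col) {
    if (col %in% names(x)) as.numeric(x[[col]]) %in% 1 else rep(FALSE, nrow(x))
  }
  steps <- list(
    age_below_range = x$age < age_range[1L],
    age_above_range = x$age > age_range[2L],
    lost_to_followup = flag("lost_followup"),
    prevalent_disease = flag("prior_cvd") | flag("cancer") | flag("ckd"),
    missing_model_inputs = flag("missing_model_inputs")
  )
  keep <- rep(TRUE, nrow(x))
  excluded <- integer(length(steps))
  for (i in seq_along(steps)) {
    drop <- keep & steps[[i]]
    excluded[i] <- sum(drop)
    keep <- keep & !drop
  }
  ledger <- data.frame(
    step = c("initial", names(steps)),
    excluded = c(0L, excluded),
    remaining = c(nrow(x), nrow(x) - cumsum(excluded))
  )
  out <- x[keep, , drop = FALSE]
  class(out) <- c("cohort_table", "data.frame")
  list(cohort = out, ledger = ledger)
}

#' Descriptive cohort summary (by sex and overall)
#'
#' Mean and SD for the continuous risk factors; count and percent for the
#' binary ones; percent treated among hypertensive subjects when a
#' hypertension flag is available (derived as SBP >= 140 or treated when
#' the column is absent). Percentages use half-up rounding to 2 decimals.
#'
#' @param cohort a non-empty `cohort_table`.
#' @return list of class `"cohort_summary"` with elements `n`,
#'   `continuous`, `categorical` and `treated_among_hypertensive`.
#' @export
summarize_cohort <- function(cohort) {
  x <- as.data.frame(cohort)
  if (nrow(x) == 0L) stop_validation("cannot summarize an empty cohort")
  male <- x$sex == "male"
  n <- c(overall = nrow(x), men = sum(male), women = sum(!male))
  pct <- c(overall = 100, men = round_half_up(100 * sum(male) / nrow(x), 2),
           women = round_half_up(100 * sum(!male) / nrow(x), 2))

  cont_vars <- intersect(c("age", "total_cholesterol", "hdl", "glucose",
                           "sbp", "bmi", "followup_years"), names(x))
  stat <- function(v, sel) c(mean(v[sel], na.rm = TRUE), sd(v[sel], na.rm = TRUE))
  continuous <- do.call(rbind, lapply(cont_vars, function(cv) {
    v <- as.numeric(x[[cv]])
    data.frame(variable = cv,
               overall_mean = mean(v, na.rm = TRUE), overall_sd = sd(v, na.rm = TRUE),
               men_mean = stat(v, male)[1L], men_sd = stat(v, male)[2L],
               women_mean = stat(v, !male)[1L], women_sd = stat(v, !male)[2L])
  }))

  htn <- if ("hypertension" %in% names(x)) {
    as.numeric(x$hypertension) %in% 1
  } else if (all(c("sbp", "bp_treated") %in% names(x))) {
    x$sbp >= 140 | as.numeric(x$bp_treated) %in% 1
  } else NULL

  cat_vars <- intersect(c("current_smoker", "diabetes", "bp_treated"), names(x))
  count_row <- function(flagv, label) {
    f <- as.numeric(flagv) %in% 1
    data.frame(variable = label,
               overall_n = sum(f), overall_pct = round_half_up(100 * mean(f), 2),
               men_n = sum(f & male),
               men_pct = round_half_up(100 * sum(f & male) / max(sum(male), 1L), 2),
               women_n = sum(f & !male),
               women_pct = round_half_up(100 * sum(f & !male) / max(sum(!male), 1L), 2))
  }
  categorical <- do.call(rbind, lapply(cat_vars, function(cv) count_row(x[[cv]], cv)))
  if (!is.null(htn)) categorical <- rbind(categorical, count_row(htn, "hypertension"))

  treated <- NULL
  if (!is.null(htn) && "bp_treated" %in% names(x) && any(htn)) {
    trt <- as.numeric(x$bp_treated) %in% 1
    treated <- data.frame(
      group = c("overall", "men", "women"),
      n_hypertensive = c(sum(htn), sum(htn & male), sum(htn & !male)),
      n_treated = c(sum(htn & trt), sum(htn & trt & male), sum(htn & trt & !male)))
    treated$pct_treated <- round_half_up(
      100 * treated$n_treated / pmax(treated$n_hypertensive, 1L), 2)
  }

  structure(list(n = n, pct = pct, continuous = continuous,
                 categorical = categorical,
                 treated_among_hypertensive = treated),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d subjects (%d men, %.2f%%; %d women, %.2f%%)\n",
              x$n["overall"], x$n["men"], x$pct["men"], x$n["women"], x$pct["women"]))
  cat("\nContinuous (mean +/- SD):\n")
  print(x$continuous, row.names = FALSE, digits = 4)
  cat("\nCategorical (n, %):\n")
  print(x$categorical, row.names = FALSE)
  if (!is.null(x$treated_among_hypertensive)) {
    cat("\nTreated among hypertensive:\n")
    print(x$treated_among_hypertensive, row.names = FALSE)
  }
  invisible(x)
}

#' Total follow-up (person-years)
#'
#' @param cohort a `cohort_table`.
#' @return named vector with total, men and women person-years.
#' @export
person_years <- function(cohort) {
  x <- as.data.frame(cohort)
  male <- x$sex == "male"
  c(total = sum(x$followup_years),
    men = sum(x$followup_years[male]),
    women = sum(x$followup_years[!male]))
}

#' Crude mortality rate over follow-up
#'
#' `100 * deaths / N`, reported at one decimal (half-up).
#'
#' @param cohort a non-empty `cohort_table`.
#' @param outcome `"cvd"` or `"all_cause"`.
#' @return percent, rounded to 1 decimal.
#' @export
crude_mortality <- function(cohort, outcome = c("cvd", "all_cause")) {
  outcome <- match.arg(outcome)
  x <- as.data.frame(cohort)
  if (nrow(x) == 0L) stop_validation("empty cohort")
  col <- if (outcome == "cvd") "cvd_death" else "all_cause_death"
  round_half_up(100 * sum(as.numeric(x[[col]]) %in% 1) / nrow(x), 1)
}
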