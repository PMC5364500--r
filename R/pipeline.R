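# End-to-end validation pipeline: score -> stratify -> discriminate ->
# calibrate (-> recalibrate) -> compare, with a machine-readable report.

PIPELINE_SCHEMA_VERSION <- "1.0"

#' Run the full validation pipeline
#'
#' Orchestrates one validation run: load (or simulate) a cohort, score
#' every model, evaluate discrimination (AUC with CI,
#' sensitivity/specificity and likelihood ratios at the model's
#' recommended cut-off and at the cohort's Youden-optimal cut-off),
#' evaluate calibration (decile collapsing + GND test), optionally
#' recalibrate, compare models pairwise (agreement, extreme
#' misclassification, Spearman rho), and write a versioned JSON report
#' plus CSV metric tables.
#'
#' @param config a named list or path to a YAML file with entries:
#'   \describe{
#'     \item{cohort}{path to a cohort CSV, or `"synthetic"`.}
#'     \item{synthetic}{options for the synthetic cohort: `n` (and any
#'       [default_config_table1()] overrides).}
#'     \item{models}{`"builtin"` or character vector of spec file paths.}
#'     \item{horizon}{evaluation horizon in years (default 5).}
#'     \item{min_events}{minimum events per calibration group (default 2).}
#'     \item{diabetes_adjust}{apply the SCORE diabetes multiplier
#'       (default TRUE).}
#'     \item{recalibrate}{`NULL`, `"mean_only"` or `"full"`.}
#'     \item{rescale}{allow baseline-survival horizon rescaling
#'       (default TRUE).}
#'     \item{seed}{integer seed.}
#'     \item{output_dir}{where to write report files (`NULL` = don't
#'       write).}
#'   }
#' @return the report, invisibly (a list mirroring the JSON).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(
    list(cohort = "synthetic", synthetic = list(n = 10000), models = "builtin",
         horizon = 5, min_events = 2, diabetes_adjust = TRUE,
         recalibrate = NULL, rescale = TRUE, seed = 1L, output_dir = NULL),
    config)
  set.seed(cfg$seed)

  cohort <- if (identical(cfg$cohort, "synthetic")) {
    gc_args <- cfg$synthetic
    gen <- default_config_table1(n = gc_args$n %||% 10000, seed = cfg$seed)
    if (length(setdiff(names(gc_args), "n")))
      gen <- utils::modifyList(gen, gc_args[setdiff(names(gc_args), "n")])
    generate_cohort(gen)
  } else {
    read_cohort(cfg$cohort)
  }

  specs <- if (identical(cfg$models, "builtin")) {
    c(builtin_recalibrated_specs(), builtin_score_specs_synthetic())
  } else {
    setNames(lapply(cfg$models, read_model_spec),
             sub("\\.[^.]+$", "", basename(cfg$models)))
  }
  if (isTRUE(cfg$diabetes_adjust)) {
    specs <- lapply(specs, function(s)
      if (s$family == "weibull_score") adjust_score_spec(s) else s)
  }

  if (!is.null(cfg$recalibrate)) {
    specs <- lapply(specs, function(s) {
      if (s$family != "cox_form") return(s)
      recalibrate(cohort, s, mode = cfg$recalibrate, h = cfg$horizon)
    })
  }

  h <- cfg$horizon
  ev <- as.numeric(cohort$cvd_death) %in% 1 & cohort$followup_years <= h
  models_out <- list()
  score_mat <- list()
  for (nm in names(specs)) {
    spec <- specs[[nm]]
    risk <- score_cohort(cohort, spec, horizon = h,
                         diabetes_adjust = isTRUE(cfg$diabetes_adjust),
                         rescale = isTRUE(cfg$rescale))
    sel <- !is.na(risk)
    if (sum(ev[sel]) < 2 || all(ev[sel]) ) next
    r <- risk[sel]; e <- ev[sel]
    auc <- auc_ci(r, e)
    rec_cut <- max(spec$thresholds)
    youden <- optimal_cutoff(r, e)
    groups <- tryCatch(
      form_groups(r, cohort$followup_years[sel], cohort$cvd_death[sel], h,
                  min_events = cfg$min_events),
      riskrecal_validation_error = function(e2) NULL)
    gnd <- if (!is.null(groups) && nrow(groups) >= 2) gnd_test(groups) else NULL
    models_out[[nm]] <- list(
      model_id = spec$model_id, sex = spec$sex, family = spec$family,
      n = sum(sel), events = sum(e),
      auc = auc,
      at_recommended_cutoff = sens_spec_at(r, e, rec_cut),
      at_youden_cutoff = sens_spec_at(r, e, youden),
      calibration = if (is.null(gnd)) NULL else list(
        groups = as.data.frame(groups),
        chart = calibration_chart_data(groups),
        gnd = unclass(gnd)))
    score_mat[[nm]] <- list(risk = risk, spec = spec)
  }

  nm_all <- names(score_mat)
  rho <- matrix(NA_real_, length(nm_all), length(nm_all),
                dimnames = list(nm_all, nm_all))
  agreement <- list()
  for (i in seq_along(nm_all)) for (j in seq_along(nm_all)) {
    if (i >= j) next
    a <- score_mat[[i]]; b <- score_mat[[j]]
    if (a$spec$sex != b$spec$sex) next
    sel <- !is.na(a$risk) & !is.na(b$risk)
    if (sum(sel) < 3) next
    # a clipped (constant) risk vector has no ranking; leave rho as NA
    if (sd(a$risk[sel]) > 0 && sd(b$risk[sel]) > 0)
      rho[i, j] <- rho[j, i] <- spearman_rho(a$risk[sel], b$risk[sel])
    ca <- stratify_risk(a$risk[sel], a$spec)
    cb <- stratify_risk(b$risk[sel], b$spec)
    ct <- crosstab_agreement(ca, cb)
    agreement[[paste(nm_all[i], nm_all[j], sep = "|")]] <- list(
      agreement_pct = ct$agreement,
      extreme_misclassified = extreme_misclassification(ca, cb))
  }
  diag(rho) <- 1

  report <- list(
    schema_version = PIPELINE_SCHEMA_VERSION,
    metadata = list(
      package_version = as.character(utils::packageVersion("riskrecal")),
      seed = cfg$seed, horizon = h, min_events = cfg$min_events,
      diabetes_adjust = isTRUE(cfg$diabetes_adjust),
      recalibration = if (is.null(cfg$recalibrate)) "none" else cfg$recalibrate,
      methods = list(auc_ci = "delong", se_sp_ci = "clopper-pearson",
                     gnd_variance = "greenwood", gnd_df = "G-1",
                     cutoff_rule = ">= (inclusive)",
                     youden_rule = "max Se+Sp-1, smallest cutoff on ties",
                     category_mapping = as.list(DEFAULT_CATEGORY_MAPPING))),
    cohort = list(n = nrow(cohort),
                  events_within_horizon = sum(ev),
                  person_years = as.list(person_years(cohort)),
                  cvd_mortality_pct = crude_mortality(cohort, "cvd"),
                  all_cause_mortality_pct = crude_mortality(cohort, "all_cause")),
    models = models_out,
    comparison = list(spearman_rho = rho, agreement = agreement))

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(cfg$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         force = TRUE)
    metrics <- do.call(rbind, lapply(models_out, function(m) data.frame(
      model = m$model_id, sex = m$sex, n = m$n, events = m$events,
      auc = m$auc$auc, auc_lo = m$auc$lo, auc_hi = m$auc$hi,
      youden_cutoff = m$at_youden_cutoff$cutoff,
      sens_youden = m$at_youden_cutoff$sensitivity,
      spec_youden = m$at_youden_cutoff$specificity,
      lr_pos = m$at_youden_cutoff$lr_pos, lr_neg = m$at_youden_cutoff$lr_neg,
      gnd_chi2 = if (is.null(m$calibration)) NA else m$calibration$gnd$chi2,
      gnd_p = if (is.null(m$calibration)) NA else m$calibration$gnd$p_value)))
    write.csv(metrics, file.path(cfg$output_dir, "metrics.csv"),
              row.names = FALSE)
  }
  invisible(report)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
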