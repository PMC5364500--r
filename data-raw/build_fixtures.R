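# Build the shipped model-spec JSON fixtures under inst/extdata/models.
# Run from repo root: Rscript data-raw/build_fixtures.R
pkgload::load_all(".", quiet = TRUE)

out <- "inst/extdata/models"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cat3 <- c("low", "intermediate", "high")
cat4 <- c("<7.5%", "7.5-9.9%", "10.0-19.9%", ">=20%")

lg <- function(cov, coef, cond = NULL) risk_term(cov, "log", coef, condition = cond)
id <- function(cov, coef) risk_term(cov, "identity", coef)
prod2 <- function(c1, t1, c2, t2, coef, cond = NULL)
  risk_term(transform = "product", coefficient = coef, condition = cond,
            factors = list(list(covariate = c1, transform = t1),
                           list(covariate = c2, transform = t2)))

frs_units <- list(total_cholesterol = "mg/dL", hdl = "mg/dL")

# general-FRS -----------------------------------------------------------
gfrs <- function(sex, a, tc, hdl, sbp_u, sbp_t, smk, dm, lbar, s5)
  model_spec(
    model_id = "general-FRS", sex = sex, family = "cox_form",
    terms = list(lg("age", a), lg("total_cholesterol", tc), lg("hdl", hdl),
                 lg("sbp", sbp_u, "bp_untreated"), lg("sbp", sbp_t, "bp_treated"),
                 id("current_smoker", smk), id("diabetes", dm)),
    mean_lp = lbar, baseline_survival = list("5" = s5), native_horizon = 5,
    thresholds = c(0.10, 0.20), categories = cat3, units = frs_units)

write_model_spec(gfrs("male",   5.1215, -0.2727, -0.4596, 3.2282, 3.3088, -0.4882, 0.6518,
                      32.45731, 0.9914698), file.path(out, "general_frs_men.json"))
write_model_spec(gfrs("female", 4.4913, -0.9884, -0.4972, 3.4325, 3.4539, -3.0644, 0.7695,
                      27.33517, 0.9934118), file.path(out, "general_frs_women.json"))

# simplified-FRS (office-based; BMI replaces lipids) ---------------------
sfrs <- function(sex, a, bmi, sbp_u, sbp_t, smk, dm, lbar, s5)
  model_spec(
    model_id = "simplified-FRS", sex = sex, family = "cox_form",
    terms = list(lg("age", a), lg("bmi", bmi),
                 lg("sbp", sbp_u, "bp_untreated"), lg("sbp", sbp_t, "bp_treated"),
                 id("current_smoker", smk), id("diabetes", dm)),
    mean_lp = lbar, baseline_survival = list("5" = s5), native_horizon = 5,
    thresholds = c(0.10, 0.20), categories = cat3, units = list())

write_model_spec(sfrs("male",   4.6867, -2.2998, 3.4576, 3.5505, -0.5276, 0.7303,
                      27.67513, 0.9914576), file.path(out, "simplified_frs_men.json"))
write_model_spec(sfrs("female", 4.0899, -0.6864, 3.4689, 3.4942, -3.0307, 0.7639,
                      30.74361, 0.993261),  file.path(out, "simplified_frs_women.json"))

# CN-ICVD (category bands; TC in mmol/L) ---------------------------------
cn <- function(sex, age, sbp_bands, bmi_ge24, tc_mid, tc_hi, smk, dm, lbar, s5)
  model_spec(
    model_id = "CN-ICVD", sex = sex, family = "cox_form",
    terms = list(
      id("age", age),
      risk_term("sbp", "bands", bands = data.frame(
        lo = c(-Inf, 120, 130, 140, 160, 180),
        hi = c(120, 130, 140, 160, 180, Inf),
        coefficient = sbp_bands)),
      risk_term("bmi", "bands", bands = data.frame(
        lo = c(-Inf, 24), hi = c(24, Inf), coefficient = c(0, bmi_ge24))),
      risk_term("total_cholesterol", "bands", bands = data.frame(
        lo = c(-Inf, 3.62, 5.17), hi = c(3.62, 5.17, Inf),
        coefficient = c(0, tc_mid, tc_hi))),
      id("current_smoker", smk), id("diabetes", dm)),
    mean_lp = lbar, baseline_survival = list("5" = s5), native_horizon = 5,
    thresholds = c(0.05, 0.10), categories = cat3,
    units = list(total_cholesterol = "mmol/L"))

write_model_spec(cn("male",   0.0844, c(0.0186, 0, 0.7914, 1.6302, 1.9703, 1.8387),
                    -0.3101, -0.0059, -0.2680, -0.4775, 0.7168, 4.400718, 0.9918239),
                 file.path(out, "cn_icvd_men.json"))
write_model_spec(cn("female", 0.0878, c(-0.3130, 0, 0.1822, 0.4560, 0.9871, 1.8207),
                    -0.0624, -0.6806, -0.8578, -3.3481, 0.8233, 3.976495, 0.9931033),
                 file.path(out, "cn_icvd_women.json"))

# PCE -------------------------------------------------------------------
pce <- function(id_, sex, terms, lbar, s5, notes = NULL)
  model_spec(model_id = id_, sex = sex, family = "cox_form", terms = terms,
             mean_lp = lbar, baseline_survival = list("5" = s5), native_horizon = 5,
             thresholds = c(0.075, 0.10, 0.20), categories = cat4,
             units = frs_units, notes = notes)

# PCE-white women
write_model_spec(pce("PCE-white", "female", list(
  lg("age", -22.3973),
  prod2("age", "log", "age", "log", 1.7899),                       # Ln Age squared
  lg("total_cholesterol", 15.0642),
  prod2("age", "log", "total_cholesterol", "log", 3.5038),
  lg("hdl", 5.1555),
  prod2("age", "log", "hdl", "log", -1.4068),
  lg("sbp", 3.4666, "bp_treated"),
  lg("sbp", 3.4459, "bp_untreated"),
  id("current_smoker", 17.8261),
  prod2("age", "log", "current_smoker", "identity", -5.6228),
  id("diabetes", 0.7707)),
  -51.67933, 0.9934143), file.path(out, "pce_white_women.json"))

# PCE-AA women
write_model_spec(pce("PCE-AA", "female", list(
  lg("age", -42.6070),
  lg("total_cholesterol", -0.9533),
  lg("hdl", 0.5844),
  prod2("age", "log", "hdl", "log", -0.2728),
  lg("sbp", -34.6531, "bp_treated"),
  prod2("age", "log", "sbp", "log", 9.4585, "bp_treated"),
  lg("sbp", -36.7922, "bp_untreated"),
  prod2("age", "log", "sbp", "log", 9.9831, "bp_untreated"),
  id("current_smoker", -3.8740),
  id("diabetes", 0.7789)),
  -162.2403, 0.9931984), file.path(out, "pce_aa_women.json"))

# PCE-white men
write_model_spec(pce("PCE-white", "male", list(
  lg("age", -7.6938),
  lg("total_cholesterol", -20.8736),
  prod2("age", "log", "total_cholesterol", "log", 5.0969),
  lg("hdl", 14.2871),
  prod2("age", "log", "hdl", "log", -3.6424),
  lg("sbp", 3.3128, "bp_treated"),
  lg("sbp", 3.2339, "bp_untreated"),
  id("current_smoker", -2.9244),
  prod2("age", "log", "current_smoker", "identity", 0.6021),
  id("diabetes", 0.6608)),
  -19.22938, 0.9915944), file.path(out, "pce_white_men.json"))

# PCE-AA men (published column coincides with general-FRS men; transcribed
# as printed, flagged)
write_model_spec(pce("PCE-AA", "male", list(
  lg("age", 5.1215),
  lg("total_cholesterol", -0.2727),
  lg("hdl", -0.4596),
  lg("sbp", 3.3088, "bp_treated"),
  lg("sbp", 3.2282, "bp_untreated"),
  id("current_smoker", -0.4882),
  id("diabetes", 0.6518)),
  32.45731, 0.9914698,
  notes = paste("transcription_note: published PCE-AA men column is identical",
                "to the general-FRS men column (likely typesetting artifact);",
                "transcribed as printed")),
  file.path(out, "pce_aa_men.json"))

# SCORE placeholders (synthetic Weibull parameters; originals user-supplied)
score_syn <- function(id_, sex, region, chd, nchd)
  model_spec(model_id = id_, sex = sex, family = "weibull_score",
             native_horizon = 10, thresholds = c(0.01, 0.05), categories = cat3,
             units = list(total_cholesterol = "mmol/L"),
             causes = list(chd = chd, non_chd = nchd), region = region,
             notes = paste("synthetic placeholder Weibull parameters for testing;",
                           "supply published SCORE parameters for real use"))

wc <- function(alpha, p, btc, bsbp, bsmk)
  list(alpha = alpha, p = p, beta_tc = btc, beta_sbp = bsbp, beta_smoker = bsmk)

write_model_spec(score_syn("SCORE-high", "male", "high",
                           wc(-21.5, 4.7, 0.24, 0.018, 0.70),
                           wc(-25.8, 5.5, 0.02, 0.022, 0.40)),
                 file.path(out, "score_high_men_synthetic.json"))
write_model_spec(score_syn("SCORE-high", "female", "high",
                           wc(-28.2, 6.2, 0.20, 0.018, 0.65),
                           wc(-30.5, 6.5, 0.02, 0.022, 0.40)),
                 file.path(out, "score_high_women_synthetic.json"))
write_model_spec(score_syn("SCORE-low", "male", "low",
                           wc(-22.1, 4.7, 0.24, 0.018, 0.70),
                           wc(-26.7, 5.6, 0.02, 0.022, 0.40)),
                 file.path(out, "score_low_men_synthetic.json"))
write_model_spec(score_syn("SCORE-low", "female", "low",
                           wc(-29.8, 6.4, 0.20, 0.018, 0.65),
                           wc(-31.0, 6.6, 0.02, 0.022, 0.40)),
                 file.path(out, "score_low_women_synthetic.json"))

cat("wrote", length(list.files(out)), "spec files\n")
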