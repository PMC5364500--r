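# Model-spec construction, validation, serialization and the shipped
# recalibrated parameter sets.

test_that("shipped general-FRS men spec carries the published mean LP and baseline survival", {
  spec <- read_model_spec(builtin_spec_files()[["general_frs_men"]])
  expect_identical(spec$mean_lp, 32.45731)
  expect_identical(spec$baseline_survival[["5"]], 0.9914698)
  expect_identical(spec$sex, "male")
  expect_length(spec$terms, 7L)
})

test_that("spec validation rejects structural violations", {
  good <- make_two_term_spec()
  bad <- good; bad$thresholds <- c(0.20, 0.10)
  expect_validation_error(validate_model_spec(bad), "strictly increasing")
  bad <- good; bad$baseline_survival <- NULL
  expect_validation_error(validate_model_spec(bad), "baseline_survival")
  bad <- good; bad$baseline_survival <- list("5" = 1.0)
  expect_validation_error(validate_model_spec(bad), "strictly in")
  bad <- good; bad$mean_lp <- NULL
  expect_validation_error(validate_model_spec(bad), "mean_lp")
  # non-partitioning bands: gap between 120 and 130
  expect_validation_error(
    risk_term("sbp", "bands",
              bands = data.frame(lo = c(-Inf, 130), hi = c(120, Inf),
                                 coefficient = c(0, 1))),
    "partition")
  expect_validation_error(model_spec("x", "male", "weibull_score",
                                     causes = list(chd = list(alpha = -20, p = 1,
                                                              beta_tc = 0, beta_sbp = 0,
                                                              beta_smoker = 0))),
                          "two causes")
})

test_that("write/read round trip preserves a spec exactly", {
  for (nm in c("general_frs_men", "cn_icvd_women", "pce_aa_women",
               "score_high_men_synthetic")) {
    spec <- read_model_spec(builtin_spec_files()[[nm]])
    path <- withr::local_tempfile(fileext = ".json")
    write_model_spec(spec, path)
    back <- read_model_spec(path)
    expect_equal(back, spec, tolerance = 0)
  }
  # YAML path too
  spec <- make_two_term_spec()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_spec(spec, path)
  expect_equal(read_model_spec(path), spec)
})

test_that("all shipped specs validate and cover both sexes of every family", {
  specs <- c(builtin_recalibrated_specs(), builtin_score_specs_synthetic())
  expect_length(specs, 14L)
  for (s in specs) expect_silent(validate_model_spec(s))
  ids <- vapply(specs, function(s) paste(s$model_id, s$sex), "")
  expect_setequal(ids, c(t(outer(c("general-FRS", "simplified-FRS", "CN-ICVD",
                                   "PCE-white", "PCE-AA", "SCORE-high", "SCORE-low"),
                                 c("male", "female"), paste))))
  # anomaly flag on the PCE-AA men transcription
  aa_men <- builtin_recalibrated_specs()[["pce_aa_men"]]
  expect_match(aa_men$notes, "transcription_note")
  # SCORE placeholders are clearly labelled synthetic
  for (s in builtin_score_specs_synthetic())
    expect_match(s$notes, "synthetic")
})

# every numeric cell of the published recalibrated coefficient tables,
# keyed by fixture file; each value must appear among that fixture's
# coefficients (bands included) exactly as printed
published_cells <- list(
  general_frs_men = c(5.1215, -0.2727, -0.4596, 3.2282, 3.3088, -0.4882, 0.6518),
  general_frs_women = c(4.4913, -0.9884, -0.4972, 3.4325, 3.4539, -3.0644, 0.7695),
  simplified_frs_men = c(4.6867, -2.2998, 3.4576, 3.5505, -0.5276, 0.7303),
  simplified_frs_women = c(4.0899, -0.6864, 3.4689, 3.4942, -3.0307, 0.7639),
  cn_icvd_men = c(0.0844, 0.0186, 0.7914, 1.6302, 1.9703, 1.8387, -0.3101,
                  -0.0059, -0.2680, -0.4775, 0.7168),
  cn_icvd_women = c(0.0878, -0.3130, 0.1822, 0.4560, 0.9871, 1.8207, -0.0624,
                    -0.6806, -0.8578, -3.3481, 0.8233),
  pce_white_women = c(-22.3973, 1.7899, 15.0642, 3.5038, 5.1555, -1.4068,
                      3.4666, 3.4459, 17.8261, -5.6228, 0.7707),
  pce_aa_women = c(-42.6070, -0.9533, 0.5844, -0.2728, -34.6531, 9.4585,
                   -36.7922, 9.9831, -3.8740, 0.7789),
  pce_white_men = c(-7.6938, -20.8736, 5.0969, 14.2871, -3.6424, 3.3128,
                    3.2339, -2.9244, 0.6021, 0.6608),
  pce_aa_men = c(5.1215, -0.2727, -0.4596, 3.3088, 3.2282, -0.4882, 0.6518))

published_summary <- list(
  general_frs_men = c(32.45731, 0.9914698),
  general_frs_women = c(27.33517, 0.9934118),
  simplified_frs_men = c(27.67513, 0.9914576),
  simplified_frs_women = c(30.74361, 0.993261),
  cn_icvd_men = c(4.400718, 0.9918239),
  cn_icvd_women = c(3.976495, 0.9931033),
  pce_white_women = c(-51.67933, 0.9934143),
  pce_aa_women = c(-162.2403, 0.9931984),
  pce_white_men = c(-19.22938, 0.9915944),
  pce_aa_men = c(32.45731, 0.9914698))

spec_coefficients <- function(spec) {
  unlist(lapply(spec$terms, function(t) {
    if (t$transform == "bands") t$bands$coefficient else t$coefficient
  }))
}

test_that("fixture transcription matches every published table cell", {
  specs <- builtin_recalibrated_specs()
  for (nm in names(published_cells)) {
    got <- spec_coefficients(specs[[nm]])
    for (cell in published_cells[[nm]])
      expect_true(any(got == cell),
                  label = sprintf("%s contains %s", nm, cell))
    # nothing beyond the published cells (plus referent zeros)
    expect_setequal(setdiff(got, c(0, published_cells[[nm]])), numeric(0))
    expect_identical(specs[[nm]]$mean_lp, published_summary[[nm]][1])
    expect_identical(unname(unlist(specs[[nm]]$baseline_survival["5"])),
                     published_summary[[nm]][2])
  }
})

test_that("spec lookups return the published coefficients", {
  specs <- builtin_recalibrated_specs()
  cn_men_age <- specs[["cn_icvd_men"]]$terms[[1L]]
  expect_identical(cn_men_age$covariate, "age")
  expect_identical(cn_men_age$coefficient, 0.0844)
  pw_women_age <- specs[["pce_white_women"]]$terms[[1L]]
  expect_identical(pw_women_age$transform, "log")
  expect_identical(pw_women_age$coefficient, -22.3973)
})

test_that("loading a missing or malformed file fails informatively", {
  expect_validation_error(read_model_spec("no/such/file.json"), "not found")
  path <- withr::local_tempfile(fileext = ".json")
  spec <- make_two_term_spec()
  spec$thresholds <- NULL
  x <- unclass(spec)
  x$thresholds <- c(0.2, 0.1)
  jsonlite::write_json(x, path, auto_unbox = TRUE, force = TRUE)
  expect_validation_error(read_model_spec(path))
})
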