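# Risk-model specifications: construction, validation, (de)serialization.
#
# A model spec is the single source of a risk equation's math; the scoring
# engine contains no hard-coded coefficients. Two families are supported:
#   cox_form      risk(h) = 1 - S0(h)^exp(L - Lbar), L a sum of terms
#   weibull_score two cause-specific Weibull equations (SCORE style)

VALID_SEX        <- c("male", "female")
VALID_FAMILIES   <- c("cox_form", "weibull_score")
VALID_TRANSFORMS <- c("identity", "log", "bands", "product")
VALID_CONDITIONS <- c("bp_treated", "bp_untreated")
SPEC_SCHEMA_VERSION <- "1.0"

#' Construct a single risk-equation term
#'
#' A term contributes `coefficient * f(x)` to the linear predictor, where
#' `f` is one of: the identity, the natural log (after unit conversion),
#' a category-band lookup (the band coefficient itself is the
#' contribution), or a product of two transformed covariates
#' (e.g. `Ln Age x Ln Total Cholesterol`).
#'
#' @param covariate covariate name (e.g. `"sbp"`); for `transform =
#'   "product"` supply `factors` instead.
#' @param transform one of `"identity"`, `"log"`, `"bands"`, `"product"`.
#' @param coefficient term coefficient (ignored for `"bands"`, which carry
#'   per-band coefficients).
#' @param condition optional predicate restricting when the term applies:
#'   `"bp_treated"` or `"bp_untreated"`.
#' @param bands for `"bands"`: a data.frame with columns `lo`, `hi`,
#'   `coefficient`; intervals are half-open `[lo, hi)` and must partition
#'   the real line (use `-Inf`/`Inf` at the ends).
#' @param factors for `"product"`: list of two `list(covariate, transform)`
#'   entries with `transform` in `identity`/`log`.
#' @return a list of class `"risk_term"`.
#' @export
risk_term <- function(covariate = NULL, transform = "identity",
                      coefficient = NULL, condition = NULL,
                      bands = NULL, factors = NULL) {
  term <- structure(
    list(covariate = covariate, transform = transform,
         coefficient = coefficient, condition = condition,
         bands = bands, factors = factors),
    class = "risk_term"
  )
  validate_term(term)
  term
}

#' @noRd
validate_term <- function(term) {
  if (!term$transform %in% VALID_TRANSFORMS)
    stop_validation("term transform '%s' is not one of %s", term$transform,
                    paste(VALID_TRANSFORMS, collapse = ", "))
  if (!is.null(term$condition) && !term$condition %in% VALID_CONDITIONS)
    stop_validation("term condition '%s' is not one of %s", term$condition,
                    paste(VALID_CONDITIONS, collapse = ", "))
  if (term$transform == "product") {
    if (length(term$factors) != 2L)
      stop_validation("product term requires exactly two factors")
    for (f in term$factors) {
      if (is.null(f$covariate) || !f$transform %in% c("identity", "log"))
        stop_validation("product factors need a covariate and an identity/log transform")
    }
    if (!is.numeric(term$coefficient))
      stop_validation("product term requires a numeric coefficient")
  } else if (term$transform == "bands") {
    b <- term$bands
    if (is.null(term$covariate))
      stop_validation("band term requires a covariate")
    if (is.null(b) || !all(c("lo", "hi", "coefficient") %in% names(b)))
      stop_validation("band term for '%s' requires bands with lo, hi, coefficient",
                      term$covariate)
    b <- b[order(b$lo), , drop = FALSE]
    if (b$lo[1L] != -Inf || b$hi[nrow(b)] != Inf ||
        (nrow(b) > 1L && any(b$lo[-1L] != b$hi[-nrow(b)])))
      stop_validation("bands for '%s' must partition the real line with half-open [lo, hi) intervals",
                      term$covariate)
  } else {
    if (is.null(term$covariate))
      stop_validation("term requires a covariate")
    if (!is.numeric(term$coefficient))
      stop_validation("term for '%s' requires a numeric coefficient", term$covariate)
  }
  invisible(term)
}

#' Construct and validate a risk-model specification
#'
#' @param model_id model identifier, e.g. `"general-FRS"`.
#' @param sex `"male"` or `"female"` (the equation the spec encodes is
#'   sex-specific).
#' @param family `"cox_form"` (linear predictor + baseline survival) or
#'   `"weibull_score"` (two cause-specific Weibull equations).
#' @param terms list of [risk_term()] objects (`cox_form` only).
#' @param mean_lp mean linear predictor Lbar, the published
#'   "Mean (Coefficient x Value)" (`cox_form` only).
#' @param baseline_survival named list mapping horizon in years (as
#'   character) to baseline survival S0 in (0, 1), e.g. `list("5" = 0.99)`.
#' @param native_horizon horizon in years the equation was built for.
#' @param thresholds strictly increasing risk cut-points (proportions)
#'   defining the risk categories.
#' @param categories category labels, `length(thresholds) + 1` of them,
#'   ordered low to high.
#' @param units named list giving the unit each covariate is expected in
#'   by the equation (`"mg/dL"` or `"mmol/L"` for lipids/glucose);
#'   profiles are stored in mmol/L and converted at the term boundary.
#' @param causes for `weibull_score`: named list with elements `chd` and
#'   `non_chd`, each `list(alpha, p, beta_tc, beta_sbp, beta_smoker)`.
#' @param region for `weibull_score`: `"high"` or `"low"` risk region.
#' @param diabetes_multiplier optional named vector `c(male=, female=)`
#'   applied to predicted risk of diabetic subjects at scoring time.
#' @param notes free-text annotations (e.g. transcription flags).
#' @return object of class `"model_spec"`.
#' @export
model_spec <- function(model_id, sex, family, terms = NULL, mean_lp = NULL,
                       baseline_survival = NULL, native_horizon = 10,
                       thresholds = NULL, categories = NULL,
                       units = list(), causes = NULL, region = NULL,
                       diabetes_multiplier = NULL, notes = NULL) {
  spec <- structure(
    list(schema_version = SPEC_SCHEMA_VERSION,
         model_id = model_id, sex = sex, family = family,
         native_horizon = native_horizon,
         baseline_survival = baseline_survival, mean_lp = mean_lp,
         terms = terms, thresholds = thresholds, categories = categories,
         units = units, causes = causes, region = region,
         diabetes_multiplier = diabetes_multiplier, notes = notes),
    class = "model_spec"
  )
  validate_model_spec(spec)
  spec
}

#' Validate a model specification
#'
#' Checks all structural invariants: family/sex enumerations, strictly
#' increasing thresholds, baseline survival strictly inside (0, 1), band
#' partitions, Weibull shape positivity, and per-family required fields.
#'
#' @param spec a `model_spec`.
#' @return the spec, invisibly; signals a validation error naming the
#'   offending field otherwise.
#' @export
validate_model_spec <- function(spec) {
  if (!is.character(spec$model_id) || !nzchar(spec$model_id))
    stop_validation("model_id must be a non-empty string")
  if (!spec$sex %in% VALID_SEX)
    stop_validation("sex must be 'male' or 'female', got '%s'", spec$sex)
  if (!spec$family %in% VALID_FAMILIES)
    stop_validation("family must be one of %s", paste(VALID_FAMILIES, collapse = ", "))
  if (!is.null(spec$thresholds)) {
    th <- spec$thresholds
    if (any(diff(th) <= 0))
      stop_validation("thresholds must be strictly increasing")
    if (any(th < 0 | th > 1))
      stop_validation("thresholds must be risk proportions in [0, 1]")
    if (!is.null(spec$categories) && length(spec$categories) != length(th) + 1L)
      stop_validation("categories must have length(thresholds) + 1 labels")
  }
  if (spec$family == "cox_form") {
    if (is.null(spec$mean_lp) || !is.numeric(spec$mean_lp))
      stop_validation("cox_form spec '%s' requires a numeric mean_lp", spec$model_id)
    bs <- spec$baseline_survival
    if (is.null(bs) || length(bs) < 1L)
      stop_validation("cox_form spec '%s' requires baseline_survival at >= 1 horizon",
                      spec$model_id)
    s0 <- unlist(bs)
    if (any(s0 <= 0 | s0 >= 1))
      stop_validation("baseline_survival values must lie strictly in (0, 1)")
    if (anyNA(suppressWarnings(as.numeric(names(bs)))))
      stop_validation("baseline_survival names must be numeric horizons in years")
    if (length(spec$terms) < 1L)
      stop_validation("cox_form spec '%s' requires at least one term", spec$model_id)
    for (term in spec$terms) validate_term(term)
  } else { # weibull_score
    if (!is.null(spec$terms))
      stop_validation("weibull_score spec '%s' takes causes, not terms", spec$model_id)
    cs <- spec$causes
    if (is.null(cs) || !setequal(names(cs), c("chd", "non_chd")))
      stop_validation("weibull_score spec '%s' requires exactly two causes: chd, non_chd",
                      spec$model_id)
    for (nm in names(cs)) {
      cc <- cs[[nm]]
      need <- c("alpha", "p", "beta_tc", "beta_sbp", "beta_smoker")
      if (!all(need %in% names(cc)))
        stop_validation("cause '%s' must supply %s", nm, paste(need, collapse = ", "))
      if (cc$p <= 0)
        stop_validation("cause '%s' shape p must be > 0", nm)
    }
    if (!is.null(spec$region) && !spec$region %in% c("high", "low"))
      stop_validation("region must be 'high' or 'low'")
  }
  if (!is.null(spec$diabetes_multiplier)) {
    dm <- spec$diabetes_multiplier
    if (!all(c("male", "female") %in% names(dm)))
      stop_validation("diabetes_multiplier needs named male and female entries")
  }
  invisible(spec)
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (%s), family %s\n", x$model_id, x$sex, x$family))
  if (x$family == "cox_form") {
    cat(sprintf("  terms: %d   mean_lp: %.6g\n", length(x$terms), x$mean_lp))
    bs <- unlist(x$baseline_survival)
    cat(sprintf("  baseline survival: %s\n",
                paste(sprintf("S0(%s)=%.7g", names(bs), bs), collapse = ", ")))
  } else {
    cat(sprintf("  causes: %s (region %s)\n",
                paste(names(x$causes), collapse = ", "),
                if (is.null(x$region)) "?" else x$region))
  }
  if (!is.null(x$thresholds))
    cat(sprintf("  thresholds: %s\n", paste(x$thresholds, collapse = ", ")))
  if (!is.null(x$notes)) cat(sprintf("  notes: %s\n", x$notes))
  invisible(x)
}

# Serialization ---------------------------------------------------------

#' @noRd
term_to_list <- function(term) {
  out <- list(covariate = term$covariate, transform = term$transform)
  if (!is.null(term$coefficient)) out$coefficient <- term$coefficient
  if (!is.null(term$condition)) out$condition <- term$condition
  if (!is.null(term$bands)) {
    b <- term$bands[order(term$bands$lo), , drop = FALSE]
    out$bands <- lapply(seq_len(nrow(b)), function(i) {
      bb <- list(coefficient = b$coefficient[i])
      if (is.finite(b$lo[i])) bb$lo <- b$lo[i]
      if (is.finite(b$hi[i])) bb$hi <- b$hi[i]
      bb
    })
  }
  if (!is.null(term$factors))
    out$factors <- lapply(term$factors, function(f)
      list(covariate = f$covariate, transform = f$transform))
  out
}

#' @noRd
term_from_list <- function(x) {
  # JSON/YAML readers may represent absent fields as empty lists
  for (nm in c("covariate", "coefficient", "condition", "bands", "factors"))
    if (length(x[[nm]]) == 0L) x[nm] <- list(NULL)
  bands <- NULL
  if (!is.null(x$bands)) {
    edge <- function(b, nm, open) {
      v <- b[[nm]]
      if (is.null(v) || length(v) == 0L) open else as.numeric(v)
    }
    bands <- data.frame(
      lo = vapply(x$bands, edge, 0, nm = "lo", open = -Inf),
      hi = vapply(x$bands, edge, 0, nm = "hi", open = Inf),
      coefficient = vapply(x$bands, function(b) as.numeric(b$coefficient), 0)
    )
  }
  risk_term(covariate = x$covariate, transform = x$transform,
            coefficient = x$coefficient, condition = x$condition,
            bands = bands, factors = x$factors)
}

#' Write a model spec to a JSON (or YAML) file
#'
#' @param spec a `model_spec`.
#' @param path output path; format chosen by extension (`.json`,
#'   `.yaml`/`.yml`).
#' @return `path`, invisibly.
#' @seealso [read_model_spec()]
#' @export
write_model_spec <- function(spec, path) {
  validate_model_spec(spec)
  x <- unclass(spec)
  x$terms <- if (is.null(x$terms)) NULL else lapply(x$terms, term_to_list)
  x <- x[!vapply(x, is.null, TRUE)]
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Load and validate a model spec file
#'
#' Reads a JSON or YAML risk-equation spec, rebuilds the term objects and
#' runs full validation; malformed files fail with an error naming the
#' offending field.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` spec file.
#' @return a validated `model_spec`.
#' @export
read_model_spec <- function(path) {
  if (!file.exists(path))
    stop_validation("model spec file not found: %s", path)
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  terms <- if (is.null(x$terms)) NULL else lapply(x$terms, term_from_list)
  bs <- x$baseline_survival
  if (!is.null(bs)) bs <- lapply(bs, as.numeric)
  dm <- x$diabetes_multiplier
  if (!is.null(dm)) dm <- unlist(dm)
  model_spec(
    model_id = x$model_id, sex = x$sex, family = x$family,
    terms = terms,
    mean_lp = if (is.null(x$mean_lp)) NULL else as.numeric(x$mean_lp),
    baseline_survival = bs,
    native_horizon = as.numeric(x$native_horizon),
    thresholds = if (is.null(x$thresholds)) NULL else as.numeric(unlist(x$thresholds)),
    categories = if (is.null(x$categories)) NULL else as.character(unlist(x$categories)),
    units = if (is.null(x$units)) list() else x$units,
    causes = x$causes, region = x$region,
    diabetes_multiplier = dm, notes = x$notes
  )
}

# Built-in specs --------------------------------------------------------

#' List / load the model specs shipped with the package
#'
#' `builtin_spec_files()` lists the spec files under
#' `inst/extdata/models`; `builtin_recalibrated_specs()` loads the ten
#' sex-specific proportional-hazards specs recalibrated to the Chinese
#' rural cohort (general-FRS, simplified-FRS, CN-ICVD, PCE-white and
#' PCE-AA, each for men and women), and
#' `builtin_score_specs_synthetic()` loads the four SCORE-family specs
#' whose Weibull parameters are synthetic placeholders (the original
#' SCORE parameters are not shipped; supply your own spec files to use
#' the published equations).
#'
#' @return named list of `model_spec` objects (or file paths for
#'   `builtin_spec_files()`).
#' @export
builtin_spec_files <- function() {
  dir <- system.file("extdata", "models", package = "riskrecal")
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  setNames(files, sub("\\.json$", "", basename(files)))
}

#' @rdname builtin_spec_files
#' @export
builtin_recalibrated_specs <- function() {
  files <- builtin_spec_files()
  files <- files[!grepl("synthetic", names(files))]
  lapply(files, read_model_spec)
}

#' @rdname builtin_spec_files
#' @export
builtin_score_specs_synthetic <- function() {
  files <- builtin_spec_files()
  files <- files[grepl("synthetic", names(files))]
  lapply(files, read_model_spec)
}
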