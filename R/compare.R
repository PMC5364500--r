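# Cross-model comparison: risk-category stratification, agreement
# tables, extreme misclassification, rank correlation.

# default correspondence from the 4-category PCE scale to the 3-category
# low/intermediate/high scale used by the other model families
DEFAULT_CATEGORY_MAPPING <- c("<7.5%" = "low", "7.5-9.9%" = "intermediate",
                              "10.0-19.9%" = "intermediate", ">=20%" = "high")

#' Assign risk categories under a spec's thresholds
#'
#' Half-open interval lookup: a risk equal to a threshold falls in the
#' higher category (e.g. exactly 20% under an equation with a 20%
#' high-risk cut-off is high risk).
#'
#' @param risk risk(s) in `[0, 1]`.
#' @param spec a [model_spec()] with `thresholds` (and optionally
#'   `categories` labels).
#' @return ordered factor of category labels.
#' @export
stratify_risk <- function(risk, spec) {
  if (any(risk < 0 | risk > 1, na.rm = TRUE))
    stop_validation("risk must lie in [0, 1]")
  th <- spec$thresholds
  if (is.null(th)) stop_validation("spec '%s' has no thresholds", spec$model_id)
  labels <- spec$categories
  if (is.null(labels)) {
    labels <- if (length(th) == 2L) c("low", "intermediate", "high")
              else paste0("cat", seq_len(length(th) + 1L))
  }
  cut(risk, breaks = c(-Inf, th, Inf), right = FALSE, labels = labels,
      ordered_result = TRUE)
}

#' Cross-tabulate two categorizations and compute percent agreement
#'
#' When the two factors share the same category set, agreement is the
#' diagonal share of the cross-table. Otherwise (e.g. a 4-category PCE
#' model against a 3-category one) the finer scale is first mapped to
#' the coarser via `mapping`.
#'
#' @param cats_a,cats_b aligned category factors.
#' @param mapping named character vector mapping the finer scale's
#'   levels onto the other scale's.
#' @return list with `table` (full cross-table of the original
#'   categories) and `agreement` (percent).
#' @export
crosstab_agreement <- function(cats_a, cats_b,
                               mapping = DEFAULT_CATEGORY_MAPPING) {
  if (length(cats_a) != length(cats_b))
    stop_validation("category vectors must have equal length")
  tab <- table(a = cats_a, b = cats_b)
  a <- as.character(cats_a); b <- as.character(cats_b)
  la <- if (is.factor(cats_a)) levels(cats_a) else sort(unique(a))
  lb <- if (is.factor(cats_b)) levels(cats_b) else sort(unique(b))
  if (!setequal(la, lb)) {
    if (all(la %in% names(mapping))) a <- unname(mapping[a])
    else if (all(lb %in% names(mapping))) b <- unname(mapping[b])
    else stop_validation("category sets differ and no mapping covers either side")
  }
  list(table = tab, agreement = 100 * mean(a == b))
}

#' Count extreme misclassification between two categorizations
#'
#' Subjects placed in the lowest category by one model and the highest
#' by the other (either direction).
#'
#' @param cats_a,cats_b aligned ordered factors.
#' @return integer count.
#' @export
extreme_misclassification <- function(cats_a, cats_b) {
  if (length(cats_a) != length(cats_b))
    stop_validation("category vectors must have equal length")
  fa <- factor(cats_a); fb <- factor(cats_b)
  lo_a <- levels(fa)[1L]; hi_a <- levels(fa)[nlevels(fa)]
  lo_b <- levels(fb)[1L]; hi_b <- levels(fb)[nlevels(fb)]
  sum((fa == lo_a & fb == hi_b) | (fa == hi_a & fb == lo_b))
}

#' Spearman rank correlation between two score vectors
#'
#' Midranks for ties. A constant vector has no ranking; the correlation
#' is undefined and reported as `NA` with a warning.
#'
#' @param scores_a,scores_b aligned numeric vectors, length >= 3.
#' @return Spearman's rho, or `NA` if undefined.
#' @export
spearman_rho <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b))
    stop_validation("score vectors must have equal length")
  if (length(scores_a) < 3L)
    stop_validation("need at least 3 paired scores")
  ok <- is.finite(scores_a) & is.finite(scores_b)
  if (sd(scores_a[ok]) == 0 || sd(scores_b[ok]) == 0) {
    warning("rank correlation undefined for a constant score vector")
    return(NA_real_)
  }
  cor(scores_a[ok], scores_b[ok], method = "spearman")
}
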