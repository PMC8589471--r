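# Frozen constants of the published impaction study: group summary statistics,
# the fitted logistic risk model, and the reference contact morphology. These
# are inputs to the simulators and the fixed scorer, not quantities this
# package re-estimates.

#' Published per-group feature distributions
#'
#' Mean and standard deviation of the five interproximal features in the
#' impaction and non-impaction groups of the source cohort. Used as the
#' default parameterisation of [generate_cohort()].
#'
#' @return A data frame with columns `feature`, `group`, `mean`, `sd`.
#' @export
published_group_stats <- function() {
  feats <- feature_names()
  data.frame(
    feature = rep(feats, 2),
    group = rep(c("nonimpaction", "impaction"), each = 5),
    mean = c(3.304, 7.763, 53.630, 55.849, 92.006,
             4.267, 8.278, 50.236, 51.462, 59.466),
    sd = c(1.187, 0.466, 10.275, 15.047, 13.091,
           0.937, 0.390, 9.673, 12.121, 29.288),
    stringsAsFactors = FALSE)
}

#' Published logistic risk model coefficients
#'
#' The fixed binary logistic model relating contact morphology to impaction:
#' `logit(p) = 0.889 L + 3.396 A - 0.071 theta_b - 0.089 theta_o - 19.797`
#' with `L` the adjacent line length (mm), `A` the adjacent surface area
#' (mm^2) and `theta_b`, `theta_o` the buccal and occlusal abduction-gap
#' angles (degrees). The tongue angle was screened out upstream and does not
#' enter the model.
#'
#' @return Named numeric vector: `intercept` plus one coefficient per feature.
#' @export
published_logistic_model <- function() {
  c(intercept = -19.797,
    adjacent_line_length_mm = 0.889,
    adjacent_surface_area_mm2 = 3.396,
    buccal_angle_deg = -0.071,
    occlusal_angle_deg = -0.089)
}

#' Published reference contact morphology
#'
#' Feature values (mean and SD) reported as the morphology at which impaction
#' incidence was observed to decrease; the mean column doubles as the default
#' [tooth_pair_spec()] scenario.
#'
#' @return Data frame with columns `feature`, `mean`, `sd`.
#' @export
published_reference_features <- function() {
  data.frame(feature = feature_names(),
             mean = c(3.52, 6.21, 52.24, 54.15, 89.26),
             sd = c(1.62, 2.31, 13.17, 13.61, 21.64),
             stringsAsFactors = FALSE)
}

#' Impaction risk from the published logistic model
#'
#' Applies the fixed published coefficients (see
#' [published_logistic_model()]) to measured features and returns the modelled
#' impaction probability. Features must be in the model's units: mm, mm^2 and
#' degrees. The tongue angle, if present, is ignored.
#'
#' @param record a data frame (one or more rows) or named vector containing
#'   `adjacent_line_length_mm`, `adjacent_surface_area_mm2`,
#'   `buccal_angle_deg` and `occlusal_angle_deg`.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
#' @examples
#' published_risk_score(data.frame(
#'   adjacent_line_length_mm = 3.52, adjacent_surface_area_mm2 = 6.21,
#'   buccal_angle_deg = 54.15, occlusal_angle_deg = 89.26))
published_risk_score <- function(record) {
  beta <- published_logistic_model()
  need <- setdiff(names(beta), "intercept")
  if (is.vector(record) && !is.list(record)) {
    record <- as.data.frame(as.list(record))
  }
  missing <- setdiff(need, names(record))
  if (length(missing)) {
    stopf("missing feature(s): %s", paste(missing, collapse = ", "))
  }
  x <- as.matrix(record[, need, drop = FALSE])
  if (any(!is.finite(x))) stopf("features must be finite")
  lp <- drop(x %*% beta[need]) + beta[["intercept"]]
  plogis(lp)
}

#' Score a feature table with the published risk model
#'
#' Convenience wrapper that appends a `risk_probability` column.
#'
#' @param features data frame of measured features.
#' @return The input with a `risk_probability` column added.
#' @export
score_features <- function(features) {
  features$risk_probability <- published_risk_score(features)
  features
}
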