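# Cohort feature-table simulator: Gaussian feature draws per group, optionally
# correlated, with outcomes taken from group membership or drawn from a
# logistic model.

#' Per-group feature distribution
#'
#' @param name group label, conventionally `"impaction"` or `"nonimpaction"`.
#' @param means,sds named numeric vectors over the five features (names as in
#'   `published_group_stats()$feature`); `sds` must be positive.
#' @param n number of subjects to draw for this group (>= 2).
#' @return An object of class `group_distribution`.
#' @export
group_distribution <- function(name, means, sds, n) {
  feats <- feature_names()
  means <- means[feats]
  sds <- sds[feats]
  if (any(is.na(means)) || any(is.na(sds))) {
    stopf("means and sds must be named over all five features")
  }
  if (any(sds <= 0)) stopf("feature standard deviations must be positive")
  n <- as.integer(n)
  if (n < 2) stopf("group size must be at least 2")
  structure(list(name = as.character(name), means = means, sds = sds, n = n),
            class = "group_distribution")
}

#' Published groups as simulator inputs
#'
#' @param n_per_group subjects per group (default 250, the recruitment size).
#' @return List of two [group_distribution()] objects.
#' @export
published_groups <- function(n_per_group = 250) {
  gs <- published_group_stats()
  lapply(split(gs, gs$group), function(g) {
    group_distribution(g$group[1],
                       stats::setNames(g$mean, g$feature),
                       stats::setNames(g$sd, g$feature),
                       n_per_group)
  })
}

#' Simulate a cohort feature table
#'
#' Draws feature vectors per group (independent normals, or correlated normals
#' when a feature correlation matrix is supplied) and attaches a binary
#' impaction outcome: either group membership (`by_group`) or a Bernoulli draw
#' from a logistic model over the features (`by_logistic_model`).
#'
#' @param groups list of [group_distribution()] objects.
#' @param outcome_rule `"by_group"` or `"by_logistic_model"`.
#' @param coefficients named vector (`intercept` plus feature coefficients)
#'   used when `outcome_rule = "by_logistic_model"`; defaults to the published
#'   model.
#' @param seed integer seed; same seed gives a bit-identical table.
#' @param correlation optional 5x5 feature correlation matrix applied within
#'   every group (Gaussian copula; with normal marginals this is simply a
#'   multivariate normal draw).
#' @return Data frame with the five feature columns, `group` and `outcome`
#'   (0/1).
#' @export
#' @examples
#' cohort <- generate_cohort(published_groups(50), seed = 1)
#' head(cohort, 3)
generate_cohort <- function(groups,
                            outcome_rule = c("by_group", "by_logistic_model"),
                            coefficients = published_logistic_model(),
                            seed = 1L,
                            correlation = NULL) {
  outcome_rule <- match.arg(outcome_rule)
  if (!length(groups)) stopf("groups must be non-empty")
  feats <- feature_names()
  if (!is.null(correlation)) {
    correlation <- as.matrix(correlation)
    if (!all(dim(correlation) == 5) ||
        max(abs(correlation - t(correlation))) > 1e-8) {
      stopf("correlation must be a symmetric 5 x 5 matrix")
    }
  }
  withr::with_seed(as.integer(seed), {
    parts <- lapply(groups, function(g) {
      if (!inherits(g, "group_distribution")) {
        stopf("each group must be a group_distribution")
      }
      z <- matrix(rnorm(g$n * 5), ncol = 5)
      if (!is.null(correlation)) {
        z <- z %*% chol(correlation)
      }
      x <- sweep(sweep(z, 2, g$sds, `*`), 2, g$means, `+`)
      colnames(x) <- feats
      df <- as.data.frame(x)
      df$group <- g$name
      df
    })
    cohort <- do.call(rbind, parts)
    rownames(cohort) <- NULL
    if (outcome_rule == "by_group") {
      cohort$outcome <- as.integer(cohort$group == "impaction")
    } else {
      need <- setdiff(names(coefficients), "intercept")
      missing <- setdiff(need, feats)
      if (length(missing)) {
        stopf("unknown coefficient name(s): %s",
              paste(missing, collapse = ", "))
      }
      lp <- drop(as.matrix(cohort[, need, drop = FALSE]) %*%
                   coefficients[need]) + coefficients[["intercept"]]
      cohort$outcome <- rbinom(nrow(cohort), 1L, plogis(lp))
    }
    cohort
  })
}
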