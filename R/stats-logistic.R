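# Binary logistic regression with the reporting conventions of the clinical
# workflow: Wald chi-square statistics, odds ratios and their Wald CIs.

#' Fit a binary logistic regression
#'
#' Maximum likelihood via iteratively reweighted least squares
#' (`stats::glm`, binomial logit), standard errors from the observed
#' information, Wald chi-square `(beta / SE)^2`, odds ratios and Wald 95%
#' confidence bounds. (Quasi-)complete separation is detected from boundary
#' fitted probabilities and reported explicitly rather than returned as a
#' silently diverged fit.
#'
#' @param X numeric matrix or data frame of features.
#' @param y binary outcome (0/1 or logical), both classes present.
#' @param level confidence level for the odds-ratio intervals.
#' @return A list of class `logistic_model`: `coefficients` (a table with
#'   estimate, SE, Wald chi2, p, OR, CI bounds), `converged`, `separation`,
#'   `iterations`, `fitted`, `loglik`.
#' @export
fit_logistic <- function(X, y, level = 0.95) {
  X <- as.matrix(X)
  if (is.logical(y)) y <- as.integer(y)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stopf("outcome must be binary 0/1")
  if (length(unique(y)) < 2) stopf("both outcome classes must be present")
  if (nrow(X) != length(y)) stopf("X and y sizes differ")
  if (any(apply(X, 2, sd) == 0)) {
    stopf("constant feature column: coefficient not identifiable")
  }
  df <- data.frame(X, check.names = TRUE)
  fit <- suppressWarnings(
    glm(y ~ ., data = cbind(df, y = y), family = binomial(),
        control = glm.control(epsilon = 1e-10, maxit = 100)))
  p_hat <- fitted(fit)
  separation <- any(p_hat > 1 - 1e-8) || any(p_hat < 1e-8) ||
    !fit$converged
  sm <- summary(fit)$coefficients
  z <- qnorm(1 - (1 - level) / 2)
  beta <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  tab <- data.frame(term = c("intercept", colnames(X)),
                    estimate = unname(beta), se = unname(se),
                    wald_chi2 = unname((beta / se)^2),
                    p = unname(pchisq((beta / se)^2, 1, lower.tail = FALSE)),
                    OR = exp(unname(beta)),
                    CI_lower = exp(unname(beta - z * se)),
                    CI_upper = exp(unname(beta + z * se)))
  structure(list(coefficients = tab, converged = fit$converged,
                 separation = separation, iterations = fit$iter,
                 fitted = p_hat, loglik = as.numeric(logLik(fit)),
                 level = level),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("<logistic_model> %sconverged in %d IRLS iterations%s\n",
              if (x$converged) "" else "NOT ", x$iterations,
              if (x$separation) " [separation detected: estimates unstable]"
              else ""))
  print(cbind(x$coefficients[1],
              round(x$coefficients[-1], 4)), row.names = FALSE)
  invisible(x)
}

#' Odds ratio and Wald confidence interval from a coefficient
#'
#' @param beta logistic regression coefficient.
#' @param se its standard error (> 0).
#' @param level confidence level.
#' @return Named vector `c(OR, CI_lower, CI_upper)`.
#' @export
#' @examples
#' odds_ratio(-0.071, 0.031)
odds_ratio <- function(beta, se, level = 0.95) {
  if (se <= 0) stopf("standard error must be positive")
  z <- qnorm(1 - (1 - level) / 2)
  c(OR = exp(beta), CI_lower = exp(beta - z * se),
    CI_upper = exp(beta + z * se))
}
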