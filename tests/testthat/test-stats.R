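# Statistical workflow: normality, group comparison, correlation, PCA
# screening, logistic regression and the published scorer.

test_that("normality description matches the distribution of the input", {
  hits_normal <- 0
  hits_expo <- 0
  for (r in 1:100) {
    withr::with_seed(300 + r, {
      nr <- describe_normality(rnorm(500))
      er <- describe_normality(rexp(500))
    })
    hits_normal <- hits_normal + (nr$sw_p > 0.05)
    hits_expo <- hits_expo + (er$sw_p < 0.05)
  }
  expect_gte(hits_normal, 90)
  expect_gte(hits_expo, 99)
  sym <- describe_normality(rep(c(-2, -1, 0, 1, 2), 20))
  expect_equal(sym$skewness, 0, tolerance = 1e-10)
  expect_error(describe_normality(rep(1, 20)), "constant")
  expect_error(describe_normality(rnorm(5)), "at least 8")
  # both KS variants report a statistic and p-value
  x <- withr::with_seed(1, rnorm(100))
  lil <- describe_normality(x, "lilliefors")
  fit <- describe_normality(x, "fitted_normal")
  expect_true(lil$ks_p >= 0 && lil$ks_p <= 1)
  expect_gte(fit$ks_p, lil$ks_p)  # naive KS is anti-conservative the other way
})

test_that("t-test behaves on identical and summary inputs", {
  x <- withr::with_seed(2, rnorm(40, 5))
  same <- two_sample_ttest(x, x)
  expect_equal(same$t, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
  y <- withr::with_seed(3, rnorm(35, 6))
  raw <- two_sample_ttest(x, y)
  summ <- ttest_from_summary(mean(x), sd(x), length(x),
                             mean(y), sd(y), length(y))
  expect_equal(raw$t, summ$t, tolerance = 1e-12)
  expect_equal(raw$p, summ$p, tolerance = 1e-12)
  expect_equal(raw$df, summ$df, tolerance = 1e-12)
  rawst <- two_sample_ttest(x, y, "student")
  sumst <- ttest_from_summary(mean(x), sd(x), length(x),
                              mean(y), sd(y), length(y), "student")
  expect_equal(rawst$p, sumst$p, tolerance = 1e-12)
  expect_error(two_sample_ttest(rep(1, 5), rep(2, 5)), "zero variance")
})

test_that("printed group summaries reproduce the borderline tongue contrast", {
  # tongue abduction-gap angle at n = 50 per group: non-significant, p near 0.09
  tt <- ttest_from_summary(53.630, 10.275, 50, 50.236, 9.673, 50)
  expect_gt(tt$p, 0.05)
  expect_equal(tt$p, 0.09, tolerance = 0.05)
  # buccal angle likewise fails the 0.05 threshold at this size
  tb <- ttest_from_summary(55.849, 15.047, 50, 51.462, 12.121, 50)
  expect_gt(tb$p, 0.05)
  expect_lt(tb$p, 0.2)
})

test_that("t-test holds its nominal type-I error under the null", {
  rejections <- 0
  reps <- 2000
  withr::with_seed(11, {
    for (r in seq_len(reps)) {
      if (two_sample_ttest(rnorm(50), rnorm(50))$p < 0.05) {
        rejections <- rejections + 1
      }
    }
  })
  expect_lt(abs(rejections / reps - 0.05), 0.015)
})

test_that("correlation p-values follow the t approximation", {
  expect_equal(corr_pvalue_from_r(0, 50), 1, tolerance = 1e-12)
  expect_identical(corr_pvalue_from_r(1, 50), 0)
  expect_identical(corr_pvalue_from_r(-1, 10), 0)
  expect_error(corr_pvalue_from_r(1.2, 10), "exceed")
  x <- withr::with_seed(4, rnorm(60))
  y <- withr::with_seed(5, rnorm(60)) + 0.4 * x
  cr <- correlation(x, y, "pearson")
  ct <- cor.test(x, y)
  expect_equal(cr$p, ct$p.value, tolerance = 1e-9)
  crs <- correlation(x, y, "spearman")
  expect_equal(crs$r, cor(x, y, method = "spearman"), tolerance = 1e-12)
})

test_that("communality identities hold and screening drops the weak item", {
  cohort <- generate_cohort(published_groups(5000)["impaction"], seed = 1,
                            correlation = weak_item_correlation())
  scr <- pca_with_screening(cohort[, 1:5])
  for (r in scr) {
    expect_equal(r$communalities, rowSums(r$loadings^2), tolerance = 1e-12)
    expect_equal(sum(r$eigenvalues), nrow(r$loadings), tolerance = 1e-10)
    expect_true(all(r$communalities >= 0 & r$communalities <= 1 + 1e-12))
  }
  expect_length(scr, 2)
  expect_identical(scr[[1]]$dropped_item, "tongue_angle_deg")
  expect_true(is.na(scr[[2]]$dropped_item))
  expect_setequal(retained_items(scr),
                  c("adjacent_line_length_mm", "adjacent_surface_area_mm2",
                    "buccal_angle_deg", "occlusal_angle_deg"))
})

test_that("two perfectly correlated items collapse onto one component", {
  x <- withr::with_seed(6, rnorm(200))
  tab <- data.frame(a = x, b = 2 * x + 1)
  scr <- pca_with_screening(tab)
  r1 <- scr[[1]]
  expect_equal(r1$eigenvalues, c(2, 0), tolerance = 1e-10)
  expect_equal(unname(r1$communalities), c(1, 1), tolerance = 1e-10)
  expect_equal(r1$retained, 1)
})

test_that("logistic fit agrees with an independent Newton maximiser", {
  withr::with_seed(7, {
    X <- cbind(rnorm(100), rnorm(100))
    eta <- 0.5 + 0.8 * X[, 1] - 1.2 * X[, 2]
    y <- rbinom(100, 1, plogis(eta))
  })
  fit <- fit_logistic(X, y)
  oracle <- newton_logistic(X, y)
  expect_equal(fit$coefficients$estimate, unname(oracle), tolerance = 1e-6)
  expect_false(fit$separation)
  # doubling a feature's units halves its coefficient
  X2 <- X
  X2[, 1] <- 2 * X2[, 1]
  fit2 <- fit_logistic(X2, y)
  expect_equal(fit2$coefficients$estimate[2],
               fit$coefficients$estimate[2] / 2, tolerance = 1e-6)
  expect_error(fit_logistic(cbind(rep(1, 50)), rep(0:1, 25)), "constant")
  expect_error(fit_logistic(X, rep(1, 100)), "both outcome classes")
})

test_that("complete separation is detected and reported", {
  X <- matrix(c(seq(-2, -0.1, length.out = 20),
                seq(0.1, 2, length.out = 20)), ncol = 1)
  y <- rep(c(0, 1), each = 20)
  fit <- fit_logistic(X, y)
  expect_true(fit$separation)
})

test_that("odds-ratio identities hold exactly", {
  or <- odds_ratio(0.7, 0.2)
  expect_equal(unname(or["OR"]), exp(0.7), tolerance = 1e-12)
  expect_equal(log(or[["CI_upper"]] / or[["OR"]]),
               -log(or[["CI_lower"]] / or[["OR"]]), tolerance = 1e-12)
  nul <- odds_ratio(0, 0.3)
  expect_equal(unname(nul["OR"]), 1, tolerance = 1e-12)
  expect_error(odds_ratio(1, 0), "positive")
})

test_that("the published scorer reproduces its closed form", {
  zero <- published_risk_score(data.frame(
    adjacent_line_length_mm = 0, adjacent_surface_area_mm2 = 0,
    buccal_angle_deg = 0, occlusal_angle_deg = 0))
  expect_equal(zero, plogis(-19.797), tolerance = 1e-12)
  ref <- published_risk_score(data.frame(
    adjacent_line_length_mm = 3.52, adjacent_surface_area_mm2 = 6.21,
    buccal_angle_deg = 54.15, occlusal_angle_deg = 89.26))
  expect_equal(qlogis(ref), -7.3679, tolerance = 1e-4)
  expect_equal(ref, 6.3e-4, tolerance = 0.01)
  # monotonicity in the stated directions
  bump <- function(col, d) {
    rec <- data.frame(adjacent_line_length_mm = 3.52,
                      adjacent_surface_area_mm2 = 6.21,
                      buccal_angle_deg = 54.15, occlusal_angle_deg = 89.26)
    rec[[col]] <- rec[[col]] + d
    published_risk_score(rec)
  }
  expect_gt(bump("adjacent_line_length_mm", 0.1), ref)
  expect_gt(bump("adjacent_surface_area_mm2", 0.1), ref)
  expect_lt(bump("buccal_angle_deg", 1), ref)
  expect_lt(bump("occlusal_angle_deg", 1), ref)
  expect_error(published_risk_score(data.frame(adjacent_line_length_mm = 1)),
               "missing feature")
})

test_that("the full analysis reproduces the expected significance pattern", {
  cohort <- generate_cohort(published_groups(250), seed = 12)
  rep <- run_full_analysis(cohort)
  gc <- rep$group_comparison
  sig <- gc$p[match(c("adjacent_line_length_mm", "adjacent_surface_area_mm2",
                      "occlusal_angle_deg"), gc$feature)]
  expect_true(all(sig < 0.001))
  expect_gte(length(rep$metadata$retained_items), 2)
  expect_s3_class(rep$pca, "pca_screening")
  expect_true(all(rep$scored$risk_probability >= 0 &
                    rep$scored$risk_probability <= 1))
})

test_that("identical groups show no systematic differences", {
  g <- published_groups(60)
  g$nonimpaction <- group_distribution("nonimpaction",
                                       g$impaction$means, g$impaction$sds, 60)
  hits <- 0
  for (r in 1:40) {
    cohort <- generate_cohort(g, seed = 400 + r)
    ps <- vapply(proxigap:::feature_names(), function(f) {
      two_sample_ttest(cohort[cohort$group == "impaction", f],
                       cohort[cohort$group == "nonimpaction", f])$p
    }, numeric(1))
    hits <- hits + all(ps > 0.05)
  }
  expect_gte(hits, 25)  # no-signal cohorts mostly show no significance
})
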