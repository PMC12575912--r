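test_that("ICC matches an independently computed two-way random absolute-agreement value", {
  # reference value 0.954542 computed with an external ICC(2,1) implementation
  r1 <- c(9.1, 7.2, 8.4, 6.5, 7.9, 8.8, 6.1, 7.4)
  r2 <- c(9.4, 6.9, 8.1, 6.9, 8.2, 8.5, 6.4, 7.1)
  r <- compute_icc(r1, r2)
  expect_equal(r$icc, 0.954542, tolerance = 1e-6)
  expect_equal(r$band, "excellent")
})

test_that("ICC is 1 for identical readers and near 0 for independent noise", {
  x <- c(3.2, 5.1, 4.4, 6.0, 2.9)
  expect_equal(compute_icc(x, x)$icc, 1)
  withr::with_seed(61, {
    r <- compute_icc(rnorm(300), rnorm(300))
    expect_lt(abs(r$icc), 0.15)
    expect_equal(r$band, "poor")
  })
  expect_error(compute_icc(rep(1, 5), rep(1, 5)), "zero total variance")
  expect_error(compute_icc(1:2, 1:2), "at least 3")
})

test_that("qualitative ICC bands follow the published thresholds", {
  expect_equal(icc_band(0.80), "excellent")
  expect_equal(icc_band(0.75), "excellent")
  expect_equal(icc_band(0.65), "good")
  expect_equal(icc_band(0.50), "fair")
  expect_equal(icc_band(0.39), "poor")
})

test_that("group comparison routes by the Shapiro-Wilk screen", {
  withr::with_seed(62, {
    g <- compare_groups(rnorm(40, 5), rnorm(50, 5))
    expect_equal(g$route, "t-test")
    expect_true(!is.null(g$summary_pos$mean))
    g2 <- compare_groups(rlnorm(40, 0, 1.5), rlnorm(50, 0, 1.5))
    expect_equal(g2$route, "mann-whitney")
    expect_true(!is.null(g2$summary_pos$median))
  })
})

test_that("identical groups compare at the U midpoint with p near 1", {
  x <- withr::with_seed(69, rlnorm(50, 0, 1.5))  # skewed: Mann-Whitney route
  g <- compare_groups(x, x)
  expect_equal(g$route, "mann-whitney")
  expect_equal(g$statistic, length(x)^2 / 2)  # midpoint of the U range
  expect_gt(g$p_value, 0.95)
})

test_that("constant data routes to Mann-Whitney with a note", {
  g <- compare_groups(rep(2, 5), c(1.2, 1.9, 2.6, 3.1, 0.8))
  expect_equal(g$route, "mann-whitney")
  expect_match(g$note, "inapplicable")
})

test_that("a calibrated location shift is detected with power above the null level", {
  # D-like shift: medians 0.72 vs 0.96 at the study's group sizes
  hits <- withr::with_seed(63, {
    sum(replicate(60, {
      pos <- rlnorm(26, log(0.72), 0.45)
      neg <- rlnorm(47, log(0.96), 0.45)
      compare_groups(pos, neg)$p_value < 0.05
    }))
  })
  expect_gt(hits / 60, 0.2)
})

test_that("univariate logistic recovers a known coefficient and is equivariant", {
  withr::with_seed(64, {
    x <- rnorm(2000)
    y <- runif(2000) < plogis(-1 + 0.8 * x)
    fit <- univariate_logistic(x, y)
    expect_lt(abs(fit$estimate - 0.8) / fit$se, 3)
    fit10 <- univariate_logistic(x * 10, y)
    expect_equal(fit10$estimate, fit$estimate / 10, tolerance = 1e-8)
    expect_equal(fit10$p_value, fit$p_value, tolerance = 1e-8)
    # null: OR near 1
    null_fit <- univariate_logistic(rnorm(2000), y)
    expect_equal(null_fit$or, 1, tolerance = 0.15)
    expect_false(fit$separation)
  })
})

test_that("complete separation is flagged, not silently reported", {
  x <- c(1:10, 21:30)
  y <- rep(c(FALSE, TRUE), each = 10)
  fit <- univariate_logistic(x, y)
  expect_true(fit$separation)
})

test_that("a single screened biomarker gives a joint model equal to its univariate fit", {
  withr::with_seed(65, {
    n <- 300
    strong <- rnorm(n)
    d <- tibble::tibble(strong = strong, noise1 = rnorm(n), noise2 = rnorm(n),
                        lvi = ifelse(runif(n) < plogis(1.5 * strong), "+", "-"))
  })
  sel <- multivariate_selection(d, c("strong", "noise1", "noise2"),
                                p_enter = 1e-4)
  expect_equal(sel$selected, "strong")
  uni <- univariate_logistic(d$strong, d$lvi)
  expect_equal(sel$multivariate$estimate, uni$estimate, tolerance = 1e-8)
  expect_equal(sel$multivariate$p_value, uni$p_value, tolerance = 1e-8)
})

test_that("two informative predictors are both recovered as independent", {
  withr::with_seed(66, {
    n <- 2000
    x1 <- rnorm(n)
    x2 <- rnorm(n)
    d <- tibble::tibble(x1 = x1, x2 = x2, junk = rnorm(n),
                        lvi = ifelse(runif(n) < plogis(-0.5 + 0.8 * x1 + 0.6 * x2),
                                     "+", "-"))
  })
  sel <- multivariate_selection(d, c("x1", "x2", "junk"))
  expect_true(all(c("x1", "x2") %in% sel$independent))
  est <- sel$multivariate$estimate[match(c("x1", "x2"), sel$multivariate$term)]
  expect_equal(est, c(0.8, 0.6), tolerance = 0.2)
})

test_that("a duplicated biomarker is flagged as collinear", {
  withr::with_seed(67, {
    n <- 200
    x <- rnorm(n)
    d <- tibble::tibble(x = x, dup = x,
                        lvi = ifelse(runif(n) < plogis(1.5 * x), "+", "-"))
  })
  expect_warning(sel <- multivariate_selection(d, c("x", "dup")), "collinear")
  expect_true(sel$collinear)
})

test_that("an empty screen returns an explicit empty-model result", {
  withr::with_seed(68, {
    d <- tibble::tibble(a = rnorm(100), b = rnorm(100),
                        lvi = rep(c("+", "-"), 50))
  })
  sel <- multivariate_selection(d, c("a", "b"), p_enter = 1e-6)
  expect_equal(sel$selected, character())
  expect_null(sel$multivariate)
})

test_that("a single-member combination reproduces the raw biomarker ROC", {
  cohort <- generate_cohort(seed = 71)
  subj <- cohort[cohort$reader == 1, ]
  cm <- combine_predictors(subj, "mtv")
  raw <- roc_analysis(subj$mtv, subj$lvi)
  expect_equal(cm$roc$auc, raw$auc, tolerance = 1e-12)
  expect_true(cm$roc$cutoff > 0 && cm$roc$cutoff < 1)  # probability scale
})

test_that("the all-biomarker combination dominates its subsets in-sample", {
  cohort <- generate_cohort(seed = 72)
  subj <- cohort[cohort$reader == 1, ]
  all_auc <- combine_predictors(subj, BIOMARKERS)$roc$auc
  for (members in preset_combinations()[c("PET", "IVIM", "DKI", "MTV+D")]) {
    expect_gte(all_auc, combine_predictors(subj, members)$roc$auc - 0.01)
  }
})

test_that("the full pipeline emits a complete, deterministic study report", {
  cohort <- generate_cohort(seed = 73)
  rep1 <- run_pipeline(cohort)
  expect_equal(nrow(rep1$icc), 9)
  expect_equal(nrow(rep1$comparison), 9)
  expect_equal(nrow(rep1$univariate), 9)
  expect_equal(nrow(rep1$roc_parameters), 9)
  expect_equal(nrow(rep1$roc_combinations), 5)
  expect_true(all(rep1$roc_parameters$fpr + rep1$roc_parameters$specificity == 100))
  expect_true(all(rep1$roc_parameters$fnr + rep1$roc_parameters$sensitivity == 100))
  rep2 <- run_pipeline(generate_cohort(seed = 73))
  expect_identical(rep1$icc, rep2$icc)
  expect_identical(rep1$roc_parameters, rep2$roc_parameters)
  expect_identical(rep1$roc_combinations, rep2$roc_combinations)
})

test_that("a noise-free cohort reports ICC = 1 for every biomarker", {
  cohort <- generate_cohort(default_cohort_config(icc = 1), seed = 74)
  rep <- run_pipeline(cohort)
  expect_true(all(rep$icc$icc == 1))
  expect_true(all(rep$icc$band == "excellent"))
})

test_that("pipeline errors name the offending stage input", {
  cohort <- generate_cohort(seed = 75)
  expect_error(run_pipeline(cohort[cohort$reader == 1, ]), "readers 1 and 2")
  bad <- cohort
  bad$mtv <- NULL
  expect_error(run_pipeline(bad), "mtv")
  one_class <- cohort[cohort$lvi == "+", ]
  expect_error(run_pipeline(one_class), "class")
})
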