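test_that("perfectly separated scores give AUC 1 and a perfect operating point", {
  y <- rep(c(TRUE, FALSE), c(10, 15))
  r <- roc_analysis(c(11:20, 1:15 / 10), y)
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)
  expect_equal(r$fpr, 0)
  expect_equal(r$fnr, 0)
})

test_that("AUC equals the exhaustive pair-counting oracle, including ties", {
  withr::with_seed(51, {
    for (i in 1:30) {
      n_pos <- sample(3:25, 1)
      n_neg <- sample(3:25, 1)
      scores <- round(c(rnorm(n_pos, 0.5), rnorm(n_neg)), 1)  # rounding forces ties
      y <- rep(c(TRUE, FALSE), c(n_pos, n_neg))
      r <- roc_analysis(scores, y, direction = "higher")
      expect_identical(r$auc, auc_pair_count(scores[y], scores[!y]))
    }
  })
})

test_that("auto direction orients AUC above one half and records the flip", {
  withr::with_seed(52, {
    x <- c(rnorm(30, 0), rnorm(40, 1))   # LOWER in the positive class
    y <- rep(c(TRUE, FALSE), c(30, 40))
    r <- roc_analysis(x, y)
    expect_equal(r$direction, "lower")
    expect_gte(r$auc, 0.5)
    expect_equal(r$auc, auc_pair_count(-x[y], -x[!y]))
  })
})

test_that("labels independent of scores give AUC near one half", {
  withr::with_seed(53, {
    x <- rnorm(2000)
    y <- rep(c(TRUE, FALSE), 1000)
    expect_equal(roc_analysis(x, y, direction = "higher")$auc, 0.5,
                 tolerance = 0.05)
  })
})

test_that("rate identities and CI containment hold on random instances", {
  withr::with_seed(54, {
    for (i in 1:20) {
      x <- rnorm(40) + rep(c(0.8, 0), c(15, 25))
      y <- rep(c(TRUE, FALSE), c(15, 25))
      r <- roc_analysis(x, y)
      expect_identical(r$fpr, 100 - r$specificity)
      expect_identical(r$fnr, 100 - r$sensitivity)
      expect_true(r$ci[1] <= r$auc && r$auc <= r$ci[2])
      expect_true(r$ci[1] >= 0 && r$ci[2] <= 1)
    }
  })
})

test_that("Youden ties break toward the higher-specificity operating point", {
  # pos {2, 4}, neg {1, 3}: cutoffs above 1.5 and above 3.5 both give J = 0.5;
  # the latter has specificity 100%
  r <- roc_analysis(c(2, 4, 1, 3), c(TRUE, TRUE, FALSE, FALSE),
                    direction = "higher")
  expect_equal(r$specificity, 100)
  expect_equal(r$sensitivity, 50)
  expect_gt(r$cutoff, 3)
})

test_that("AUC and DeLong CI agree with the reference ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(55, {
    for (i in 1:10) {
      x <- rnorm(60) + rep(c(1, 0), c(25, 35))
      y <- rep(c(TRUE, FALSE), c(25, 35))
      r <- roc_analysis(x, y, direction = "higher")
      pr <- pROC::roc(y, x, direction = "<", levels = c(FALSE, TRUE), quiet = TRUE)
      expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
      ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
      expect_equal(unname(r$ci), pmin(pmax(ci[c(1, 3)], 0), 1), tolerance = 1e-9)
    }
  })
})

test_that("the DeLong comparison matches the reference implementation", {
  skip_if_not_installed("pROC")
  for (seed in 1:5) {
    inst <- make_paired_scores(20, 30, 1, 0.5, seed)
    dl <- delong_compare(inst$a, inst$b, inst$y, "higher", "higher")
    ra <- pROC::roc(inst$y, inst$a, direction = "<", levels = c(FALSE, TRUE), quiet = TRUE)
    rb <- pROC::roc(inst$y, inst$b, direction = "<", levels = c(FALSE, TRUE), quiet = TRUE)
    rt <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
    expect_equal(dl$z, unname(rt$statistic), tolerance = 1e-9)
    expect_equal(dl$p_value, rt$p.value, tolerance = 1e-9)
  }
})

test_that("identical and rank-identical scores compare as Z = 0, p = 1", {
  inst <- make_paired_scores(15, 20, 1, 1, 3)
  same <- delong_compare(inst$a, inst$a, inst$y)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  mono <- delong_compare(inst$a, exp(inst$a), inst$y)
  expect_equal(mono$delta, 0)
  expect_equal(mono$z, 0)
  expect_equal(mono$p_value, 1)
})

test_that("single-class inputs are rejected", {
  expect_error(roc_analysis(1:5, rep(TRUE, 5)), "both classes")
  expect_error(delong_compare(1:5, 5:1, rep(FALSE, 5)), "both classes")
})
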