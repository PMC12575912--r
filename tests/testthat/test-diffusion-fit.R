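b_ivim <- bvalue_scheme("ivim")
b_dki <- bvalue_scheme("dki")

test_that("ADC inverts a clean mono-exponential exactly and is 0 on flat signal", {
  expect_equal(fit_adc(b_ivim, exp(-b_ivim * 1e-3)), 1e-3, tolerance = 1e-12)
  expect_equal(fit_adc(b_ivim, rep(2, length(b_ivim))), 0, tolerance = 1e-12)
  expect_error(fit_adc(c(500, 500), c(1, 1)), "distinct")
})

test_that("two-point ADC equals the log-ratio formula and shows perfusion contamination", {
  s <- ivim_signal(c(0, 800), lvi_pos_ivim$d, lvi_pos_ivim$dstar, lvi_pos_ivim$f)
  adc <- fit_adc(c(0, 800), s)
  expect_equal(adc, log(s[1] / s[2]) / 800, tolerance = 1e-12)
  expect_equal(adc, 1.3915e-3, tolerance = 1e-4)
  expect_gt(adc, lvi_pos_ivim$d)  # perfusion biases ADC above D
})

test_that("ADC of a bi-exponential signal strictly exceeds the generating D when f > 0", {
  for (f in c(0.05, 0.2, 0.4)) {
    for (d in c(0.5e-3, 1e-3, 2e-3)) {
      s <- ivim_signal(bvalue_scheme("dwi"), d, 50e-3, f)
      expect_gt(fit_adc(c(0, 800), s), d)
    }
  }
})

test_that("segmented IVIM fit inverts clean signals from the group medians", {
  for (p in list(lvi_pos_ivim, lvi_neg_ivim)) {
    fit <- fit_ivim_segmented(b_ivim, ivim_signal(b_ivim, p$d, p$dstar, p$f))
    expect_lt(rel_err(fit$d, p$d), 1e-4)
    expect_lt(rel_err(fit$dstar, p$dstar), 1e-4)
    expect_lt(rel_err(fit$f, p$f), 1e-4)
    expect_false(fit$clipped)
  }
})

test_that("full IVIM fit inverts clean signals to near machine precision", {
  for (p in list(lvi_pos_ivim, lvi_neg_ivim,
                 list(d = 1.5e-3, dstar = 20e-3, f = 0.12))) {
    s <- ivim_signal(b_ivim, p$d, p$dstar, p$f, s0 = 3.7)
    fit <- fit_ivim_full(b_ivim, s)
    expect_lt(rel_err(fit$d, p$d), 1e-6)
    expect_lt(rel_err(fit$dstar, p$dstar), 1e-6)
    expect_lt(rel_err(fit$f, p$f), 1e-6)
    expect_lt(rel_err(fit$s0, 3.7), 1e-6)
  }
})

test_that("full fit recovers truth from a perturbed initialization", {
  s <- ivim_signal(b_ivim, lvi_neg_ivim$d, lvi_neg_ivim$dstar, lvi_neg_ivim$f)
  init <- fit_ivim_segmented(b_ivim, s)
  init$d <- init$d * 1.5
  init$dstar <- init$dstar * 1.5
  init$f <- min(init$f * 1.5, 1)
  fit <- fit_ivim_full(b_ivim, s, init)
  expect_lt(rel_err(fit$d, lvi_neg_ivim$d), 1e-4)
  expect_lt(rel_err(fit$dstar, lvi_neg_ivim$dstar), 1e-4)
  expect_lt(rel_err(fit$f, lvi_neg_ivim$f), 1e-4)
})

test_that("an f = 0 signal fits to f ~ 0 with D at the generating value", {
  s <- ivim_signal(b_ivim, 1.1e-3, 30e-3, 0)
  fit <- fit_ivim_segmented(b_ivim, s)
  expect_lt(fit$f, 1e-6)
  expect_lt(rel_err(fit$d, 1.1e-3), 1e-6)
})

test_that("full refinement never increases the residual objective", {
  clean <- ivim_signal(b_ivim, lvi_pos_ivim$d, lvi_pos_ivim$dstar, lvi_pos_ivim$f)
  withr::with_seed(31, {
    for (i in 1:20) {
      s <- add_rician_noise(clean, 1, 30)
      seg <- fit_ivim_segmented(b_ivim, s)
      full <- fit_ivim_full(b_ivim, s, seg)
      expect_lte(full$rss, seg$rss + 1e-12)
    }
  })
})

test_that("full fit at least matches a dense grid search on noisy curves", {
  clean <- ivim_signal(b_ivim, lvi_pos_ivim$d, lvi_pos_ivim$dstar, lvi_pos_ivim$f)
  rss_profiled <- function(s, d, dstar, f) {
    g <- (1 - f) * exp(-b_ivim * d) + f * exp(-b_ivim * (dstar + d))
    s0 <- sum(s * g) / sum(g * g)
    sum((s - s0 * g)^2)
  }
  withr::with_seed(32, {
    for (i in 1:5) {
      s <- add_rician_noise(clean, 1, 50)
      full <- fit_ivim_full(b_ivim, s)
      grid_best <- min(sapply(seq(0.3e-3, 1.5e-3, length.out = 20), function(d) {
        min(sapply(exp(seq(log(5e-3), log(0.3), length.out = 20)), function(ds) {
          min(sapply(seq(0.05, 0.8, length.out = 20), function(f) {
            rss_profiled(s, d, ds, f)
          }))
        }))
      }))
      expect_lte(full$rss, grid_best + 1e-10)
    }
  })
})

test_that("IVIM precondition on the b-value split is enforced", {
  expect_error(fit_ivim_segmented(c(0, 100, 400, 600), rep(1, 4)), "below")
  expect_error(fit_ivim_segmented(c(0, 25, 50, 400, 600), exp(-(1:5))), ">= 3")
})

test_that("under Rician noise D* is far less stable than D", {
  clean <- ivim_signal(b_ivim, lvi_pos_ivim$d, lvi_pos_ivim$dstar, lvi_pos_ivim$f)
  fits <- withr::with_seed(33, replicate(100, {
    f <- fit_ivim_segmented(b_ivim, add_rician_noise(clean, 1, 50))
    c(f$d, f$dstar)
  }))
  expect_gt(sd(fits[2, ]) / median(fits[2, ]), sd(fits[1, ]) / median(fits[1, ]))
  expect_gt(sd(fits[2, ]), sd(fits[1, ]))
})

test_that("DKI fit inverts clean signals exactly and matches the closed-form solve", {
  for (p in list(lvi_pos_dki, lvi_neg_dki)) {
    s <- dki_signal(b_dki, p$dapp, p$kapp, validity = "none")
    fit <- fit_dki(b_dki, s)
    expect_lt(rel_err(fit$dapp, p$dapp), 1e-9)
    expect_lt(rel_err(fit$kapp, p$kapp), 1e-9)
  }
  # exactly three distinct b-values: interpolation equals the 2x2 solve of
  # the linear system in (Dapp, Dapp^2 Kapp / 6) built on the two positive b
  b3 <- c(0, 500, 1000)
  s3 <- dki_signal(b3, 2e-3, 0.9, validity = "none")
  y <- log(s3 / s3[1])
  A <- rbind(c(-500, 500^2), c(-1000, 1000^2))
  sol <- solve(A, y[2:3])
  fit3 <- fit_dki(b3, s3)
  expect_equal(fit3$dapp, sol[1], tolerance = 1e-10)
  expect_equal(fit3$kapp, 6 * sol[2] / sol[1]^2, tolerance = 1e-10)
})

test_that("a mono-exponential curve fits to the Kapp = 0 boundary", {
  s <- exp(-b_dki * 1.8e-3)
  fit <- fit_dki(b_dki, s)
  expect_equal(fit$kapp, 0, tolerance = 1e-12)
  expect_equal(fit$dapp, 1.8e-3, tolerance = 1e-9)
  # concave log-signal (negative curvature) must clip to the boundary
  s_neg <- exp(-b_dki * 1.8e-3 - b_dki^2 * 1e-7)
  fit_neg <- fit_dki(b_dki, s_neg)
  expect_identical(fit_neg$kapp, 0)
  expect_true(fit_neg$clipped)
})

test_that("DKI fit rejects schemes with too few distinct b-values", {
  expect_error(fit_dki(c(0, 800), c(1, 0.3)), "distinct")
})

test_that("ROI aggregation is the permutation-invariant arithmetic mean", {
  expect_equal(roi_aggregate(5), 5)
  expect_equal(roi_aggregate(c(1, 2, 3)), 2)
  v <- withr::with_seed(3, runif(50))
  expect_equal(roi_aggregate(v), roi_aggregate(rev(v)))
  expect_error(roi_aggregate(numeric(0)), "non-empty")
})
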