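# Inversion of the three diffusion signal models. All fitters take the
# b-values (s/mm2) and measured intensities as plain vectors; diffusivities
# are returned in mm2/s (i.e. 0.72e-3, not 0.72).

IVIM_BOUNDS <- list(d = c(1e-5, 5e-3), dstar = c(1e-5, 0.5), f = c(0, 1))

#' Mono-exponential ADC fit
#'
#' Ordinary least-squares slope of `log(signal)` against b, negated. With
#' exactly two b-values this is the textbook two-point ADC
#' `log(S1/S2) / (b2 - b1)`. When the underlying signal is bi-exponential
#' with perfusion fraction f > 0, the low-b perfusion decay contaminates
#' the estimate upward (ADC > D).
#'
#' @param b Numeric vector of b-values, s/mm2 (>= 2 distinct).
#' @param signal Positive intensities, same length as `b`.
#' @return ADC in mm2/s.
#' @examples
#' s <- ivim_signal(c(0, 800), d = 0.72e-3, dstar = 75.06e-3, f = 0.4156)
#' fit_adc(c(0, 800), s)   # ~1.39e-3, well above D
#' @export
fit_adc <- function(b, signal) {
  check_curve(b, signal, min_b = 2)
  -unname(coef(lm(log(signal) ~ b))[2])
}

#' Segmented bi-exponential IVIM fit
#'
#' The standard two-stage inversion of the ill-posed IVIM problem:
#' \enumerate{
#'   \item `D` from a log-linear fit over the high-b segment
#'     (`b >= b_threshold`), where the pseudo-diffusion term has decayed;
#'   \item `f` from the gap between the measured b = 0 intensity and the
#'     high-b intercept (`f = 1 - exp(intercept)/S(0)`);
#'   \item `D*` by a bounded one-dimensional least-squares fit of the full
#'     curve with `D` and `f` held fixed and the overall scale `s0`
#'     profiled out analytically.
#' }
#' Estimates are clipped to the box `D` in \[1e-5, 5e-3\], `D*` in
#' \[`D`, 0.5\] mm2/s, `f` in \[0, 1\]; clipping is flagged.
#'
#' @inheritParams fit_adc
#' @param b_threshold Split between perfusion-sensitive and pure-diffusion
#'   b-values, s/mm2 (default 200).
#' @return An `ivim_fit` list: `d`, `dstar`, `f`, `s0`, `rss`, `clipped`,
#'   `converged`, `method`.
#' @examples
#' b <- bvalue_scheme("ivim")
#' s <- ivim_signal(b, d = 0.96e-3, dstar = 68.19e-3, f = 0.41)
#' fit_ivim_segmented(b, s)
#' @export
fit_ivim_segmented <- function(b, signal, b_threshold = 200) {
  check_curve(b, signal, min_b = 4)
  hi <- b >= b_threshold
  lo <- b < b_threshold
  if (sum(hi) < 3 || sum(lo) < 2) {
    stop("need >= 3 b-values at/above the threshold and >= 2 below",
         call. = FALSE)
  }
  clipped <- FALSE
  # stage 1: tissue diffusion from the high-b log-linear segment
  fit_hi <- lm(log(signal[hi]) ~ b[hi])
  d <- -unname(coef(fit_hi)[2])
  if (d < IVIM_BOUNDS$d[1] || d > IVIM_BOUNDS$d[2]) {
    d <- min(max(d, IVIM_BOUNDS$d[1]), IVIM_BOUNDS$d[2])
    clipped <- TRUE
  }
  # stage 2: perfusion fraction from the b = 0 intercept gap
  s0_meas <- mean(signal[b == 0])
  f <- 1 - exp(unname(coef(fit_hi)[1])) / s0_meas
  if (f < 0 || f > 1) {
    f <- min(max(f, 0), 1)
    clipped <- TRUE
  }
  # stage 3: pseudo-diffusion by 1-D profile least squares (s0 analytic)
  shape <- function(dstar) (1 - f) * exp(-b * d) + f * exp(-b * (dstar + d))
  rss_of <- function(dstar) {
    g <- shape(dstar)
    s0 <- sum(signal * g) / sum(g * g)
    sum((signal - s0 * g)^2)
  }
  lower <- max(d, IVIM_BOUNDS$dstar[1])
  opt <- optimize(rss_of, interval = c(lower, IVIM_BOUNDS$dstar[2]), tol = 1e-10)
  dstar <- opt$minimum
  g <- shape(dstar)
  s0 <- sum(signal * g) / sum(g * g)
  structure(list(d = d, dstar = dstar, f = f, s0 = s0, rss = opt$objective,
                 clipped = clipped, converged = TRUE, method = "segmented",
                 b_threshold = b_threshold),
            class = "ivim_fit")
}

#' Full (simultaneous) bi-exponential IVIM fit
#'
#' Bounded Levenberg–Marquardt least squares over (`D`, `D*`, `f`, `s0`)
#' jointly, initialized from a segmented fit. The returned fit never has a
#' larger residual sum of squares than its initialization: if the optimizer
#' fails or does not improve, the initialization is returned with
#' `converged = FALSE`.
#'
#' @inheritParams fit_adc
#' @param init An `ivim_fit` (typically from [fit_ivim_segmented()]) or a
#'   list with elements `d`, `dstar`, `f` (and optionally `s0`).
#' @return An `ivim_fit` list (`method = "full"`).
#' @export
fit_ivim_full <- function(b, signal, init = fit_ivim_segmented(b, signal)) {
  check_curve(b, signal, min_b = 4)
  s0_init <- init$s0 %||% mean(signal[b == 0])
  par0 <- c(d = init$d, dstar = init$dstar, f = init$f, s0 = s0_init)
  resid_of <- function(p) {
    signal - p[4] * ((1 - p[3]) * exp(-b * p[1]) + p[3] * exp(-b * (p[2] + p[1])))
  }
  rss0 <- sum(resid_of(par0)^2)
  opt <- tryCatch(
    minpack.lm::nls.lm(
      par0, fn = resid_of,
      lower = c(IVIM_BOUNDS$d[1], IVIM_BOUNDS$dstar[1], IVIM_BOUNDS$f[1], 1e-12),
      upper = c(IVIM_BOUNDS$d[2], IVIM_BOUNDS$dstar[2], IVIM_BOUNDS$f[2], Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(opt) || opt$deviance > rss0) {
    out <- init
    out$method <- "full"
    out$converged <- FALSE
    return(out)
  }
  p <- unname(opt$par)
  clipped <- FALSE
  if (p[2] < p[1]) {  # keep the D* >= D ordering, resolve toward segmented
    p[2] <- p[1]
    clipped <- TRUE
  }
  structure(list(d = p[1], dstar = p[2], f = p[3], s0 = p[4],
                 rss = sum(resid_of(c(p[1], p[2], p[3], p[4]))^2),
                 clipped = clipped || isTRUE(init$clipped),
                 converged = opt$info %in% 1:4, method = "full"),
            class = "ivim_fit")
}

#' Diffusion kurtosis fit
#'
#' Least-squares fit of `log(signal)` to the quadratic kurtosis exponent
#' `log(s0) - b*Dapp + b^2*Dapp^2*Kapp/6`. The quadratic is linear in
#' `(Dapp, Dapp^2*Kapp/6)`, so the fit is an ordinary polynomial
#' regression; the constraints `Dapp > 0`, `Kapp >= 0` are enforced by
#' falling back to the mono-exponential fit (`Kapp = 0`) when the
#' unconstrained curvature is negative. With exactly three distinct
#' b-values and clean data the result is the exact closed-form solve.
#'
#' @inheritParams fit_adc
#' @return A `dki_fit` list: `dapp`, `kapp`, `s0`, `clipped`.
#' @examples
#' b <- bvalue_scheme("dki")
#' s <- suppressWarnings(dki_signal(b, dapp = 2.69e-3, kapp = 0.70))
#' fit_dki(b, s)
#' @export
fit_dki <- function(b, signal) {
  check_curve(b, signal, min_b = 3)
  y <- log(signal)
  X <- cbind(1, -b, b^2)
  if (qr(X)$rank < 3) {
    stop("degenerate design: b and b^2 are collinear over this scheme",
         call. = FALSE)
  }
  beta <- qr.solve(X, y)  # least squares via QR
  dapp <- beta[2]
  curv <- beta[3]
  clipped <- FALSE
  if (dapp <= 0 || curv < 0) {
    # boundary: mono-exponential (Kapp = 0)
    fit <- lm(y ~ b)
    dapp <- max(-unname(coef(fit)[2]), .Machine$double.eps)
    clipped <- TRUE
    return(structure(list(dapp = dapp, kapp = 0,
                          s0 = exp(unname(coef(fit)[1])), clipped = clipped),
                     class = "dki_fit"))
  }
  kapp <- 6 * curv / dapp^2
  structure(list(dapp = unname(dapp), kapp = unname(kapp),
                 s0 = exp(unname(beta[1])), clipped = clipped),
            class = "dki_fit")
}

#' ROI aggregation of voxel-wise parameter values
#'
#' The per-lesion value entering the cohort table is the arithmetic mean of
#' the voxel-wise parameter over the delineated region of interest.
#'
#' @param values Non-empty numeric vector of per-voxel values.
#' @return Arithmetic mean.
#' @export
roi_aggregate <- function(values) {
  if (length(values) == 0 || !is.numeric(values)) {
    stop("roi_aggregate needs a non-empty numeric vector", call. = FALSE)
  }
  mean(values)
}

check_curve <- function(b, signal, min_b) {
  if (!is.numeric(b) || !is.numeric(signal) || length(b) != length(signal)) {
    stop("b and signal must be numeric vectors of equal length", call. = FALSE)
  }
  if (length(unique(b)) < min_b) {
    stop("need at least ", min_b, " distinct b-values", call. = FALSE)
  }
  if (any(!is.finite(signal)) || any(signal <= 0)) {
    stop("signal intensities must be finite and positive", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.ivim_fit <- function(x, ...) {
  cat(sprintf("IVIM fit (%s): D = %.4g, D* = %.4g, f = %.4f, s0 = %.4g%s\n",
              x$method, x$d, x$dstar, x$f, x$s0,
              if (x$clipped) " [clipped]" else ""))
  invisible(x)
}

#' @export
print.dki_fit <- function(x, ...) {
  cat(sprintf("DKI fit: Dapp = %.4g, Kapp = %.4f, s0 = %.4g%s\n",
              x$dapp, x$kapp, x$s0, if (x$clipped) " [Kapp at boundary]" else ""))
  invisible(x)
}
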