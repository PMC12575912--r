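#' Bi-exponential IVIM forward signal model
#'
#' Evaluates the intravoxel incoherent motion signal equation
#' \deqn{S_b/S_0 = (1 - f)\exp(-bD) + f\exp(-b(D^* + D))}
#' where `D` is the true (tissue) diffusion coefficient, `D*` the
#' pseudo-diffusion coefficient of capillary microperfusion, and `f` the
#' perfusion fraction.
#'
#' @param b Numeric vector of b-values, s/mm2.
#' @param d True diffusion coefficient, mm2/s (e.g. 0.72e-3).
#' @param dstar Pseudo-diffusion coefficient, mm2/s; must be >= `d`.
#' @param f Perfusion fraction in \[0, 1\].
#' @param s0 Signal at b = 0 (arbitrary units), > 0.
#' @return Numeric vector of signal intensities, one per b-value.
#' @examples
#' b <- bvalue_scheme("ivim")
#' ivim_signal(b, d = 0.72e-3, dstar = 75.06e-3, f = 0.4156)
#' @export
ivim_signal <- function(b, d, dstar, f, s0 = 1) {
  stopifnot(is.numeric(b), all(is.finite(b)), all(b >= 0))
  if (!is.finite(d) || d <= 0) stop("d must be > 0", call. = FALSE)
  if (!is.finite(dstar) || dstar < d) {
    stop("dstar must be >= d (pseudo-diffusion is faster than true diffusion)",
         call. = FALSE)
  }
  if (!is.finite(f) || f < 0 || f > 1) stop("f must lie in [0, 1]", call. = FALSE)
  if (!is.finite(s0) || s0 <= 0) stop("s0 must be > 0", call. = FALSE)
  s0 * ((1 - f) * exp(-b * d) + f * exp(-b * (dstar + d)))
}

#' Diffusion kurtosis forward signal model
#'
#' Evaluates the DKI signal equation
#' \deqn{S_b = S_0 \exp(-b D_{app} + b^2 D_{app}^2 K_{app}/6)}
#' with `Dapp` the kurtosis-corrected diffusivity and `Kapp` the apparent
#' kurtosis (departure from Gaussian diffusion). The quadratic expansion is
#' only a valid decay model for `b <= 3 / (Dapp * Kapp)`
#' (see [dki_validity_bound()]); beyond that bound the modeled signal turns
#' upward, which is unphysical.
#'
#' @param b Numeric vector of b-values, s/mm2.
#' @param dapp Kurtosis-corrected diffusion coefficient, mm2/s, > 0.
#' @param kapp Apparent kurtosis, dimensionless, >= 0.
#' @param s0 Signal at b = 0, > 0.
#' @param validity What to do when some `b` exceeds the validity bound:
#'   `"warn"` (default; the signal is still returned), `"error"`, or
#'   `"none"`.
#' @return Numeric vector of signal intensities.
#' @examples
#' b <- bvalue_scheme("dki")
#' suppressWarnings(dki_signal(b, dapp = 2.29e-3, kapp = 0.84))
#' @export
dki_signal <- function(b, dapp, kapp, s0 = 1,
                       validity = c("warn", "error", "none")) {
  validity <- match.arg(validity)
  stopifnot(is.numeric(b), all(is.finite(b)), all(b >= 0))
  if (!is.finite(dapp) || dapp <= 0) stop("dapp must be > 0", call. = FALSE)
  if (!is.finite(kapp) || kapp < 0) stop("kapp must be >= 0", call. = FALSE)
  if (!is.finite(s0) || s0 <= 0) stop("s0 must be > 0", call. = FALSE)
  bound <- dki_validity_bound(dapp, kapp)
  if (validity != "none" && any(b > bound)) {
    msg <- sprintf(
      "b-values %s exceed the kurtosis-model validity bound 3/(Dapp*Kapp) = %.1f s/mm2",
      paste(b[b > bound], collapse = ", "), bound)
    if (validity == "error") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  s0 * exp(-b * dapp + b^2 * dapp^2 * kapp / 6)
}

#' Validity bound of the kurtosis signal expansion
#'
#' The b-value at which the quadratic kurtosis exponent stops decreasing:
#' `3 / (dapp * kapp)`. Infinite when `kapp = 0` (mono-exponential decay).
#'
#' @inheritParams dki_signal
#' @return Bound in s/mm2.
#' @export
dki_validity_bound <- function(dapp, kapp) {
  if (kapp <= 0) Inf else 3 / (dapp * kapp)
}

#' Add Rician noise to a magnitude MR signal
#'
#' Magnitude MR data are Rician distributed: each noisy intensity is
#' `sqrt((s + n1)^2 + n2^2)` with `n1`, `n2` independent zero-mean Gaussian
#' noise of standard deviation `s0 / snr`. At high SNR this is close to
#' additive Gaussian noise; at low SNR it biases intensities upward (a pure
#' noise voxel has mean `sigma * sqrt(pi/2)`, the Rayleigh mean).
#'
#' @param signal Numeric vector of noise-free intensities, >= 0.
#' @param s0 Reference intensity at b = 0 used to scale the noise.
#' @param snr Signal-to-noise ratio `s0 / sigma`; `Inf` returns the input.
#' @param seed Optional integer seed; when given the call is reproducible
#'   and does not disturb the global RNG stream.
#' @return Numeric vector of noisy intensities (all > 0 almost surely).
#' @examples
#' s <- ivim_signal(bvalue_scheme("ivim"), 1e-3, 20e-3, 0.2)
#' add_rician_noise(s, s0 = 1, snr = 50, seed = 1)
#' @export
add_rician_noise <- function(signal, s0 = max(signal), snr, seed = NULL) {
  stopifnot(is.numeric(signal), all(is.finite(signal)))
  if (!is.finite(s0) || s0 <= 0) stop("s0 must be > 0", call. = FALSE)
  if (is.na(snr) || snr <= 0) stop("snr must be > 0", call. = FALSE)
  if (is.infinite(snr)) return(signal)
  sigma <- s0 / snr
  draw <- function() {
    n <- length(signal)
    sqrt((signal + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
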