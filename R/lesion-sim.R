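#' Generate a synthetic PET lesion volume
#'
#' Builds a voxel grid of SUV values holding one spherical lesion at the
#' grid center on a uniform background, a deliberately simple stand-in for
#' a reconstructed FDG-PET volume used to exercise the VOI extraction and
#' metric code. The uptake profile is either uniform or radially tapered
#' (linearly from `suv_peak` at the center to the background at the lesion
#' edge), with optional additive Gaussian noise clamped at zero.
#'
#' @param suv_peak Peak lesion SUV, g/cm3; must exceed `background`.
#' @param background Background SUV, >= 0.
#' @param radius Lesion radius, mm.
#' @param spacing Voxel spacing, mm; scalar or length-3 (per axis).
#' @param dim Optional grid dimensions (length-3 integer); default is the
#'   smallest odd grid leaving a 2-voxel margin around the sphere.
#' @param profile `"uniform"` or `"tapered"`.
#' @param noise_sd Standard deviation of additive Gaussian noise (SUV
#'   units); 0 for a noise-free volume.
#' @param seed Optional seed for the noise.
#' @return A `pet_volume`: list with `suv` (3-D array, g/cm3) and `spacing`
#'   (mm per axis).
#' @examples
#' vol <- generate_lesion_volume(suv_peak = 6.07, background = 1,
#'                               radius = 10, spacing = 2)
#' max(vol$suv)
#' @export
generate_lesion_volume <- function(suv_peak, background = 0, radius = 10,
                                   spacing = 2, dim = NULL,
                                   profile = c("uniform", "tapered"),
                                   noise_sd = 0, seed = NULL) {
  profile <- match.arg(profile)
  if (!is.finite(suv_peak) || !is.finite(background) ||
      background < 0 || suv_peak <= background) {
    stop("need suv_peak > background >= 0", call. = FALSE)
  }
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  if (radius <= max(spacing)) stop("radius must exceed the voxel spacing", call. = FALSE)
  if (is.null(dim)) {
    dim <- 2L * (ceiling(radius / spacing) + 2L) + 1L
  }
  dim <- as.integer(dim)
  if (length(dim) == 1) dim <- rep(dim, 3L)
  half_extent <- (dim - 1) / 2 * spacing
  if (any(radius > half_extent)) {
    stop("lesion radius exceeds the grid extent", call. = FALSE)
  }
  center <- (dim + 1) / 2
  ax <- lapply(1:3, function(k) (seq_len(dim[k]) - center[k]) * spacing[k])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  r <- sqrt(r2)
  suv <- array(background, dim)
  inside <- r <= radius
  suv[inside] <- if (profile == "uniform") {
    suv_peak
  } else {
    suv_peak - (suv_peak - background) * r[inside] / radius
  }
  if (noise_sd > 0) {
    add <- function() array(rnorm(length(suv), 0, noise_sd), dim)
    noise <- if (is.null(seed)) add() else withr::with_seed(seed, add())
    suv <- pmax(suv + noise, 0)
  }
  structure(list(suv = suv, spacing = spacing), class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  cat(sprintf("PET volume: %s voxels at %s mm, SUV range [%.3g, %.3g]\n",
              paste(dim(x$suv), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$suv), max(x$suv)))
  invisible(x)
}
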