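#' Extract a lesion volume of interest by isocontour thresholding
#'
#' Standard automatic FDG-PET VOI rule: threshold the volume at a fraction
#' of the global SUVmax (default 40%) and keep the 26-connected component
#' containing the hottest voxel.
#'
#' @param volume A `pet_volume` (see [generate_lesion_volume()]) or a list
#'   with `suv` (3-D array) and `spacing` (mm per axis).
#' @param threshold_fraction Isocontour level as a fraction of SUVmax,
#'   in (0, 1).
#' @return A `lesion_voi`: list with the logical `mask`, the `volume`, the
#'   absolute `threshold` (g/cm3) and the `fraction` used.
#' @export
extract_voi <- function(volume, threshold_fraction = 0.4) {
  vol <- as_pet_volume(volume)
  if (!is.finite(threshold_fraction) ||
      threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop("threshold_fraction must lie in (0, 1)", call. = FALSE)
  }
  suv <- vol$suv
  suvmax <- max(suv)
  if (suvmax <= 0) stop("volume has no positive uptake", call. = FALSE)
  thr <- threshold_fraction * suvmax
  above <- suv >= thr
  if (!any(above)) stop("no voxel at or above the threshold", call. = FALSE)
  seed <- which.max(suv)
  mask <- connected_component(above, seed)
  structure(list(mask = mask, volume = vol, threshold = thr,
                 fraction = threshold_fraction),
            class = "lesion_voi")
}

# 26-connected component of `mask` containing linear index `seed`,
# grown by vectorized frontier expansion.
connected_component <- function(mask, seed) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  lab <- array(FALSE, d)
  lab[seed] <- TRUE
  frontier <- matrix(arrayInd(seed, d), ncol = 3)
  while (nrow(frontier) > 0) {
    cand <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k) {
      sweep(frontier, 2, offs[k, ], "+")
    }))
    ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
          cand[, 2] >= 1 & cand[, 2] <= d[2] &
          cand[, 3] >= 1 & cand[, 3] <= d[3]
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0) break
    lin <- cand[, 1] + (cand[, 2] - 1) * d[1] + (cand[, 3] - 1) * d[1] * d[2]
    keep <- !duplicated(lin) & mask[lin] & !lab[lin]
    lin <- lin[keep]
    if (length(lin) == 0) break
    lab[lin] <- TRUE
    frontier <- matrix(arrayInd(lin, d), ncol = 3)
  }
  lab
}

#' PET metrics of a lesion VOI
#'
#' Computes the three standard PET lesion metrics over the VOI mask:
#' SUVmax (max over the mask, g/cm3), metabolic tumor volume
#' MTV = voxel count x voxel volume (cm3), SUVmean, and total lesion
#' glycolysis TLG = SUVmean x MTV (g). TLG = SUVmean x MTV holds exactly
#' by construction.
#'
#' @param voi A `lesion_voi` from [extract_voi()].
#' @return One-row tibble: `suvmax`, `suvmean`, `mtv_cm3`, `tlg_g`,
#'   `n_voxels`, `threshold_fraction`.
#' @export
compute_pet_metrics <- function(voi) {
  stopifnot(inherits(voi, "lesion_voi"))
  vals <- voi$volume$suv[voi$mask]
  if (length(vals) == 0) stop("empty VOI mask", call. = FALSE)
  voxel_cm3 <- prod(voi$volume$spacing) / 1000  # mm3 -> cm3
  mtv <- length(vals) * voxel_cm3
  suvmean <- mean(vals)
  tibble::tibble(
    suvmax = max(vals),
    suvmean = suvmean,
    mtv_cm3 = mtv,
    tlg_g = suvmean * mtv,
    n_voxels = length(vals),
    threshold_fraction = voi$fraction
  )
}

as_pet_volume <- function(volume) {
  if (inherits(volume, "pet_volume")) return(volume)
  if (is.list(volume) && !is.null(volume$suv) && !is.null(volume$spacing)) {
    if (any(volume$suv < 0)) stop("SUV values must be >= 0", call. = FALSE)
    if (any(volume$spacing <= 0)) stop("spacing must be positive", call. = FALSE)
    return(structure(list(suv = volume$suv, spacing = volume$spacing),
                     class = "pet_volume"))
  }
  stop("not a PET volume (need fields suv and spacing)", call. = FALSE)
}
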