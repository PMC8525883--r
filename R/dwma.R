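# Objective DWMA (diffuse white matter abnormality) quantification: voxels of
# a T2-weighted volume whose intensity exceeds mean + alpha * SD of the
# cerebral (white + gray matter) tissue, swept over a series of thresholds.

#' Bundle tissue masks into a segmentation object
#'
#' @param wm,gm,csf Logical (or 0/1) arrays on the T2 grid: white matter,
#'   gray matter, cerebrospinal fluid. Must be pairwise disjoint.
#' @param voxel_volume Voxel volume in cubic millimetres (> 0).
#' @return A `tissue_segmentation` list.
#' @export
tissue_segmentation <- function(wm, gm, csf, voxel_volume = 1) {
  wm <- array(as.logical(wm), dim(wm))
  gm <- array(as.logical(gm), dim(gm))
  csf <- array(as.logical(csf), dim(csf))
  stopifnot(identical(dim(wm), dim(gm)), identical(dim(wm), dim(csf)))
  if (any(wm & gm) || any(wm & csf) || any(gm & csf)) {
    stop("tissue masks must be pairwise disjoint")
  }
  if (!is.finite(voxel_volume) || voxel_volume <= 0) stop("voxel_volume must be > 0")
  structure(list(wm = wm, gm = gm, csf = csf, voxel_volume = voxel_volume),
            class = "tissue_segmentation")
}

#' Detect DWMA at a single intensity threshold
#'
#' A voxel is DWMA when it belongs to cerebral tissue (white or gray matter)
#' and its T2 intensity exceeds `mean + alpha * SD`, where mean and SD are
#' computed over all cerebral-tissue voxels. The detected volume is the voxel
#' count times the voxel volume.
#'
#' @param intensity Numeric T2 intensity array.
#' @param seg A [tissue_segmentation()] on the same grid.
#' @param alpha Positive threshold multiplier.
#' @return List with `mask` (logical array, subset of wm | gm), `volume_mm3`,
#'   and the `threshold` used.
#' @export
detect_dwma <- function(intensity, seg, alpha) {
  stopifnot(inherits(seg, "tissue_segmentation"), is.finite(alpha), alpha > 0)
  if (!identical(dim(intensity), dim(seg$wm))) {
    stop("intensity grid does not match segmentation grid")
  }
  cerebral <- seg$wm | seg$gm
  if (!any(cerebral)) stop("empty cerebral mask (wm | gm): cannot quantify DWMA")
  vals <- intensity[cerebral]
  thr <- mean(vals) + alpha * stats::sd(vals)
  mask <- cerebral & (intensity > thr)
  list(mask = mask, volume_mm3 = sum(mask) * seg$voxel_volume, threshold = thr)
}

#' DWMA feature vector: threshold sweep plus volumetric confounders
#'
#' Sweeps the threshold multiplier alpha from 1.4 to 2.0 in increments of
#' 0.1 and records, at each alpha, the DWMA volume normalized by total
#' cerebral white matter volume. Four volumetric confounders are appended:
#' white matter, gray matter, CSF, and total cerebral (wm + gm) volume,
#' giving the fixed 11-element feature vector. Note the 11th element: seven
#' thresholds plus the three tissue volumes total ten, and total cerebral
#' volume — the natural companion of the normalizing white-matter denominator
#' — completes the fixed dimensionality of eleven.
#'
#' @param intensity Numeric T2 intensity array.
#' @param seg A [tissue_segmentation()].
#' @param alphas Threshold multipliers (default `seq(1.4, 2.0, by = 0.1)`).
#' @return Named numeric vector of length `length(alphas) + 4`: normalized
#'   DWMA volumes (non-increasing in alpha) then `wm_volume`, `gm_volume`,
#'   `csf_volume`, `cerebral_volume` in cubic millimetres.
#' @export
dwma_features <- function(intensity, seg, alphas = seq(1.4, 2.0, by = 0.1)) {
  stopifnot(inherits(seg, "tissue_segmentation"))
  wm_vol <- sum(seg$wm) * seg$voxel_volume
  if (wm_vol <= 0) stop("zero white-matter volume: normalized DWMA undefined")
  gm_vol <- sum(seg$gm) * seg$voxel_volume
  csf_vol <- sum(seg$csf) * seg$voxel_volume
  norm_vols <- vapply(alphas, function(a) {
    detect_dwma(intensity, seg, a)$volume_mm3 / wm_vol
  }, numeric(1))
  out <- c(norm_vols, wm_vol, gm_vol, csf_vol, wm_vol + gm_vol)
  names(out) <- c(sprintf("dwma_norm_a%.1f", alphas),
                  "wm_volume", "gm_volume", "csf_volume", "cerebral_volume")
  out
}

#' Compute a DWMA feature vector from NIfTI files
#'
#' File-level convenience used by the command-line entry point.
#' @param t2_path T2 intensity NIfTI; `wm_path`, `gm_path`, `csf_path` binary
#'   mask NIfTIs on the same grid.
#' @inheritParams dwma_features
#' @export
dwma_features_from_files <- function(t2_path, wm_path, gm_path, csf_path,
                                     alphas = seq(1.4, 2.0, by = 0.1)) {
  t2 <- read_volume(t2_path)
  seg <- tissue_segmentation(read_volume(wm_path)$data > 0.5,
                             read_volume(gm_path)$data > 0.5,
                             read_volume(csf_path)$data > 0.5,
                             voxel_volume = t2$voxel_volume)
  dwma_features(t2$data, seg, alphas)
}
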