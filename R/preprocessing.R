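# ROI preparation: isotropic resampling and equal-probability quantization.
# Everything downstream (texture matrices, descriptors) consumes these two
# containers only.

#' Isotropic masked region of interest
#'
#' @param intensities cropped HU grid
#' @param mask congruent logical grid
#' @param spacing_mm the single isotropic spacing
#' @return object of class `isotropic_roi`
#' @export
isotropic_roi <- function(intensities, mask, spacing_mm) {
  stopifnot(identical(dim(intensities), dim(mask)), length(spacing_mm) == 1,
            spacing_mm > 0)
  if (!any(mask)) stopf("empty segmentation")
  structure(list(intensities = intensities, mask = mask,
                 spacing_mm = spacing_mm),
            class = "isotropic_roi")
}

#' Resample a volume and mask onto an isotropic lattice and crop to the lesion
#'
#' Nearest-neighbor interpolation for both grids (the mask stays binary and
#' no new intensity values are invented). The output is cropped to the mask
#' bounding box plus a 2-voxel margin.
#'
#' @param volume a [ct_volume()]
#' @param mask a [segmentation_mask()] on the same grid
#' @param target_spacing_mm isotropic target spacing (default 1 mm, inside
#'   the 1-3 mm reconstruction range of thoracic CT)
#' @return an [isotropic_roi()]
#' @export
resample_isotropic <- function(volume, mask, target_spacing_mm = 1) {
  stopifnot(inherits(volume, "ct_volume"),
            inherits(mask, "segmentation_mask"))
  if (length(target_spacing_mm) != 1 || target_spacing_mm <= 0)
    stopf("target spacing must be a single positive number")
  if (!identical(dim(mask$labels), dim(volume$intensities)))
    stopf("geometry error: mask and volume grids differ")
  d <- dim(volume$intensities)
  sp <- volume$spacing_mm
  t <- target_spacing_mm
  idx_axis <- function(a) {
    extent <- (d[a] - 1) * sp[a]
    tc <- seq(0, extent, by = t)
    pmin(pmax(round(tc / sp[a]) + 1, 1), d[a])
  }
  ix <- idx_axis(1); iy <- idx_axis(2); iz <- idx_axis(3)
  vol_rs <- volume$intensities[ix, iy, iz, drop = FALSE]
  msk_rs <- mask$labels[ix, iy, iz, drop = FALSE]
  if (!any(msk_rs)) stopf("degenerate lesion: mask empty after resampling")
  w <- which(msk_rs, arr.ind = TRUE)
  lo <- pmax(apply(w, 2, min) - 2, 1)
  hi <- pmin(apply(w, 2, max) + 2, dim(msk_rs))
  isotropic_roi(vol_rs[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
                msk_rs[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
                t)
}

#' Gray levels of the default quantization ladder
#' @export
default_gray_levels <- function() c(8L, 16L, 24L, 32L, 40L, 48L, 64L)

#' Equal-probability quantization of an ROI
#'
#' Decision thresholds are the empirical quantiles of the in-mask intensities
#' at ranks `ceiling(k * N / G)`, so each of the G levels holds (up to ties)
#' the same number of voxels. Voxels equal to a threshold go to the lower
#' level; out-of-mask voxels get level 0 and never influence the thresholds.
#' A constant ROI maps entirely to level 1. If G exceeds the number of
#' distinct in-mask values the quantizer falls back to a rank-dense mapping
#' with a warning.
#'
#' @param roi an [isotropic_roi()]
#' @param G number of gray levels (>= 2)
#' @return object of class `quantized_roi` with fields `levels` (integer
#'   grid, 0 outside the mask), `G`, `thresholds`, `mask`, `spacing_mm`
#' @export
quantize_equal_probability <- function(roi, G) {
  stopifnot(inherits(roi, "isotropic_roi"))
  G <- as.integer(G)
  if (G < 2) stopf("G must be at least 2")
  v <- roi$intensities[roi$mask]
  n <- length(v)
  lv <- integer(n)
  uniq <- sort(unique(v))
  if (length(uniq) == 1) {
    lv[] <- 1L
    thresholds <- numeric(0)
  } else if (length(uniq) < G) {
    warning(sprintf(
      "G = %d exceeds the %d distinct in-mask intensities; using rank-dense levels",
      G, length(uniq)), call. = FALSE)
    lv <- match(v, uniq)
    thresholds <- uniq[-length(uniq)]
  } else {
    s <- sort(v)
    thresholds <- s[ceiling(seq_len(G - 1) * n / G)]
    lv <- findInterval(v, unique(thresholds), left.open = TRUE) + 1L
    # duplicated thresholds (heavy ties) collapse levels; renumber densely so
    # the level range stays contiguous
    if (anyDuplicated(thresholds)) lv <- match(lv, sort(unique(lv)))
  }
  levels <- array(0L, dim(roi$mask))
  levels[roi$mask] <- lv
  structure(list(levels = levels, G = G, thresholds = thresholds,
                 mask = roi$mask, spacing_mm = roi$spacing_mm),
            class = "quantized_roi")
}
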