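#' Calibrated CT volume
#'
#' Container for a 3-D grid of Hounsfield-unit intensities with its voxel
#' geometry. The package-wide axis convention is `(x, y, z)` with index 1 at
#' the origin; the world coordinate of voxel `(i, j, k)` is
#' `origin_mm + (c(i, j, k) - 1) * voxel_spacing_mm`.
#'
#' @param intensities numeric 3-D array of HU values (rescale already applied)
#' @param spacing_mm strictly positive voxel spacing, length 3
#' @param origin_mm world coordinate of the first voxel, length 3
#' @return an object of class `ct_volume`
#' @export
ct_volume <- function(intensities, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (length(dim(intensities)) != 3)
    stopf("intensities must be a 3-D array")
  if (length(spacing_mm) != 3 || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stopf("voxel spacing must be three strictly positive numbers")
  if (any(!is.finite(intensities)))
    stopf("intensities contain non-finite values")
  structure(list(intensities = intensities,
                 spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<ct_volume> %dx%dx%d voxels, spacing %s mm, HU range [%.1f, %.1f]\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing_mm, 4), collapse = "x"),
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Binary tumor segmentation aligned to a CT volume
#'
#' Nonzero labels are collapsed to a single binary foreground. Geometry must
#' match the reference volume exactly.
#'
#' @param labels 3-D array (logical or numeric label volume)
#' @param reference the [ct_volume()] the mask annotates
#' @return an object of class `segmentation_mask`
#' @export
segmentation_mask <- function(labels, reference) {
  stopifnot(inherits(reference, "ct_volume"))
  if (!identical(dim(labels), dim(reference$intensities)))
    stopf(paste0("geometry error: mask grid %s does not match volume grid %s"),
          paste(dim(labels), collapse = "x"),
          paste(dim(reference$intensities), collapse = "x"))
  fg <- array(labels != 0, dim(labels))
  if (!any(fg)) stopf("empty segmentation")
  structure(list(labels = fg,
                 spacing_mm = reference$spacing_mm,
                 origin_mm = reference$origin_mm),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("<segmentation_mask> %d foreground voxels (%.1f mm3)\n",
              sum(x$labels), sum(x$labels) * prod(x$spacing_mm)))
  invisible(x)
}

#' Keep the largest 26-connected component of a binary array
#' @keywords internal
largest_component <- function(fg) {
  lab <- cpp_label_zones(as.integer(fg), as.integer(dim(fg)), TRUE)
  if (max(lab) <= 1) return(fg)
  counts <- tabulate(lab[lab > 0])
  array(lab == which.max(counts), dim(fg))
}

#' Read a CT volume from a DICOM series directory or a NIfTI file
#'
#' @param path directory of `.dcm` files, or a `.nii` / `.nii.gz` file
#' @return a [ct_volume()] in HU, slices sorted by spatial position
#' @export
read_ct_series <- function(path) {
  if (dir.exists(path)) return(read_dicom_series(path))
  if (!file.exists(path)) stopf("file not found: %s", path)
  nii <- read_nifti(path)
  ct_volume(nii$data, spacing_mm = nii$spacing, origin_mm = nii$origin)
}

#' Write a CT volume to NIfTI
#' @param volume a [ct_volume()]
#' @param path `.nii` or `.nii.gz` output path
#' @export
write_ct_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  write_nifti(volume$intensities, path, spacing = volume$spacing_mm,
              origin = volume$origin_mm, datatype = 64L)
}

#' Read a segmentation mask and bind it to its reference volume
#'
#' Nonzero labels become foreground; if the foreground has several
#' 26-connected components only the largest lesion is kept (the pipeline
#' analyses one target lesion per subject).
#'
#' @param path NIfTI label volume
#' @param reference the [ct_volume()] the mask belongs to
#' @param spacing_tol geometry agreement tolerance in mm
#' @return a [segmentation_mask()]
#' @export
read_mask <- function(path, reference, spacing_tol = 1e-4) {
  stopifnot(inherits(reference, "ct_volume"))
  nii <- read_nifti(path)
  if (!identical(dim(nii$data), dim(reference$intensities)))
    stopf("geometry error: mask %s is %s but volume is %s", path,
          paste(dim(nii$data), collapse = "x"),
          paste(dim(reference$intensities), collapse = "x"))
  if (any(abs(nii$spacing - reference$spacing_mm) > spacing_tol))
    stopf("geometry error: mask %s spacing (%s) differs from volume (%s)",
          path, paste(signif(nii$spacing, 6), collapse = "x"),
          paste(signif(reference$spacing_mm, 6), collapse = "x"))
  fg <- nii$data != 0
  if (!any(fg)) stopf("empty segmentation: %s", path)
  segmentation_mask(largest_component(array(fg, dim(nii$data))), reference)
}

#' Write a segmentation mask as an unsigned 8-bit NIfTI label volume
#' @param mask a [segmentation_mask()]
#' @param path `.nii` or `.nii.gz` output path
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "segmentation_mask"))
  write_nifti(array(as.integer(mask$labels), dim(mask$labels)), path,
              spacing = mask$spacing_mm, origin = mask$origin_mm,
              datatype = 2L)
}

#' World coordinate of a voxel index
#' @param index 1-based voxel index, length 3
#' @param geom a `ct_volume` or `segmentation_mask`
#' @return world coordinate in mm
#' @export
world_coordinate <- function(index, geom) {
  geom$origin_mm + (as.numeric(index) - 1) * geom$spacing_mm
}
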