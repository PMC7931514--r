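#' SUV image container
#'
#' A 3D grid of standardized-uptake values (SUV, g/ml) together with its voxel
#' spacing in mm. All pipeline stages (segmentation, preprocessing, feature
#' extraction) consume this container. Values must be finite and non-negative;
#' spacing components must be positive.
#'
#' @param values numeric 3D array of SUV values (g/ml).
#' @param spacing numeric length-3 vector, voxel edge lengths (dx, dy, dz) in mm.
#' @return An object of class `suv_image` with elements `values` and `spacing`.
#' @examples
#' img <- suv_image(array(1, c(8, 8, 8)), spacing = c(2, 2, 2))
#' voxel_volume_cc(img)
#' @export
suv_image <- function(values, spacing = c(2, 2, 2)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive numbers (mm)")
  if (any(!is.finite(values)))
    stop("SUV values must be finite")
  if (any(values < 0))
    stop("SUV values must be non-negative")
  structure(list(values = values, spacing = spacing), class = "suv_image")
}

#' @export
print.suv_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<suv_image> %d x %d x %d voxels, spacing %g x %g x %g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  SUV range [%.4g, %.4g], mean %.4g\n",
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

#' @export
dim.suv_image <- function(x) dim(x$values)

#' Voxel volume in cc
#'
#' @param x an `suv_image` or a numeric length-3 spacing vector in mm.
#' @return Voxel volume in cubic centimetres (1 cc = 1000 mm^3).
#' @export
voxel_volume_cc <- function(x) {
  sp <- if (inherits(x, "suv_image")) x$spacing else as.numeric(x)
  prod(sp) / 1000
}

# Physical coordinates (mm) of voxel centers along one axis: index i -> (i-1)*d
axis_mm <- function(n, d) (seq_len(n) - 1) * d

#' Spherical voxel mask
#'
#' Voxel membership uses the voxel-center-inside-sphere test (no partial
#' volume weighting): a voxel belongs to the sphere iff the Euclidean distance
#' from its center to `center_vox` (in mm, respecting anisotropic spacing) is
#' at most `radius_mm`.
#'
#' @param dim integer length-3 grid dimensions.
#' @param spacing voxel spacing in mm.
#' @param center_vox sphere center in voxel coordinates (may be fractional).
#' @param radius_mm sphere radius in mm.
#' @return Logical 3D array.
#' @export
sphere_mask <- function(dim, spacing, center_vox, radius_mm) {
  if (radius_mm <= 0) stop("radius_mm must be positive")
  dx <- outer(
    outer((seq_len(dim[1]) - center_vox[1])^2 * spacing[1]^2,
          (seq_len(dim[2]) - center_vox[2])^2 * spacing[2]^2, "+"),
    (seq_len(dim[3]) - center_vox[3])^2 * spacing[3]^2, "+")
  array(dx <= radius_mm^2, dim)
}

# radius (mm) of a sphere of given volume in cc
sphere_radius_mm <- function(volume_cc) (3 * volume_cc * 1000 / (4 * pi))^(1 / 3)

# does a sphere fit fully inside the grid?
sphere_inside <- function(dim, spacing, center_vox, radius_mm) {
  lo <- (center_vox - 1) * spacing - radius_mm
  hi <- (center_vox - 1) * spacing + radius_mm
  all(lo >= 0) && all(hi <= (dim - 1) * spacing)
}

check_same_grid <- function(a, b, what = "masks") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s are defined on different grids", what))
  invisible(TRUE)
}

# bounding box of a logical mask, as list(i=, j=, k=) index ranges
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask")
  lapply(1:3, function(a) range(idx[, a]))
}

crop_to_bbox <- function(arr, bb) {
  arr[bb[[1]][1]:bb[[1]][2], bb[[2]][1]:bb[[2]][2], bb[[3]][1]:bb[[3]][2],
      drop = FALSE]
}

#' Read / write SUV volumes as NIfTI-1
#'
#' Thin wrappers around \pkg{RNifti}: the affine encodes the voxel spacing.
#' Masks are written as 0/1 volumes.
#'
#' @param x an `suv_image`, or a logical mask array for `write_mask_nifti`.
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `read_suv_nifti` returns an `suv_image`; the writers return `path`
#'   invisibly.
#' @export
write_suv_nifti <- function(x, path) {
  stopifnot(inherits(x, "suv_image"))
  nii <- RNifti::asNifti(x$values)
  nii <- RNifti::`pixdim<-`(nii, x$spacing)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname write_suv_nifti
#' @export
read_suv_nifti <- function(path) {
  nii <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(nii)[1:3]
  suv_image(array(as.numeric(nii), dim(nii)[1:3]), spacing = sp)
}

#' @rdname write_suv_nifti
#' @param spacing voxel spacing in mm (for mask writing).
#' @export
write_mask_nifti <- function(x, path, spacing = c(2, 2, 2)) {
  nii <- RNifti::asNifti(array(as.integer(x), dim(x)))
  nii <- RNifti::`pixdim<-`(nii, spacing)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname write_suv_nifti
#' @export
read_mask_nifti <- function(path) {
  nii <- RNifti::readNifti(path)
  array(as.numeric(nii) != 0, dim(nii)[1:3])
}
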