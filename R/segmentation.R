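#' Background SUV estimate from two reference spheres
#'
#' Two spheres of constant diameter are placed in normal-appearing brain
#' (conventionally cerebrum and cerebellum). The background SUV is the mean of
#' the two per-sphere mean SUVs -- not the pooled voxel mean, so a larger
#' sphere does not dominate. Sphere membership is the voxel-center-inside
#' test.
#'
#' @param image an [suv_image()].
#' @param centers list of two sphere centers in voxel coordinates.
#' @param diameter_mm sphere diameter in mm (default 30); the standard
#'   protocol uses one constant diameter, but a length-2 vector is accepted.
#' @return A `background_estimate` with `suv_bg`, `sphere_means`, `centers`,
#'   `diameter_mm` and the combined `mask`.
#' @export
estimate_background <- function(image, centers, diameter_mm = 30) {
  stopifnot(inherits(image, "suv_image"), length(centers) == 2L)
  d <- dim(image$values); sp <- image$spacing
  r <- rep(diameter_mm / 2, length.out = 2)
  masks <- lapply(1:2, function(i) {
    ctr <- centers[[i]]
    if (!sphere_inside(d, sp, ctr, r[i]))
      stop("background sphere exceeds the image grid")
    sphere_mask(d, sp, ctr, r[i])
  })
  means <- vapply(masks, function(m) mean(image$values[m]), numeric(1))
  structure(list(suv_bg = mean(means), sphere_means = means,
                 centers = centers, diameter_mm = diameter_mm,
                 mask = masks[[1]] | masks[[2]]),
            class = "background_estimate")
}

#' @export
print.background_estimate <- function(x, ...) {
  cat(sprintf("<background_estimate> SUV(Bg.) = %.4f (sphere means %.4f, %.4f; d = %g mm)\n",
              x$suv_bg, x$sphere_means[1], x$sphere_means[2], x$diameter_mm))
  invisible(x)
}

#' Threshold segmentation at a multiple of background SUV
#'
#' A voxel enters `v_threshold` iff its SUV is at least `factor` times the
#' background SUV (inclusive comparison: a voxel exactly at the threshold is
#' tumor). The mask may be empty; downstream stages that require a PET-positive
#' volume raise an error then.
#'
#' @param image an [suv_image()].
#' @param bg a [estimate_background()] result, or a positive number (SUV).
#' @param factor threshold multiplier (default 1.8).
#' @return Logical mask `v_threshold`.
#' @export
threshold_segment <- function(image, bg, factor = 1.8) {
  suv_bg <- if (inherits(bg, "background_estimate")) bg$suv_bg else as.numeric(bg)
  if (!is.finite(suv_bg) || suv_bg <= 0) stop("background SUV must be positive")
  image$values >= factor * suv_bg
}

#' Remove operator-identified non-tumor uptake
#'
#' Expert cleanup of the threshold volume is represented by an explicit
#' exclusion mask (vessels, extracerebral uptake); the pipeline never
#' auto-classifies such regions. An empty exclusion mask is the identity.
#'
#' @param v_threshold logical mask from [threshold_segment()].
#' @param exclusion_mask logical mask on the same grid, or NULL.
#' @return Logical mask `v_pet = v_threshold & !exclusion_mask`.
#' @export
apply_exclusion <- function(v_threshold, exclusion_mask = NULL) {
  if (is.null(exclusion_mask)) return(v_threshold)
  check_same_grid(v_threshold, exclusion_mask)
  v_threshold & !exclusion_mask
}

#' Isotropic margin expansion of a mask
#'
#' A voxel enters the dilated mask iff the Euclidean distance from its center
#' to the nearest input-mask voxel center is at most `margin_mm`. Anisotropic
#' spacing is respected exactly: the dilation is a union of shifts by all
#' integer offsets whose physical length does not exceed the margin (which is
#' equivalent to thresholding the exact Euclidean distance transform at the
#' margin).
#'
#' @param v_pet non-empty logical mask.
#' @param margin_mm margin in mm (default 3.0; 0 is the identity).
#' @param spacing voxel spacing in mm.
#' @return Logical mask `v_pet3mm`.
#' @export
dilate_margin <- function(v_pet, margin_mm = 3.0, spacing = c(2, 2, 2)) {
  if (!any(v_pet)) stop("cannot dilate an empty mask")
  if (margin_mm < 0) stop("margin_mm must be >= 0")
  if (margin_mm == 0) return(v_pet)
  rmax <- floor(margin_mm / spacing)
  offs <- as.matrix(expand.grid(di = -rmax[1]:rmax[1], dj = -rmax[2]:rmax[2],
                                dk = -rmax[3]:rmax[3]))
  dist2 <- (offs[, 1] * spacing[1])^2 + (offs[, 2] * spacing[2])^2 +
           (offs[, 3] * spacing[3])^2
  offs <- offs[dist2 <= margin_mm^2, , drop = FALSE]
  out <- array(FALSE, dim(v_pet))
  for (r in seq_len(nrow(offs)))
    out <- out | shift_array(v_pet, offs[r, ], fill = FALSE)
  out
}

#' Connected component containing the SUV maximum
#'
#' Splits `v_pet` into connected components (26-connectivity by default) and
#' keeps the component containing the global SUV maximum within the mask.
#' If the maximum is attained in several components, the component of the
#' lexicographically first maximal voxel (by (i, j, k)) wins.
#'
#' @param image an [suv_image()].
#' @param v_pet non-empty logical mask.
#' @param connectivity 26 (default) or 6.
#' @return Logical mask `v_petmax`.
#' @export
extract_max_component <- function(image, v_pet, connectivity = 26) {
  stopifnot(inherits(image, "suv_image"))
  check_same_grid(image$values, v_pet, "image and mask")
  if (!any(v_pet)) stop("v_pet is empty: no PET-positive volume")
  bb <- mask_bbox(v_pet)
  vp <- crop_to_bbox(v_pet, bb)
  vals <- crop_to_bbox(image$values, bb)
  comp_vals <- array(NA_integer_, dim(vp))
  comp_vals[vp] <- 1L   # one region; components split it spatially
  labs <- label_components(comp_vals, connectivity)
  mx <- max(vals[vp])
  idx <- which(vp & vals == mx, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2], idx[, 3]), , drop = FALSE]
  winner <- labs[idx[1, 1], idx[1, 2], idx[1, 3]]
  out <- array(FALSE, dim(v_pet))
  out[bb[[1]][1]:bb[[1]][2], bb[[2]][1]:bb[[2]][2], bb[[3]][1]:bb[[3]][2]] <-
    !is.na(labs) & labs == winner
  out
}

#' Place a background reference sphere
#'
#' Finds a deterministic placement for a sphere of `volume_cc` (default 4 cc,
#' the background reference volume used when comparing tumor against normal
#' tissue) fully inside the grid and disjoint from `avoid`. Candidate centers
#' are scanned over a regular grid, nearest-to-corner first, so the placement
#' is reproducible without randomness.
#'
#' @param image an [suv_image()].
#' @param volume_cc sphere volume in cc.
#' @param avoid logical mask the sphere must not intersect (e.g. `v_pet3mm`).
#' @return Logical mask `v_bg`.
#' @export
place_background_sphere <- function(image, volume_cc = 4.0, avoid = NULL) {
  stopifnot(inherits(image, "suv_image"))
  d <- dim(image$values); sp <- image$spacing
  r <- sphere_radius_mm(volume_cc)
  step <- pmax(1L, floor(r / sp))
  cand <- expand.grid(i = seq(1 + ceiling(r / sp[1]), d[1] - ceiling(r / sp[1]), by = step[1]),
                      j = seq(1 + ceiling(r / sp[2]), d[2] - ceiling(r / sp[2]), by = step[2]),
                      k = seq(1 + ceiling(r / sp[3]), d[3] - ceiling(r / sp[3]), by = step[3]))
  if (nrow(cand) == 0) stop("no room for the background sphere")
  for (row in seq_len(nrow(cand))) {
    ctr <- as.numeric(cand[row, ])
    if (!sphere_inside(d, sp, ctr, r)) next
    m <- sphere_mask(d, sp, ctr, r)
    if (!is.null(avoid) && any(m & avoid)) next
    return(m)
  }
  stop("no placement found for the background sphere outside the avoid mask")
}

#' Full three-step tumor contouring
#'
#' Runs the contouring chain on one image: background estimation from two
#' reference spheres, thresholding at `factor` times the background SUV,
#' exclusion-mask cleanup, then derivation of the 3 mm margin volume
#' (`v_pet3mm`) and the SUV-maximum component (`v_petmax`), plus a 4 cc
#' background reference sphere disjoint from `v_pet3mm`. The nesting
#' `v_petmax` in `v_pet` in `v_pet3mm` and `v_pet` in `v_threshold` is
#' asserted on every run.
#'
#' @param image an [suv_image()].
#' @param bg_centers list of two background-sphere centers (voxel coords).
#' @param exclusion_mask optional logical mask of non-tumor uptake.
#' @param factor threshold multiplier (default 1.8).
#' @param margin_mm margin for `v_pet3mm` (default 3).
#' @param bg_diameter_mm diameter of the two background spheres (default 30).
#' @param bg_volume_cc volume of the reference sphere `v_bg` (default 4).
#' @param connectivity component connectivity (default 26).
#' @return A `contour_set`: list with masks `v_threshold`, `v_pet`,
#'   `v_pet3mm`, `v_petmax`, `v_bg`, plus the `background_estimate`.
#' @export
segment_tumor <- function(image, bg_centers, exclusion_mask = NULL,
                          factor = 1.8, margin_mm = 3.0,
                          bg_diameter_mm = 30, bg_volume_cc = 4.0,
                          connectivity = 26) {
  bg <- estimate_background(image, bg_centers, bg_diameter_mm)
  v_threshold <- threshold_segment(image, bg, factor)
  v_pet <- apply_exclusion(v_threshold, exclusion_mask)
  if (!any(v_pet))
    stop("no PET-positive volume: threshold segmentation is empty after exclusion")
  v_pet3mm <- dilate_margin(v_pet, margin_mm, image$spacing)
  v_petmax <- extract_max_component(image, v_pet, connectivity)
  v_bg <- place_background_sphere(image, bg_volume_cc, avoid = v_pet3mm)
  stopifnot(all(v_pet[v_petmax]), all(v_pet3mm[v_pet]),
            all(v_threshold[v_pet]), !any(v_bg & v_pet3mm))
  structure(list(v_threshold = v_threshold, v_pet = v_pet,
                 v_pet3mm = v_pet3mm, v_petmax = v_petmax, v_bg = v_bg,
                 background = bg),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat("<contour_set>\n")
  for (nm in c("v_threshold", "v_pet", "v_pet3mm", "v_petmax", "v_bg"))
    cat(sprintf("  %-11s %6d voxels\n", nm, sum(x[[nm]])))
  cat(sprintf("  SUV(Bg.) = %.4f\n", x$background$suv_bg))
  invisible(x)
}

#' 40%-of-maximum sphere segmentation
#'
#' Phantom-sphere delineation used by the robustness screen: within a search
#' region around a known sphere, keep the voxels whose SUV is at least 40% of
#' the maximum uptake inside the region, then keep the connected component
#' containing that maximum.
#'
#' @param image an [suv_image()].
#' @param region logical search region containing one hot sphere.
#' @param fraction threshold fraction of the region maximum (default 0.40).
#' @return Logical mask.
#' @export
segment_sphere_40pct <- function(image, region, fraction = 0.40) {
  stopifnot(inherits(image, "suv_image"), any(region))
  mx <- max(image$values[region])
  m <- region & (image$values >= fraction * mx)
  extract_max_component(image, m)
}
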