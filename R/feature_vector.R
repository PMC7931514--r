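# The frozen 135-name feature catalogue and the single entry point that
# computes the full vector for one (image, mask) pair.

glcm_catalogue <- function() c("Acor", "Variance_CM", "Energy_CM",
                               "Contrast_CM", "Entropy_CM", "Homogeneity",
                               "Correlation", "Dissimilarity")

ngtdm_catalogue <- function() c("Coarseness", "Contrast_NGTDM", "Busyness",
                                "Complexity", "TS")

histogram_catalogue <- function() c("SUV_min", "SUV_max", "SUV_mean",
                                    "SUV_median", "SUV_range", "Variance",
                                    "Skewness", "Kurtosis", "Entropy_H",
                                    "Energy_H")

shape_catalogue <- function() c("VoxelCount", "Volume_cc", "SurfaceArea",
                                "Sphericity", "Compactness", "Eccentricity",
                                "Elongation", "Flatness")

texture_catalogue <- function() c(glcm_catalogue(), glrlm_catalogue(),
                                  glszm_catalogue(), ngtdm_catalogue())

#' The 135-name radiomics feature catalogue
#'
#' Ten first-order histogram statistics and eight shape descriptors computed
#' on the raw volume, plus 39 texture features (8 GLCM, 13 GLRLM, 13 GLSZM,
#' 5 NGTDM) computed three times: on the fixed-bin-width discretized volume
#' (base names), on the equal-probability-quantized volume (prefix `Q`), and
#' on the wavelet band-pass filtered volume (prefix `WF_`). The catalogue is
#' frozen: [compute_feature_vector()] always returns exactly these names in
#' this order. A JSON manifest of the catalogue ships in
#' `inst/extdata/feature_manifest.json` (see [feature_manifest()]).
#'
#' @return Character vector of 135 feature names.
#' @export
feature_catalogue <- function() {
  tex <- texture_catalogue()
  c(histogram_catalogue(), shape_catalogue(),
    tex, paste0("Q", tex), paste0("WF_", tex))
}

#' Feature catalogue manifest
#'
#' Returns the catalogue with group/transform annotations, as shipped in the
#' package's JSON manifest. The manifest is versioned; the catalogue is
#' best-effort with respect to published 135-feature panels and is guaranteed
#' to contain every feature name used by the modelling stage.
#'
#' @return A data.frame with columns `name`, `family`, `transform`.
#' @export
feature_manifest <- function() {
  tex <- texture_catalogue()
  fam <- c(rep("histogram", 10), rep("shape", 8),
           rep(c(rep("GLCM", 8), rep("GLRLM", 13), rep("GLSZM", 13),
                 rep("NGTDM", 5)), 3))
  trans <- c(rep("raw", 18), rep("FBW", 39), rep("Q", 39), rep("WF", 39))
  data.frame(name = feature_catalogue(), family = fam, transform = trans,
             stringsAsFactors = FALSE)
}

texture_block <- function(disc, connectivity = 26) {
  c(glcm_features(build_glcm(disc)),
    glrlm_features(build_glrlm(disc)),
    glszm_features(build_glszm(disc, connectivity)),
    ngtdm_features(build_ngtdm(disc)))
}

#' Compute the full 135-entry radiomics feature vector
#'
#' Runs the whole extraction chain for one (image, mask) pair: histogram and
#' shape features on the raw volume; texture features on the fixed-bin-width
#' discretized volume; `Q`-variants on the equal-probability-quantized volume;
#' `WF_`-variants on the wavelet band-pass filtered volume (then FBW
#' discretized). A pure function: the same input always yields the identical
#' vector. Features undefined on degenerate regions are NA, never dropped.
#'
#' @param image an [suv_image()].
#' @param mask non-empty logical mask on the image grid.
#' @param bin_width FBW bin width in SUV (default 0.01).
#' @param q_levels equal-probability quantization levels (default 64).
#' @param wavelet_ratio,wavelet_basis,wavelet_orientation parameters of
#'   [wavelet_bandpass()] (defaults 0.5, "coif1", "attenuate").
#' @param connectivity zone/component connectivity (default 26).
#' @return Named numeric vector of exactly 135 features, in catalogue order.
#' @examples
#' s <- gen_brain_pet(lesions = list(lesion_spec(c(13, 13, 13), 8, 4, 0.2)),
#'                    scanner = scanner_profile(0, 0),
#'                    grid_shape = c(25, 25, 25), seed = 2)
#' fv <- compute_feature_vector(s$image, s$lesion_mask)
#' fv[c("SUV_mean", "SZLGE", "Busyness")]
#' @export
compute_feature_vector <- function(image, mask, bin_width = 0.01,
                                   q_levels = 64, wavelet_ratio = 0.5,
                                   wavelet_basis = "coif1",
                                   wavelet_orientation = "attenuate",
                                   connectivity = 26) {
  stopifnot(inherits(image, "suv_image"))
  check_same_grid(image$values, mask, "image and mask")
  if (!any(mask)) stop("mask is empty")
  # crop to the mask bounding box padded by 8 voxels (the wavelet filter's
  # spatial support); features depend only on in-mask voxels and, for the
  # WF variants, on this fixed neighborhood, so results are
  # translation-invariant
  bb <- lapply(mask_bbox(mask), function(r)
    c(max(1, r[1] - 8), r[2] + 8))
  d <- dim(mask)
  bb <- lapply(1:3, function(a) c(bb[[a]][1], min(d[a], bb[[a]][2])))
  image <- suv_image(crop_to_bbox(image$values, bb), image$spacing)
  mask <- crop_to_bbox(mask, bb)
  hist_f <- histogram_features(image, mask, bin_width)
  shape_f <- shape_features(mask, image$spacing)
  base <- texture_block(discretize_fbw(image, mask, bin_width), connectivity)
  qv <- texture_block(equal_probability_quantize(image, mask, q_levels),
                      connectivity)
  wf_vals <- wavelet_bandpass(image$values, ratio = wavelet_ratio,
                              basis = wavelet_basis,
                              orientation = wavelet_orientation)
  wf <- texture_block(discretize_fbw(wf_vals, mask, bin_width), connectivity)
  out <- c(hist_f, shape_f, base,
           stats::setNames(qv, paste0("Q", names(qv))),
           stats::setNames(wf, paste0("WF_", names(wf))))
  stopifnot(identical(names(out), feature_catalogue()))
  out
}

#' Feature table over subjects and contours
#'
#' Applies [compute_feature_vector()] to a list of (image, mask) pairs and
#' returns one row per pair with the 135 named feature columns plus
#' provenance columns `subject` and `contour`.
#'
#' @param images list of [suv_image()] objects (one per subject).
#' @param masks list of logical masks, parallel to `images`.
#' @param subjects character vector of subject ids.
#' @param contour single contour label recorded in the output (e.g.
#'   "petmax", "pet3mm", "bg").
#' @param ... passed to [compute_feature_vector()].
#' @return A data.frame with `subject`, `contour` and 135 feature columns.
#' @export
feature_table <- function(images, masks, subjects = NULL, contour = "roi",
                          ...) {
  n <- length(images)
  stopifnot(length(masks) == n)
  if (is.null(subjects)) subjects <- sprintf("S%03d", seq_len(n))
  rows <- lapply(seq_len(n), function(i)
    compute_feature_vector(images[[i]], masks[[i]], ...))
  tab <- as.data.frame(do.call(rbind, rows))
  cbind(data.frame(subject = subjects, contour = contour,
                   stringsAsFactors = FALSE), tab)
}
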