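# Feature formulas for the four texture matrices, plus first-order histogram
# and shape descriptors. Degenerate inputs (single gray level, single voxel,
# zero denominators) yield NA_real_, never an error: the screening and
# modelling stages exclude flagged values pairwise.

#' GLCM features
#'
#' Autocorrelation `Acor = sum i j p(i,j)`, joint variance
#' `Variance_CM = sum (i - mu)^2 p(i,j)` with `mu = sum i p(i,j)`, plus
#' energy, contrast, entropy (log2), homogeneity (inverse difference),
#' correlation and dissimilarity.
#'
#' @param g a `glcm` from [build_glcm()].
#' @return Named numeric vector of 8 features.
#' @export
glcm_features <- function(g) {
  p <- g$p; ng <- g$ng
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  mu <- sum(i * p)
  varcm <- sum((i - mu)^2 * p)
  pos <- p > 0
  corr <- if (varcm > 0) (sum(i * j * p) - mu^2) / varcm else NA_real_
  c(Acor = sum(i * j * p),
    Variance_CM = varcm,
    Energy_CM = sum(p^2),
    Contrast_CM = sum((i - j)^2 * p),
    Entropy_CM = -sum(p[pos] * log2(p[pos])),
    Homogeneity = sum(p / (1 + abs(i - j))),
    Correlation = corr,
    Dissimilarity = sum(abs(i - j) * p))
}

#' GLRLM features
#'
#' The run-length catalogue on the merged-direction matrix: run emphases
#' (SRE/LRE), gray-level and run-length non-uniformities (GLN/RLN), run
#' percentage (RP, runs per scanned voxel over all 13 directions),
#' low/high-gray emphases and the joint emphases, plus gray-level variance
#' (GLV) and run-length variance (RLV).
#'
#' @param r a `glrlm` from [build_glrlm()].
#' @return Named numeric vector of 13 features.
#' @export
glrlm_features <- function(r) {
  P <- r$counts; p <- r$p; nr <- r$nr
  if (nr == 0) return(stats::setNames(rep(NA_real_, 13), glrlm_catalogue()))
  ng <- nrow(P); rmax <- ncol(P)
  i <- matrix(seq_len(ng), ng, rmax)
  rr <- matrix(seq_len(rmax), ng, rmax, byrow = TRUE)
  mu_i <- sum(p * i); mu_r <- sum(p * rr)
  c(SRE = sum(p / rr^2),
    LRE = sum(p * rr^2),
    GLN = sum(rowSums(P)^2) / nr,
    RLN = sum(colSums(P)^2) / nr,
    RP = nr / sum(rr * P),
    LGRE = sum(p / i^2),
    HGRE = sum(p * i^2),
    SRLGE = sum(p / (i^2 * rr^2)),
    SRHGE = sum(p * i^2 / rr^2),
    LRLGE = sum(p * rr^2 / i^2),
    LRHGE = sum(p * i^2 * rr^2),
    GLV = sum(p * (i - mu_i)^2),
    RLV = sum(p * (rr - mu_r)^2))
}

glrlm_catalogue <- function() c("SRE", "LRE", "GLN", "RLN", "RP", "LGRE",
                                "HGRE", "SRLGE", "SRHGE", "LRLGE", "LRHGE",
                                "GLV", "RLV")

#' GLSZM features
#'
#' Zone-size catalogue: small/large-zone emphases (SZE/LZE), the normalized
#' gray-level non-uniformity `GLN2 = sum_i (sum_s P(i,s))^2 / Nz^2` (in
#' (0, 1]), zone-size non-uniformity (ZSN), zone percentage (ZP), low/high
#' gray-level emphases, the joint emphases including the small-zone
#' low-gray-level emphasis `SZLGE = sum p(i,s) / (i^2 s^2)`, and the zone
#' gray-level (GLV2) and zone-size (ZSV) variances.
#'
#' @param z a `glszm` from [build_glszm()].
#' @return Named numeric vector of 13 features.
#' @export
glszm_features <- function(z) {
  P <- z$counts; p <- z$p; nz <- z$nz
  if (nz == 0) return(stats::setNames(rep(NA_real_, 13), glszm_catalogue()))
  ng <- nrow(P); smax <- ncol(P)
  i <- matrix(seq_len(ng), ng, smax)
  s <- matrix(seq_len(smax), ng, smax, byrow = TRUE)
  mu_i <- sum(p * i); mu_s <- sum(p * s)
  c(SZE = sum(p / s^2),
    LZE = sum(p * s^2),
    GLN2 = sum(rowSums(P)^2) / nz^2,
    ZSN = sum(colSums(P)^2) / nz,
    ZP = nz / z$n_voxels,
    LGZE = sum(p / i^2),
    HGZE = sum(p * i^2),
    SZLGE = sum(p / (i^2 * s^2)),
    SZHGE = sum(p * i^2 / s^2),
    LZLGE = sum(p * s^2 / i^2),
    LZHGE = sum(p * i^2 * s^2),
    GLV2 = sum(p * (i - mu_i)^2),
    ZSV = sum(p * (s - mu_s)^2))
}

glszm_catalogue <- function() c("SZE", "LZE", "GLN2", "ZSN", "ZP", "LGZE",
                                "HGZE", "SZLGE", "SZHGE", "LZLGE", "LZHGE",
                                "GLV2", "ZSV")

#' Small-zone low-gray-level emphasis
#'
#' `SZLGE = sum_{i,s} p(i,s) / (i^2 s^2)`: large when the region contains
#' many small zones of low gray level. This is the single feature with the
#' best univariate prognostic performance in the motivating application.
#'
#' @param z a `glszm`.
#' @return A single number (NA if the matrix holds no zones).
#' @export
szlge <- function(z) {
  stopifnot(inherits(z, "glszm"))
  unname(glszm_features(z)["SZLGE"])
}

#' NGTDM features
#'
#' Busyness `sum_i p_i s_i / sum_{i,j} |i p_i - j p_j|` (over ordered pairs of
#' occupied levels), strength `TS = sum_{i,j} (p_i + p_j)(i - j)^2 / sum_i s_i`,
#' plus coarseness, NGTDM contrast and complexity. Fewer than two occupied
#' levels, or a zero denominator, flags the affected features as NA.
#'
#' @param t an `ngtdm` from [build_ngtdm()].
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(t) {
  p <- t$p; s <- t$s
  occ <- which(p > 0)
  n_occ <- length(occ)
  nv <- t$n_valid
  coarse <- if (sum(p * s) > 0) 1 / sum(p * s) else NA_real_
  if (n_occ < 2) {
    return(c(Coarseness = coarse, Contrast_NGTDM = NA_real_,
             Busyness = NA_real_, Complexity = NA_real_, TS = NA_real_))
  }
  io <- occ; po <- p[occ]; so <- s[occ]
  ii <- matrix(io, n_occ, n_occ); jj <- t(ii)
  pi_ <- matrix(po, n_occ, n_occ); pj <- t(pi_)
  si_ <- matrix(so, n_occ, n_occ); sj <- t(si_)
  contr <- (sum(pi_ * pj * (ii - jj)^2) / (n_occ * (n_occ - 1))) * (sum(s) / nv)
  busy_den <- sum(abs(ii * pi_ - jj * pj))
  busy <- if (busy_den > 0) sum(po * so) / busy_den else NA_real_
  complx <- sum(abs(ii - jj) * (pi_ * si_ + pj * sj) / (pi_ + pj)) / nv
  ts_den <- sum(s)
  ts <- if (ts_den > 0) sum((pi_ + pj) * (ii - jj)^2) / ts_den else NA_real_
  c(Coarseness = coarse, Contrast_NGTDM = contr, Busyness = busy,
    Complexity = complx, TS = ts)
}

#' @rdname ngtdm_features
#' @export
ngtdm_busyness <- function(t) unname(ngtdm_features(t)["Busyness"])

#' @rdname ngtdm_features
#' @export
ngtdm_strength <- function(t) unname(ngtdm_features(t)["TS"])

#' First-order (histogram) features
#'
#' Statistics of the raw SUV values inside the mask. Variance, skewness and
#' kurtosis use population (1/n) moments; `Kurtosis` is excess kurtosis.
#' `Entropy_H` and `Energy_H` (uniformity) are computed on the fixed-bin-width
#' discretized histogram anchored at the ROI minimum.
#'
#' @param image an [suv_image()] (or numeric 3D array).
#' @param mask non-empty logical mask.
#' @param bin_width histogram bin width in SUV for entropy/uniformity.
#' @return Named numeric vector of 10 features.
#' @export
histogram_features <- function(image, mask, bin_width = 0.01) {
  vals <- if (inherits(image, "suv_image")) image$values else image
  check_same_grid(vals, mask, "image and mask")
  if (!any(mask)) stop("mask is empty")
  v <- vals[mask]
  n <- length(v)
  m <- mean(v)
  m2 <- mean((v - m)^2); m3 <- mean((v - m)^3); m4 <- mean((v - m)^4)
  skew <- if (m2 > 0) m3 / m2^1.5 else NA_real_
  kurt <- if (m2 > 0) m4 / m2^2 - 3 else NA_real_
  lev <- floor((v - min(v)) / bin_width) + 1
  q <- tabulate(lev) / n
  q <- q[q > 0]
  c(SUV_min = min(v), SUV_max = max(v), SUV_mean = m,
    SUV_median = stats::median(v), SUV_range = max(v) - min(v),
    Variance = m2, Skewness = skew, Kurtosis = kurt,
    Entropy_H = -sum(q * log2(q)), Energy_H = sum(q^2))
}

#' Shape features
#'
#' Geometry of the binary mask: voxel count, volume (cc), surface area (cm^2,
#' by exposed-face counting on the voxel grid), sphericity
#' `(36 pi V^2)^(1/3) / A`, compactness `V / (sqrt(pi) A^(3/2))`, and the
#' principal-axis descriptors from the voxel-center covariance eigenvalues
#' (lambda_1 >= lambda_2 >= lambda_3): eccentricity
#' `sqrt(1 - lambda_3 / lambda_1)`, elongation `sqrt(lambda_2 / lambda_1)`
#' and flatness `sqrt(lambda_3 / lambda_1)`. Axis descriptors are NA for a
#' single-voxel (or otherwise degenerate) mask.
#'
#' @param mask non-empty logical 3D mask.
#' @param spacing voxel spacing in mm.
#' @return Named numeric vector of 8 features.
#' @export
shape_features <- function(mask, spacing = c(2, 2, 2)) {
  if (!any(mask)) stop("mask is empty")
  n <- sum(mask)
  vol_mm3 <- n * prod(spacing)
  # exposed faces per axis
  area_mm2 <- 0
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                 spacing[1] * spacing[2])
  for (ax in 1:3) {
    for (sgn in c(-1L, 1L)) {
      off <- c(0L, 0L, 0L); off[ax] <- sgn
      nb <- shift_array(mask, off, fill = FALSE)
      area_mm2 <- area_mm2 + sum(mask & !nb) * face_area[ax]
    }
  }
  spher <- (36 * pi * vol_mm3^2)^(1 / 3) / area_mm2
  compact <- vol_mm3 / (sqrt(pi) * area_mm2^1.5)
  idx <- which(mask, arr.ind = TRUE)
  xyz <- idx %*% diag(spacing)
  if (n >= 2) {
    cv <- stats::cov(xyz) * (n - 1) / n
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
    if (ev[1] > 0) {
      ecc <- sqrt(1 - ev[3] / ev[1])
      elo <- sqrt(ev[2] / ev[1])
      fla <- sqrt(ev[3] / ev[1])
    } else ecc <- elo <- fla <- NA_real_
  } else ecc <- elo <- fla <- NA_real_
  c(VoxelCount = n, Volume_cc = vol_mm3 / 1000,
    SurfaceArea = area_mm2 / 100, Sphericity = spher, Compactness = compact,
    Eccentricity = ecc, Elongation = elo, Flatness = fla)
}
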