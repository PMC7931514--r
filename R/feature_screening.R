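#' Screening configuration
#'
#' Thresholds shared by all feature filters: significance level `alpha`,
#' the strong-correlation rule (`p < alpha` and `|r| > strong_corr_r`,
#' Spearman), and the Bonferroni family size `bonferroni_k` where a filter
#' corrects for multiplicity.
#'
#' @param alpha significance level (default 0.05).
#' @param strong_corr_r Spearman threshold for "strong" correlation
#'   (default 0.8; the absolute value of r is compared, so strong negative
#'   correlation is equally disqualifying).
#' @param bonferroni_k family size for Bonferroni correction (set per family;
#'   NULL means "use the number of features tested").
#' @return A `screening_config` list.
#' @export
screening_config <- function(alpha = 0.05, strong_corr_r = 0.8,
                             bonferroni_k = NULL) {
  stopifnot(alpha > 0, alpha < 1, strong_corr_r > 0, strong_corr_r < 1)
  structure(list(alpha = alpha, strong_corr_r = strong_corr_r,
                 bonferroni_k = bonferroni_k), class = "screening_config")
}

# Paired Wilcoxon signed-rank p value with the conventions the screens need:
# all differences zero -> p = 1 (no evidence of a shift); exact null
# distribution for n <= 25 without ties, normal approximation with tie and
# continuity correction otherwise (stats::wilcox.test handles the switch).
paired_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[is.finite(d)]
  if (length(d) == 0 || all(d == 0)) return(1)
  suppressWarnings(stats::wilcox.test(d, exact = length(d) <= 25)$p.value)
}

# Spearman correlation and p value; constant input -> r = NA, p = 1.
spearman_rp <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(c(r = NA_real_, p = 1))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  c(r = unname(ct$estimate), p = ct$p.value)
}

strong_correlation <- function(x, y, cfg) {
  rp <- spearman_rp(x, y)
  isTRUE(!is.na(rp["r"]) && rp["p"] < cfg$alpha && abs(rp["r"]) > cfg$strong_corr_r)
}

#' Scanner robustness screen
#'
#' Paired Wilcoxon signed-rank test per feature between the same contours
#' rendered under two scanner profiles. A feature is robust when the test
#' fails to reject at uncorrected `alpha` (identical renderings give p = 1 by
#' convention). The standard design pools sphere and background contours into
#' one test per feature.
#'
#' @param features_a,features_b data.frames of per-contour feature values
#'   (same columns, same row order = same contours) under the two scanners.
#' @param cfg a [screening_config()].
#' @return data.frame with columns `feature`, `p`, `robust`.
#' @export
scanner_robustness <- function(features_a, features_b,
                               cfg = screening_config()) {
  stopifnot(identical(names(features_a), names(features_b)),
            nrow(features_a) == nrow(features_b))
  if (nrow(features_a) < 6) stop("at least 6 paired contours are required")
  nm <- names(features_a)
  p <- vapply(nm, function(f)
    paired_signed_rank_p(features_a[[f]], features_b[[f]]), numeric(1))
  data.frame(feature = nm, p = unname(p), robust = unname(p >= cfg$alpha),
             stringsAsFactors = FALSE)
}

#' Intrinsic size-dependence screen
#'
#' Spearman rank correlation between each feature and the contour voxel
#' count over background contours spanning the volume range. A feature is
#' size-dependent under the strong-correlation rule
#' (`p < alpha` and `|r| > strong_corr_r`); a constant feature has undefined
#' r and is reported size-independent with an NA correlation.
#'
#' @param features data.frame of per-contour feature values.
#' @param voxel_counts integer vector, one per contour.
#' @param cfg a [screening_config()].
#' @return data.frame with columns `feature`, `r`, `p`, `size_dependent`.
#' @export
size_dependence <- function(features, voxel_counts,
                            cfg = screening_config()) {
  stopifnot(nrow(features) == length(voxel_counts))
  if (nrow(features) < 10) stop("at least 10 contours are required")
  res <- t(vapply(names(features), function(f)
    spearman_rp(features[[f]], voxel_counts), c(r = 0, p = 0)))
  dep <- !is.na(res[, "r"]) & res[, "p"] < cfg$alpha &
         abs(res[, "r"]) > cfg$strong_corr_r
  data.frame(feature = names(features), r = unname(res[, "r"]),
             p = unname(res[, "p"]), size_dependent = unname(dep),
             stringsAsFactors = FALSE)
}

#' Tumor vs background discrimination screen
#'
#' Paired Wilcoxon signed-rank test per feature between a tumor contour and
#' the 4 cc background reference sphere of the same subject, Bonferroni
#' corrected over the K features tested (by default K = the number of
#' features passed in, which should already be the size-independent set).
#'
#' @param features_tumor,features_bg data.frames of per-subject values (same
#'   columns, same row order = same subjects).
#' @param cfg a [screening_config()]; `bonferroni_k` overrides K.
#' @return data.frame with `feature`, `p`, `significant`, plus attribute
#'   `bonferroni_k`.
#' @export
tumor_vs_background <- function(features_tumor, features_bg,
                                cfg = screening_config()) {
  stopifnot(identical(names(features_tumor), names(features_bg)),
            nrow(features_tumor) == nrow(features_bg))
  if (nrow(features_tumor) < 6) stop("at least 6 subjects are required")
  nm <- names(features_tumor)
  K <- if (is.null(cfg$bonferroni_k)) length(nm) else cfg$bonferroni_k
  thr <- bonferroni_threshold(cfg$alpha, K)
  p <- vapply(nm, function(f)
    paired_signed_rank_p(features_tumor[[f]], features_bg[[f]]), numeric(1))
  out <- data.frame(feature = nm, p = unname(p),
                    significant = unname(p < thr), stringsAsFactors = FALSE)
  attr(out, "bonferroni_k") <- K
  out
}

#' Added value over SUVmax and volume
#'
#' A feature has added value when it is not strongly Spearman-correlated
#' (`p < alpha` and `|r| > strong_corr_r`) with either the conventional
#' indices SUVmax or volume. Constant features are reported independent with
#' an NA flag.
#'
#' @param features data.frame of per-subject feature values.
#' @param suvmax,volume numeric vectors, one per subject.
#' @param cfg a [screening_config()].
#' @return data.frame with `feature`, `r_suvmax`, `r_volume`, `independent`.
#' @export
added_value <- function(features, suvmax, volume, cfg = screening_config()) {
  stopifnot(nrow(features) == length(suvmax), nrow(features) == length(volume))
  if (nrow(features) < 10) stop("at least 10 subjects are required")
  rows <- lapply(names(features), function(f) {
    rs <- spearman_rp(features[[f]], suvmax)
    rv <- spearman_rp(features[[f]], volume)
    dep_s <- !is.na(rs["r"]) && rs["p"] < cfg$alpha &&
             abs(rs["r"]) > cfg$strong_corr_r
    dep_v <- !is.na(rv["r"]) && rv["p"] < cfg$alpha &&
             abs(rv["r"]) > cfg$strong_corr_r
    data.frame(feature = f, r_suvmax = unname(rs["r"]),
               r_volume = unname(rv["r"]),
               independent = !(dep_s || dep_v), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Phantom-based screening report
#'
#' Convenience wrapper running the scanner-robustness and size-dependence
#' screens from phantom renderings and combining the per-feature flags into
#' one report.
#'
#' @param features_a,features_b paired per-contour feature tables under two
#'   scanner profiles (for robustness).
#' @param size_features per-contour feature table over background contours.
#' @param voxel_counts contour voxel counts for the size screen.
#' @param cfg a [screening_config()].
#' @return data.frame with per-feature `robust`, `size_dependent` flags and
#'   the underlying statistics.
#' @export
screening_report <- function(features_a, features_b, size_features,
                             voxel_counts, cfg = screening_config()) {
  rob <- scanner_robustness(features_a, features_b, cfg)
  sz <- size_dependence(size_features, voxel_counts, cfg)
  stopifnot(identical(rob$feature, sz$feature))
  data.frame(feature = rob$feature, p_scanner = rob$p, robust = rob$robust,
             r_size = sz$r, p_size = sz$p, size_dependent = sz$size_dependent,
             stringsAsFactors = FALSE)
}
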