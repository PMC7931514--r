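# Construction of the four 3D texture matrices from a discretized volume.
# All builders crop to the mask bounding box, count over the 13 unique 3D
# directions at Chebyshev distance 1 where directions apply, and use the
# "merged" aggregation: counts from all directions are pooled into a single
# matrix before normalization (rotationally stable; configurable elsewhere is
# not needed since all consumers use merged).

disc_levels_cropped <- function(disc) {
  stopifnot(inherits(disc, "disc_volume"))
  bb <- mask_bbox(disc$mask)
  lev <- disc$levels
  lev[!disc$mask] <- NA_integer_
  crop_to_bbox(lev, bb)
}

#' Gray-level co-occurrence matrix (3D, merged directions)
#'
#' Counts co-occurrences of gray-level pairs over the 13 unique direction
#' offsets at distance 1, symmetrizes, pools all directions into one matrix
#' and normalizes it to a joint probability `p(i, j)`. Pairs with either voxel
#' outside the mask are skipped.
#'
#' @param disc a `disc_volume` from [discretize_fbw()] or
#'   [equal_probability_quantize()].
#' @return A `glcm`: list with `p` (Ng x Ng probabilities), `counts`
#'   (symmetrized pair counts) and `ng`.
#' @export
build_glcm <- function(disc) {
  lev <- disc_levels_cropped(disc)
  ng <- disc$ng
  if (!any(!is.na(lev))) stop("empty mask")
  offs <- offsets_13()
  counts <- matrix(0, ng, ng)
  for (r in seq_len(nrow(offs))) {
    nb <- shift_array(lev, offs[r, ], fill = NA_integer_)
    ok <- !is.na(lev) & !is.na(nb)
    if (!any(ok)) next
    a <- lev[ok]; b <- nb[ok]
    tab <- tabulate((a - 1L) * ng + b, nbins = ng * ng)
    counts <- counts + matrix(tab, ng, ng, byrow = TRUE)
  }
  counts <- counts + t(counts)   # symmetrize (adds the antipodal directions)
  tot <- sum(counts)
  p <- if (tot > 0) counts / tot else counts
  structure(list(p = p, counts = counts, ng = ng), class = "glcm")
}

#' Gray-level run length matrix (3D, merged directions)
#'
#' Counts maximal runs of equal gray level along each of the 13 directions,
#' confined to the mask (an out-of-mask voxel terminates a run), pooling all
#' directions into one `Ng x Rmax` count matrix.
#'
#' @param disc a `disc_volume`.
#' @return A `glrlm`: list with `counts` (`P(i, r)` run counts), `p`
#'   (normalized by the total run count `nr`), `nr`, `ng` and `n_voxels`.
#' @export
build_glrlm <- function(disc) {
  lev <- disc_levels_cropped(disc)
  ng <- disc$ng
  d <- dim(lev)
  n_vox <- sum(!is.na(lev))
  if (n_vox == 0) stop("empty mask")
  offs <- offsets_13()
  rmax <- max(d)
  counts <- matrix(0, ng, rmax)
  I <- array(rep(seq_len(d[1]), times = d[2] * d[3]), d)
  J <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d)
  K <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  coords <- list(I, J, K)
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    # steps from the line start: distance to the grid face the line enters by
    t <- array(Inf, d)
    for (ax in 1:3) {
      if (off[ax] == 1) t <- pmin(t, coords[[ax]] - 1)
      else if (off[ax] == -1) t <- pmin(t, d[ax] - coords[[ax]])
    }
    base <- lapply(1:3, function(ax) coords[[ax]] - t * off[ax])
    line_id <- (base[[1]] - 1) + d[1] * (base[[2]] - 1) +
               d[1] * d[2] * (base[[3]] - 1)
    ord <- order(line_id, t)
    v <- lev[ord]; l <- line_id[ord]
    key <- ifelse(is.na(v), -seq_along(v), l * (ng + 1) + v)
    rl <- rle(key)
    keep <- rl$values >= 0
    run_lev <- rl$values[keep] %% (ng + 1)
    run_len <- rl$lengths[keep]
    if (length(run_lev)) {
      tab <- tabulate((run_lev - 1) * rmax + run_len, nbins = ng * rmax)
      counts <- counts + matrix(tab, ng, rmax, byrow = TRUE)
    }
  }
  nr <- sum(counts)
  structure(list(counts = counts, p = if (nr > 0) counts / nr else counts,
                 nr = nr, ng = ng, n_voxels = n_vox), class = "glrlm")
}

#' Gray-level size zone matrix
#'
#' Zones are connected components (26-connectivity by default) of equal-level
#' voxels inside the mask; `P(i, s)` counts the zones of level `i` and size
#' `s` voxels. The matrix is direction-free.
#'
#' @param disc a `disc_volume`.
#' @param connectivity zone connectivity, 26 (default) or 6.
#' @return A `glszm`: list with `counts`, `p` (normalized by the zone count
#'   `nz`), `nz`, `ng` and `n_voxels`.
#' @export
build_glszm <- function(disc, connectivity = 26) {
  lev <- disc_levels_cropped(disc)
  ng <- disc$ng
  n_vox <- sum(!is.na(lev))
  if (n_vox == 0) stop("empty mask")
  labs <- label_components(lev, connectivity)
  inm <- !is.na(labs)
  zone_size <- tabulate(labs[inm])
  zone_level <- lev[inm][match(seq_along(zone_size), labs[inm])]
  smax <- max(zone_size)
  counts <- matrix(0, ng, smax)
  tab <- tabulate((zone_level - 1) * smax + zone_size, nbins = ng * smax)
  counts <- counts + matrix(tab, ng, smax, byrow = TRUE)
  nz <- length(zone_size)
  structure(list(counts = counts, p = counts / nz, nz = nz, ng = ng,
                 n_voxels = n_vox), class = "glszm")
}

#' Neighborhood gray tone difference matrix
#'
#' For every in-mask voxel with at least one in-mask neighbor (26-neighborhood
#' restricted to the mask), accumulates the absolute difference between its
#' level and the mean level of its neighbors into `s_i`, and the level
#' occupancy fractions `p_i` over those valid voxels.
#'
#' @param disc a `disc_volume`.
#' @return An `ngtdm`: list with vectors `p` and `s` (length Ng), `ng` and
#'   `n_valid` (number of contributing voxels).
#' @export
build_ngtdm <- function(disc) {
  lev <- disc_levels_cropped(disc)
  ng <- disc$ng
  if (!any(!is.na(lev))) stop("empty mask")
  offs <- offsets_full(26)
  num <- array(0, dim(lev)); cnt <- array(0, dim(lev))
  lev0 <- lev; lev0[is.na(lev)] <- 0
  ind <- !is.na(lev)
  for (r in seq_len(nrow(offs))) {
    num <- num + shift_array(lev0, offs[r, ], fill = 0)
    cnt <- cnt + shift_array(ind + 0, offs[r, ], fill = 0)
  }
  valid <- ind & cnt > 0
  n_valid <- sum(valid)
  mean_nb <- num[valid] / cnt[valid]
  lv <- lev[valid]
  s <- vapply(seq_len(ng), function(i) sum(abs(i - mean_nb)[lv == i]),
              numeric(1))
  p <- tabulate(lv, nbins = ng) / n_valid
  structure(list(p = p, s = s, ng = ng, n_valid = n_valid), class = "ngtdm")
}
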