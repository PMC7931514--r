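#' Fixed-bin-width discretization
#'
#' Maps SUV values inside the mask to integer gray levels
#' `floor((SUV - min_ROI) / W) + 1`, anchored at the ROI minimum, so the level
#' map is invariant to adding a constant to all ROI values. With the default
#' bin width `W = 0.01` SUV, typical tumor ROIs produce a few hundred levels.
#'
#' @param image an [suv_image()] (or numeric 3D array).
#' @param mask non-empty logical mask on the image grid.
#' @param bin_width bin width W in SUV (> 0), default 0.01.
#' @return A `disc_volume`: list with `levels` (integer array, NA outside
#'   mask), `ng` (number of levels = max level), `mask`, and the mapping
#'   record (`origin`, `bin_width`).
#' @examples
#' img <- suv_image(array(c(1.00, 1.01, 1.35, 1), c(4, 1, 1)))
#' m <- array(c(TRUE, TRUE, TRUE, FALSE), c(4, 1, 1))
#' discretize_fbw(img, m)$ng  # 36
#' @export
discretize_fbw <- function(image, mask, bin_width = 0.01) {
  vals <- if (inherits(image, "suv_image")) image$values else image
  check_same_grid(vals, mask, "image and mask")
  if (!any(mask)) stop("mask is empty")
  if (bin_width <= 0) stop("bin_width must be > 0")
  v <- vals[mask]
  # the 1e-6 guard keeps values at exact bin-edge multiples of W in the
  # upper bin despite floating-point rounding of (v - min) / W
  lev <- floor((v - min(v)) / bin_width + 1e-6) + 1
  levels <- array(NA_integer_, dim(vals))
  levels[mask] <- as.integer(lev)
  structure(list(levels = levels, ng = as.integer(max(lev)), mask = mask,
                 origin = min(v), bin_width = bin_width),
            class = "disc_volume")
}

#' @export
print.disc_volume <- function(x, ...) {
  cat(sprintf("<disc_volume> %d voxels, Ng = %d\n", sum(x$mask), x$ng))
  invisible(x)
}

#' Equal-probability quantization
#'
#' Assigns gray levels by empirical quantile edges so that each of the
#' `n_levels` output levels holds as equal a voxel count as ties permit
#' (histogram equalization on the ROI). Levels that attract no voxels are
#' dropped and the remaining ones renumbered consecutively, so `ng` is the
#' number of occupied levels.
#'
#' @param image an [suv_image()] (or numeric 3D array).
#' @param mask non-empty logical mask.
#' @param n_levels number of target levels (>= 2), default 64.
#' @return A `disc_volume` (mapping record stores the quantile edges).
#' @export
equal_probability_quantize <- function(image, mask, n_levels = 64) {
  vals <- if (inherits(image, "suv_image")) image$values else image
  check_same_grid(vals, mask, "image and mask")
  if (!any(mask)) stop("mask is empty")
  if (n_levels < 2) stop("n_levels must be >= 2")
  v <- vals[mask]
  edges <- stats::quantile(v, probs = seq(0, 1, length.out = n_levels + 1),
                           type = 7, names = FALSE)
  lev <- findInterval(v, unique(edges), rightmost.closed = TRUE,
                      all.inside = TRUE)
  # renumber occupied levels 1..ng
  lev <- match(lev, sort(unique(lev)))
  levels <- array(NA_integer_, dim(vals))
  levels[mask] <- as.integer(lev)
  structure(list(levels = levels, ng = as.integer(max(lev)), mask = mask,
                 origin = NA_real_, bin_width = NA_real_,
                 quantile_edges = edges),
            class = "disc_volume")
}

#' Wavelet band-pass filtering
#'
#' One-level separable 3D discrete wavelet transform (decimated, symmetric
#' boundary extension) into the eight sub-bands LLL..HHH; the six mixed
#' ("band-pass") sub-bands containing both a low-pass and a high-pass factor
#' are reweighted relative to LLL and HHH by `ratio`, then the volume is
#' reconstructed. With the default orientation the weights are normalized so
#' that the non-band-pass weight is 1: `ratio = 0.5` halves the band-pass
#' sub-bands and leaves the image mean unchanged; `ratio = 1` is the identity
#' (perfect reconstruction). `orientation = "boost"` instead fixes the
#' band-pass weight at 1 and scales the other two sub-bands by `ratio`.
#'
#' @param image an [suv_image()] (or numeric 3D array).
#' @param ratio band-pass to other sub-band weight ratio (> 0), default 0.5
#'   (i.e. 1:2).
#' @param basis wavelet basis: "coif1" (default), "db2" or "haar".
#' @param orientation "attenuate" (default; non-band-pass weight 1) or
#'   "boost" (band-pass weight 1).
#' @param symmetrize average the filter response over the eight axis-reversal
#'   orientations of the grid (default TRUE). A decimated wavelet transform
#'   is phase-dependent, so a single orientation would make the filtered
#'   features depend on which end of each axis is "first"; group-averaging
#'   makes the operator exactly equivariant under grid reflections while
#'   remaining linear and leaving the identity (unit ratio) untouched.
#' @return An object of the same type as `image` with the filtered values
#'   (negative values can occur; they are kept, since discretization is
#'   anchored at the ROI minimum).
#' @export
wavelet_bandpass <- function(image, ratio = 0.5, basis = "coif1",
                             orientation = c("attenuate", "boost"),
                             symmetrize = TRUE) {
  orientation <- match.arg(orientation)
  if (ratio <= 0) stop("ratio must be > 0")
  vals <- if (inherits(image, "suv_image")) image$values else image
  filt <- wavelet_filters(basis)
  if (any(dim(vals) < length(filt$dec_lo)))
    stop("image dimensions must be at least the filter length (",
         length(filt$dec_lo), ")")
  w_bp <- if (orientation == "attenuate") ratio else 1
  w_other <- if (orientation == "attenuate") 1 else 1 / ratio
  filter_once <- function(v) {
    sub <- dwt3(v, filt)
    for (nm in names(sub$bands)) {
      n_h <- nchar(gsub("[^H]", "", nm))
      w <- if (n_h %in% c(0L, 3L)) w_other else w_bp
      sub$bands[[nm]] <- sub$bands[[nm]] * w
    }
    idwt3(sub, filt)
  }
  if (symmetrize) {
    out <- array(0, dim(vals))
    for (fx in 0:1) for (fy in 0:1) for (fz in 0:1) {
      v <- vals
      for (ax in 1:3) if (c(fx, fy, fz)[ax] == 1L) v <- flip_axis(v, ax)
      f <- filter_once(v)
      for (ax in 3:1) if (c(fx, fy, fz)[ax] == 1L) f <- flip_axis(f, ax)
      out <- out + f
    }
    out <- out / 8
  } else {
    out <- filter_once(vals)
  }
  if (inherits(image, "suv_image")) {
    image$values <- pmax(out, 0)   # container requires non-negative SUV
    attr(image, "wavelet_raw_min") <- min(out)
    image
  } else out
}

# --- 1D/3D decimated DWT with symmetric boundary extension ------------------

wavelet_filters <- function(basis = c("coif1", "db2", "haar")) {
  basis <- match.arg(basis)
  dec_lo <- switch(basis,
    haar = c(0.7071067811865476, 0.7071067811865476),
    db2 = c(-0.12940952255126037, 0.22414386804201339,
            0.8365163037378079, 0.48296291314453416),
    coif1 = c(-0.015655728135791993, -0.07273261951252645,
              0.3848648468648578, 0.8525720202116004,
              0.3378976624574818, -0.07273261951252645))
  L <- length(dec_lo)
  dec_hi <- rev(dec_lo) * (-1)^(seq_len(L))   # QMF
  list(dec_lo = dec_lo, dec_hi = dec_hi,
       rec_lo = rev(dec_lo), rec_hi = rev(dec_hi))
}

dwt1 <- function(x, filt_dec) {
  n <- length(x); L <- length(filt_dec)
  ext <- c(x[(L - 1):1], x, x[n:(n - L + 2)])
  cv <- stats::convolve(ext, rev(filt_dec), type = "open")
  cv[seq(L + 1, by = 2, length.out = floor((n + L - 1) / 2))]
}

idwt1 <- function(a, d, n, filt) {
  L <- length(filt$rec_lo)
  up <- function(v) {
    u <- numeric(2 * length(v))
    u[seq(1, by = 2, length.out = length(v))] <- v
    u
  }
  s <- stats::convolve(up(a), rev(filt$rec_lo), type = "open") +
       stats::convolve(up(d), rev(filt$rec_hi), type = "open")
  s[(L - 1):(L - 2 + n)]
}

# The per-axis transforms are linear in the fibre, so they are applied as one
# matrix product per axis: the analysis/synthesis operators for a given fibre
# length are built once (columns = responses to unit vectors, which keeps them
# consistent with dwt1/idwt1 by construction) and cached per call.

dwt_operator <- function(n, filt_dec) {
  vapply(seq_len(n), function(i) {
    e <- numeric(n); e[i] <- 1
    dwt1(e, filt_dec)
  }, numeric(floor((n + length(filt_dec) - 1) / 2)))
}

idwt_operator <- function(m, n, filt, which = c("lo", "hi")) {
  which <- match.arg(which)
  zero <- numeric(m)
  vapply(seq_len(m), function(i) {
    e <- numeric(m); e[i] <- 1
    if (which == "lo") idwt1(e, zero, n, filt) else idwt1(zero, e, n, filt)
  }, numeric(n))
}

# Multiply operator M (m x n) along axis `ax` of a 3D array.
mult_axis <- function(arr, ax, M) {
  d <- dim(arr)
  perm <- c(ax, setdiff(1:3, ax))
  mat <- matrix(aperm(arr, perm), nrow = d[ax])
  res <- M %*% mat
  out <- array(res, c(nrow(M), d[perm[2]], d[perm[3]]))
  aperm(out, order(perm))
}

dwt3 <- function(vals, filt) {
  n <- dim(vals)
  ops <- lapply(1:3, function(ax) list(
    L = dwt_operator(n[ax], filt$dec_lo),
    H = dwt_operator(n[ax], filt$dec_hi)))
  bands <- list(L = mult_axis(vals, 1, ops[[1]]$L),
                H = mult_axis(vals, 1, ops[[1]]$H))
  for (ax in 2:3) {
    nb <- list()
    for (nm in names(bands)) for (b in c("L", "H"))
      nb[[paste0(nm, b)]] <- mult_axis(bands[[nm]], ax, ops[[ax]][[b]])
    bands <- nb
  }
  list(bands = bands, n = n)
}

idwt3 <- function(sub, filt) {
  bands <- sub$bands; n <- sub$n
  m <- vapply(1:3, function(ax)
    floor((n[ax] + length(filt$dec_lo) - 1) / 2), numeric(1))
  ops <- lapply(1:3, function(ax) list(
    L = idwt_operator(m[ax], n[ax], filt, "lo"),
    H = idwt_operator(m[ax], n[ax], filt, "hi")))
  for (ax in 3:1) {
    nb <- list()
    prefixes <- unique(substr(names(bands), 1, ax - 1))
    for (p in prefixes) {
      merged <- mult_axis(bands[[paste0(p, "L")]], ax, ops[[ax]]$L) +
                mult_axis(bands[[paste0(p, "H")]], ax, ops[[ax]]$H)
      nb[[if (nzchar(p)) p else "x"]] <- merged
    }
    bands <- nb
  }
  bands[["x"]]
}
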