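# Low-level 3D array operations shared by the generators, segmentation and
# texture code. All of these are pure functions of their inputs.

# Shift a 3D array by integer offset (di, dj, dk), filling vacated entries
# with `fill`. shift_array(a, c(1,0,0))[i,j,k] == a[i-1,j,k].
shift_array <- function(a, off, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- off[ax]
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) {
      dst[[ax]] <- (1 + o):d[ax]; src[[ax]] <- 1:(d[ax] - o)
    } else {
      dst[[ax]] <- 1:(d[ax] + o); src[[ax]] <- (1 - o):d[ax]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# The 13 unique 3D direction offsets at Chebyshev distance 1 (one of each
# antipodal pair, first non-zero component positive).
offsets_13 <- function() {
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  keep <- apply(offs, 1, function(o) {
    nz <- o[o != 0]
    length(nz) > 0 && nz[1] > 0
  })
  unname(offs[keep, , drop = FALSE])
}

# All 26 neighbor offsets, or the 6 face offsets.
offsets_full <- function(connectivity = 26) {
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- unname(offs[rowSums(abs(offs)) > 0, , drop = FALSE])
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  else if (connectivity != 26) stop("connectivity must be 6 or 26")
  offs
}

# Connected-component labelling of equal-valued regions.
# `values`: integer array (NA outside the mask). Two in-mask voxels are in the
# same component iff they are neighbors (given connectivity) and have equal
# value. Returns an integer array of labels (NA outside mask); labels are the
# minimal linear index of each component, then renumbered 1..n_components in
# order of that minimal index (deterministic).
label_components <- function(values, connectivity = 26) {
  d <- dim(values)
  offs <- offsets_full(connectivity)
  inmask <- !is.na(values)
  lab <- array(NA_real_, d)
  lab[inmask] <- which(inmask)
  vals <- values
  repeat {
    new_lab <- lab
    for (r in seq_len(nrow(offs))) {
      off <- offs[r, ]
      nb_lab <- shift_array(lab, off, fill = NA_real_)
      nb_val <- shift_array(vals, off, fill = NA)
      ok <- inmask & !is.na(nb_lab) & !is.na(nb_val) & (nb_val == vals)
      upd <- ok & (nb_lab < new_lab)
      new_lab[upd] <- nb_lab[upd]
    }
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  u <- sort(unique(lab[inmask]))
  out <- array(NA_integer_, d)
  out[inmask] <- match(lab[inmask], u)
  out
}

# Separable Gaussian smoothing of a 3D array, sigma given in mm per axis.
# Kernel truncated at 4 sigma, renormalized; edges handled by replication.
gaussian_smooth3 <- function(a, sigma_mm, spacing) {
  if (length(sigma_mm) == 1) sigma_mm <- rep(sigma_mm, 3)
  for (ax in 1:3) {
    s_vox <- sigma_mm[ax] / spacing[ax]
    if (s_vox <= 0) next
    r <- max(1L, ceiling(4 * s_vox))
    k <- exp(-((-r:r)^2) / (2 * s_vox^2))
    k <- k / sum(k)
    acc <- array(0, dim(a))
    off <- c(0L, 0L, 0L)
    for (m in -r:r) {
      off[] <- 0L; off[ax] <- m
      # replicate edges: shift with NA then fill from nearest valid plane
      sh <- shift_array_replicate(a, off)
      acc <- acc + k[m + r + 1] * sh
    }
    a <- acc
  }
  a
}

# Shift with edge replication (clamped indexing) along a single-axis offset.
shift_array_replicate <- function(a, off) {
  d <- dim(a)
  idx <- lapply(1:3, function(ax) {
    i <- seq_len(d[ax]) - off[ax]
    pmin(pmax(i, 1L), d[ax])
  })
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# reverse a 3D array along one axis
flip_axis <- function(a, ax) {
  idx <- lapply(dim(a), seq_len)
  idx[[ax]] <- rev(idx[[ax]])
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# FWHM (mm) -> Gaussian sigma (mm)
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
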