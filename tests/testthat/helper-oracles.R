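# Independent brute-force oracles for the texture matrices and features.
# Deliberately naive: explicit per-voxel loops, no shared code with the
# package implementation.

# Wrap a bare integer level array (NA outside mask) as a disc_volume.
make_disc <- function(levels) {
  levels <- array(as.integer(levels), dim(levels))
  structure(list(levels = levels, ng = max(levels, na.rm = TRUE),
                 mask = !is.na(levels), origin = NA_real_,
                 bin_width = NA_real_),
            class = "disc_volume")
}

# Random small ROI: levels 1..ng with a random (non-empty) mask.
random_roi <- function(dims, ng) {
  lev <- array(sample.int(ng, prod(dims), replace = TRUE), dims)
  drop_mask <- array(runif(prod(dims)) < 0.25, dims)
  if (all(drop_mask)) drop_mask[1] <- FALSE
  lev[drop_mask] <- NA_integer_
  lev
}

all_offsets26 <- function() {
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs[rowSums(abs(offs)) > 0, , drop = FALSE]
}

inside <- function(d, v) all(v >= 1) && all(v <= d)

oracle_glcm <- function(lev, ng) {
  d <- dim(lev)
  offs <- all_offsets26()
  counts <- matrix(0, ng, ng)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    a <- lev[i, j, k]
    if (is.na(a)) next
    for (r in seq_len(nrow(offs))) {
      v <- c(i, j, k) + offs[r, ]
      if (!inside(d, v)) next
      b <- lev[v[1], v[2], v[3]]
      if (is.na(b)) next
      counts[a, b] <- counts[a, b] + 1
    }
  }
  list(p = counts / sum(counts), counts = counts)
}

oracle_glrlm <- function(lev, ng) {
  d <- dim(lev)
  dirs <- fetrad:::offsets_13()
  rmax <- max(d)
  counts <- matrix(0, ng, rmax)
  for (r in seq_len(nrow(dirs))) {
    dir <- dirs[r, ]
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      a <- lev[i, j, k]
      if (is.na(a)) next
      prev <- c(i, j, k) - dir
      prev_lev <- if (inside(d, prev)) lev[prev[1], prev[2], prev[3]] else NA
      if (!is.na(prev_lev) && prev_lev == a) next  # not a run start
      len <- 1
      cur <- c(i, j, k) + dir
      while (inside(d, cur) && !is.na(lev[cur[1], cur[2], cur[3]]) &&
             lev[cur[1], cur[2], cur[3]] == a) {
        len <- len + 1
        cur <- cur + dir
      }
      counts[a, len] <- counts[a, len] + 1
    }
  }
  list(counts = counts, nr = sum(counts))
}

oracle_glszm <- function(lev, ng, connectivity = 26) {
  d <- dim(lev)
  offs <- if (connectivity == 26) all_offsets26() else {
    o <- all_offsets26(); o[rowSums(abs(o)) == 1, , drop = FALSE]
  }
  visited <- array(FALSE, d)
  zones <- list()
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (is.na(lev[i, j, k]) || visited[i, j, k]) next
    a <- lev[i, j, k]
    stack <- list(c(i, j, k))
    visited[i, j, k] <- TRUE
    size <- 0
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (r in seq_len(nrow(offs))) {
        w <- v + offs[r, ]
        if (!inside(d, w) || visited[w[1], w[2], w[3]]) next
        b <- lev[w[1], w[2], w[3]]
        if (is.na(b) || b != a) next
        visited[w[1], w[2], w[3]] <- TRUE
        stack[[length(stack) + 1]] <- w
      }
    }
    zones[[length(zones) + 1]] <- c(level = a, size = size)
  }
  zl <- vapply(zones, `[[`, numeric(1), "level")
  zs <- vapply(zones, `[[`, numeric(1), "size")
  smax <- max(zs)
  counts <- matrix(0, ng, smax)
  for (q in seq_along(zl)) counts[zl[q], zs[q]] <- counts[zl[q], zs[q]] + 1
  list(counts = counts, nz = length(zl), n_voxels = sum(!is.na(lev)))
}

oracle_ngtdm <- function(lev, ng) {
  d <- dim(lev)
  offs <- all_offsets26()
  s <- numeric(ng); cnt <- numeric(ng); n_valid <- 0
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    a <- lev[i, j, k]
    if (is.na(a)) next
    nb <- c()
    for (r in seq_len(nrow(offs))) {
      v <- c(i, j, k) + offs[r, ]
      if (!inside(d, v)) next
      b <- lev[v[1], v[2], v[3]]
      if (!is.na(b)) nb <- c(nb, b)
    }
    if (length(nb) == 0) next
    n_valid <- n_valid + 1
    cnt[a] <- cnt[a] + 1
    s[a] <- s[a] + abs(a - mean(nb))
  }
  list(p = cnt / n_valid, s = s, n_valid = n_valid)
}

# Literal-formula feature oracles on matrix representations -------------------

oracle_glcm_features <- function(p) {
  ng <- nrow(p)
  acor <- varcm <- mu <- 0
  for (i in 1:ng) for (j in 1:ng) mu <- mu + i * p[i, j]
  for (i in 1:ng) for (j in 1:ng) {
    acor <- acor + i * j * p[i, j]
    varcm <- varcm + (i - mu)^2 * p[i, j]
  }
  ent <- 0; en <- 0; ctr <- 0; hom <- 0; dis <- 0
  for (i in 1:ng) for (j in 1:ng) {
    if (p[i, j] > 0) ent <- ent - p[i, j] * log2(p[i, j])
    en <- en + p[i, j]^2
    ctr <- ctr + (i - j)^2 * p[i, j]
    hom <- hom + p[i, j] / (1 + abs(i - j))
    dis <- dis + abs(i - j) * p[i, j]
  }
  corr <- if (varcm > 0) (acor - mu^2) / varcm else NA_real_
  c(Acor = acor, Variance_CM = varcm, Energy_CM = en, Contrast_CM = ctr,
    Entropy_CM = ent, Homogeneity = hom, Correlation = corr,
    Dissimilarity = dis)
}

oracle_glrlm_features <- function(counts) {
  nr <- sum(counts)
  ng <- nrow(counts); rmax <- ncol(counts)
  acc <- c(SRE = 0, LRE = 0, LGRE = 0, HGRE = 0, SRLGE = 0, SRHGE = 0,
           LRLGE = 0, LRHGE = 0)
  mu_i <- mu_r <- 0; nv <- 0
  for (i in 1:ng) for (r in 1:rmax) {
    p <- counts[i, r] / nr
    acc["SRE"] <- acc["SRE"] + p / r^2
    acc["LRE"] <- acc["LRE"] + p * r^2
    acc["LGRE"] <- acc["LGRE"] + p / i^2
    acc["HGRE"] <- acc["HGRE"] + p * i^2
    acc["SRLGE"] <- acc["SRLGE"] + p / (i^2 * r^2)
    acc["SRHGE"] <- acc["SRHGE"] + p * i^2 / r^2
    acc["LRLGE"] <- acc["LRLGE"] + p * r^2 / i^2
    acc["LRHGE"] <- acc["LRHGE"] + p * i^2 * r^2
    mu_i <- mu_i + p * i; mu_r <- mu_r + p * r
    nv <- nv + r * counts[i, r]
  }
  glv <- rlv <- 0
  for (i in 1:ng) for (r in 1:rmax) {
    p <- counts[i, r] / nr
    glv <- glv + p * (i - mu_i)^2
    rlv <- rlv + p * (r - mu_r)^2
  }
  gln <- sum(rowSums(counts)^2) / nr
  rln <- sum(colSums(counts)^2) / nr
  c(acc["SRE"], acc["LRE"], GLN = gln, RLN = rln, RP = nr / nv,
    acc["LGRE"], acc["HGRE"], acc["SRLGE"], acc["SRHGE"], acc["LRLGE"],
    acc["LRHGE"], GLV = glv, RLV = rlv)[c("SRE", "LRE", "GLN", "RLN", "RP",
                                          "LGRE", "HGRE", "SRLGE", "SRHGE",
                                          "LRLGE", "LRHGE", "GLV", "RLV")]
}

oracle_glszm_features <- function(counts, n_voxels) {
  nz <- sum(counts)
  ng <- nrow(counts); smax <- ncol(counts)
  out <- c(SZE = 0, LZE = 0, LGZE = 0, HGZE = 0, SZLGE = 0, SZHGE = 0,
           LZLGE = 0, LZHGE = 0)
  mu_i <- mu_s <- 0
  for (i in 1:ng) for (s in 1:smax) {
    p <- counts[i, s] / nz
    out["SZE"] <- out["SZE"] + p / s^2
    out["LZE"] <- out["LZE"] + p * s^2
    out["LGZE"] <- out["LGZE"] + p / i^2
    out["HGZE"] <- out["HGZE"] + p * i^2
    out["SZLGE"] <- out["SZLGE"] + p / (i^2 * s^2)
    out["SZHGE"] <- out["SZHGE"] + p * i^2 / s^2
    out["LZLGE"] <- out["LZLGE"] + p * s^2 / i^2
    out["LZHGE"] <- out["LZHGE"] + p * i^2 * s^2
    mu_i <- mu_i + p * i; mu_s <- mu_s + p * s
  }
  glv2 <- zsv <- 0
  for (i in 1:ng) for (s in 1:smax) {
    p <- counts[i, s] / nz
    glv2 <- glv2 + p * (i - mu_i)^2
    zsv <- zsv + p * (s - mu_s)^2
  }
  c(out["SZE"], out["LZE"], GLN2 = sum(rowSums(counts)^2) / nz^2,
    ZSN = sum(colSums(counts)^2) / nz, ZP = nz / n_voxels,
    out["LGZE"], out["HGZE"], out["SZLGE"], out["SZHGE"], out["LZLGE"],
    out["LZHGE"], GLV2 = glv2, ZSV = zsv)[c("SZE", "LZE", "GLN2", "ZSN",
                                            "ZP", "LGZE", "HGZE", "SZLGE",
                                            "SZHGE", "LZLGE", "LZHGE",
                                            "GLV2", "ZSV")]
}

oracle_ngtdm_features <- function(p, s, n_valid) {
  occ <- which(p > 0)
  coarse <- if (sum(p * s) > 0) 1 / sum(p * s) else NA_real_
  if (length(occ) < 2)
    return(c(Coarseness = coarse, Contrast_NGTDM = NA, Busyness = NA,
             Complexity = NA, TS = NA))
  num_b <- den_b <- ctr1 <- cmpl <- ts_num <- 0
  for (i in occ) {
    num_b <- num_b + p[i] * s[i]
    for (j in occ) {
      den_b <- den_b + abs(i * p[i] - j * p[j])
      ctr1 <- ctr1 + p[i] * p[j] * (i - j)^2
      cmpl <- cmpl + abs(i - j) * (p[i] * s[i] + p[j] * s[j]) / (p[i] + p[j])
      ts_num <- ts_num + (p[i] + p[j]) * (i - j)^2
    }
  }
  n_occ <- length(occ)
  c(Coarseness = coarse,
    Contrast_NGTDM = ctr1 / (n_occ * (n_occ - 1)) * sum(s) / n_valid,
    Busyness = if (den_b > 0) num_b / den_b else NA_real_,
    Complexity = cmpl / n_valid,
    TS = if (sum(s) > 0) ts_num / sum(s) else NA_real_)
}

# Hand risk-table two-group log-rank oracle (literal enumeration).
oracle_logrank <- function(time, event, group) {
  ts <- sort(unique(time[event]))
  O <- E <- V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group)
    d <- sum(event & time == t); d1 <- sum(event & time == t & group)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# pad a count matrix with zero columns up to `nc` columns
pad_cols <- function(m, nc) {
  if (ncol(m) < nc) m <- cbind(m, matrix(0, nrow(m), nc - ncol(m)))
  m
}

# agreement to `tol` relative error (absolute below magnitude 1); NAs must
# match as NAs
expect_rel_equal <- function(got, want, tol = 1e-10) {
  both_na <- is.na(got) & is.na(want)
  close <- !is.na(got) & !is.na(want) &
    abs(got - want) <= tol * pmax(1, abs(want))
  expect_true(all(both_na | close),
              label = paste("agreement within", tol, "relative"))
}
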