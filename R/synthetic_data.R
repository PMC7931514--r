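#' Lesion specification for synthetic brain PET
#'
#' Describes one hot lesion: a sphere of given radius whose uptake is
#' `contrast` times the background SUV, modulated by a multiplicative
#' heterogeneity field `1 + g` where `g` is a zero-mean Gaussian random field
#' with standard deviation `heterogeneity_sd` and correlation length
#' `texture_corr_mm` (the field is clipped below at 0.1 so uptake stays
#' positive).
#'
#' @param center lesion center in voxel coordinates.
#' @param radius_mm lesion radius in mm (> 0).
#' @param contrast lesion-to-background SUV ratio (> 1).
#' @param heterogeneity_sd SD of the multiplicative heterogeneity field.
#' @param texture_corr_mm Gaussian correlation length of that field, mm.
#' @return A `lesion_spec` list.
#' @export
lesion_spec <- function(center, radius_mm, contrast,
                        heterogeneity_sd = 0, texture_corr_mm = 4) {
  if (radius_mm <= 0) stop("radius_mm must be > 0")
  if (contrast <= 1) stop("contrast must be > 1")
  if (heterogeneity_sd < 0) stop("heterogeneity_sd must be >= 0")
  structure(list(center = center, radius_mm = radius_mm, contrast = contrast,
                 heterogeneity_sd = heterogeneity_sd,
                 texture_corr_mm = texture_corr_mm), class = "lesion_spec")
}

#' Scanner profile
#'
#' The imaging chain is reduced to a Gaussian point-spread function (applied
#' to the noiseless tracer distribution) followed by additive Gaussian noise
#' in SUV units. Two distinct profiles stand in for two PET/CT systems in
#' robustness experiments.
#'
#' @param psf_fwhm_mm full width at half maximum of the Gaussian blur, mm
#'   (>= 0; a typical clinical value is 4.8).
#' @param noise_sd SD of additive Gaussian SUV noise (>= 0).
#' @return A `scanner_profile` list.
#' @export
scanner_profile <- function(psf_fwhm_mm = 4.8, noise_sd = 0.05) {
  if (psf_fwhm_mm < 0 || noise_sd < 0) stop("psf_fwhm_mm and noise_sd must be >= 0")
  structure(list(psf_fwhm_mm = psf_fwhm_mm, noise_sd = noise_sd),
            class = "scanner_profile")
}

#' Generate a synthetic tumor-bearing brain PET image
#'
#' Builds a piecewise-constant tracer distribution (uniform background plus
#' hot lesions with optional intra-lesion heterogeneity), convolves it with
#' the scanner PSF, then adds Gaussian SUV noise clipped at zero. The returned
#' mask is the pre-blur lesion support, i.e. the ground truth against which
#' threshold segmentation is judged.
#'
#' @param bg_suv background SUV (default 1.0).
#' @param lesions list of [lesion_spec()] objects (may be empty).
#' @param scanner a [scanner_profile()].
#' @param grid_shape integer length-3 grid dimensions.
#' @param spacing voxel spacing mm (default 2 mm isotropic).
#' @param seed integer RNG seed; identical seeds give bit-identical images.
#' @return list with `image` (an [suv_image()]) and `lesion_mask` (logical
#'   array, union of lesion supports).
#' @examples
#' s <- gen_brain_pet(lesions = list(lesion_spec(c(17, 17, 17), 8, 4)),
#'                    scanner = scanner_profile(0, 0),
#'                    grid_shape = c(33, 33, 33), seed = 1)
#' range(s$image$values)
#' @export
gen_brain_pet <- function(bg_suv = 1.0, lesions = list(),
                          scanner = scanner_profile(),
                          grid_shape = c(64, 64, 64), spacing = c(2, 2, 2),
                          seed = 1) {
  stopifnot(bg_suv > 0)
  grid_shape <- as.integer(grid_shape)
  set.seed(as.integer(seed))
  vals <- array(bg_suv, grid_shape)
  lesion_mask <- array(FALSE, grid_shape)
  for (les in lesions) {
    if (!sphere_inside(grid_shape, spacing, les$center, les$radius_mm))
      stop("lesion extends outside the grid")
    m <- sphere_mask(grid_shape, spacing, les$center, les$radius_mm)
    lesion_val <- bg_suv * les$contrast
    if (les$heterogeneity_sd > 0) {
      field <- gaussian_random_field(grid_shape, spacing,
                                     les$texture_corr_mm,
                                     les$heterogeneity_sd)
      vals[m] <- lesion_val * pmax(1 + field[m], 0.1)
    } else {
      vals[m] <- lesion_val
    }
    lesion_mask <- lesion_mask | m
  }
  if (scanner$psf_fwhm_mm > 0)
    vals <- gaussian_smooth3(vals, fwhm_to_sigma(scanner$psf_fwhm_mm), spacing)
  if (scanner$noise_sd > 0)
    vals <- vals + array(stats::rnorm(prod(grid_shape), 0, scanner$noise_sd),
                         grid_shape)
  vals <- pmax(vals, 0)
  list(image = suv_image(vals, spacing), lesion_mask = lesion_mask)
}

# Zero-mean unit-free Gaussian random field: white noise smoothed with a
# Gaussian kernel of the requested correlation length, rescaled to sd `sd`.
gaussian_random_field <- function(grid_shape, spacing, corr_mm, sd) {
  w <- array(stats::rnorm(prod(grid_shape)), grid_shape)
  if (corr_mm > 0) w <- gaussian_smooth3(w, corr_mm, spacing)
  s <- stats::sd(as.vector(w))
  if (s > 0) w <- w / s
  w * sd
}

#' Generate a NEMA-like sphere phantom image
#'
#' Six fillable hot spheres (volumes in cc) in a warm uniform background,
#' rendered through a [scanner_profile()]. The phantom geometry is simplified
#' to non-overlapping spheres on a ring inside a box; only sphere and
#' background statistics matter to the downstream screening stages.
#'
#' @param sphere_volumes_cc six sphere volumes in cc, each in [0.5, 25].
#' @param sphere_to_bg_ratio sphere-to-background activity ratio (> 1).
#' @param bg_suv background SUV.
#' @param scanner a [scanner_profile()].
#' @param grid_shape,spacing image grid (default 96^3 at 2 mm: a 192 mm box).
#' @param seed RNG seed.
#' @return list with `image` ([suv_image()]), `sphere_masks` (list of 6
#'   logical arrays, analytic supports) and `sphere_centers` (voxel coords).
#' @export
gen_nema_phantom <- function(sphere_volumes_cc = c(0.5, 1.2, 2.6, 5.6, 11.5, 25),
                             sphere_to_bg_ratio = 4, bg_suv = 1.0,
                             scanner = scanner_profile(),
                             grid_shape = c(96, 96, 96), spacing = c(2, 2, 2),
                             seed = 1) {
  if (length(sphere_volumes_cc) != 6L)
    stop("exactly 6 sphere volumes are required")
  if (any(sphere_volumes_cc < 0.5 | sphere_volumes_cc > 25))
    stop("sphere volumes must lie in [0.5, 25] cc")
  if (sphere_to_bg_ratio <= 1) stop("sphere_to_bg_ratio must be > 1")
  grid_shape <- as.integer(grid_shape)
  set.seed(as.integer(seed))
  radii <- sphere_radius_mm(sphere_volumes_cc)
  # ring layout in the central axial plane
  ctr <- (grid_shape + 1) / 2
  ring_r_mm <- 0.28 * min((grid_shape - 1) * spacing)
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  centers <- lapply(seq_len(6), function(i) {
    c(ctr[1] + ring_r_mm * cos(ang[i]) / spacing[1],
      ctr[2] + ring_r_mm * sin(ang[i]) / spacing[2],
      ctr[3])
  })
  # check non-overlap and containment
  for (i in 1:6) {
    if (!sphere_inside(grid_shape, spacing, centers[[i]], radii[i]))
      stop("phantom sphere extends outside the grid; enlarge grid_shape")
    for (j in seq_len(i - 1)) {
      dmm <- sqrt(sum(((centers[[i]] - centers[[j]]) * spacing)^2))
      if (dmm <= radii[i] + radii[j])
        stop("phantom spheres overlap; enlarge grid or reduce volumes")
    }
  }
  vals <- array(bg_suv, grid_shape)
  sphere_masks <- vector("list", 6)
  for (i in 1:6) {
    m <- sphere_mask(grid_shape, spacing, centers[[i]], radii[i])
    vals[m] <- bg_suv * sphere_to_bg_ratio
    sphere_masks[[i]] <- m
  }
  if (scanner$psf_fwhm_mm > 0)
    vals <- gaussian_smooth3(vals, fwhm_to_sigma(scanner$psf_fwhm_mm), spacing)
  if (scanner$noise_sd > 0)
    vals <- vals + array(stats::rnorm(prod(grid_shape), 0, scanner$noise_sd),
                         grid_shape)
  list(image = suv_image(pmax(vals, 0), spacing),
       sphere_masks = sphere_masks, sphere_centers = centers)
}

#' Spherical background contours of log-uniform volume
#'
#' Places `n` spherical masks fully inside the image and disjoint from
#' `avoid`, with volumes drawn log-uniformly from `volume_range_cc`. Used for
#' the intrinsic size-dependence screen, which needs contours spanning orders
#' of magnitude in volume.
#'
#' @param image an [suv_image()] (geometry source).
#' @param n number of contours.
#' @param volume_range_cc length-2 volume range in cc.
#' @param avoid optional logical mask of voxels the contours must not touch
#'   (e.g. phantom spheres or lesions).
#' @param seed RNG seed.
#' @param max_tries placement attempts per contour before giving up.
#' @return list of `n` logical masks (attribute `volumes_cc` records the drawn
#'   volumes).
#' @export
gen_background_contours <- function(image, n = 102,
                                    volume_range_cc = c(0.8, 234),
                                    avoid = NULL, seed = 1, max_tries = 200) {
  stopifnot(inherits(image, "suv_image"), n >= 1)
  d <- dim(image$values); sp <- image$spacing
  set.seed(as.integer(seed))
  vols <- exp(stats::runif(n, log(volume_range_cc[1]), log(volume_range_cc[2])))
  vols <- sort(vols, decreasing = TRUE)  # place big ones first
  out <- vector("list", n)
  for (i in seq_len(n)) {
    r <- sphere_radius_mm(vols[i])
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      ctr <- stats::runif(3, 1 + r / sp, d - r / sp)
      if (!sphere_inside(d, sp, ctr, r)) next
      m <- sphere_mask(d, sp, ctr, r)
      if (!is.null(avoid) && any(m & avoid)) next
      out[[i]] <- m
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf("could not place a %.1f cc background contour without overlap", vols[i]))
  }
  attr(out, "volumes_cc") <- vols
  out
}

#' Cohort specification for feature-level simulation
#'
#' Ground-truth parameters for a synthetic radiomics cohort: per-feature
#' Gaussian marginals, Cox proportional-hazards coefficients driving
#' time-to-progression (TTP) and overall-survival (OS) times (exponential
#' baseline), an expected censoring fraction, and logistic coefficients for
#' the recurrence-location (RL) label.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param feature_means,feature_sds named numeric vectors (same names).
#' @param cox_coefficients_ttp,cox_coefficients_os named coefficient vectors;
#'   names must be a subset of the feature names. Covariates enter the hazard
#'   centered at their mean so `baseline_hazard` is the hazard of an average
#'   subject.
#' @param baseline_hazard events per day for an average subject.
#' @param censor_rate expected fraction of censored subjects, in [0, 1].
#' @param rl_logistic_coefficients named vector for the RL label; the name
#'   `"(Intercept)"` is honoured, remaining names must be features (also
#'   centered).
#' @param seed RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 32,
                        feature_means = c(SZLGE = 0.03),
                        feature_sds = c(SZLGE = 0.01),
                        cox_coefficients_ttp = numeric(0),
                        cox_coefficients_os = numeric(0),
                        baseline_hazard = 1 / 150,
                        censor_rate = 0.2,
                        rl_logistic_coefficients = numeric(0),
                        seed = 1) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (censor_rate < 0 || censor_rate > 1) stop("censor_rate must be in [0, 1]")
  if (!identical(sort(names(feature_means)), sort(names(feature_sds))))
    stop("feature_means and feature_sds must share names")
  for (v in list(cox_coefficients_ttp, cox_coefficients_os)) {
    if (length(v) && !all(names(v) %in% names(feature_means)))
      stop("Cox coefficient names must refer to generated features")
  }
  rl_nm <- setdiff(names(rl_logistic_coefficients), "(Intercept)")
  if (length(rl_nm) && !all(rl_nm %in% names(feature_means)))
    stop("RL coefficient names must refer to generated features")
  structure(list(n_subjects = as.integer(n_subjects),
                 feature_means = feature_means, feature_sds = feature_sds,
                 cox_coefficients_ttp = cox_coefficients_ttp,
                 cox_coefficients_os = cox_coefficients_os,
                 baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate,
                 rl_logistic_coefficients = rl_logistic_coefficients,
                 seed = as.integer(seed)), class = "cohort_spec")
}

#' Generate a synthetic cohort table
#'
#' Features are drawn Normal(mean, sd) per name. TTP and OS times are drawn
#' from an exponential proportional-hazards model, hazard
#' `baseline_hazard * exp(beta' (x - mu))`; independent exponential censoring
#' times are calibrated (by root finding on the marginal censoring
#' probability) to give the requested expected censoring fraction. The RL
#' label is Bernoulli(logistic(gamma' (x - mu))) and is defined only for
#' subjects whose TTP event was observed (NA otherwise).
#'
#' @param spec a [cohort_spec()].
#' @return A `data.frame` with columns `subject`, one column per feature,
#'   `ttp_days`, `ttp_event`, `os_days`, `os_event`, `rl_label`.
#' @examples
#' tab <- gen_cohort(cohort_spec(n_subjects = 8, seed = 7))
#' head(tab)
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  nm <- names(spec$feature_means)
  X <- sapply(nm, function(f)
    stats::rnorm(n, spec$feature_means[[f]], spec$feature_sds[[f]]))
  X <- matrix(X, nrow = n, dimnames = list(NULL, nm))
  Xc <- sweep(X, 2, spec$feature_means[nm])

  draw_surv <- function(beta) {
    lp <- if (length(beta)) as.vector(Xc[, names(beta), drop = FALSE] %*% beta)
          else rep(0, n)
    rate <- spec$baseline_hazard * exp(lp)
    times <- stats::rexp(n, rate)
    cens <- rep(Inf, n)
    if (spec$censor_rate > 0) {
      mu <- calibrate_censor_rate(rate, spec$censor_rate)
      cens <- stats::rexp(n, mu)
    }
    list(time = pmin(times, cens), event = times <= cens)
  }
  ttp <- draw_surv(spec$cox_coefficients_ttp)
  os <- draw_surv(spec$cox_coefficients_os)

  gamma <- spec$rl_logistic_coefficients
  lp_rl <- rep(0, n)
  if ("(Intercept)" %in% names(gamma)) lp_rl <- lp_rl + gamma[["(Intercept)"]]
  g2 <- gamma[setdiff(names(gamma), "(Intercept)")]
  if (length(g2)) lp_rl <- lp_rl + as.vector(Xc[, names(g2), drop = FALSE] %*% g2)
  rl <- stats::rbinom(n, 1, stats::plogis(lp_rl))
  rl[!ttp$event] <- NA_integer_

  out <- data.frame(subject = sprintf("S%03d", seq_len(n)), X,
                    ttp_days = pmax(ttp$time, 1e-6),
                    ttp_event = ttp$event,
                    os_days = pmax(os$time, 1e-6),
                    os_event = os$event,
                    rl_label = rl,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out
}

# Find the exponential censoring rate mu with mean_i mu/(mu+rate_i) = target.
calibrate_censor_rate <- function(rates, target) {
  if (target <= 0) return(0)
  f <- function(mu) mean(mu / (mu + rates)) - target
  lo <- min(rates) * 1e-8; hi <- max(rates) * 1e8
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}
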