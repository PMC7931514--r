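#' Kaplan-Meier median-split log-rank test
#'
#' Dichotomizes the feature at the cohort median (ties go to the low group:
#' the high group is strictly above the median), then compares the two groups
#' with the standard two-group log-rank test (1 df chi-square).
#'
#' @param values numeric feature values, one per subject.
#' @param time positive event/censoring times.
#' @param event logical event indicators.
#' @return A `km_result`: list with `chisq`, `p`, `n_low`, `n_high`,
#'   `cut` (the median), and the `survdiff` fit.
#' @export
km_logrank <- function(values, time, event) {
  ok <- is.finite(values) & is.finite(time)
  values <- values[ok]; time <- time[ok]; event <- event[ok]
  n <- length(values)
  if (n < 6) stop("at least 6 subjects are required")
  cut <- stats::median(values)
  grp <- values > cut
  if (all(grp) || !any(grp))
    stop("degenerate median split: feature is constant")
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  chisq <- sd$chisq
  structure(list(chisq = chisq,
                 p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
                 n_low = sum(!grp), n_high = sum(grp), cut = cut,
                 survdiff = sd), class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("<km_result> median split at %.4g (%d low / %d high): chisq = %.3f, p = %.4g\n",
              x$cut, x$n_low, x$n_high, x$chisq, x$p))
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise significance level.
#' @param k number of comparisons (>= 1).
#' @return `alpha / k`.
#' @examples bonferroni_threshold(0.05, 38)  # ~0.0013
#' @export
bonferroni_threshold <- function(alpha, k) {
  if (k < 1) stop("k must be >= 1")
  alpha / k
}

#' Redundancy groups and representative selection
#'
#' Builds a graph over candidate features with an edge wherever two features
#' are strongly Spearman-correlated (`p < alpha` and `|r| > strong_corr_r`);
#' connected components are redundancy groups, and each group is represented
#' by its member with the smallest log-rank p value (ties broken by name
#' order).
#'
#' @param features data.frame of per-subject values for the candidate
#'   features.
#' @param km_p named numeric vector of log-rank p values for the candidates.
#' @param cfg a [screening_config()].
#' @return list with `representatives` (character vector) and `groups`
#'   (list of character vectors).
#' @export
redundancy_groups <- function(features, km_p, cfg = screening_config()) {
  nm <- names(features)
  if (length(nm) == 0)
    return(list(representatives = character(0), groups = list()))
  stopifnot(all(nm %in% names(km_p)))
  k <- length(nm)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(k)) for (j in seq_len(i - 1)) {
    if (strong_correlation(features[[i]], features[[j]], cfg)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  groups <- split(nm, roots)
  names(groups) <- NULL
  reps <- vapply(groups, function(g) {
    g <- g[order(km_p[g], g)]
    g[1]
  }, character(1))
  list(representatives = unname(reps), groups = groups)
}

#' Fit a multivariate Cox radiomics signature
#'
#' Combines the selected representative features into a multivariate Cox
#' proportional-hazards model (Efron tie handling) for one endpoint. The risk
#' score of a subject is the linear predictor `beta' x`; the fitted object
#' also carries the Kaplan-Meier median split of the risk score with its
#' log-rank p, mirroring how a signature is displayed as two survival curves.
#' A warning (not an error) is issued when the number of events is below five
#' per covariate.
#'
#' @param features data.frame (or matrix) of the selected features, one row
#'   per subject.
#' @param time,event the endpoint's times and event indicators.
#' @param endpoint label, e.g. "TTP" or "OS".
#' @return A `fet_signature` object: the `coxph` fit plus coefficients,
#'   hazard ratios with 95% CI, the three overall test p values
#'   (likelihood-ratio, Wald, score), risk scores and the risk-score KM split.
#' @export
fit_cox_signature <- function(features, time, event, endpoint = "TTP") {
  X <- as.data.frame(features)
  stopifnot(nrow(X) == length(time), nrow(X) == length(event))
  if (sum(event) < 5 * ncol(X))
    warning(sprintf("only %d events for %d covariates (< 5 per covariate)",
                    sum(event), ncol(X)))
  dat <- cbind(data.frame(.time = time, .event = as.integer(event)), X)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(sprintf("`%s`", names(X)), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  if (!is.null(fit$info) || any(!is.finite(stats::coef(fit))))
    stop("Cox fit did not converge")
  if (any(abs(stats::coef(fit)) > 50))
    stop("Cox fit suggests separation (divergent coefficient)")
  sm <- summary(fit)
  beta <- stats::coef(fit)
  ci <- stats::confint(fit)
  risk <- as.vector(as.matrix(X) %*% beta)
  km <- km_logrank(risk, time, event)
  structure(list(endpoint = endpoint, features = names(X), fit = fit,
                 coefficients = beta,
                 hr = exp(beta), hr_ci = exp(ci),
                 overall_tests = c(likelihood_ratio = unname(sm$logtest["pvalue"]),
                                   wald = unname(sm$waldtest["pvalue"]),
                                   score = unname(sm$sctest["pvalue"])),
                 risk_score = risk, km = km),
            class = "fet_signature")
}

#' @export
print.fet_signature <- function(x, ...) {
  cat(sprintf("<fet_signature> %s radiomics signature (%d features, n = %d)\n",
              x$endpoint, length(x$features), length(x$risk_score)))
  tab <- cbind(coef = x$coefficients, HR = x$hr, x$hr_ci)
  colnames(tab)[3:4] <- c("HR lo95", "HR hi95")
  print(round(tab, 4))
  cat(sprintf("  overall tests: LR p = %.4g, Wald p = %.4g, score p = %.4g\n",
              x$overall_tests[1], x$overall_tests[2], x$overall_tests[3]))
  cat(sprintf("  risk-score median split log-rank p = %.4g\n", x$km$p))
  invisible(x)
}

#' @export
summary.fet_signature <- function(object, ...) summary(object$fit, ...)

#' @export
coef.fet_signature <- function(object, ...) object$coefficients

#' @export
predict.fet_signature <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$risk_score)
  X <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  as.vector(X %*% object$coefficients)
}

#' Recurrence-location model: imbalance-adjusted bootstrap logistic regression
#'
#' Fits a binary logistic model for recurrence location on one or more
#' predictors. Model coefficients are the mean over `n_boot` stratified
#' bootstrap fits in which both classes are resampled to equal expected
#' proportion (the imbalance adjustment). Discrimination (AUC) and
#' sensitivity at the probability-0.5 operating point are estimated with the
#' 0.632+ bootstrap, combining apparent and out-of-bag performance.
#'
#' @param predictors numeric vector, matrix or data.frame of predictor
#'   values, one row per subject.
#' @param labels binary labels (1 = recurrence inside the initial PET
#'   volume); NAs are dropped with their rows.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @return A `fet_rl_model`: coefficients (bootstrap means), `auc`,
#'   `sensitivity`, the apparent/out-of-bag components and settings.
#' @export
fit_rl_model <- function(predictors, labels, n_boot = 1000, seed = 1) {
  X <- as.matrix(as.data.frame(predictors))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- stats::complete.cases(X) & !is.na(labels)
  X <- X[keep, , drop = FALSE]
  y <- as.integer(labels[keep])
  n <- length(y)
  if (n < 10) stop("at least 10 labelled subjects are required")
  if (length(unique(y)) < 2) stop("both classes must be present")
  set.seed(as.integer(seed))
  idx0 <- which(y == 0); idx1 <- which(y == 1)
  n_half <- ceiling(n / 2)

  fit_glm <- function(rows) {
    d <- data.frame(y = y[rows], X[rows, , drop = FALSE])
    suppressWarnings(stats::glm(y ~ ., data = d, family = stats::binomial()))
  }
  full_fit <- fit_glm(seq_len(n))
  p_app <- stats::predict(full_fit, type = "response")
  auc_app <- auc_rank(p_app, y)
  sens_app <- mean(p_app[y == 1] >= 0.5)

  coefs <- matrix(NA_real_, n_boot, ncol(X) + 1)
  auc_oob <- sens_oob <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    rows <- c(sample(idx0, n_half, replace = TRUE),
              sample(idx1, n - n_half, replace = TRUE))
    fit_b <- fit_glm(rows)
    coefs[b, ] <- stats::coef(fit_b)
    oob <- setdiff(seq_len(n), unique(rows))
    if (length(oob) >= 2 && length(unique(y[oob])) == 2) {
      d_oob <- data.frame(X[oob, , drop = FALSE])
      p_oob <- suppressWarnings(
        stats::predict(fit_b, newdata = d_oob, type = "response"))
      auc_oob[b] <- auc_rank(p_oob, y[oob])
      if (any(y[oob] == 1)) sens_oob[b] <- mean(p_oob[y[oob] == 1] >= 0.5)
    }
  }
  auc <- boot632plus(auc_app, mean(auc_oob, na.rm = TRUE), gamma = 0.5)
  # no-information sensitivity: chance a random positive is called positive
  sens <- boot632plus(sens_app, mean(sens_oob, na.rm = TRUE),
                      gamma = mean(p_app >= 0.5))
  structure(list(predictors = colnames(X),
                 coefficients = stats::setNames(colMeans(coefs, na.rm = TRUE),
                                                c("(Intercept)", colnames(X))),
                 auc = auc, sensitivity = sens,
                 auc_apparent = auc_app, auc_oob = mean(auc_oob, na.rm = TRUE),
                 sens_apparent = sens_app,
                 sens_oob = mean(sens_oob, na.rm = TRUE),
                 n = n, n_boot = n_boot, seed = seed,
                 threshold = 0.5, full_fit = full_fit),
            class = "fet_rl_model")
}

#' @export
print.fet_rl_model <- function(x, ...) {
  cat(sprintf("<fet_rl_model> recurrence-location logistic model (n = %d, %d bootstraps)\n",
              x$n, x$n_boot))
  cat("  predictors:", paste(x$predictors, collapse = ", "), "\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  AUC = %.3f (0.632+; apparent %.3f, oob %.3f)\n",
              x$auc, x$auc_apparent, x$auc_oob))
  cat(sprintf("  sensitivity at p >= %.2f: %.3f\n", x$threshold, x$sensitivity))
  invisible(x)
}

#' @export
coef.fet_rl_model <- function(object, ...) object$coefficients

#' @export
predict.fet_rl_model <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$predictors, drop = FALSE])
  lp <- object$coefficients[1] + as.vector(X %*% object$coefficients[-1])
  stats::plogis(lp)
}

# Rank-based AUC (probability that a positive outranks a negative; ties 0.5).
auc_rank <- function(score, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# 0.632+ combination of apparent and out-of-bag performance, on the
# "higher is better" scale with no-information value `gamma`. The
# no-information cap enters only the relative-overfitting ratio R; the final
# average uses the raw out-of-bag error, which keeps a null predictor's
# estimate centered on `gamma` instead of being pulled above it by the cap.
boot632plus <- function(perf_app, perf_oob, gamma = 0.5) {
  if (!is.finite(perf_oob)) return(perf_app)
  err_app <- 1 - perf_app; err_oob <- 1 - perf_oob; err_gamma <- 1 - gamma
  R <- if (err_gamma > err_app)
    (min(err_oob, err_gamma) - err_app) / (err_gamma - err_app) else 0
  R <- min(max(R, 0), 1)
  w <- 0.632 / (1 - 0.368 * R)
  1 - ((1 - w) * err_app + w * err_oob)
}

#' Recurrence-location label from masks
#'
#' Implements the definition used for the RL endpoint: the recurrence is
#' "inside" (label 1) when more than 50% of the recurrence volume lies within
#' the initial PET-positive volume.
#'
#' @param recurrence_mask logical mask of the recurrence volume.
#' @param initial_v_pet logical mask of the initial PET volume.
#' @return 1 (inside) or 0 (outside).
#' @export
rl_label_from_masks <- function(recurrence_mask, initial_v_pet) {
  check_same_grid(recurrence_mask, initial_v_pet)
  if (!any(recurrence_mask)) stop("empty recurrence mask")
  as.integer(sum(recurrence_mask & initial_v_pet) / sum(recurrence_mask) > 0.5)
}
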