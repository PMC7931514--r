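#' Run the full prognostic analysis on a feature table
#'
#' Executes the cohort-level stage chain: restriction to scanner-robust
#' features, per-feature Kaplan-Meier median-split log-rank tests for TTP and
#' OS with Bonferroni flagging (K = number of features actually tested),
#' redundancy-group representative selection among the `p < alpha`
#' candidates, multivariate Cox signatures for both endpoints, and the
#' recurrence-location bootstrap logistic model fitted on the TTP-signature
#' risk score and on the single best feature.
#'
#' @param features data.frame of per-subject feature values (columns are
#'   feature names; a `subject` column, if present, is carried through).
#' @param outcomes data.frame with columns `ttp_days`, `ttp_event`,
#'   `os_days`, `os_event`, `rl_label` (NA where undefined), and optionally
#'   `subject` (must match `features` if both are present).
#' @param robust_features optional character vector: only these columns are
#'   analysed (the scanner-robustness restriction).
#' @param cfg a [screening_config()].
#' @param n_boot bootstrap resamples for the RL model.
#' @param seed RNG seed for the RL bootstrap.
#' @return A `fetrad_run`: list with `km` (per-endpoint data.frames of
#'   chi-square/p/Bonferroni flags), `bonferroni_k`, `candidates`, `groups`,
#'   `signatures` (per endpoint, `fet_signature` or NULL), `rl` (models on
#'   the signature score and the best feature), and the configuration used.
#' @export
run_full_pipeline <- function(features, outcomes, robust_features = NULL,
                              cfg = screening_config(), n_boot = 1000,
                              seed = 1) {
  features <- as.data.frame(features)
  if ("subject" %in% names(outcomes) && "subject" %in% names(features)) {
    if (!identical(as.character(outcomes$subject),
                   as.character(features$subject)))
      stop("subject ids of features and outcomes do not match")
  }
  feat_cols <- setdiff(names(features),
                       c("subject", "contour"))
  X <- features[, feat_cols, drop = FALSE]
  X <- X[, vapply(X, is.numeric, logical(1)), drop = FALSE]
  if (!is.null(robust_features))
    X <- X[, intersect(names(X), robust_features), drop = FALSE]
  if (ncol(X) == 0) stop("no features to analyse")

  endpoints <- list(
    TTP = list(time = outcomes$ttp_days, event = outcomes$ttp_event),
    OS = list(time = outcomes$os_days, event = outcomes$os_event))

  km <- list(); candidates <- list(); groups <- list(); signatures <- list()
  K <- ncol(X)
  thr <- bonferroni_threshold(cfg$alpha, K)
  for (ep in names(endpoints)) {
    tt <- endpoints[[ep]]
    rows <- lapply(names(X), function(f) {
      res <- tryCatch(km_logrank(X[[f]], tt$time, tt$event),
                      error = function(e) NULL)
      if (is.null(res))
        data.frame(feature = f, chisq = NA_real_, p = NA_real_,
                   stringsAsFactors = FALSE)
      else data.frame(feature = f, chisq = res$chisq, p = res$p,
                      stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$significant_unadj <- !is.na(tab$p) & tab$p < cfg$alpha
    tab$significant_bonferroni <- !is.na(tab$p) & tab$p < thr
    km[[ep]] <- tab
    cand <- tab$feature[tab$significant_unadj]
    candidates[[ep]] <- cand
    if (length(cand)) {
      km_p <- stats::setNames(tab$p, tab$feature)[cand]
      gr <- redundancy_groups(X[, cand, drop = FALSE], km_p, cfg)
      groups[[ep]] <- gr
      signatures[[ep]] <- tryCatch(
        fit_cox_signature(X[, gr$representatives, drop = FALSE],
                          tt$time, tt$event, endpoint = ep),
        error = function(e) NULL)
    } else {
      groups[[ep]] <- list(representatives = character(0), groups = list())
      signatures[[ep]] <- NULL
    }
  }

  # RL stage: signature risk score and single best TTP feature as predictors
  rl <- list(signature = NULL, best_feature = NULL)
  rl_ok <- !is.na(outcomes$rl_label)
  if (sum(rl_ok) >= 10 && length(unique(outcomes$rl_label[rl_ok])) == 2) {
    if (!is.null(signatures$TTP)) {
      rl$signature <- tryCatch(
        fit_rl_model(data.frame(risk_score = signatures$TTP$risk_score),
                     outcomes$rl_label, n_boot = n_boot, seed = seed),
        error = function(e) NULL)
    }
    ttp_tab <- km$TTP
    best <- ttp_tab$feature[order(ttp_tab$p)][1]
    if (!is.na(best)) {
      rl$best_feature <- tryCatch(
        fit_rl_model(stats::setNames(data.frame(X[[best]]), best),
                     outcomes$rl_label, n_boot = n_boot, seed = seed + 1),
        error = function(e) NULL)
    }
  }

  structure(list(km = km, bonferroni_k = K, bonferroni_threshold = thr,
                 candidates = candidates, groups = groups,
                 signatures = signatures, rl = rl,
                 config = cfg, n_boot = n_boot, seed = seed),
            class = "fetrad_run")
}

#' @export
print.fetrad_run <- function(x, ...) {
  cat("<fetrad_run>\n")
  cat(sprintf("  %d features tested; Bonferroni threshold p < %.4g\n",
              x$bonferroni_k, x$bonferroni_threshold))
  for (ep in names(x$km)) {
    tab <- x$km[[ep]]
    cat(sprintf("  %s: %d candidates (p < %.2g), %d past Bonferroni\n",
                ep, sum(tab$significant_unadj, na.rm = TRUE),
                x$config$alpha, sum(tab$significant_bonferroni, na.rm = TRUE)))
    sig <- x$signatures[[ep]]
    if (!is.null(sig))
      cat(sprintf("    signature: %s (LR p = %.4g)\n",
                  paste(sig$features, collapse = " + "),
                  sig$overall_tests["likelihood_ratio"]))
  }
  if (!is.null(x$rl$signature))
    cat(sprintf("  RL (TTP signature): AUC = %.3f, sensitivity = %.3f\n",
                x$rl$signature$auc, x$rl$signature$sensitivity))
  if (!is.null(x$rl$best_feature))
    cat(sprintf("  RL (%s): AUC = %.3f, sensitivity = %.3f\n",
                x$rl$best_feature$predictors[1], x$rl$best_feature$auc,
                x$rl$best_feature$sensitivity))
  invisible(x)
}

#' Persist pipeline results as CSV/JSON tables
#'
#' Writes the univariate tables, signature coefficients and RL metrics of a
#' [run_full_pipeline()] result into a directory, deterministically (byte
#' identical for identical runs).
#'
#' @param run a `fetrad_run`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (ep in names(run$km)) {
    utils::write.csv(fmt_num_df(run$km[[ep]]),
                     file.path(out_dir, sprintf("km_%s.csv", tolower(ep))),
                     row.names = FALSE)
    sig <- run$signatures[[ep]]
    if (!is.null(sig)) {
      tab <- data.frame(feature = sig$features,
                        coef = sig$coefficients, hr = sig$hr,
                        hr_lo95 = sig$hr_ci[, 1], hr_hi95 = sig$hr_ci[, 2])
      utils::write.csv(fmt_num_df(tab),
                       file.path(out_dir, sprintf("signature_%s.csv", tolower(ep))),
                       row.names = FALSE)
    }
  }
  rl_sum <- list()
  for (nm in names(run$rl)) {
    m <- run$rl[[nm]]
    if (!is.null(m))
      rl_sum[[nm]] <- list(predictors = m$predictors, auc = round(m$auc, 6),
                           sensitivity = round(m$sensitivity, 6),
                           coefficients = round(m$coefficients, 6))
  }
  meta <- list(bonferroni_k = run$bonferroni_k,
               bonferroni_threshold = round(run$bonferroni_threshold, 8),
               candidates = run$candidates,
               representatives = lapply(run$groups, `[[`, "representatives"),
               rl = rl_sum, seed = run$seed, n_boot = run$n_boot)
  jsonlite::write_json(meta, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

# round numeric columns for stable, platform-independent CSV bytes
fmt_num_df <- function(df, digits = 10) {
  for (j in seq_along(df)) if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], digits)
  df
}
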