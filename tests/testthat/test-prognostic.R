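test_that("log-rank statistic matches hand risk-table enumeration", {
  # 8-subject fixture, all events observed
  time <- c(3, 5, 7, 9, 12, 15, 20, 30)
  event <- rep(TRUE, 8)
  feat <- c(1, 1, 2, 1, 2, 2, 1, 2)   # median split: (1,1,1,1) vs (2,2,2,2)
  res <- km_logrank(feat, time, event)
  oracle <- oracle_logrank(time, event, feat > median(feat))
  expect_equal(res$chisq, oracle$chisq, tolerance = 1e-12)
  expect_equal(res$p, oracle$p, tolerance = 1e-12)
  # fixtures with censoring, against the oracle
  set.seed(31)
  for (rep in 1:10) {
    n <- 10
    time <- round(rexp(n, 1 / 50)) + 1
    event <- runif(n) < 0.8
    feat <- rnorm(n)
    if (length(unique(feat > median(feat))) < 2) next
    res <- km_logrank(feat, time, event)
    oracle <- oracle_logrank(time, event, feat > median(feat))
    expect_equal(res$chisq, oracle$chisq, tolerance = 1e-12)
  }
})

test_that("log-rank on identical groups gives chi-square 0 and p 1", {
  time <- rep(c(5, 10, 15, 20), 2)
  event <- rep(TRUE, 8)
  feat <- rep(c(0, 1), each = 4)
  res <- km_logrank(feat, time, event)
  expect_equal(res$chisq, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
  expect_error(km_logrank(rep(1, 8), time, event), "degenerate")
  expect_error(km_logrank(1:4, time[1:4], event[1:4]), "at least 6")
})

test_that("Bonferroni threshold is alpha over K", {
  expect_equal(bonferroni_threshold(0.05, 50), 0.001)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  # the univariate family threshold prints as p < 0.0013 for K = 38
  expect_equal(round(bonferroni_threshold(0.05, 38), 4), 0.0013)
  expect_error(bonferroni_threshold(0.05, 0), "k must be")
})

test_that("redundancy groups collapse correlated features transitively", {
  set.seed(32)
  n <- 40
  A <- rnorm(n)
  B <- 2 * A
  C <- A + rnorm(n, 0, 0.15)        # strongly rank-correlated with A and B
  D <- rnorm(n)
  feats <- data.frame(A = A, B = B, C = C, D = D)
  km_p <- c(A = 0.04, B = 0.01, C = 0.20, D = 0.03)
  gr <- redundancy_groups(feats, km_p)
  expect_length(gr$groups, 2)
  expect_setequal(gr$representatives, c("B", "D"))   # B has the smallest p
  # mutually uncorrelated candidates are all retained
  feats2 <- data.frame(X = rnorm(n), Y = rnorm(n), Z = rnorm(n))
  gr2 <- redundancy_groups(feats2, c(X = 0.1, Y = 0.2, Z = 0.3))
  expect_setequal(gr2$representatives, c("X", "Y", "Z"))
  expect_length(redundancy_groups(feats2[0], c())$representatives, 0)
})

test_that("Cox signature recovers a two-group hazard ratio and is self-consistent", {
  set.seed(33)
  n <- 300
  grp <- rep(0:1, each = n / 2)
  beta <- 0.9
  time <- rexp(n, 0.01 * exp(beta * grp))
  event <- rep(TRUE, n)
  sig <- fit_cox_signature(data.frame(grp = grp), time, event, "TTP")
  se <- sqrt(diag(sig$fit$var))
  expect_lt(abs(coef(sig)[["grp"]] - beta), 2 * se[1])
  expect_true(all(sig$hr_ci[, 1] <= sig$hr_ci[, 2]))
  expect_equal(unname(sig$hr), unname(exp(coef(sig))))
  expect_true(all(sig$overall_tests >= 0 & sig$overall_tests <= 1))
  # refitting on the model's own risk score returns coefficient 1
  sig2 <- fit_cox_signature(data.frame(score = sig$risk_score), time, event)
  expect_lt(abs(coef(sig2)[["score"]] - 1), 1e-6)
  # predict() reproduces the linear predictor
  expect_equal(predict(sig, data.frame(grp = grp)), sig$risk_score)
})

test_that("Cox signature warns on sparse events and errors on separation", {
  set.seed(34)
  n <- 20
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  time <- rexp(n, 0.01)
  event <- c(rep(TRUE, 6), rep(FALSE, n - 6))
  expect_warning(fit_cox_signature(X, time, event), "events")
})

test_that("likelihood-ratio p is roughly uniform under the null", {
  set.seed(35)
  ps <- replicate(150, {
    n <- 40
    suppressWarnings(
      fit_cox_signature(data.frame(x = rnorm(n)), rexp(n, 0.01),
                        rep(TRUE, n))$overall_tests[["likelihood_ratio"]])
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_gt(min(ps), 0)
})

test_that("RL model handles separation, nulls and balance", {
  set.seed(36)
  n <- 32
  # perfectly separating predictor: AUC 1
  y <- rep(c(0, 1), each = n / 2)
  x <- y * 2 + c(rep(0, n / 2), rep(1, n / 2)) * 0 + seq(0, 0.1, length.out = n)
  m <- fit_rl_model(x + y * 5, y, n_boot = 60, seed = 1)
  expect_equal(m$auc, 1.0, tolerance = 1e-9)
  # label-independent predictor: AUC near 0.5 (averaged over refits)
  aucs <- vapply(1:8, function(s)
    fit_rl_model(rnorm(n), rbinom(n, 1, 0.4), n_boot = 60, seed = s)$auc,
    numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.12)
  # determinism under a fixed seed
  m1 <- fit_rl_model(x, y, n_boot = 40, seed = 7)
  m2 <- fit_rl_model(x, y, n_boot = 40, seed = 7)
  expect_identical(m1$coefficients, m2$coefficients)
  expect_error(fit_rl_model(x[1:8], y[1:8], n_boot = 10), "at least 10")
  expect_error(fit_rl_model(x, rep(1, n), n_boot = 10), "both classes")
})

test_that("internal rank AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(37)
  for (rep in 1:5) {
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- rnorm(40) + y
    got <- fetrad:::auc_rank(s, y)
    want <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                           direction = "<")))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("recurrence-location label follows the >50% overlap rule", {
  rec <- array(FALSE, c(6, 6, 1)); rec[1:2, 1:2, 1] <- TRUE   # 4 voxels
  vpet <- array(FALSE, c(6, 6, 1)); vpet[1:2, 1, 1] <- TRUE   # overlap 2
  expect_equal(rl_label_from_masks(rec, vpet), 0)   # exactly 50% is outside
  vpet[1:2, 2, 1] <- TRUE                           # overlap 4
  expect_equal(rl_label_from_masks(rec, vpet), 1)
  expect_error(rl_label_from_masks(array(FALSE, c(6, 6, 1)), vpet), "empty")
})

test_that("the full pipeline recovers a strong hazard-driving feature", {
  spec <- cohort_spec(n_subjects = 200,
                      feature_means = setNames(rep(0, 6), paste0("f", 1:6)),
                      feature_sds = setNames(rep(1, 6), paste0("f", 1:6)),
                      cox_coefficients_ttp = c(f3 = 1.5),
                      cox_coefficients_os = c(f3 = 0.5),
                      censor_rate = 0.2,
                      rl_logistic_coefficients = c("(Intercept)" = 0, f3 = 1),
                      seed = 41)
  tab <- gen_cohort(spec)
  run <- run_full_pipeline(tab[paste0("f", 1:6)], tab, n_boot = 80, seed = 5)
  ttp <- run$km$TTP
  expect_true(ttp$significant_bonferroni[ttp$feature == "f3"])
  expect_true("f3" %in% run$signatures$TTP$features)
  expect_equal(run$bonferroni_k, 6)
  # determinism
  run2 <- run_full_pipeline(tab[paste0("f", 1:6)], tab, n_boot = 80, seed = 5)
  expect_identical(run$rl$signature$coefficients,
                   run2$rl$signature$coefficients)
  expect_identical(run$km, run2$km)
  # mismatched subject ids are rejected
  feats_bad <- cbind(subject = rev(tab$subject), tab[paste0("f", 1:6)])
  expect_error(run_full_pipeline(feats_bad, tab), "subject ids")
})

test_that("an all-null cohort rarely passes Bonferroni", {
  set.seed(42)
  hits <- replicate(20, {
    spec <- cohort_spec(n_subjects = 32,
                        feature_means = setNames(rep(0, 5), paste0("g", 1:5)),
                        feature_sds = setNames(rep(1, 5), paste0("g", 1:5)),
                        cox_coefficients_ttp = c(g1 = 0),
                        censor_rate = 0.2, seed = sample.int(1e6, 1))
    tab <- gen_cohort(spec)
    run <- run_full_pipeline(tab[paste0("g", 1:5)], tab, n_boot = 20,
                             seed = 1)
    sum(run$km$TTP$significant_bonferroni)
  })
  expect_lte(mean(hits > 0), 0.2)
})
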