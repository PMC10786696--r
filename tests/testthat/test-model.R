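test_that("constrained fit recovers nonnegative truth and matches the MLE", {
  set.seed(71)
  n <- 2000
  X <- cbind(f1 = rnorm(n), f2 = rnorm(n))
  eta <- -0.5 + X %*% c(1, 2)
  y <- rbinom(n, 1, plogis(eta))
  fit <- fit_constrained_logistic(X, y)
  expect_true(all(fit$coefficients >= 0))
  expect_lt(max(abs(fit$coefficients - c(1, 2))), 0.15)
  # with nonnegative truth the constraint is inactive: agrees with glm()
  mle <- glm(y ~ X, family = binomial())
  expect_lt(max(abs(fit$coefficients - coef(mle)[-1])), 0.02)
  expect_lt(abs(fit$intercept - coef(mle)[1]), 0.02)
  expect_true(fit$converged)
})

test_that("a negatively associated feature is pinned at exactly zero", {
  set.seed(13)
  n <- 400
  X <- cbind(up = rnorm(n), down = rnorm(n))
  y <- rbinom(n, 1, plogis(1.5 * X[, "up"] - 2 * X[, "down"]))
  fit <- fit_constrained_logistic(X, y)
  expect_identical(unname(fit$coefficients["down"]), 0)
  expect_gt(fit$coefficients["up"], 0.5)
  # the unconstrained mode recovers the negative slope
  fit_u <- fit_constrained_logistic(X, y, nonneg = FALSE)
  expect_lt(fit_u$coefficients["down"], -1)
})

test_that("null labels give near-zero mean coefficients", {
  set.seed(5150)
  coefs <- t(replicate(100, {
    X <- cbind(a = rnorm(300), b = rnorm(300))
    y <- rbinom(300, 1, 0.5)
    fit_constrained_logistic(X, y)$coefficients
  }))
  expect_lt(max(abs(colMeans(coefs))), 0.05)
})

test_that("degenerate label inputs are rejected", {
  X <- matrix(rnorm(20), ncol = 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_constrained_logistic(X, rep(1, 10)), "single class")
  expect_error(fit_constrained_logistic(X, c(1, rep(0, 9))), "2 samples")
  Xna <- X; Xna[1] <- NA
  expect_error(fit_constrained_logistic(Xna, rep(c(0, 1), 5)), "missing")
})

test_that("separation is handled by the ridge and flagged", {
  X <- matrix(c(1:5, 11:15), ncol = 1, dimnames = list(NULL, "x"))
  y <- rep(c(0, 1), each = 5)
  fit <- fit_constrained_logistic(X, y)
  expect_true(fit$separation)
  expect_true(is.finite(fit$coefficients))
  expect_true(all(predict(fit, X)[y == 1] > 0.5))
})

test_that("closed-form Shapley equals exhaustive coalition enumeration", {
  set.seed(88)
  p <- 5
  X <- matrix(rnorm(60 * p), ncol = p,
              dimnames = list(NULL, paste0("f", 1:p)))
  y <- rbinom(60, 1, plogis(X %*% c(1, 0.5, 0, 0.2, 0)))
  fit <- fit_constrained_logistic(X, y)
  sh <- shapley_values(fit, X, X)
  for (i in c(1, 7, 42)) {
    exact <- shapley_exact(fit, X[i, , drop = FALSE], X)
    expect_equal(unname(sh$phi[i, ]), unname(exact), tolerance = 1e-9)
  }
  # efficiency: per-sample attributions sum to logodds minus background mean
  lo <- predict(fit, X, type = "link")
  expect_equal(unname(rowSums(sh$phi)), unname(lo - mean(lo)),
               tolerance = 1e-9)
  # zero-weight feature gets exactly zero attribution
  fit0 <- fit
  fit0$coefficients[] <- c(1, 0, 0, 0, 0)
  sh0 <- shapley_values(fit0, X[1, , drop = FALSE], X)
  expect_equal(unname(sh0$phi[1, -1]), rep(0, 4))
  expect_equal(unname(sh0$phi[1, 1]), unname(X[1, 1] - mean(X[, 1])))
})

test_that("feature ranking is by mean |phi| with flagged lexicographic ties", {
  rep1 <- list(mean_abs = c(B = 0.2, A = 0.5, C = 0))
  rk <- rank_features(rep1)
  expect_equal(rk$feature, c("A", "B", "C"))
  expect_false(any(rk$tied))
  rep2 <- list(mean_abs = c(zeta = 0.3, alpha = 0.3, mid = 0.4))
  rk2 <- rank_features(rep2)
  expect_equal(rk2$feature, c("mid", "alpha", "zeta"))
  expect_equal(rk2$tied, c(FALSE, TRUE, TRUE))
})

test_that("confusion metrics use the standard definitions", {
  y <- c(rep(1, 10), rep(0, 10))
  pred <- c(rep(1, 8), 0, 0, rep(0, 9), 1)  # TP=8 FN=2 TN=9 FP=1
  m <- confusion_metrics(y, pred)
  expect_equal(unname(m["sensitivity"]), 0.8)
  expect_equal(unname(m["specificity"]), 0.9)
  expect_equal(unname(m["ppv"]), 8 / 9)
  expect_equal(unname(m["npv"]), 9 / 11)
  expect_equal(unname(m["accuracy"]), 0.85)
  expect_equal(m[["precision"]], m[["ppv"]])
  expect_equal(unname(confusion_metrics(y, y)), rep(1, 7))
  m0 <- confusion_metrics(y, rep(0, 20))  # no positive predictions
  expect_true(is.na(m0["ppv"]))
  expect_equal(unname(m0["specificity"]), 1)
  expect_equal(unname(m0["npv"]), 0.5)
})

test_that("AUC equals the pair-counting oracle and honors tie/monotone rules", {
  r <- roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.3, 0.2))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(c(0, 1), c(0.1, 0.9))$auc, 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.4, 4))$auc, 0.5)
  set.seed(31)
  y <- rbinom(100, 1, 0.4)
  s <- round(rnorm(100, y), 1)  # rounding makes ties
  expect_equal(roc_auc(y, s)$auc, auc_pair_counting(y, s), tolerance = 1e-12)
  # invariance under strictly monotone transforms
  expect_equal(roc_auc(y, exp(s))$auc, roc_auc(y, s)$auc)
  expect_error(roc_auc(rep(1, 5), rnorm(5)), "both classes")
  # curve endpoints
  cv <- roc_auc(y, s)$curve
  expect_equal(c(cv$fpr[1], cv$tpr[1]), c(0, 0))
  expect_equal(c(cv$fpr[nrow(cv)], cv$tpr[nrow(cv)]), c(1, 1))
})

test_that("cross-validation partitions are valid, seeded and leakage-free", {
  tab <- generate_cohort(strong_cohort_spec(seed = 2))
  fm <- build_feature_matrix(tab)
  trio <- c("alt", "cfdna_total_ng_ml", "cf_monocyte")
  cv1 <- repeated_kfold(fm$X, fm$y, feature_set = trio, repeats = 3, seed = 77)
  cv2 <- repeated_kfold(fm$X, fm$y, feature_set = trio, repeats = 3, seed = 77)
  expect_identical(cv1$oof, cv2$oof)
  expect_identical(cv1$summary, cv2$summary)
  # every sample is tested exactly once per repeat
  expect_false(anyNA(cv1$oof))
  expect_equal(sum(cv1$folds$n_test[cv1$folds$repeat_i == 1]), length(fm$y))
  # leakage check: an independent per-fold recomputation that scales with
  # training-fold statistics only must reproduce the out-of-fold predictions
  cv_single <- repeated_kfold(fm$X, fm$y, feature_set = trio, repeats = 1,
                              seed = 123)
  folds <- cfgvhd:::with_seed(123, cfgvhd:::stratified_folds(fm$y, 5L))
  Xt <- fm$X[, trio]
  for (k in 1:5) {
    tr <- folds != k
    mu <- colMeans(Xt[tr, ])
    sdv <- apply(Xt[tr, ], 2, sd)
    fit_k <- fit_constrained_logistic(scale(Xt[tr, ], mu, sdv), fm$y[tr])
    pred_k <- predict(fit_k, scale(Xt[!tr, , drop = FALSE], mu, sdv))
    expect_equal(unname(cv_single$oof[!tr, 1]), unname(pred_k),
                 tolerance = 1e-10)
  }
})

test_that("cross-validated metrics are perfect on separable data and chance on permuted labels", {
  set.seed(10)
  n <- 60
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(sig = y * 10 + rnorm(n, sd = 0.1), noise = rnorm(n))
  cv <- repeated_kfold(X, y, K = 5, repeats = 2, seed = 1)
  expect_equal(cv$summary$mean, rep(1, 8))
  yp <- sample(y)
  cvp <- repeated_kfold(X, yp, K = 5, repeats = 20, seed = 2)
  expect_gt(mean_cv_auc(cvp), 0.3)
  expect_lt(mean_cv_auc(cvp), 0.7)
})

test_that("feature matrix construction keeps complete transplant cases only", {
  tab <- generate_cohort(cohort_spec(seed = 33))
  fm <- build_feature_matrix(tab)
  expect_equal(nrow(fm$X), complete_case_count(tab))
  expect_false(anyNA(fm$X))
  expect_setequal(colnames(fm$X), model_features())
  expect_true(all(fm$y %in% 0:1))
  expect_false(any(tab$sample_id[tab$group == "healthy"] %in% fm$sample_id))
})

test_that("the feature sweep evaluates nested sets and prefers fewer on flat signal", {
  set.seed(6)
  n <- 120
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(strong = y * 3 + rnorm(n), n1 = rnorm(n), n2 = rnorm(n),
             n3 = rnorm(n))
  sw <- feature_sweep(X, y, ranking = c("strong", "n1", "n2", "n3"),
                      K = 5, repeats = 5, seed = 42)
  expect_equal(sw$table$size, 1:4)
  expect_equal(nrow(sw$table), 4L)
  # a single informative feature: metrics essentially flat beyond size 1
  expect_lt(max(sw$table$mean_auc) - sw$table$mean_auc[1], 0.05)
  expect_equal(sw$best_features[1], "strong")
})

test_that("the full pipeline recovers strongly planted features", {
  tab <- generate_cohort(strong_cohort_spec(seed = 14))
  pipe <- cgvhd_pipeline(tab, repeats = 5, seed = 14)
  trio <- c("alt", "cfdna_total_ng_ml", "cf_monocyte")
  expect_setequal(pipe$ranking[1:3], trio)
  expect_gt(mean_cv_auc(pipe$best), 0.9)
  expect_true(all(pipe$fit$coefficients >= 0))
})
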