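#' Confusion-matrix metrics at a fixed threshold
#'
#' Standard definitions: sensitivity (= recall) = TP/(TP+FN); specificity =
#' TN/(TN+FP); PPV (= precision) = TP/(TP+FP); NPV = TN/(TN+FN); accuracy =
#' (TP+TN)/N. Ratios with a zero denominator are `NA` (undefined), never 0.
#'
#' @param y_true 0/1 true labels.
#' @param y_pred 0/1 predicted labels.
#' @return Named numeric vector: `accuracy`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `precision`, `recall`.
#' @export
confusion_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred),
            all(y_true %in% c(0, 1)), all(y_pred %in% c(0, 1)))
  tp <- sum(y_true == 1 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  ppv <- ratio(tp, tp + fp)
  npv <- ratio(tn, tn + fn)
  c(accuracy = (tp + tn) / length(y_true),
    sensitivity = sens, specificity = spec,
    ppv = ppv, npv = npv, precision = ppv, recall = sens)
}

#' ROC curve and AUC
#'
#' The AUC is the probability that a randomly chosen positive sample
#' outscores a randomly chosen negative one, with ties counted 1/2 —
#' computed from midranks, which is identical to trapezoidal integration of
#' the ROC curve. Invariant under strictly monotone transforms of the scores.
#'
#' @param y_true 0/1 labels; both classes must be present.
#' @param scores Numeric classifier scores (higher = more positive).
#' @return A `roc` list: `auc` and `curve` (data.frame `threshold`, `fpr`,
#'   `tpr` over all distinct score thresholds).
#' @export
roc_auc <- function(y_true, scores) {
  stopifnot(length(y_true) == length(scores), !anyNA(scores))
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)  # midranks handle ties
  auc <- (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y_true == 1) / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & y_true == 0) / n0, 0)
  structure(list(auc = auc,
                 curve = data.frame(threshold = c(Inf, thr),
                                    fpr = c(0, fpr), tpr = c(0, tpr))),
            class = "roc")
}

#' @export
print.roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d thresholds)\n", x$auc, nrow(x$curve)))
  invisible(x)
}

#' @export
plot.roc <- function(x, ...) {
  plot(x$curve$fpr, x$curve$tpr, type = "l",
       xlab = "1 - specificity", ylab = "sensitivity",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  graphics::legend("bottomright", sprintf("AUC = %.2f", x$auc), bty = "n")
}

# Stratified fold assignment: within each class, shuffle and deal round-robin.
stratified_folds <- function(y, K) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(K), length(idx))
  }
  fold
}

#' Repeated stratified k-fold cross-validation of the constrained classifier
#'
#' For each of `repeats` randomizations, samples are split into `K`
#' stratified folds; per fold, features are z-scored with training-fold
#' statistics only, the (non)constrained logistic model is fitted on the
#' training folds, and test-fold probabilities are scored. Threshold metrics
#' use probability 0.5 by default; AUC is threshold-free. Metrics are
#' aggregated as mean and SD across all folds x repeats. Deterministic for a
#' fixed `seed`. A degenerate randomization leaving a single class in some
#' training split is re-drawn and flagged.
#'
#' @param X Feature matrix (complete cases).
#' @param y 0/1 labels.
#' @param feature_set Columns of `X` to use (default: all).
#' @param K Number of folds (default 5).
#' @param repeats Number of repeats (default 20).
#' @param seed Integer seed.
#' @param nonneg Constrain slopes (default `TRUE`).
#' @param threshold Probability threshold for the confusion metrics.
#' @param lambda Ridge penalty passed to [fit_constrained_logistic()].
#' @return A `cv_report` list: `folds` (per repeat x fold metrics),
#'   `summary` (mean and SD per metric), `oof` (samples x repeats matrix of
#'   out-of-fold probabilities), `roc` (ROC of the repeat-averaged
#'   out-of-fold scores), `refolded` (count of re-drawn randomizations), and
#'   the settings.
#' @export
repeated_kfold <- function(X, y, feature_set = colnames(X), K = 5L,
                           repeats = 20L, seed = NULL, nonneg = TRUE,
                           threshold = 0.5, lambda = 1e-4) {
  X <- as.matrix(X)[, feature_set, drop = FALSE]
  y <- as.integer(y)
  n <- length(y)
  stopifnot(K >= 2L, n >= K)
  metric_names <- c("accuracy", "sensitivity", "specificity", "ppv", "npv",
                    "precision", "recall", "auc")
  rows <- list()
  oof <- matrix(NA_real_, n, repeats)
  refolded <- 0L
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      repeat {
        fold <- stratified_folds(y, K)
        ok <- all(vapply(seq_len(K), function(k)
          length(unique(y[fold != k])) == 2L, logical(1)))
        if (ok) break
        refolded <- refolded + 1L
      }
      for (k in seq_len(K)) {
        tr <- fold != k
        mu <- colMeans(X[tr, , drop = FALSE])
        sdv <- apply(X[tr, , drop = FALSE], 2L, sd)
        sdv[sdv == 0] <- 1
        scale_to <- function(M) sweep(sweep(M, 2L, mu), 2L, sdv, "/")
        fit <- fit_constrained_logistic(scale_to(X[tr, , drop = FALSE]),
                                        y[tr], nonneg = nonneg,
                                        lambda = lambda)
        prob <- predict(fit, scale_to(X[!tr, , drop = FALSE]))
        oof[!tr, r] <- prob
        cm <- confusion_metrics(y[!tr], as.integer(prob >= threshold))
        auc <- if (length(unique(y[!tr])) == 2L)
          roc_auc(y[!tr], prob)$auc else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          repeat_i = r, fold = k, n_test = sum(!tr),
          t(c(cm, auc = auc)))
      }
    }
  })
  folds <- do.call(rbind, rows)
  summary <- data.frame(
    metric = metric_names,
    mean = vapply(metric_names, function(m) mean(folds[[m]], na.rm = TRUE), 0),
    sd = vapply(metric_names, function(m) sd(folds[[m]], na.rm = TRUE), 0),
    row.names = NULL)
  structure(list(folds = folds, summary = summary, oof = oof,
                 roc = roc_auc(y, rowMeans(oof)),
                 y = y, feature_set = feature_set, K = K, repeats = repeats,
                 threshold = threshold, nonneg = nonneg,
                 refolded = refolded),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %d-fold x %d repeats, features: %s\n",
              x$K, x$repeats, paste(x$feature_set, collapse = ", ")))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Mean cross-validated AUC of a report
#'
#' @param report A `cv_report`.
#' @return Mean AUC across folds and repeats.
#' @export
mean_cv_auc <- function(report) {
  report$summary$mean[report$summary$metric == "auc"]
}

#' Nested feature-set sweep over a Shapley ranking
#'
#' Evaluates nested feature sets — the top-1, top-2, ... ranked features —
#' each by repeated stratified k-fold cross-validation, and selects the best
#' set as the one with the highest mean AUC, ties broken in favor of fewer
#' features. The same seed (hence identical fold assignments) is used for
#' every set size so that sizes are compared on the same splits.
#'
#' @param X Feature matrix.
#' @param y 0/1 labels.
#' @param ranking Character vector of features in importance order (e.g.
#'   `rank_features(...)$feature`).
#' @param sizes Set sizes to evaluate (default `1:min(7, length(ranking))`).
#' @param K,repeats,seed,nonneg,lambda Passed to [repeated_kfold()].
#' @return A `feature_sweep` list: `table` (per-size mean/SD of every
#'   metric), `reports` (the underlying `cv_report`s), `best_size`,
#'   `best_features`.
#' @export
feature_sweep <- function(X, y, ranking,
                          sizes = seq_len(min(7L, length(ranking))),
                          K = 5L, repeats = 20L, seed = NULL,
                          nonneg = TRUE, lambda = 1e-4) {
  stopifnot(all(ranking %in% colnames(X)), max(sizes) <= length(ranking))
  reports <- lapply(sizes, function(s)
    repeated_kfold(X, y, feature_set = ranking[seq_len(s)], K = K,
                   repeats = repeats, seed = seed, nonneg = nonneg,
                   lambda = lambda))
  tab <- do.call(rbind, lapply(seq_along(sizes), function(i) {
    s <- reports[[i]]$summary
    row <- data.frame(size = sizes[i],
                      features = paste(ranking[seq_len(sizes[i])],
                                       collapse = "+"))
    for (m in s$metric) {
      row[[paste0("mean_", m)]] <- s$mean[s$metric == m]
      row[[paste0("sd_", m)]] <- s$sd[s$metric == m]
    }
    row
  }))
  best_i <- which(tab$mean_auc == max(tab$mean_auc))[1L]  # ties: fewest features
  structure(list(table = tab, reports = reports,
                 best_size = tab$size[best_i],
                 best_features = ranking[seq_len(tab$size[best_i])]),
            class = "feature_sweep")
}

#' @export
print.feature_sweep <- function(x, ...) {
  cat("feature_sweep: best set size", x$best_size, "->",
      paste(x$best_features, collapse = ", "), "\n")
  print(x$table[, c("size", "features", "mean_auc", "sd_auc",
                    "mean_specificity", "mean_ppv")], digits = 3)
  invisible(x)
}

#' Full cGVHD classifier pipeline on a cohort table
#'
#' Convenience wrapper running the complete modeling stage: complete-case
#' feature matrix, full-data constrained fit on z-scored features, Shapley
#' attribution and ranking, and the nested feature-set sweep with repeated
#' stratified 5-fold cross-validation.
#'
#' @param table Cohort data.frame.
#' @param K,repeats Cross-validation settings (defaults 5 and 20).
#' @param sweep_sizes Feature-set sizes to evaluate (default 1..7).
#' @param seed Integer seed.
#' @param nonneg Constrain slopes (default `TRUE`).
#' @return A list: `data` (feature matrix), `fit`, `shapley`, `ranking`,
#'   `sweep`, `best` (the best set's `cv_report`).
#' @export
cgvhd_pipeline <- function(table, K = 5L, repeats = 20L,
                           sweep_sizes = 1:7, seed = NULL, nonneg = TRUE) {
  fm <- build_feature_matrix(table)
  Xs <- scale(fm$X)
  fit <- fit_constrained_logistic(Xs, fm$y, nonneg = nonneg)
  shap <- shapley_values(fit, Xs, Xs)
  ranking <- shap$ranking$feature
  sweep <- feature_sweep(fm$X, fm$y, ranking, sizes = sweep_sizes,
                         K = K, repeats = repeats, seed = seed,
                         nonneg = nonneg)
  list(data = fm, fit = fit, shapley = shap, ranking = ranking,
       sweep = sweep,
       best = sweep$reports[[which(sweep$table$size == sweep$best_size)]])
}
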