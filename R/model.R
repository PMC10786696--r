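#' Build the classifier feature matrix from a cohort table
#'
#' Restricts to transplanted samples, applies listwise deletion over the 17
#' model features (only complete cases are modeled), and encodes the label as
#' 1 for clinically evident cGVHD.
#'
#' @param table Cohort data.frame (from [generate_cohort()] or assembled from
#'   [quantify_sample()] output plus clinical data).
#' @param features Feature columns (default [model_features()]).
#' @return A list: `X` (numeric matrix, rows = complete-case samples), `y`
#'   (0/1 integer labels), `sample_id`.
#' @export
build_feature_matrix <- function(table, features = model_features()) {
  stopifnot(all(features %in% names(table)))
  sub <- table[table$group %in% c("hct_no_gvhd", "hct_cgvhd"), , drop = FALSE]
  keep <- complete.cases(sub[, features, drop = FALSE])
  sub <- sub[keep, , drop = FALSE]
  list(X = as.matrix(sub[, features, drop = FALSE]),
       y = as.integer(sub$group == "hct_cgvhd"),
       sample_id = sub$sample_id)
}

#' Nonnegativity-constrained logistic regression
#'
#' Maximum-likelihood logistic regression with all slope coefficients
#' box-constrained to be nonnegative (the intercept stays free), encoding the
#' prior that disease only elevates the markers. The objective is the
#' Bernoulli negative log-likelihood plus a weak L2 ridge (`lambda`, default
#' 1e-4) that guarantees a unique optimum even under complete separation;
#' optimization is L-BFGS-B with an analytic gradient, so the convex problem
#' is solved deterministically. Coefficients at the active bound are exactly
#' zero. Set `nonneg = FALSE` for the unconstrained comparison fit.
#'
#' @param X Numeric feature matrix (no intercept column).
#' @param y 0/1 labels, at least 2 samples per class.
#' @param nonneg Constrain slopes to be >= 0 (default `TRUE`).
#' @param lambda Ridge penalty on slopes (default 1e-4).
#' @param maxit Maximum L-BFGS-B iterations.
#' @return A `constrained_lr` list: `intercept`, `coefficients` (named, >= 0
#'   when `nonneg`), `converged`, `loglik` (unpenalized), `separation`
#'   (flagged when the training data are completely separated), `nonneg`,
#'   `lambda`.
#' @export
fit_constrained_logistic <- function(X, y, nonneg = TRUE, lambda = 1e-4,
                                     maxit = 1000L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) stop("labels contain a single class")
  if (min(table(y)) < 2L) stop("need at least 2 samples per class")
  if (anyNA(X)) stop("X contains missing values; model complete cases only")
  p <- ncol(X)
  nll <- function(theta) {
    eta <- theta[1L] + X %*% theta[-1L]
    # log(1 + exp(eta)) computed stably
    sum(ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))) - y * eta) +
      lambda * sum(theta[-1L]^2)
  }
  grad <- function(theta) {
    eta <- drop(theta[1L] + X %*% theta[-1L])
    r <- plogis(eta) - y
    c(sum(r), drop(crossprod(X, r)) + 2 * lambda * theta[-1L])
  }
  lower <- c(-Inf, rep(if (nonneg) 0 else -Inf, p))
  opt <- optim(rep(0, p + 1L), nll, grad, method = "L-BFGS-B",
               lower = lower, control = list(maxit = maxit))
  beta <- opt$par[-1L]
  if (nonneg) beta[beta < 1e-12] <- 0
  names(beta) <- colnames(X)
  eta <- drop(opt$par[1L] + X %*% beta)
  ll <- sum(y * eta - ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))))
  separation <- all((eta > 0) == (y == 1)) && max(abs(eta)) > 15
  structure(list(intercept = opt$par[1L], coefficients = beta,
                 converged = opt$convergence == 0L, loglik = ll,
                 separation = separation, nonneg = nonneg, lambda = lambda),
            class = "constrained_lr")
}

#' @export
print.constrained_lr <- function(x, ...) {
  cat(sprintf("%s logistic regression (ridge %g)%s\n",
              if (x$nonneg) "Nonnegativity-constrained" else "Unconstrained",
              x$lambda, if (x$separation) " [separation flagged]" else ""))
  cat(sprintf("  intercept: %.4g, loglik: %.4g\n", x$intercept, x$loglik))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict from a constrained logistic fit
#'
#' @param object A `constrained_lr` fit.
#' @param newdata Feature matrix with the same columns as the training data.
#' @param type `"response"` (probability) or `"link"` (log-odds).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.constrained_lr <- function(object, newdata, type = "response", ...) {
  eta <- drop(object$intercept +
                as.matrix(newdata)[, names(object$coefficients), drop = FALSE] %*%
                object$coefficients)
  if (type == "link") eta else plogis(eta)
}

#' Shapley attributions for a linear log-odds model
#'
#' Interventional Shapley values on the log-odds scale. For a logistic model
#' the log-odds are linear in the features, so with a feature-independence
#' background the Shapley value has the closed form
#' `phi[i, j] = beta[j] * (x[i, j] - mean(background[, j]))`; the exhaustive
#' coalition enumeration is available as [shapley_exact()] for verification.
#' Per sample, the attributions sum to that sample's log-odds minus the mean
#' background log-odds (efficiency).
#'
#' @param fit A `constrained_lr` fit.
#' @param X Feature matrix of samples to explain.
#' @param background Feature matrix serving as the reference distribution,
#'   conventionally the training set.
#' @return A `shapley_report` list: `phi` (samples x features matrix of
#'   attributions), `mean_abs` (named per-feature mean absolute attribution),
#'   `base_value` (mean background log-odds), `ranking` (from
#'   [rank_features()]).
#' @export
shapley_values <- function(fit, X, background) {
  stopifnot(inherits(fit, "constrained_lr"))
  background <- as.matrix(background)
  if (!nrow(background)) stop("empty background set")
  X <- as.matrix(X)
  feats <- names(fit$coefficients)
  bg_mean <- colMeans(background[, feats, drop = FALSE])
  phi <- sweep(X[, feats, drop = FALSE], 2L, bg_mean, "-")
  phi <- sweep(phi, 2L, fit$coefficients, "*")
  mean_abs <- colMeans(abs(phi))
  rep <- structure(list(phi = phi, mean_abs = mean_abs,
                        base_value = fit$intercept +
                          sum(fit$coefficients * bg_mean)),
                   class = "shapley_report")
  rep$ranking <- rank_features(rep)
  rep
}

#' Exhaustive-coalition Shapley values (verification oracle)
#'
#' Computes Shapley values for one sample by enumerating all 2^p coalitions
#' of features, with absent features set to the background mean in the
#' log-odds value function. Exponential in `p`; limited to `p <= 12`.
#' For a linear log-odds model this must agree with the closed form in
#' [shapley_values()] to numerical precision.
#'
#' @param fit A `constrained_lr` fit.
#' @param x A single sample (named numeric vector or 1-row matrix).
#' @param background Background feature matrix (means are used).
#' @return Named numeric vector of per-feature attributions.
#' @export
shapley_exact <- function(fit, x, background) {
  feats <- names(fit$coefficients)
  p <- length(feats)
  if (p > 12L) stop("exhaustive enumeration limited to 12 features")
  x <- as.numeric(as.matrix(x)[1L, feats])
  m <- colMeans(as.matrix(background)[, feats, drop = FALSE])
  beta <- fit$coefficients
  value <- function(members) {  # log-odds with absent features at background
    z <- m
    z[members] <- x[members]
    fit$intercept + sum(beta * z)
  }
  phi <- setNames(numeric(p), feats)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  fact <- factorial(0:p)
  for (j in seq_len(p)) {
    without_j <- subsets[!subsets[[j]], , drop = FALSE]
    for (r in seq_len(nrow(without_j))) {
      s <- as.logical(without_j[r, ])
      w <- fact[sum(s) + 1L] * fact[p - sum(s)] / fact[p + 1L]
      sj <- s
      sj[j] <- TRUE
      phi[j] <- phi[j] + w * (value(sj) - value(s))
    }
  }
  phi
}

#' Rank features by mean absolute Shapley attribution
#'
#' Descending mean |phi|; exact ties are broken lexicographically by feature
#' name and flagged.
#'
#' @param report A `shapley_report`.
#' @return Data.frame: `feature`, `mean_abs_shap`, `rank`, `tied`.
#' @export
rank_features <- function(report) {
  stopifnot(!is.null(report$mean_abs))
  v <- report$mean_abs
  ord <- order(-v, names(v))
  tied <- duplicated(v[ord]) | duplicated(v[ord], fromLast = TRUE)
  data.frame(feature = names(v)[ord], mean_abs_shap = unname(v[ord]),
             rank = seq_along(v), tied = tied,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.shapley_report <- function(x, ...) {
  cat("shapley_report (log-odds scale), base value", round(x$base_value, 4), "\n")
  print(x$ranking, digits = 4)
  invisible(x)
}
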