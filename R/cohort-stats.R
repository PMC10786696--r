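#' Two-sample Mann-Whitney comparison
#'
#' Nonparametric, unpaired comparison of one feature between two groups.
#' Missing values are dropped within each vector. The exact null distribution
#' is used when `n1 * n2 <= 400` and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#' Significance thresholds are applied downstream, not here.
#'
#' @param a,b Numeric vectors (the two groups).
#' @return A `group_comparison` list: `n1`, `n2`, `U` (Mann-Whitney U of the
#'   first sample, in `[0, n1*n2]`), `p` (two-tailed), `median_a`, `median_b`,
#'   `exact` (logical).
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("a group is empty after dropping NAs")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) * length(b) <= 400) && !ties
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  structure(list(n1 = length(a), n2 = length(b),
                 U = unname(wt$statistic), p = wt$p.value,
                 median_a = median(a), median_b = median(b),
                 exact = exact),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney (%s): U = %g, n = %d/%d, p = %.4g\n",
              if (x$exact) "exact" else "normal approx.",
              x$U, x$n1, x$n2, x$p))
  cat(sprintf("  medians: %.4g vs %.4g\n", x$median_a, x$median_b))
  invisible(x)
}

significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Spearman rank correlation matrix with significance stars
#'
#' Pairwise-complete Spearman correlations between the requested features,
#' with midranks for ties and star annotations (`*` p<0.05, `**` p<0.01,
#' `***` p<0.001). Pairs with fewer than 3 complete observations or with a
#' constant feature get `NA` and are flagged.
#'
#' @param table Data.frame holding the features.
#' @param features Character vector of column names (default:
#'   [model_features()] columns present in `table`).
#' @return A `correlation_matrix` list with matrices `rho`, `p`, `stars`,
#'   `n` (complete pairs) and a `flagged` logical matrix.
#' @export
spearman_matrix <- function(table, features = NULL) {
  if (is.null(features)) features <- intersect(model_features(), names(table))
  stopifnot(length(features) >= 2L, all(features %in% names(table)))
  x <- as.matrix(table[, features, drop = FALSE])
  p0 <- length(features)
  rho <- p <- n <- matrix(NA_real_, p0, p0, dimnames = list(features, features))
  flagged <- matrix(FALSE, p0, p0, dimnames = list(features, features))
  diag(rho) <- 1
  for (i in seq_len(p0)) for (j in seq_len(p0)) {
    if (j <= i) next
    ok <- complete.cases(x[, c(i, j)])
    n[i, j] <- n[j, i] <- sum(ok)
    if (sum(ok) < 3L || sd(x[ok, i]) == 0 || sd(x[ok, j]) == 0) {
      flagged[i, j] <- flagged[j, i] <- TRUE
      next
    }
    ct <- suppressWarnings(cor.test(x[ok, i], x[ok, j], method = "spearman"))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  structure(list(features = features, rho = rho, p = p,
                 stars = matrix(significance_stars(p), p0, p0,
                                dimnames = list(features, features)),
                 n = n, flagged = flagged),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("Spearman correlation matrix (", length(x$features), "features )\n")
  print(round(x$rho, 2))
  invisible(x)
}

#' Write a correlation matrix to CSV files
#'
#' @param x A `correlation_matrix`.
#' @param prefix Path prefix; writes `<prefix>_rho.csv`, `<prefix>_p.csv`,
#'   `<prefix>_stars.csv`.
#' @return The paths, invisibly.
#' @export
write_correlation_matrix <- function(x, prefix) {
  paths <- paste0(prefix, c("_rho.csv", "_p.csv", "_stars.csv"))
  write.csv(x$rho, paths[1L])
  write.csv(x$p, paths[2L])
  write.csv(x$stars, paths[3L])
  invisible(paths)
}

#' Group medians and all pairwise Mann-Whitney comparisons
#'
#' For each feature, reports per-group median and IQR and a Mann-Whitney
#' comparison for every pair of group levels (e.g. healthy vs transplanted
#' without cGVHD vs transplanted with cGVHD). No multiple-testing correction
#' is applied by default, matching the descriptive presentation this package
#' models; set `adjust = TRUE` for Benjamini-Hochberg adjusted p-values in an
#' extra column.
#'
#' @param table Cohort data.frame.
#' @param group_col Name of the grouping column.
#' @param features Feature columns to compare (default: [model_features()]
#'   columns present in `table`).
#' @param adjust Add Benjamini-Hochberg adjusted p-values (default `FALSE`).
#' @return A `group_summary` list: `summary` (group x feature medians/IQRs)
#'   and `comparisons` (one row per feature per group pair with `U`, `p`,
#'   medians and group sizes).
#' @export
group_summary <- function(table, group_col = "group", features = NULL,
                          adjust = FALSE) {
  if (!group_col %in% names(table))
    stop("unknown grouping column: ", group_col)
  if (is.null(features)) features <- intersect(model_features(), names(table))
  g <- as.character(table[[group_col]])
  levels <- unique(g[!is.na(g)])
  levels <- levels[vapply(levels, function(l) sum(g == l, na.rm = TRUE) > 0L,
                          logical(1))]
  if (length(levels) < 2L) stop("grouping needs at least 2 nonempty levels")
  summ <- do.call(rbind, lapply(levels, function(l) {
    do.call(rbind, lapply(features, function(f) {
      v <- table[[f]][g == l]
      data.frame(group = l, feature = f, n = sum(!is.na(v)),
                 median = median(v, na.rm = TRUE),
                 iqr = IQR(v, na.rm = TRUE), stringsAsFactors = FALSE)
    }))
  }))
  pairs <- utils::combn(levels, 2L, simplify = FALSE)
  comp <- do.call(rbind, lapply(features, function(f) {
    do.call(rbind, lapply(pairs, function(pr) {
      mw <- mann_whitney(table[[f]][g == pr[1L]], table[[f]][g == pr[2L]])
      data.frame(feature = f, group1 = pr[1L], group2 = pr[2L],
                 n1 = mw$n1, n2 = mw$n2, U = mw$U, p = mw$p,
                 median1 = mw$median_a, median2 = mw$median_b,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (adjust) comp$p_adj <- p.adjust(comp$p, method = "BH")
  structure(list(summary = summ, comparisons = comp, group_col = group_col),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("group_summary over '", x$group_col, "':\n", sep = "")
  print(head(x$comparisons, 20), digits = 3)
  if (nrow(x$comparisons) > 20) cat("  ...\n")
  invisible(x)
}

#' Dichotomize an organ score into absent (0) versus present (1-3)
#'
#' Helper mirroring the organ-level analysis: compares an organ's cfDNA
#' between samples with clinical score 0 and score 1-3.
#'
#' @param table Cohort data.frame with `score_<organ>` and `cf_<organ>`
#'   columns.
#' @param organ One of `"skin"`, `"gi"`, `"liver"`, `"lung"`.
#' @param groups Which groups to include (default: transplanted samples).
#' @return A `group_comparison` from [mann_whitney()].
#' @export
organ_score_comparison <- function(table, organ,
                                   groups = c("hct_no_gvhd", "hct_cgvhd")) {
  stopifnot(organ %in% names(ORGAN_FEATURES))
  sub <- table[table$group %in% groups, , drop = FALSE]
  score <- sub[[paste0("score_", organ)]]
  v <- sub[[ORGAN_FEATURES[[organ]]]]
  mann_whitney(v[score == 0L], v[score > 0L])
}
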