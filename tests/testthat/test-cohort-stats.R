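test_that("Mann-Whitney matches full permutation enumeration exactly", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / 3)
  expect_true(mw$exact)
  # random tie-free small samples against the enumeration oracle
  set.seed(404)
  for (i in 1:20) {
    n1 <- sample(2:4, 1)
    n2 <- sample(2:4, 1)
    v <- sample(seq_len(50), n1 + n2)  # distinct values, no ties
    a <- v[seq_len(n1)]
    b <- v[-seq_len(n1)]
    mw <- mann_whitney(a, b)
    or <- mw_enumeration(a, b)
    expect_equal(mw$U, or$U)
    expect_equal(mw$p, or$p)
  }
})

test_that("Mann-Whitney handles ties, identical samples and missing data", {
  x <- c(1, 2, 3, 4)
  mw <- mann_whitney(x, x)  # all ties -> approximate path
  expect_false(mw$exact)
  expect_equal(mw$p, 1)
  expect_equal(mw$U, length(x)^2 / 2)
  # NAs are dropped within each vector
  mw2 <- mann_whitney(c(1, 2, NA), c(3, 4))
  expect_equal(mw2$n1, 2L)
  expect_equal(mw2$p, 1 / 3)
  expect_error(mann_whitney(c(NA_real_, NA), c(1, 2)), "empty")
  # U stays within [0, n1*n2]
  expect_gte(mw$U, 0)
  expect_lte(mw$U, mw$n1 * mw$n2)
})

test_that("Mann-Whitney is calibrated under a large-sample null", {
  set.seed(2718)
  rej <- replicate(1000, mann_whitney(rnorm(50), rnorm(50))$p < 0.05)
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("Spearman matrix equals Pearson of midranks and known values", {
  d <- data.frame(x = 1:5, y = c(1, 3, 2, 5, 4), z = 2 * (1:5) + 1,
                  w = -(1:5))
  cm <- spearman_matrix(d, c("x", "y", "z", "w"))
  expect_equal(cm$rho["x", "y"], 0.8)    # 1 - 6*4/(5*24)
  expect_equal(cm$rho["x", "z"], 1)
  expect_equal(cm$rho["x", "w"], -1)
  # oracle identity on messy data with ties and missingness
  set.seed(11)
  m <- data.frame(a = round(rnorm(40), 1), b = round(rnorm(40), 1),
                  c = rpois(40, 3))
  m$b[c(3, 17)] <- NA
  cm2 <- spearman_matrix(m, c("a", "b", "c"))
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    ok <- complete.cases(m[, pair])
    oracle <- cor(rank(m[ok, pair[1]]), rank(m[ok, pair[2]]))
    expect_equal(cm2$rho[pair[1], pair[2]], oracle, tolerance = 1e-12)
  }
  # symmetry, unit diagonal, range
  expect_identical(cm2$rho, t(cm2$rho))
  expect_equal(unname(diag(cm2$rho)), rep(1, 3))
  expect_true(all(abs(cm2$rho) <= 1, na.rm = TRUE))
})

test_that("constant features and star annotation behave as documented", {
  d <- data.frame(a = 1:10, b = rep(5, 10), c = c(1:9, 20))
  cm <- spearman_matrix(d, c("a", "b", "c"))
  expect_true(is.na(cm$rho["a", "b"]))
  expect_true(cm$flagged["a", "b"])
  expect_false(is.na(cm$rho["a", "c"]))
  expect_identical(significance_stars(c(0.2, 0.04, 0.009, 5e-4, NA)),
                   c("", "*", "**", "***", ""))
})

test_that("group_summary reports medians and all pairwise comparisons", {
  tab <- generate_cohort(strong_cohort_spec(seed = 9))
  gs <- group_summary(tab, "group", features = c("alt", "cfdna_total_ng_ml"))
  expect_equal(nrow(gs$comparisons), 2 * choose(3, 2))
  expect_equal(nrow(gs$summary), 2 * 3)
  # planted effect: strong separation between the transplant groups
  p_tot <- gs$comparisons$p[gs$comparisons$feature == "cfdna_total_ng_ml" &
                              gs$comparisons$group1 == "hct_no_gvhd" &
                              gs$comparisons$group2 == "hct_cgvhd"]
  expect_lt(p_tot, 0.05)
  expect_error(group_summary(tab, "not_a_column"), "unknown grouping")
  gs_adj <- group_summary(tab, "group", features = c("alt"), adjust = TRUE)
  expect_true("p_adj" %in% names(gs_adj$comparisons))
})

test_that("group comparisons are calibrated under planted and null effects", {
  # calibrated default effect: total cfDNA separates the transplant groups
  hits <- vapply(1:60, function(s) {
    tab <- generate_cohort(cohort_spec(seed = s))
    mann_whitney(tab$cfdna_total_ng_ml[tab$group == "hct_cgvhd"],
                 tab$cfdna_total_ng_ml[tab$group == "hct_no_gvhd"])$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # under a fully null generator the p-values are uniform
  ps <- vapply(1:200, function(s) {
    tab <- generate_cohort(null_cohort_spec(seed = s))
    mann_whitney(tab$cfdna_total_ng_ml[tab$group == "hct_cgvhd"],
                 tab$cfdna_total_ng_ml[tab$group == "hct_no_gvhd"])$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("organ-score dichotomy compares score 0 against score 1-3", {
  tab <- generate_cohort(strong_cohort_spec(seed = 4, organ_coupling = 1,
                                            missing_rate = 0))
  cmp <- organ_score_comparison(tab, "liver")
  expect_s3_class(cmp, "group_comparison")
  expect_equal(cmp$n1 + cmp$n2, sum(tab$group != "healthy"))
  # strong coupling drives the organ's cfDNA up with its score
  expect_gt(cmp$median_b, cmp$median_a)
})
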