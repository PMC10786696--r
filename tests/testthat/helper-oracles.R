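# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Exact two-tailed Mann-Whitney by brute-force enumeration of all
# choose(n1+n2, n1) group assignments (no ties assumed).
mw_enumeration <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(pooled), n1)
  u_all <- apply(idx, 2L, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_lo, p_hi)))
}

# AUC by explicit positive-negative pair counting, ties worth 1/2.
auc_pair_counting <- function(y, scores) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# A small two-tissue panel built in code (3 liver + 2 skin loci).
tiny_panel <- function() {
  marker_panel(
    marker_id = c("L1", "L2", "L3", "S1", "S2"),
    chrom = rep("chr1", 5),
    start = c(100, 500, 900, 1300, 1700),
    end = c(180, 590, 1000, 1395, 1790),
    strand = c("+", "+", "-", "+", "-"),
    target_celltype = c("liver", "liver", "liver", "skin", "skin"),
    cpg_offsets = list(c(5L, 12L, 30L), c(8L, 22L, 40L, 60L),
                       c(10L, 25L), c(6L, 18L, 44L), c(9L, 27L, 50L)))
}

# A cohort spec with strong planted effects, for functional tests that need
# reliable signal rather than the calibrated default magnitudes.
strong_cohort_spec <- function(seed = 1L, ...) {
  eff <- setNames(numeric(length(model_features())), model_features())
  eff[c("alt", "cfdna_total_ng_ml", "cf_monocyte")] <- c(1.4, 1.5, 1.6)
  cohort_spec(effect_sizes = eff, seed = seed, ...)
}

# A completely null cohort spec (no group effects at all).
null_cohort_spec <- function(seed = 1L, ...) {
  cohort_spec(effect_sizes = setNames(numeric(17), model_features()),
              organ_coupling = 0, seed = seed, ...)
}
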