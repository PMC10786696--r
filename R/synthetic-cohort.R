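#' The 17 model features
#'
#' Feature names of the classifier matrix: five blood-biochemistry values,
#' total cfDNA (ng/mL), and eleven tissue/immune cfDNA concentrations (genome
#' equivalents per mL plasma).
#'
#' @return Character vector of length 17.
#' @export
model_features <- function() {
  c("ggtp", "alp", "alt", "ast", "tbil", "cfdna_total_ng_ml",
    "cf_skin", "cf_lung", "cf_gi", "cf_liver",
    "cf_neutrophil", "cf_monocyte", "cf_eosinophil",
    "cf_b_cell", "cf_t_cell", "cf_cd8_t", "cf_treg")
}

# Baseline medians for healthy samples, on the natural scale. Biochemistry in
# IU/L (TBil mg/dL), total cfDNA in ng/mL, tissue cfDNA in GE/mL. Plausible
# values for adult plasma; the generator is a stand-in, not patient data.
FEATURE_BASELINES <- c(
  ggtp = 25, alp = 80, alt = 22, ast = 24, tbil = 0.6,
  cfdna_total_ng_ml = 7,
  cf_skin = 15, cf_lung = 5, cf_gi = 8, cf_liver = 10,
  cf_neutrophil = 150, cf_monocyte = 30, cf_eosinophil = 10,
  cf_b_cell = 15, cf_t_cell = 40, cf_cd8_t = 15, cf_treg = 5)

# Log-scale elevation of tissue cfDNA in transplanted patients regardless of
# cGVHD status (heightened turnover after transplant).
HCT_SHIFTS <- c(cf_gi = 0.5, cf_liver = 0.5, cf_lung = 0.5,
                cf_t_cell = 0.5, cf_cd8_t = 0.5, cf_neutrophil = 0.5)

ORGAN_FEATURES <- c(skin = "cf_skin", gi = "cf_gi",
                    liver = "cf_liver", lung = "cf_lung")

#' Default cGVHD effect sizes for the synthetic cohort
#'
#' Log-scale shifts applied to the cGVHD group. The defaults plant signal on
#' exactly three features — ALT, total cfDNA and monocyte cfDNA — with a
#' common magnitude calibrated so that the three-feature classifier reaches a
#' cross-validated AUC of about 0.8 on the default cohort. These are
#' synthetic calibration values, not measurements.
#'
#' @return Named numeric vector over [model_features()].
#' @export
default_effect_sizes <- function() {
  eff <- setNames(numeric(length(model_features())), model_features())
  eff[c("alt", "cfdna_total_ng_ml", "cf_monocyte")] <- c(0.5, 0.55, 0.6)
  eff
}

#' @rdname default_effect_sizes
#' @export
default_latent_loadings <- function() {
  feats <- model_features()
  lam <- setNames(rep(0.3, length(feats)), feats)
  lam[c("ggtp", "alp", "alt", "ast", "tbil")] <- 0.15
  lam
}

#' Specify a synthetic transplant cohort
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: three groups (healthy controls, transplanted without cGVHD,
#' transplanted with cGVHD), log-normal features sharing a latent
#' "cell-death burden" factor that induces positive inter-feature
#' correlation, log-scale elevation of selected features in the cGVHD group,
#' NIH-style organ scores (0-3) coupled to the matching organ's cfDNA, and
#' completely-at-random incomplete-feature missingness.
#'
#' @param n_healthy,n_hct_no_gvhd,n_hct_cgvhd Group sizes. Defaults 25/36/65:
#'   the transplant split matches the cohort design this package models; the
#'   healthy-control count is a stand-in.
#' @param effect_sizes Named log-scale shifts for the cGVHD group
#'   ([default_effect_sizes()]). Negative values are permitted (with a
#'   warning) for null simulations.
#' @param latent_loading Loading of the shared latent factor on each
#'   feature's log scale; controls inter-feature correlation. Either a single
#'   number (applied to all features) or a named per-feature vector. The
#'   default loads the cfDNA features at 0.3 and the biochemistry features at
#'   0.15: cell-death burden moves all cfDNA measures together, while enzyme
#'   leakage tracks it more loosely.
#' @param sigma Idiosyncratic log-scale standard deviation per feature.
#' @param organ_coupling Extra log-scale shift of an organ's cfDNA per unit
#'   of that organ's clinical score.
#' @param missing_rate Probability a sample has at least one feature blanked.
#'   Default 8/101, so that a 101-sample transplant cohort has 93 complete
#'   cases in expectation.
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_healthy = 25L, n_hct_no_gvhd = 36L,
                        n_hct_cgvhd = 65L,
                        effect_sizes = default_effect_sizes(),
                        latent_loading = default_latent_loadings(),
                        sigma = 0.6,
                        organ_coupling = 0.1,
                        missing_rate = 8 / 101, seed = 1L) {
  stopifnot(n_healthy >= 0, n_hct_no_gvhd >= 0, n_hct_cgvhd >= 0)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  eff <- setNames(numeric(length(model_features())), model_features())
  if (length(effect_sizes)) {
    bad <- setdiff(names(effect_sizes), model_features())
    if (length(bad)) stop("unknown feature in effect_sizes: ",
                          paste(bad, collapse = ", "))
    eff[names(effect_sizes)] <- effect_sizes
  }
  if (any(eff < 0))
    warning("negative effect size for a feature documented as elevated: ",
            paste(names(eff)[eff < 0], collapse = ", "))
  lam <- setNames(numeric(length(model_features())), model_features())
  if (length(latent_loading) == 1L && is.null(names(latent_loading))) {
    lam[] <- latent_loading
  } else {
    bad <- setdiff(names(latent_loading), model_features())
    if (length(bad)) stop("unknown feature in latent_loading: ",
                          paste(bad, collapse = ", "))
    lam[names(latent_loading)] <- latent_loading
  }
  structure(list(n_healthy = as.integer(n_healthy),
                 n_hct_no_gvhd = as.integer(n_hct_no_gvhd),
                 n_hct_cgvhd = as.integer(n_hct_cgvhd),
                 effect_sizes = eff,
                 latent_loading = lam, sigma = sigma,
                 organ_coupling = organ_coupling,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic transplant cohort table
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame with one row per sample: `sample_id`, `group`
#'   (`healthy`, `hct_no_gvhd`, `hct_cgvhd`), organ scores `score_skin`,
#'   `score_gi`, `score_liver`, `score_lung` (0-3), `severity`
#'   (`none`/`mild`/`moderate`/`severe`, derived from the maximal organ
#'   score), `days_post_hct` (> 100 for transplanted samples, `NA` for
#'   healthy), and the 17 features of [model_features()]. Missing features
#'   are `NA`. The generating spec is attached as attribute `"spec"`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_healthy + spec$n_hct_no_gvhd + spec$n_hct_cgvhd
  group <- rep(c("healthy", "hct_no_gvhd", "hct_cgvhd"),
               c(spec$n_healthy, spec$n_hct_no_gvhd, spec$n_hct_cgvhd))
  feats <- model_features()
  tab <- with_seed(spec$seed, {
    scores <- matrix(0L, nrow = n, ncol = 4,
                     dimnames = list(NULL, paste0("score_", names(ORGAN_FEATURES))))
    is_cgvhd <- group == "hct_cgvhd"
    n_cg <- sum(is_cgvhd)
    if (n_cg) {
      sc <- matrix(sample(0:3, 4 * n_cg, replace = TRUE,
                          prob = c(0.45, 0.3, 0.15, 0.1)),
                   nrow = n_cg, ncol = 4)
      allzero <- rowSums(sc) == 0L
      if (any(allzero))  # clinically evident disease has at least one organ involved
        sc[cbind(which(allzero),
                 sample.int(4, sum(allzero), replace = TRUE))] <- 1L
      scores[is_cgvhd, ] <- sc
    }
    severity <- c("none", "mild", "moderate", "severe")[
      apply(scores, 1L, max) + 1L]
    is_hct <- group != "healthy"
    days <- rep(NA_integer_, n)
    days[is_hct] <- pmax(101L, as.integer(round(
      rlnorm(sum(is_hct), meanlog = log(783), sdlog = 0.9))))
    z <- rnorm(n)  # shared cell-death burden
    x <- matrix(NA_real_, nrow = n, ncol = length(feats),
                dimnames = list(NULL, feats))
    for (f in feats) {
      mu <- log(FEATURE_BASELINES[[f]]) +
        ifelse(is_hct, ifelse(is.na(HCT_SHIFTS[f]), 0, HCT_SHIFTS[f]), 0) +
        ifelse(is_cgvhd, spec$effect_sizes[[f]], 0)
      organ <- names(ORGAN_FEATURES)[ORGAN_FEATURES == f]
      if (length(organ))
        mu <- mu + spec$organ_coupling * scores[, paste0("score_", organ)]
      x[, f] <- exp(mu + spec$latent_loading[[f]] * z +
                      spec$sigma * rnorm(n))
    }
    out <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                      group = group, scores, severity = severity,
                      days_post_hct = days, x,
                      stringsAsFactors = FALSE)
    inject_missingness(out, spec$missing_rate,
                       seed = sample.int(.Machine$integer.max, 1L))
  })
  attr(tab, "spec") <- spec
  tab
}

#' Blank features completely at random
#'
#' Flags each sample independently with probability `rate`; every flagged
#' sample has at least one of the 17 model features set to `NA`. The input
#' table is not modified (value semantics).
#'
#' @param table A cohort data.frame containing the [model_features()] columns.
#' @param rate Per-sample missingness probability in [0, 1).
#' @param seed Integer seed (optional).
#' @return A copy of `table` with injected `NA`s.
#' @export
inject_missingness <- function(table, rate, seed = NULL) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  if (rate == 0) return(table)
  feats <- intersect(model_features(), names(table))
  with_seed(seed, {
    flagged <- which(runif(nrow(table)) < rate)
    for (i in flagged) {
      k <- sample.int(3L, 1L, prob = c(0.7, 0.2, 0.1))
      table[i, sample(feats, k)] <- NA_real_
    }
  })
  table
}

#' Count samples with all model features present
#'
#' @param table A cohort data.frame.
#' @param groups Groups to count over; defaults to the transplanted groups,
#'   the ones entering the classifier.
#' @return Integer count of complete cases.
#' @export
complete_case_count <- function(table,
                                groups = c("hct_no_gvhd", "hct_cgvhd")) {
  sub <- table[table$group %in% groups, model_features(), drop = FALSE]
  sum(complete.cases(sub))
}
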