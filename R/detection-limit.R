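# Probability that a single molecule is called fully unmethylated under the
# all-observed-CpGs rule, given its true source and per-CpG noise rates.
# Target-tissue molecules are truly unmethylated at all C CpGs and survive
# only if no CpG fails conversion; background molecules are methylated and
# are miscalled only if every CpG converts inappropriately.
unmeth_call_prob <- function(n_cpg, rate, from_target) {
  if (from_target) (1 - rate)^n_cpg else rate^n_cpg
}

# One simulated mixture: per-marker molecule counts are drawn at the count
# level under exactly the generative model of generate_reads() with the
# default (all-unmethylated) calling rule, then averaged over markers.
simulate_tissue_estimate <- function(n_cpg_per_marker, fraction,
                                     reads_per_marker, bf, ic) {
  ests <- vapply(n_cpg_per_marker, function(C) {
    n_target <- rbinom(1L, reads_per_marker, fraction)
    u <- rbinom(1L, n_target, (1 - bf)^C) +
      rbinom(1L, reads_per_marker - n_target, ic^C)
    u / reads_per_marker
  }, numeric(1))
  mean(ests)
}

#' Spike-in detection-limit simulation
#'
#' Emulates the spike-in experiment that established assay sensitivity:
#' target-tissue DNA is mixed into a leukocyte background at each fraction of
#' `grid`, quantified with the cell type's markers, and compared with matched
#' 0% controls. A replicate is "detected" when its estimated tissue fraction
#' exceeds the control distribution in a one-sided Monte-Carlo test at level
#' `alpha`; because the control statistic is discrete (often degenerate at 0
#' for multi-CpG markers), ties are broken uniformly at random, which makes
#' the test exactly level-`alpha` under the null. The detection limit is the
#' smallest grid fraction detected in at least `min_rate` of replicates.
#'
#' @param panel A `marker_panel`.
#' @param celltype Target cell type to spike in.
#' @param grid Ascending spike fractions as proportions (e.g. `0.005` = 0.5%).
#' @param reads_per_marker Sequencing depth per locus (default 10000).
#' @param replicates Replicates per grid fraction (>= 20; default 50).
#' @param alpha One-sided test level (default 0.05).
#' @param bisulfite_failure_rate,inappropriate_conversion_rate Per-CpG noise
#'   rates, as in [mixture_spec()].
#' @param min_rate Required detection rate at the limit (default 0.95).
#' @param null_replicates Extra null mixtures used to estimate the
#'   false-detection rate of the test (default 200).
#' @param seed Integer seed.
#' @return A `detection_limit` list: `lod` (smallest robustly detected
#'   fraction, `NA` if none on the grid), `rate_table` (per-fraction detection
#'   rates and mean estimates), `null_rate` (0%-control false-detection rate),
#'   `slope` (linearity: regression slope of estimated on true fraction),
#'   `alpha`, and the simulation parameters.
#' @export
detection_limit <- function(panel, celltype, grid,
                            reads_per_marker = 10000L, replicates = 50L,
                            alpha = 0.05,
                            bisulfite_failure_rate = 0.005,
                            inappropriate_conversion_rate = 0.005,
                            min_rate = 0.95, null_replicates = 200L,
                            seed = NULL) {
  panel <- validate_panel(panel)
  if (length(grid) == 0L) stop("empty fraction grid")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be sorted ascending")
  if (any(grid < 0) || any(grid > 1)) stop("grid fractions must lie in [0, 1]")
  if (replicates < 20L) stop("at least 20 replicates are required")
  loci <- panel[panel$target_celltype == celltype, , drop = FALSE]
  if (!nrow(loci)) stop("panel has no markers for celltype ", celltype)
  n_cpg <- lengths(loci$cpg_offsets)
  bf <- bisulfite_failure_rate
  ic <- inappropriate_conversion_rate
  with_seed(seed, {
    controls <- replicate(replicates, simulate_tissue_estimate(
      n_cpg, 0, reads_per_marker, bf, ic))
    detect <- function(est) {
      # randomized Monte-Carlo exceedance p-value, exact under discreteness
      b <- sum(controls > est)
      e <- sum(controls == est)
      p <- (b + runif(1L) * (1 + e)) / (length(controls) + 1L)
      p <= alpha
    }
    rate_table <- data.frame(fraction = grid, rate = NA_real_,
                             mean_estimate = NA_real_)
    est_all <- list()
    for (g in seq_along(grid)) {
      ests <- replicate(replicates, simulate_tissue_estimate(
        n_cpg, grid[g], reads_per_marker, bf, ic))
      rate_table$rate[g] <- mean(vapply(ests, detect, logical(1)))
      rate_table$mean_estimate[g] <- mean(ests)
      est_all[[g]] <- ests
    }
    null_ests <- replicate(null_replicates, simulate_tissue_estimate(
      n_cpg, 0, reads_per_marker, bf, ic))
    null_rate <- mean(vapply(null_ests, detect, logical(1)))
  })
  hit <- which(rate_table$rate >= min_rate)
  lod <- if (length(hit)) grid[min(hit)] else NA_real_
  fit <- lm(est ~ frac, data = data.frame(
    est = unlist(est_all), frac = rep(grid, each = replicates)))
  structure(list(lod = lod, rate_table = rate_table, null_rate = null_rate,
                 slope = unname(coef(fit)[2L]), alpha = alpha,
                 celltype = celltype, n_markers = nrow(loci),
                 reads_per_marker = reads_per_marker,
                 replicates = replicates, min_rate = min_rate,
                 bisulfite_failure_rate = bf,
                 inappropriate_conversion_rate = ic),
            class = "detection_limit")
}

#' @export
print.detection_limit <- function(x, ...) {
  cat("detection_limit:", x$celltype, "(", x$n_markers, "markers,",
      x$reads_per_marker, "reads/marker )\n")
  cat(sprintf("  LOD (rate >= %.2f): %s\n", x$min_rate,
              if (is.na(x$lod)) "not reached on grid"
              else sprintf("%.3g%%", 100 * x$lod)))
  cat(sprintf("  null false-detection rate: %.3f (alpha %.2f)\n",
              x$null_rate, x$alpha))
  cat(sprintf("  linearity slope: %.3f\n", x$slope))
  print(x$rate_table, digits = 3)
  invisible(x)
}
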