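#' Quantification configuration
#'
#' QC and calling thresholds for per-molecule methylation patterns.
#'
#' @param max_noncpg_retention Maximum tolerated fraction of non-CpG reference
#'   cytosines read as C before a molecule is flagged as a failed bisulfite
#'   conversion (default 0.1).
#' @param max_missing Maximum tolerated fraction of missing CpG calls per
#'   molecule (default 0.2).
#' @param prefix_len Number of leading bases used for reference-prefix read
#'   assignment when read names carry no marker tag (default 15).
#' @return A `quant_config` list.
#' @export
quant_config <- function(max_noncpg_retention = 0.1, max_missing = 0.2,
                         prefix_len = 15L) {
  stopifnot(max_noncpg_retention >= 0, max_noncpg_retention <= 1,
            max_missing >= 0, max_missing <= 1)
  structure(list(max_noncpg_retention = max_noncpg_retention,
                 max_missing = max_missing,
                 prefix_len = as.integer(prefix_len)),
            class = "quant_config")
}

# 1 ng of DNA corresponds to 1000 / mass_pg haploid genome equivalents.
GE_MASS_PG_DEFAULT <- 3.3

#' Call per-molecule methylation patterns at one locus
#'
#' For each read assigned to the locus, reads out the base at every CpG-C
#' position of the reference: T means the cytosine was unmethylated (and so
#' converted), C means methylated (protected), anything else is a missing
#' call. Bisulfite-conversion QC checks the non-CpG reference cytosines,
#' which are always unmethylated and must essentially all read T; molecules
#' retaining more than `max_noncpg_retention` of them as C are flagged as
#' failed conversions. Reads failing QC are flagged (`qc_pass = FALSE`),
#' never silently dropped.
#'
#' @param reads Named character vector of read sequences assigned to this
#'   locus (empty is allowed and yields an empty result).
#' @param locus One-row subset of a `marker_panel`.
#' @param reference Reference amplicon sequence for the locus (pre-bisulfite,
#'   plus strand), e.g. from [panel_references()].
#' @param config A [quant_config()].
#' @return A data.frame with one row per read: `molecule_id`, `marker_id`,
#'   `calls` (string over `U`/`M`/`.`), `n_cpg`, `n_unmethylated`,
#'   `n_missing`, `noncpg_retention`, `conversion_ok`, `short_read`,
#'   `qc_pass`.
#' @export
call_molecule_patterns <- function(reads, locus, reference,
                                   config = quant_config()) {
  stopifnot(is.character(reference), length(reference) == 1L)
  marker_id <- locus$marker_id[1L]
  cpg_pos <- locus$cpg_offsets[[1L]] + 1L
  n_cpg <- length(cpg_pos)
  if (length(reads) == 0L)
    return(data.frame(molecule_id = character(), marker_id = character(),
                      calls = character(), n_cpg = integer(),
                      n_unmethylated = integer(), n_missing = integer(),
                      noncpg_retention = numeric(), conversion_ok = logical(),
                      short_read = logical(), qc_pass = logical(),
                      stringsAsFactors = FALSE))
  span <- nchar(reference)
  ref_chars <- strsplit(reference, "", fixed = TRUE)[[1L]]
  noncpg_c <- setdiff(which(ref_chars == "C"), cpg_pos)
  short <- nchar(reads) < span
  n <- length(reads)
  call_mat <- matrix(".", nrow = n, ncol = n_cpg)
  for (j in seq_len(n_cpg)) {
    b <- substring(reads, cpg_pos[j], cpg_pos[j])
    call_mat[, j] <- ifelse(b == "T", "U", ifelse(b == "C", "M", "."))
  }
  call_mat[short, ] <- "."
  retention <- rep(0, n)
  if (length(noncpg_c)) {
    kept <- matrix(FALSE, nrow = n, ncol = length(noncpg_c))
    for (j in seq_along(noncpg_c))
      kept[, j] <- substring(reads, noncpg_c[j], noncpg_c[j]) == "C"
    retention <- rowMeans(kept)
  }
  retention[short] <- NA_real_
  conversion_ok <- !short & retention <= config$max_noncpg_retention
  conversion_ok[short] <- FALSE
  n_unmeth <- rowSums(call_mat == "U")
  n_miss <- rowSums(call_mat == ".")
  qc_pass <- conversion_ok & (n_miss / n_cpg) <= config$max_missing
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_len(n))
  data.frame(molecule_id = ids, marker_id = marker_id,
             calls = apply(call_mat, 1L, paste, collapse = ""),
             n_cpg = n_cpg, n_unmethylated = as.integer(n_unmeth),
             n_missing = as.integer(n_miss),
             noncpg_retention = retention, conversion_ok = conversion_ok,
             short_read = short, qc_pass = qc_pass,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign reads to panel loci
#'
#' Reads whose name starts with `"<marker_id>|"` are assigned by that tag
#' (the synthetic generator's convention); otherwise a read is assigned to
#' the locus whose reference it matches exactly over the first
#' `config$prefix_len` bases of the bisulfite-converted reference. Because the
#' converted prefix differs between fully methylated and fully converted
#' molecules, both variants are matched. Unassignable reads are dropped with
#' a message.
#'
#' @param reads Named character vector of read sequences.
#' @param panel A `marker_panel`.
#' @param references Named references from [panel_references()].
#' @param config A [quant_config()].
#' @return Named list of read vectors, one element per marker id.
#' @export
assign_reads <- function(reads, panel, references, config = quant_config()) {
  ids <- names(reads)
  out <- setNames(vector("list", nrow(panel)), panel$marker_id)
  tag <- if (!is.null(ids)) sub("\\|.*$", "", ids) else rep("", length(reads))
  tagged <- tag %in% panel$marker_id
  for (m in panel$marker_id)
    out[[m]] <- reads[tagged & tag == m]
  rest <- reads[!tagged]
  if (length(rest)) {
    L <- config$prefix_len
    prefix_map <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(panel))) {
      m <- panel$marker_id[i]
      ref <- substr(references[[m]], 1L, L)
      # converted prefixes: all Cs read T except protected (methylated) CpGs
      cpg_in <- panel$cpg_offsets[[i]] + 1L
      conv_all <- chartr("C", "T", ref)           # fully converted
      meth <- strsplit(ref, "", fixed = TRUE)[[1L]]
      noncg <- setdiff(which(meth == "C"), cpg_in)
      meth[noncg] <- "T"                          # only non-CpG Cs convert
      conv_meth <- paste(meth, collapse = "")
      assign(conv_all, m, envir = prefix_map)
      assign(conv_meth, m, envir = prefix_map)
    }
    pre <- substr(rest, 1L, L)
    hit <- vapply(pre, function(p)
      if (exists(p, envir = prefix_map, inherits = FALSE))
        get(p, envir = prefix_map) else NA_character_, character(1))
    unas <- sum(is.na(hit))
    if (unas) message(unas, " reads could not be assigned to any locus")
    for (m in unique(hit[!is.na(hit)]))
      out[[m]] <- c(out[[m]], rest[!is.na(hit) & hit == m])
  }
  out
}

#' Unmethylated-molecule count and fraction for one marker
#'
#' Counts QC-passing molecules that satisfy the unmethylated-molecule rule:
#' at least `k` unmethylated calls out of the observed (non-missing) CpGs.
#' The default (`k = NULL`) requires *all* observed CpGs unmethylated — the
#' maximally specific rule, since molecules carrying multiple unmethylated
#' CpGs identify the target tissue nearly unambiguously.
#'
#' @param patterns Pattern data.frame from [call_molecule_patterns()].
#' @param k Minimum number of unmethylated CpGs required, or `NULL` for
#'   "all observed".
#' @return One-row data.frame: `marker_id`, `n_total` (QC-passing molecules),
#'   `n_unmethylated`, `fraction`. With zero QC-passing molecules the
#'   fraction is `NA` (undefined, never 0: zero would be a biological claim).
#' @export
unmethylated_fraction <- function(patterns, k = NULL) {
  marker_id <- if (nrow(patterns)) patterns$marker_id[1L] else NA_character_
  ok <- patterns[patterns$qc_pass, , drop = FALSE]
  n_total <- nrow(ok)
  if (n_total == 0L)
    return(data.frame(marker_id = marker_id, n_total = 0L,
                      n_unmethylated = 0L, fraction = NA_real_,
                      stringsAsFactors = FALSE))
  observed <- ok$n_cpg - ok$n_missing
  thresh <- if (is.null(k)) observed else pmin(k, observed)
  hit <- observed > 0L & ok$n_unmethylated >= thresh
  data.frame(marker_id = marker_id, n_total = n_total,
             n_unmethylated = as.integer(sum(hit)),
             fraction = sum(hit) / n_total, stringsAsFactors = FALSE)
}

#' Per-marker unmethylated fractions for a whole read set
#'
#' @param reads Named character vector of reads (or an `amplicon_reads`
#'   object, whose reads and references are then used directly).
#' @param panel A `marker_panel`.
#' @param references Named reference sequences; defaults to
#'   [panel_references()] for synthetic panels.
#' @param k Unmethylated-molecule rule, see [unmethylated_fraction()].
#' @param config A [quant_config()].
#' @return Data.frame with one row per marker: `marker_id`,
#'   `target_celltype`, `n_total`, `n_unmethylated`, `fraction`.
#' @export
marker_fractions <- function(reads, panel, references = NULL, k = NULL,
                             config = quant_config()) {
  if (inherits(reads, "amplicon_reads")) {
    references <- reads$references
    reads <- reads$reads
  }
  panel <- validate_panel(panel)
  if (is.null(references)) references <- panel_references(panel)
  by_locus <- assign_reads(reads, panel, references, config)
  res <- lapply(seq_len(nrow(panel)), function(i) {
    m <- panel$marker_id[i]
    pats <- call_molecule_patterns(by_locus[[m]], panel[i, , drop = FALSE],
                                   references[[m]], config)
    cnt <- unmethylated_fraction(pats, k = k)
    cnt$marker_id <- m
    cnt$target_celltype <- panel$target_celltype[i]
    cnt
  })
  out <- do.call(rbind, res)
  out[, c("marker_id", "target_celltype", "n_total", "n_unmethylated",
          "fraction")]
}

#' Average marker fractions into per-cell-type fractions
#'
#' The tissue fraction is the unweighted arithmetic mean of that cell type's
#' marker fractions, over markers with a non-missing fraction. If every
#' marker of a cell type is missing, the tissue fraction is missing.
#'
#' @param marker_counts Data.frame from [marker_fractions()] (needs columns
#'   `target_celltype` and `fraction`).
#' @param panel A `marker_panel` (defines the cell types reported).
#' @return Data.frame: `celltype`, `n_markers_used`, `fraction`.
#' @export
tissue_fraction <- function(marker_counts, panel) {
  cts <- unique(panel$target_celltype)
  res <- lapply(cts, function(ct) {
    fr <- marker_counts$fraction[marker_counts$target_celltype == ct]
    used <- sum(!is.na(fr))
    data.frame(celltype = ct, n_markers_used = used,
               fraction = if (used) mean(fr, na.rm = TRUE) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Absolute tissue cfDNA concentration in genome equivalents per mL
#'
#' Multiplies the tissue's proportion of cfDNA by the total cfDNA
#' concentration and converts mass to genome equivalents, using a haploid
#' genome mass of `ge_mass_pg` picograms (default 3.3 pg, i.e. about 303
#' genome equivalents per nanogram).
#'
#' @param fraction Tissue fraction(s) in [0, 1]; `NA` propagates.
#' @param total_cfdna_ng_per_ml Total cfDNA concentration, ng/mL.
#' @param ge_mass_pg Picograms of DNA per haploid genome equivalent.
#' @return Concentration(s) in genome equivalents per mL plasma.
#' @export
absolute_concentration <- function(fraction, total_cfdna_ng_per_ml,
                                   ge_mass_pg = GE_MASS_PG_DEFAULT) {
  if (any(stats::na.omit(fraction) < 0) || any(stats::na.omit(fraction) > 1))
    stop("fraction must lie in [0, 1]")
  if (any(stats::na.omit(total_cfdna_ng_per_ml) < 0))
    stop("total_cfdna_ng_per_ml must be nonnegative")
  if (ge_mass_pg <= 0) stop("ge_mass_pg must be positive")
  fraction * total_cfdna_ng_per_ml * 1000 / ge_mass_pg
}

#' Quantify one plasma sample: reads to tissue profile
#'
#' Runs the full per-sample quantification: read assignment, per-molecule
#' pattern calling, per-marker unmethylated fractions, per-cell-type
#' averaging, and conversion to absolute concentrations.
#'
#' @param reads Named character read vector, an `amplicon_reads` object, or a
#'   FASTQ path.
#' @param panel A `marker_panel`.
#' @param total_cfdna_ng_per_ml Measured total cfDNA of the sample, ng/mL.
#' @param references Optional named reference sequences.
#' @param k Unmethylated-molecule rule ([unmethylated_fraction()]).
#' @param ge_mass_pg Genome-equivalent mass constant, pg.
#' @param config A [quant_config()].
#' @return A `tissue_profile` data.frame: `celltype`, `n_markers_used`,
#'   `fraction`, `ge_per_ml`, with the constants used attached as attributes
#'   `ge_mass_pg` and `rule`.
#' @export
quantify_sample <- function(reads, panel, total_cfdna_ng_per_ml,
                            references = NULL, k = NULL,
                            ge_mass_pg = GE_MASS_PG_DEFAULT,
                            config = quant_config()) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastq_reads(reads)
  mc <- marker_fractions(reads, panel, references, k = k, config = config)
  tf <- tissue_fraction(mc, panel)
  tf$ge_per_ml <- absolute_concentration(tf$fraction, total_cfdna_ng_per_ml,
                                         ge_mass_pg)
  attr(tf, "ge_mass_pg") <- ge_mass_pg
  attr(tf, "rule") <- if (is.null(k)) "all" else k
  attr(tf, "total_cfdna_ng_per_ml") <- total_cfdna_ng_per_ml
  class(tf) <- c("tissue_profile", "data.frame")
  tf
}

#' Read or write a molecule-pattern table
#'
#' TSV exchange format for pre-called patterns: columns `marker_id`,
#' `molecule_id`, `calls` (string over `U`/`M`/`.`), `conversion_ok`.
#' Derived QC fields are recomputed on read.
#'
#' @param path File path.
#' @param config A [quant_config()] (for the missing-call cap on read).
#' @return For `read_patterns`, a pattern data.frame compatible with
#'   [unmethylated_fraction()].
#' @export
read_patterns <- function(path, config = quant_config()) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker_id", "molecule_id", "calls", "conversion_ok")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("pattern table missing columns: ",
                         paste(miss, collapse = ", "))
  tab$n_cpg <- nchar(tab$calls)
  tab$n_unmethylated <- nchar(gsub("[^U]", "", tab$calls))
  tab$n_missing <- nchar(gsub("[^.]", "", tab$calls, fixed = FALSE))
  tab$conversion_ok <- as.logical(tab$conversion_ok)
  tab$qc_pass <- tab$conversion_ok &
    tab$n_missing / pmax(tab$n_cpg, 1L) <= config$max_missing
  tab
}

#' @param patterns Pattern data.frame.
#' @rdname read_patterns
#' @export
write_patterns <- function(patterns, path) {
  write.table(patterns[, c("marker_id", "molecule_id", "calls",
                           "conversion_ok")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.tissue_profile <- function(x, ...) {
  cat("tissue_profile (rule:", attr(x, "rule"),
      "; GE mass:", attr(x, "ge_mass_pg"), "pg)\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}
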