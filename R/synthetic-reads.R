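#' Specify a synthetic cfDNA tissue mixture
#'
#' Describes a plasma-like mixture of DNA from known cell types used to
#' generate synthetic bisulfite amplicon reads. Molecules are all-or-none
#' methylated by source: a molecule drawn from cell type `c` is fully
#' unmethylated at loci targeting `c` and fully methylated at every other
#' locus; partial methylation arises only through the two per-CpG noise rates.
#'
#' @param fractions Named numeric vector of cfDNA proportions per cell type
#'   (names from [panel_celltypes()] plus the background `"leukocyte_other"`).
#'   Must sum to 1 within 1e-9.
#' @param total_cfdna_ng_per_ml Total cfDNA concentration of the simulated
#'   sample, ng per mL plasma.
#' @param reads_per_marker Number of sequenced molecules per locus.
#' @param bisulfite_failure_rate Probability that a truly unmethylated
#'   cytosine fails conversion and reads as C. Must lie in [0, 0.1].
#' @param inappropriate_conversion_rate Probability that a methylated CpG
#'   cytosine is converted anyway and reads as T. Must lie in [0, 0.1].
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `mixture_spec` list.
#' @export
mixture_spec <- function(fractions,
                         total_cfdna_ng_per_ml = 10,
                         reads_per_marker = 1000L,
                         bisulfite_failure_rate = 0.005,
                         inappropriate_conversion_rate = 0.005,
                         seed = 1L) {
  stopifnot(is.numeric(fractions), !is.null(names(fractions)))
  valid <- c(panel_celltypes(), "leukocyte_other")
  bad <- setdiff(names(fractions), valid)
  if (length(bad)) stop("unknown celltype in fractions: ",
                        paste(bad, collapse = ", "))
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("mixture fractions must sum to 1 (got ", sum(fractions), ")")
  if (any(fractions < 0)) stop("mixture fractions must be nonnegative")
  if (total_cfdna_ng_per_ml <= 0) stop("total_cfdna_ng_per_ml must be positive")
  reads_per_marker <- as.integer(reads_per_marker)
  if (is.na(reads_per_marker) || reads_per_marker < 1L)
    stop("reads_per_marker must be a positive integer")
  for (r in c(bisulfite_failure_rate, inappropriate_conversion_rate))
    if (r < 0 || r > 0.1)
      stop("noise rates must lie in [0, 0.1]")
  structure(list(fractions = fractions,
                 total_cfdna_ng_per_ml = total_cfdna_ng_per_ml,
                 reads_per_marker = reads_per_marker,
                 bisulfite_failure_rate = bisulfite_failure_rate,
                 inappropriate_conversion_rate = inappropriate_conversion_rate,
                 seed = as.integer(seed)),
            class = "mixture_spec")
}

# Deterministic synthetic reference amplicon for one locus: 'CG' dinucleotides
# at the declared offsets, no incidental CpGs, and ~15% non-CpG cytosines so
# that bisulfite-conversion QC has positions to check. Seeded from the marker
# id, so references are stable across mixture specs and seeds.
locus_reference <- function(locus_id, locus_len, cpg_offsets) {
  with_seed(string_seed(locus_id), {
    s <- sample(c("A", "G", "T"), locus_len, replace = TRUE)
    s[cpg_offsets + 1L] <- "C"
    s[cpg_offsets + 2L] <- "G"
    # candidate non-CpG C sites: next base must not be G and the position must
    # not collide with a designated CpG C or G
    taken <- c(cpg_offsets + 1L, cpg_offsets + 2L)
    cand <- setdiff(which(s != "G"), taken)          # position itself
    cand <- cand[cand < locus_len]
    cand <- cand[s[cand + 1L] != "G" & !((cand + 1L) %in% taken)]
    ncc <- cand[runif(length(cand)) < 0.15]
    s[ncc] <- "C"
    paste(s, collapse = "")
  })
}

#' Reference amplicon sequences for a panel
#'
#' Synthetic per-locus reference sequences (plus-strand, pre-bisulfite) used
#' by the read generator and by [call_molecule_patterns()]. Deterministic per
#' marker id.
#'
#' @param panel A `marker_panel`.
#' @return Named character vector of reference sequences.
#' @export
panel_references <- function(panel) {
  panel <- validate_panel(panel)
  refs <- vapply(seq_len(nrow(panel)), function(i) {
    locus_reference(panel$marker_id[i], panel$end[i] - panel$start[i],
                    panel$cpg_offsets[[i]])
  }, character(1))
  names(refs) <- panel$marker_id
  refs
}

#' Generate synthetic bisulfite amplicon reads for a tissue mixture
#'
#' Emulates the spike-in experiment used to establish assay sensitivity:
#' molecules are drawn per locus from the mixture, methylated all-or-none by
#' source, bisulfite-converted in silico (per-cytosine independent noise), and
#' emitted as reads. Every molecule's true source is recorded in a truth
#' table, which downstream recovery tests use as the oracle.
#'
#' @param panel A `marker_panel`.
#' @param spec A [mixture_spec()].
#' @param dir Optional output directory; if given, writes `reads.fastq`,
#'   `truth.tsv` and `references.fasta` there.
#' @return An `amplicon_reads` list with elements `reads` (named character
#'   vector of read sequences; names encode `marker|molecule|src=celltype`),
#'   `truth` (data.frame: `read_id`, `marker_id`, `source_celltype`),
#'   `references` (named character) and `spec`.
#' @export
generate_reads <- function(panel, spec, dir = NULL) {
  panel <- validate_panel(panel)
  stopifnot(inherits(spec, "mixture_spec"))
  refs <- panel_references(panel)
  sources <- names(spec$fractions)
  n <- spec$reads_per_marker
  bf <- spec$bisulfite_failure_rate
  ic <- spec$inappropriate_conversion_rate
  out_reads <- vector("list", nrow(panel))
  out_truth <- vector("list", nrow(panel))
  with_seed(spec$seed, {
    for (i in seq_len(nrow(panel))) {
      id <- panel$marker_id[i]
      ref <- strsplit(refs[[id]], "", fixed = TRUE)[[1L]]
      cpg_pos <- panel$cpg_offsets[[i]] + 1L
      noncpg_c <- setdiff(which(ref == "C"), cpg_pos)
      src <- sources[sample.int(length(sources), n, replace = TRUE,
                                prob = spec$fractions)]
      unmeth <- src == panel$target_celltype[i]
      cpos <- sort(c(cpg_pos, noncpg_c))
      letters_at <- matrix("", nrow = n, ncol = length(cpos))
      for (j in seq_along(cpos)) {
        u <- runif(n)
        if (cpos[j] %in% cpg_pos) {
          letters_at[, j] <- ifelse(unmeth,
                                    ifelse(u < bf, "C", "T"),
                                    ifelse(u < ic, "T", "C"))
        } else {
          letters_at[, j] <- ifelse(u < bf, "C", "T")  # always unmethylated
        }
      }
      # stitch constant segments around the variable cytosine positions
      bounds <- c(0L, cpos, length(ref) + 1L)
      segs <- vapply(seq_len(length(cpos) + 1L), function(k) {
        lo <- bounds[k] + 1L; hi <- bounds[k + 1L] - 1L
        if (lo > hi) "" else paste(ref[lo:hi], collapse = "")
      }, character(1))
      args <- vector("list", 2L * length(cpos) + 1L)
      args[[1L]] <- segs[1L]
      for (j in seq_along(cpos)) {
        args[[2L * j]] <- letters_at[, j]
        args[[2L * j + 1L]] <- segs[j + 1L]
      }
      reads <- do.call(paste0, args)
      ids <- sprintf("%s|mol%06d|src=%s", id, seq_len(n), src)
      names(reads) <- ids
      out_reads[[i]] <- reads
      out_truth[[i]] <- data.frame(read_id = ids, marker_id = id,
                                   source_celltype = src,
                                   stringsAsFactors = FALSE)
    }
  })
  res <- structure(list(reads = unlist(out_reads),
                        truth = do.call(rbind, out_truth),
                        references = refs,
                        spec = spec),
                   class = "amplicon_reads")
  rownames(res$truth) <- NULL
  if (!is.null(dir)) write_reads(res, dir)
  res
}

#' Write synthetic reads to FASTQ, truth TSV and reference FASTA
#'
#' @param x An `amplicon_reads` object from [generate_reads()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reads <- function(x, dir) {
  stopifnot(inherits(x, "amplicon_reads"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- Biostrings::DNAStringSet(x$reads)
  Biostrings::writeXStringSet(seqs, file.path(dir, "reads.fastq"),
                              format = "fastq")
  refs <- Biostrings::DNAStringSet(x$references)
  Biostrings::writeXStringSet(refs, file.path(dir, "references.fasta"),
                              format = "fasta")
  write.table(x$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read amplicon reads from a FASTQ file
#'
#' @param path FASTQ file path.
#' @return Named character vector of read sequences.
#' @export
read_fastq_reads <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}
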