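#' Cell types addressable by the marker panel
#'
#' Enumerated labels for the cell types whose uniquely unmethylated loci the
#' panel targets: four solid tissues damaged in chronic GVHD (liver, skin,
#' lung, gastrointestinal epithelium) and seven immune/inflammatory cell
#' types. The synthetic mixture generator additionally recognises the
#' background label `"leukocyte_other"`, which is methylated at every panel
#' locus.
#'
#' @return Character vector of valid `target_celltype` labels.
#' @export
panel_celltypes <- function() {
  c("liver", "skin", "lung", "gi",
    "neutrophil", "monocyte", "eosinophil",
    "b_cell", "t_cell", "cd8_t", "treg")
}

PANEL_COLUMNS <- c("marker_id", "chrom", "start", "end", "strand",
                   "target_celltype", "cpg_offsets")

#' Construct a marker panel
#'
#' A `marker_panel` is a data.frame with one row per amplicon locus and a
#' list-column of CpG offsets. Coordinates are 0-based half-open (BED
#' convention); `cpg_offsets` are offsets of the C of each CpG relative to
#' `start`, strictly increasing, with at least two CpGs per marker — molecules
#' carrying multiple unmethylated CpGs are what give the assay its
#' tissue-of-origin specificity.
#'
#' @param marker_id Character, unique marker identifiers.
#' @param chrom Character chromosome names.
#' @param start,end Integer genomic coordinates, 0-based half-open.
#' @param strand `"+"` or `"-"`.
#' @param target_celltype One of [panel_celltypes()] per locus: the cell type
#'   in which the locus is unmethylated.
#' @param cpg_offsets List of integer vectors, one per locus.
#' @return A validated `marker_panel` object.
#' @seealso [load_panel()], [write_panel()], [example_panel()]
#' @export
marker_panel <- function(marker_id, chrom, start, end, strand,
                         target_celltype, cpg_offsets) {
  p <- data.frame(marker_id = as.character(marker_id),
                  chrom = as.character(chrom),
                  start = as.integer(start),
                  end = as.integer(end),
                  strand = as.character(strand),
                  target_celltype = as.character(target_celltype),
                  stringsAsFactors = FALSE)
  p$cpg_offsets <- lapply(cpg_offsets, function(x) as.integer(x))
  class(p) <- c("marker_panel", "data.frame")
  validate_panel(p)
}

#' Validate a marker panel
#'
#' Enforces the panel invariants: unique marker ids, no duplicated
#' (chrom, start, end), valid strand and cell-type labels, `start < end`,
#' strictly increasing CpG offsets inside `[0, end - start)`, and at least two
#' CpGs per marker.
#'
#' @param panel A `marker_panel`.
#' @return The panel, invisibly usable; throws an informative error on any
#'   invariant violation.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "data.frame"))
  missing_cols <- setdiff(PANEL_COLUMNS, names(panel))
  if (length(missing_cols))
    stop("panel is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(panel) == 0L) stop("panel has no loci")
  if (anyDuplicated(panel$marker_id))
    stop("duplicate marker_id: ",
         paste(unique(panel$marker_id[duplicated(panel$marker_id)]),
               collapse = ", "))
  key <- paste(panel$chrom, panel$start, panel$end)
  if (anyDuplicated(key))
    stop("duplicate locus coordinates: ", key[duplicated(key)][1L])
  if (!all(panel$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  bad_ct <- setdiff(panel$target_celltype, panel_celltypes())
  if (length(bad_ct))
    stop("unknown target_celltype: ", paste(bad_ct, collapse = ", "))
  if (any(panel$start < 0L) || any(panel$end <= panel$start))
    stop("coordinates must satisfy 0 <= start < end")
  for (i in seq_len(nrow(panel))) {
    off <- panel$cpg_offsets[[i]]
    id <- panel$marker_id[i]
    if (length(off) < 2L)
      stop("marker ", id, " has fewer than 2 CpGs")
    if (any(diff(off) <= 0L))
      stop("marker ", id, ": cpg_offsets not strictly increasing")
    if (any(off < 0L) || any(off >= panel$end[i] - panel$start[i]))
      stop("marker ", id, ": cpg_offsets outside [0, end - start)")
  }
  class(panel) <- unique(c("marker_panel", class(panel)))
  panel
}

#' Read a marker panel from a TSV file
#'
#' The file format is tab-separated with a header row and columns
#' `marker_id, chrom, start, end, strand, target_celltype, cpg_offsets`,
#' where `cpg_offsets` is a comma-joined list of integers. Coordinates are
#' 0-based half-open.
#'
#' @param path Path to the panel TSV.
#' @return A validated `marker_panel`.
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("panel parse error: file has no data rows: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, PANEL_COLUMNS))
    stop("panel parse error at line 1: expected header '",
         paste(PANEL_COLUMNS, collapse = "\t"), "'")
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nfield <- lengths(rows)
  if (any(nfield != length(PANEL_COLUMNS))) {
    bad <- which(nfield != length(PANEL_COLUMNS))[1L]
    stop("panel parse error at line ", bad + 1L, ": expected ",
         length(PANEL_COLUMNS), " fields, found ", nfield[bad])
  }
  m <- do.call(rbind, rows)
  start <- suppressWarnings(as.integer(m[, 3L]))
  end <- suppressWarnings(as.integer(m[, 4L]))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1L]
    stop("panel parse error at line ", bad + 1L, ": non-integer coordinate")
  }
  offsets <- lapply(seq_along(rows), function(i) {
    off <- suppressWarnings(as.integer(strsplit(m[i, 7L], ",", fixed = TRUE)[[1L]]))
    if (length(off) == 0L || anyNA(off))
      stop("panel parse error at line ", i + 1L, ": bad cpg_offsets '",
           m[i, 7L], "'")
    off
  })
  marker_panel(marker_id = m[, 1L], chrom = m[, 2L], start = start, end = end,
               strand = m[, 5L], target_celltype = m[, 6L],
               cpg_offsets = offsets)
}

#' Write a marker panel to a TSV file
#'
#' Inverse of [load_panel()]: `load_panel(write_panel(p, f))` reproduces `p`
#' exactly, including unicode marker ids.
#'
#' @param panel A validated `marker_panel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  panel <- validate_panel(panel)
  lines <- c(paste(PANEL_COLUMNS, collapse = "\t"),
             vapply(seq_len(nrow(panel)), function(i) {
               paste(panel$marker_id[i], panel$chrom[i], panel$start[i],
                     panel$end[i], panel$strand[i], panel$target_celltype[i],
                     paste(panel$cpg_offsets[[i]], collapse = ","),
                     sep = "\t")
             }, character(1)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}

#' Export the marker spans as 6-column BED
#'
#' @param panel A `marker_panel`.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
panel_to_bed <- function(panel, path) {
  panel <- validate_panel(panel)
  bed <- data.frame(panel$chrom, panel$start, panel$end, panel$marker_id,
                    0L, panel$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Synthetic example marker panel
#'
#' A deterministic stand-in panel with the solid-tissue marker counts of the
#' assay this package models — 5 liver, 5 skin, 10 lung and 8 gastrointestinal
#' loci — plus 4 markers for each of the seven immune cell types (immune
#' counts are a package choice; see the methods vignette). Coordinates and
#' CpG layouts are synthetic: they do not correspond to real genomic loci and
#' exist so that every downstream stage can be exercised without external
#' data. The same panel ships as
#' `system.file("extdata", "synthetic_marker_panel.tsv", package = "cfgvhd")`.
#'
#' @return A validated `marker_panel` with 56 loci.
#' @export
example_panel <- function() {
  counts <- c(liver = 5L, skin = 5L, lung = 10L, gi = 8L,
              neutrophil = 4L, monocyte = 4L, eosinophil = 4L,
              b_cell = 4L, t_cell = 4L, cd8_t = 4L, treg = 4L)
  prefix <- c(liver = "LIV", skin = "SKN", lung = "LNG", gi = "GIT",
              neutrophil = "NEU", monocyte = "MON", eosinophil = "EOS",
              b_cell = "BCL", t_cell = "TCL", cd8_t = "CD8", treg = "TRG")
  rows <- list()
  with_seed(20240116, {
    chrom_i <- 0L
    for (ct in names(counts)) {
      chrom_i <- chrom_i + 1L
      chrom <- paste0("chr", chrom_i)
      for (k in seq_len(counts[[ct]])) {
        len <- sample(90:140, 1L)
        n_cpg <- sample(4:8, 1L)
        # CpG Cs at least 2 bp apart, leaving room for the final G
        off <- sort(sample(seq(5L, len - 6L, by = 2L), n_cpg))
        start <- 1e6L * chrom_i + 2000L * k
        rows[[length(rows) + 1L]] <- list(
          marker_id = sprintf("%s-%03d", prefix[[ct]], k),
          chrom = chrom, start = start, end = start + len,
          strand = sample(c("+", "-"), 1L), target_celltype = ct,
          cpg_offsets = off)
      }
    }
  })
  marker_panel(
    marker_id = vapply(rows, `[[`, "", "marker_id"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    start = vapply(rows, function(r) r$start, 0),
    end = vapply(rows, function(r) r$end, 0),
    strand = vapply(rows, `[[`, "", "strand"),
    target_celltype = vapply(rows, `[[`, "", "target_celltype"),
    cpg_offsets = lapply(rows, `[[`, "cpg_offsets"))
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("marker_panel:", nrow(x), "loci,",
      length(unique(x$target_celltype)), "cell types\n")
  tab <- table(x$target_celltype)
  cat(paste0("  ", names(tab), ": ", as.integer(tab), collapse = "\n"), "\n")
  invisible(x)
}
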