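# A hand-built locus: 5 CpGs at 0-based offsets {4,10,16,22,26}, non-CpG
# cytosines at offsets {1,7,13}; everything checkable by eye.
handmade_locus <- function() {
  chars <- rep("A", 30)
  cpg <- c(4L, 10L, 16L, 22L, 26L)
  chars[cpg + 1L] <- "C"
  chars[cpg + 2L] <- "G"
  chars[c(2, 8, 14)] <- "C"
  list(panel = marker_panel("HM1", "chr9", 0, 30, "+", "liver", list(cpg)),
       ref = paste(chars, collapse = ""))
}

with_cpgs <- function(ref, base_at_cpg, convert_noncpg = TRUE, keep_c = integer()) {
  chars <- strsplit(ref, "")[[1]]
  chars[c(5, 11, 17, 23, 27)] <- base_at_cpg
  noncpg <- c(2, 8, 14)
  if (convert_noncpg) chars[setdiff(noncpg, keep_c)] <- "T"
  paste(chars, collapse = "")
}

test_that("pattern calling reads CpG states and flags failed conversions", {
  hm <- handmade_locus()
  reads <- c(clean_unmeth = with_cpgs(hm$ref, "T"),
             clean_meth = with_cpgs(hm$ref, "C"),
             bad_conv = with_cpgs(hm$ref, "T", keep_c = c(2, 8)),  # 2/3 retained
             partial = with_cpgs(hm$ref, c("T", "T", "C", "T", "T")),
             with_gap = with_cpgs(hm$ref, c("T", "N", "T", "T", "T")),
             short = "TTAC")
  pat <- call_molecule_patterns(reads, hm$panel, hm$ref)
  expect_equal(pat$calls, c("UUUUU", "MMMMM", "UUUUU", "UUMUU", "U.UUU",
                            "....."))
  expect_equal(pat$conversion_ok, c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(pat$noncpg_retention[3], 2 / 3)
  expect_true(pat$short_read[6])
  expect_equal(pat$qc_pass, c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(pat$n_missing, c(0L, 0L, 0L, 0L, 1L, 5L))
  # no reads at a locus is an empty result, not an error
  expect_equal(nrow(call_molecule_patterns(character(), hm$panel, hm$ref)), 0L)
})

test_that("unmethylated-molecule rule counts what it should", {
  hm <- handmade_locus()
  reads <- c(replicate(3, with_cpgs(hm$ref, "T")),
             replicate(7, with_cpgs(hm$ref, "C")))
  names(reads) <- sprintf("r%02d", 1:10)
  pat <- call_molecule_patterns(reads, hm$panel, hm$ref)
  uf <- unmethylated_fraction(pat)
  expect_equal(uf$fraction, 0.3)
  expect_equal(uf$n_total, 10L)
  expect_equal(uf$n_unmethylated, 3L)
  # 4-of-5 molecule: excluded under the default rule, included at k = C - 1
  pat45 <- call_molecule_patterns(
    c(m = with_cpgs(hm$ref, c("T", "T", "C", "T", "T"))), hm$panel, hm$ref)
  expect_equal(unmethylated_fraction(pat45)$n_unmethylated, 0L)
  expect_equal(unmethylated_fraction(pat45, k = 4)$n_unmethylated, 1L)
  # zero QC-passing molecules: fraction is missing, never zero
  bad <- call_molecule_patterns(
    c(b = with_cpgs(hm$ref, "T", keep_c = c(2, 8, 14))), hm$panel, hm$ref)
  expect_true(is.na(unmethylated_fraction(bad)$fraction))
})

test_that("tissue fractions are unweighted means over non-missing markers", {
  mc <- data.frame(marker_id = paste0("L", 1:5),
                   target_celltype = "liver",
                   fraction = c(0.02, 0.04, 0.0, 0.02, 0.02))
  p <- example_panel()
  tf <- tissue_fraction(mc, p[p$target_celltype == "liver", ])
  expect_equal(tf$fraction, 0.02)
  mc$fraction[2] <- NA
  tf2 <- tissue_fraction(mc, p[p$target_celltype == "liver", ])
  expect_equal(tf2$fraction, mean(c(0.02, 0, 0.02, 0.02)))
  expect_equal(tf2$n_markers_used, 4L)
  mc$fraction <- NA_real_
  expect_true(is.na(tissue_fraction(mc, p[p$target_celltype == "liver", ])$fraction))
})

test_that("genome-equivalent conversion is exact and linear", {
  expect_equal(absolute_concentration(0, 50), 0)
  expect_equal(absolute_concentration(0.01, 10), 0.01 * 10 * 1000 / 3.3)
  expect_equal(absolute_concentration(1, 3.3e-3), 1)
  expect_true(is.na(absolute_concentration(NA, 10)))
  expect_error(absolute_concentration(-0.1, 10), "fraction")
  expect_error(absolute_concentration(0.5, -1), "nonnegative")
  # linear in each argument
  expect_equal(absolute_concentration(0.4, 7), 2 * absolute_concentration(0.2, 7))
  expect_equal(absolute_concentration(0.4, 14), 2 * absolute_concentration(0.4, 7))
})

test_that("quantify_sample runs reads to a tissue profile end to end", {
  p <- tiny_panel()
  spec <- mixture_spec(c(liver = 0.2, leukocyte_other = 0.8),
                       reads_per_marker = 1500, seed = 31)
  rd <- generate_reads(p, spec)
  prof <- quantify_sample(rd$reads, p, total_cfdna_ng_per_ml = 12,
                          references = rd$references)
  liver <- prof[prof$celltype == "liver", ]
  expect_lt(abs(liver$fraction - 0.2 * (1 - 0.005)^3), 0.03)
  expect_equal(liver$ge_per_ml,
               absolute_concentration(liver$fraction, 12))
  expect_equal(attr(prof, "rule"), "all")
})

test_that("pattern tables round-trip through TSV", {
  hm <- handmade_locus()
  reads <- c(a = with_cpgs(hm$ref, "T"), b = with_cpgs(hm$ref, "C"))
  pat <- call_molecule_patterns(reads, hm$panel, hm$ref)
  f <- withr::local_tempfile()
  write_patterns(pat, f)
  back <- read_patterns(f)
  expect_equal(back$calls, pat$calls)
  expect_equal(back$qc_pass, pat$qc_pass)
  expect_equal(unmethylated_fraction(back)$fraction,
               unmethylated_fraction(pat)$fraction)
})

test_that("detection-limit simulation is calibrated and monotone", {
  p <- tiny_panel()
  dl <- detection_limit(p, "liver", grid = c(0.0002, 0.002, 0.5),
                        reads_per_marker = 2000, replicates = 30,
                        null_replicates = 400, seed = 17)
  # null calibration: false-detection rate near alpha
  expect_gte(dl$null_rate, 0.02)
  expect_lte(dl$null_rate, 0.08)
  # detection rate non-decreasing in spike fraction; certain at 50%
  expect_true(all(diff(dl$rate_table$rate) >= 0))
  expect_equal(dl$rate_table$rate[3], 1)
  # deeper sequencing cannot hurt detection
  dl_deep <- detection_limit(p, "liver", grid = c(0.0002, 0.002, 0.5),
                             reads_per_marker = 20000, replicates = 30,
                             seed = 17)
  expect_true(all(dl_deep$rate_table$rate >= dl$rate_table$rate - 0.1))
  expect_error(detection_limit(p, "liver", numeric()), "empty")
  expect_error(detection_limit(p, "liver", 0.01, replicates = 5), "20")
  expect_error(detection_limit(p, "treg", 0.01), "no markers")
})
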