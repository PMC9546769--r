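# Exome hard filters, per-cell reference lists and TP/FP/FN classification.

snp_sim <- function() cached_sim("snp_main", function()
  simulate_dataset(sim_config(seed = 37, n_cells = 3, reads_per_cell = 3000,
                              frac_umi_reads = 0, p_background = 0,
                              n_het_snps = 50, p_carrier = 1,
                              error_rate = 0)))

test_that("hard filters apply the strict published thresholds", {
  base <- data.frame(chrom = "chr1", pos = 1:6, ref = "A", alt = "G",
                     qual = 100, dp = 50L, QD = 10, FS = 5, SOR = 1, MQ = 60,
                     MQRankSum = 0, ReadPosRankSum = 0,
                     stringsAsFactors = FALSE)
  base$QD[2] <- 1.5          # fails QD > 2
  base$QD[3] <- 2            # boundary: strict inequality -> fails
  base$FS[4] <- 60           # boundary FS < 60 -> fails
  base$MQRankSum[5] <- NA    # missing annotation passes by default
  base$alt[6] <- "GT"        # indel -> excluded
  ref <- hard_filter_exome(base)
  expect_equal(ref$variants$pos, c(1L, 5L))
  strict <- hard_filter_exome(base, missing_passes = FALSE)
  expect_equal(strict$variants$pos, 1L)
})

test_that("simulated decoy variants are removed, planted SNPs retained", {
  sim <- snp_sim()
  capture <- sim$annotation[, c("chrom", "start", "end")]
  ref <- hard_filter_exome(sim$exome_variants, capture)
  tv <- sim$truth$variants
  expect_setequal(paste(ref$variants$chrom, ref$variants$pos),
                  paste(tv$chrom, tv$pos))
})

test_that("the reference list keeps exome SNPs covered by more than 2 reads", {
  v <- data.frame(chrom = "chr1", pos = c(100L, 200L), ref = "A", alt = "G",
                  qual = 100, dp = 50L, QD = 10, FS = 5, SOR = 1, MQ = 60,
                  MQRankSum = 0, ReadPosRankSum = 0, stringsAsFactors = FALSE)
  exome <- hard_filter_exome(v)
  aln <- make_aln("chr1", c(50L, 60L, 70L, 150L, 160L),
                  c(125L, 135L, 145L, 225L, 235L), "+")
  ref <- reference_list_for_cell(exome, aln)   # pos 100 cov 3, pos 200 cov 2
  expect_equal(ref$pos, 100L)
})

test_that("classification identities hold and truth calls score 100% TP", {
  sim <- snp_sim()
  capture <- sim$annotation[, c("chrom", "start", "end")]
  exome <- hard_filter_exome(sim$exome_variants, capture)
  for (cl in sprintf("c%03d", 1:3)) {
    a <- sim$alignments[sim$alignments$cell == cl, ]
    ref <- reference_list_for_cell(exome, a)
    res <- classify_cell_snps(truth_calls_for_cell(sim, cl), ref, capture,
                              cell = cl)
    expect_equal(res$n_tp + res$n_fn, res$n_reference)
    expect_equal(res$pct_tp, 100)
    expect_equal(res$n_fp, 0L)
    expect_lte(res$n_tp_qual, res$n_tp)
    expect_lte(res$n_fp_qual, res$n_fp)
    # empty call set: all reference SNPs become false negatives
    none <- classify_cell_snps(umi5p:::empty_variants(), ref, capture)
    expect_equal(none$n_tp, 0L)
    expect_equal(none$n_fp, 0L)
    expect_equal(none$n_fn, nrow(ref))
  }
})

test_that("a wrong alt allele at a reference position is a false positive", {
  ref_list <- data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                         stringsAsFactors = FALSE)
  call <- data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                     qual = 50, dp = 10L, stringsAsFactors = FALSE)
  res <- classify_cell_snps(call, ref_list)
  expect_equal(res$n_fp, 1L)
  expect_equal(res$n_tp, 0L)
  # position-only matching accepts it
  loose <- classify_cell_snps(call, ref_list, match_alt = FALSE)
  expect_equal(loose$n_tp, 1L)
})

test_that("injected miscalls at non-reference sites appear only as FP", {
  sim <- snp_sim()
  capture <- sim$annotation[, c("chrom", "start", "end")]
  exome <- hard_filter_exome(sim$exome_variants, capture)
  cl <- "c001"
  a <- sim$alignments[sim$alignments$cell == cl, ]
  ref <- reference_list_for_cell(exome, a)
  calls <- truth_calls_for_cell(sim, cl)
  k <- 7L
  used <- paste(exome$variants$chrom, exome$variants$pos)
  inj <- data.frame(chrom = capture$chrom[1:k],
                    pos = capture$start[1:k] + 37L, ref = "A", alt = "G",
                    qual = 99, dp = 10L, stringsAsFactors = FALSE)
  stopifnot(!paste(inj$chrom, inj$pos) %in% used)
  for (nm in umi5p:::VCF_INFO_KEYS) inj[[nm]] <- NA_real_
  res <- classify_cell_snps(rbind(calls, inj), ref, capture, cell = cl)
  expect_equal(res$n_fp, k)
  expect_equal(res$pct_tp, 100)
})

test_that("the pileup caller recovers well-covered planted SNPs without FPs", {
  sim <- snp_sim()
  capture <- sim$annotation[, c("chrom", "start", "end")]
  exome <- hard_filter_exome(sim$exome_variants, capture)
  a <- sim$alignments[sim$alignments$cell == "c002", ]
  calls <- call_cell_snps(a, sim$genome)
  ref <- reference_list_for_cell(exome, a)
  res <- classify_cell_snps(calls, ref, capture, cell = "c002")
  expect_equal(res$n_fp, 0L)           # no errors were simulated
  expect_gt(res$pct_tp, 80)            # low-coverage het sites may be missed
  # all calls sit at planted positions with the planted alt
  tv <- sim$truth$variants
  expect_true(all(paste(calls$chrom, calls$pos, calls$alt) %in%
                    paste(tv$chrom, tv$pos, tv$alt)))
})

test_that("depth curves are consistent at the extremes and monotone on average", {
  sim <- snp_sim()
  capture <- sim$annotation[, c("chrom", "start", "end")]
  exome <- hard_filter_exome(sim$exome_variants, capture)
  a <- sim$alignments[sim$alignments$cell == "c001", ]
  n_ids <- length(unique(a$read_id))
  dc <- depth_curve(a, sim$genome, exome, c(0L, 500L, n_ids), seed = 3,
                    cell = "c001")
  expect_equal(dc$n_tp[1], 0L)
  expect_equal(dc$n_fp[1], 0L)
  expect_true(all(dc$n_tp + dc$n_fn == dc$n_reference))
  expect_lte(dc$n_tp[2], dc$n_tp[3])
  # the full-depth point equals the undownsampled classification
  full <- classify_cell_snps(call_cell_snps(a, sim$genome),
                             reference_list_for_cell(exome, a), capture,
                             cell = "c001", depth = n_ids)
  expect_equal(dc$n_tp[3], full$n_tp)
  expect_equal(dc$n_reference[3], full$n_reference)
  expect_true(dc$clamped[1] == FALSE && !dc$clamped[3])
  over <- depth_curve(a, sim$genome, exome, n_ids + 100L, cell = "c001")
  expect_true(over$clamped)
  expect_equal(over$n_tp, full$n_tp)
})

test_that("cell aggregation pools coverage and is seed-deterministic", {
  sim <- snp_sim()
  capture <- sim$annotation[, c("chrom", "start", "end")]
  exome <- hard_filter_exome(sim$exome_variants, capture)
  single <- vapply(sprintf("c%03d", 1:3), function(cl) {
    a <- sim$alignments[sim$alignments$cell == cl, ]
    classify_cell_snps(call_cell_snps(a, sim$genome),
                       reference_list_for_cell(exome, a), capture)$n_tp
  }, integer(1))
  pooled <- aggregate_cells(sim$alignments, sim$genome, exome,
                            k = 3L, seed = 5)
  expect_gte(pooled$n_tp, max(single))
  p2 <- aggregate_cells(sim$alignments, sim$genome, exome, k = 2L, seed = 5)
  p3 <- aggregate_cells(sim$alignments, sim$genome, exome, k = 2L, seed = 5)
  expect_identical(attr(p2, "cells"), attr(p3, "cells"))
  expect_error(aggregate_cells(sim$alignments, sim$genome, exome, k = 10L),
               "exceeds")
})
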