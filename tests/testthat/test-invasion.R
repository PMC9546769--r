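# Upstream-context extraction, deduplication, matching and filtering.

test_that("upstream context follows the strand-aware definition", {
  g <- c(chr1 = paste(rep("ACGT", 100), collapse = ""))
  aln <- make_aln("chr1", c(100L, 60L), c(175L, 100L), c("+", "-"),
                  umi = c("AAAAAAAA", "CCCCCCCC"))
  up <- annotate_upstream(aln, g, window = 20L)
  expect_equal(up$upstream[1], unname(substr(g, 81, 100)))
  expect_equal(up$upstream[2], unname(revcomp(substr(g, 101, 120))))
  expect_equal(up$read_start, c(100L, 100L))

  # reads too close to the contig edge are dropped and counted
  edge <- make_aln("chr1", c(5L, 390L), c(80L, 400L), c("+", "-"),
                   umi = "AAAAAAAA")
  up2 <- annotate_upstream(edge, g)
  expect_equal(nrow(up2), 0L)
  expect_equal(attr(up2, "n_dropped_edge"), 2L)
  expect_warning(annotate_upstream(
    make_aln("chrX", 100L, 175L, "+", umi = "AAAAAAAA"), g), "absent")
})

test_that("dedup collapses identical keys, keeps distinct upstream, is idempotent", {
  r <- data.frame(read_id = c("a", "b", "c", "d"),
                  umi = c("AAAAAAAA", "AAAAAAAA", "AAAAAAAA", "AAAAAAAA"),
                  chrom = "chr1", read_start = 100L,
                  strand = c("+", "+", "+", "-"),
                  upstream = c("A", "A", "C", "A"), stringsAsFactors = FALSE)
  dd <- dedup_5p(r)
  expect_equal(dd$read_id, c("a", "c", "d"))
  expect_identical(dedup_5p(dd), dd)
  # order-insensitive survivor key multiset
  perm <- r[c(3, 1, 4, 2), ]
  keyset <- function(d) sort(paste(d$umi, d$strand, d$upstream))
  expect_identical(keyset(dedup_5p(perm)), keyset(dd))
})

test_that("UMI-upstream matching returns the minimal consecutive-5'-mismatch level", {
  expect_equal(match_umi_upstream("ACGTACGT", "TTTTTTTTTTTTACGTACGT"), 0L)
  # TACGT present only as the 5-suffix: levels 0-2 fail, 3 succeeds
  up <- "AAAAAAAAAAAAAAATACGT"
  expect_equal(match_umi_upstream("TTTTACGT", up), 3L)
  expect_true(is.na(match_umi_upstream("TTTTACGT", up, max_mismatch = 2L)))
  # spacer+GGG motif conditioning
  expect_equal(match_umi_upstream("ACGTACGT", "AAAAACGTACGTCTAACGGG",
                                  motif = "spacer_GGG", spacer = "CTAAC"), 0L)
  expect_true(is.na(match_umi_upstream("ACGTACGT", "AAAAACGTACGTCTAACGGG",
                                       motif = "GGG")))
  expect_error(match_umi_upstream("ACGTACGT", up, max_mismatch = 4L), "0..3")
  expect_error(match_umi_upstream("ACGT", up), "8 nt")
})

test_that("matcher agrees with exhaustive (m, offset) enumeration", {
  set.seed(31)
  n <- 2000
  umis <- random_dna(n, 8)
  ups <- random_dna(n, 20)
  # salt in guaranteed positives at random offsets and levels
  pos <- sample(n, 300)
  for (i in pos) {
    m <- sample(0:3, 1)
    q <- substring(umis[i], m + 1)
    o <- sample(20 - nchar(q) + 1, 1)
    substr(ups[i], o, o + nchar(q) - 1) <- q
  }
  for (motif in c("none", "GGG")) {
    mstr <- if (motif == "GGG") "GGG" else ""
    fast <- match_umi_upstream(umis, ups, 3L, motif)
    slow <- mapply(match_oracle, umis, ups,
                   MoreArgs = list(max_mismatch = 3L, motif_str = mstr))
    expect_identical(fast, unname(slow))
  }
  # adjacent-only variant
  fast_adj <- match_umi_upstream(umis, ups, 3L, adjacent_only = TRUE)
  slow_adj <- mapply(match_oracle, umis, ups,
                     MoreArgs = list(max_mismatch = 3L, motif_str = "",
                                     adjacent_only = TRUE))
  expect_identical(fast_adj, unname(slow_adj))
})

test_that("report fractions are monotone in mismatch level and motif stringency", {
  sim <- cached_sim("inv_mixed", function()
    simulate_dataset(sim_config(seed = 17, n_cells = 2, reads_per_cell = 3000,
                                frac_umi_reads = 1, p_background = 0,
                                p_invasion = 0.3, error_rate = 0)))
  dd <- dedup_5p(annotate_upstream(sim$alignments, sim$genome))
  rep <- invasion_report(dd)
  tab <- rep$table
  for (mode in unique(tab$motif)) {
    expect_false(is.unsorted(tab$n_match[tab$motif == mode]))
  }
  for (m in 0:3) {
    expect_lte(tab$n_match[tab$motif == "GGG" & tab$mismatch == m],
               tab$n_match[tab$motif == "none" & tab$mismatch == m])
    expect_lte(tab$n_match[tab$motif == "spacer_GGG" & tab$mismatch == m],
               tab$n_match[tab$motif == "GGG" & tab$mismatch == m])
  }
  expect_true(all(tab$pct >= 0 & tab$pct <= 100))
  # empty input is flagged absent, not zero
  empty <- invasion_report(dd[0, ])
  expect_equal(empty$n_dedup_reads, 0L)
  expect_true(all(is.na(empty$table$pct)))
})

test_that("the invasion filter removes verbatim matches but spares level-2 ones", {
  set.seed(41)
  g <- c(chr1 = random_dna(1, 300))
  up20 <- substr(g[[1]], 81, 100)
  hit <- make_aln("chr1", 100L, 175L, "+", umi = substr(up20, 13, 20))
  miss_umi <- paste0("TT", substr(up20, 15, 20))   # matches only at level 2
  lvl2 <- make_aln("chr1", 100L, 175L, "+", umi = miss_umi)
  up <- annotate_upstream(rbind(hit, lvl2), g)
  fl <- filter_invasion(up, max_mismatch = 1L)
  expect_equal(fl$n_removed, 1L)
  expect_equal(fl$retained$umi, miss_umi)
  fl2 <- filter_invasion(up, max_mismatch = 2L)
  expect_equal(fl2$n_removed, 2L)
})

test_that("filter recall on truth-invasion reads is near-total at zero error", {
  sim <- cached_sim("inv_mixed", function()
    simulate_dataset(sim_config(seed = 17, n_cells = 2, reads_per_cell = 3000,
                                frac_umi_reads = 1, p_background = 0,
                                p_invasion = 0.3, error_rate = 0)))
  up <- annotate_upstream(sim$alignments, sim$genome)
  fl <- filter_invasion(up, max_mismatch = 1L)
  tr <- sim$truth$reads
  inv_ids <- tr$read_id[tr$is_invasion]
  kept_inv <- sum(fl$retained$read_id %in% inv_ids)
  expect_gte(1 - kept_inv / length(inv_ids), 0.99)
  # consistency with the report on the same deduplicated input
  dd <- dedup_5p(up)
  rep <- invasion_report(dd)
  fl_dd <- filter_invasion(dd, max_mismatch = 1L)
  expect_equal(fl_dd$n_removed,
               rep$table$n_match[rep$table$motif == "none" &
                                   rep$table$mismatch == 1L])
})

test_that("read-start profile tallies the bases adjacent to the read start", {
  set.seed(51)
  r <- data.frame(umi = "ACGTACGT", chrom = "chr1", read_start = 50L,
                  strand = "+",
                  upstream = paste0(random_dna(200, 17), "GGG"),
                  stringsAsFactors = FALSE)
  prof <- readstart_profile(r, window = 6L, seed = 1)
  expect_equal(colnames(prof), c("-6", "-5", "-4", "-3", "-2", "-1"))
  expect_true(all(abs(colSums(prof) - 1) < 1e-12))
  expect_equal(unname(prof["G", c("-3", "-2", "-1")]), c(1, 1, 1))
  # uniform background stays within multinomial noise
  r2 <- data.frame(upstream = random_dna(4000, 20), stringsAsFactors = FALSE)
  prof2 <- readstart_profile(r2, seed = 2)
  expect_true(all(abs(prof2 - 0.25) < 4 * sqrt(0.25 * 0.75 / 4000)))
})

test_that("feature assignment distinguishes exonic and intergenic reads", {
  ann <- data.frame(chrom = "chr1", start = c(100L, 400L), end = c(300L, 500L),
                    gene = c("gA", "gI"), strand = c("+", "+"),
                    type = c("exon", "intron"), stringsAsFactors = FALSE)
  reads <- make_aln("chr1", c(150L, 410L, 700L), c(225L, 485L, 775L),
                    c("-", "+", "+"), umi = "AAAAAAAA")
  out <- assign_features(reads, ann)
  expect_equal(out$feature, c("exonic", "intronic", "intergenic"))
  expect_equal(out$feature_gene, c("gA", "gI", NA))
  expect_equal(out$antisense, c(TRUE, FALSE, NA))
})
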