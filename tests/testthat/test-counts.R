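# Gene assignment, molecule counting and the edit-distance diagnostic.

test_that("gene assignment enforces the 25% overlap fraction and ambiguity rule", {
  ann <- data.frame(chrom = "chr1", start = c(100L, 500L, 520L, 1000L),
                    end = c(150L, 700L, 720L, 1200L),
                    gene = c("gA", "gB", "gD", "gC"),
                    strand = c("+", "+", "+", "-"),
                    stringsAsFactors = FALSE)
  # 75-bp reads: 18-bp overlap (24%) unassigned, 19-bp (25.3%) assigned
  reads <- make_aln("chr1", c(132L, 131L, 480L, 1050L),
                    c(207L, 206L, 555L, 1125L), "+",
                    read_id = c("r18", "r19", "rAmb", "rMinus"))
  out <- assign_genes(reads, ann, stranded = FALSE)
  expect_true(is.na(out$gene[out$read_id == "r18"]))   # 150-132 = 18 bp
  expect_equal(out$gene[out$read_id == "r19"], "gA")   # 150-131 = 19 bp
  # rAmb: 55 bp in gB and 35 bp in gD, both >= 25% -> ambiguous
  expect_true(is.na(out$gene[out$read_id == "rAmb"]))
  expect_equal(out$gene[out$read_id == "rMinus"], "gC")
  # stranded mode refuses the antisense hit
  str <- assign_genes(reads, ann, stranded = TRUE)
  expect_true(is.na(str$gene[str$read_id == "rMinus"]))
})

test_that("directional collapse merges one-off UMIs under the count rule", {
  umis <- c(rep("AAAAAAAA", 5), "AAAAAAAT")
  r <- data.frame(gene = "g1", cell = "c1", umi = umis,
                  stringsAsFactors = FALSE)
  expect_equal(unname(count_molecules(r, "unique")["g1", "c1"]), 2L)
  expect_equal(unname(count_molecules(r, "directional")["g1", "c1"]), 1L)
  # equal counts do not satisfy count(a) >= 2*count(b) - 1 unless both are 1
  expect_equal(umi5p:::directional_components(c(rep("AAAAAAAA", 3), rep("AAAAAAAT", 3))), 2L)
  expect_equal(umi5p:::directional_components(c("AAAAAAAA", "AAAAAAAT")), 1L)
  # chain: 5x A8 -> 2x A7T -> transitively collapsible 1x A6TT
  expect_equal(umi5p:::directional_components(c(rep("AAAAAAAA", 5), rep("AAAAAAAT", 2),
                                        "AAAAAATT")), 1L)
  expect_error(count_molecules(r, "nonsense"))
})

test_that("counting is order-invariant and bounded by read count", {
  set.seed(23)
  r <- data.frame(gene = sample(c("g1", "g2"), 200, TRUE),
                  cell = sample(c("c1", "c2"), 200, TRUE),
                  umi = random_dna(200, 8), stringsAsFactors = FALSE)
  r$umi[1:50] <- r$umi[51:100]  # inject duplicates
  a <- count_molecules(r, "directional")
  b <- count_molecules(r[sample(nrow(r)), ], "directional")
  expect_identical(unclass(a), unclass(b))
  u <- count_molecules(r, "unique")
  reads_tab <- unclass(table(factor(r$gene, rownames(u)),
                             factor(r$cell, colnames(u))))
  expect_true(all(unclass(a) <= unclass(u)))
  expect_true(all(unclass(u) <= reads_tab))
})

test_that("unique counts equal planted molecule numbers despite PCR duplicates", {
  sim <- cached_sim("cnt_dup", function()
    simulate_dataset(sim_config(seed = 25, n_cells = 2, reads_per_cell = 600,
                                frac_umi_reads = 1, p_background = 0,
                                p_invasion = 0, p_tso_tagmentation = 0,
                                error_rate = 0, duplicate_factor = 4)))
  umi_reads <- sim$alignments[sim$alignments$mate == 1L, ]
  umi_reads <- assign_genes(umi_reads, sim$annotation, stranded = TRUE)
  mu <- count_molecules(umi_reads, "unique")
  tr <- sim$truth$reads[!duplicated(sim$truth$reads$molecule), ]
  truth <- unclass(table(factor(tr$gene, rownames(mu)),
                         factor(tr$cell, colnames(mu))))
  expect_equal(unclass(mu), truth, ignore_attr = TRUE)
  # gene with no reads stays at zero
  expect_equal(sum(mu[!rownames(mu) %in% tr$gene, ]), 0L)
})

test_that("internal counting recovers per-gene read numbers from simulation", {
  sim <- cached_sim("cnt_int", function()
    simulate_dataset(sim_config(seed = 26, n_cells = 2, reads_per_cell = 800,
                                frac_umi_reads = 0, p_background = 0.1,
                                error_rate = 0)))
  internal <- sim$alignments[is.na(sim$alignments$umi), ]
  mi <- count_internal(internal, sim$annotation)
  tr <- sim$truth$reads[sim$truth$reads$read_class == "internal", ]
  truth <- unclass(table(factor(tr$gene, rownames(mi)),
                         factor(tr$cell, colnames(mi))))
  expect_equal(unclass(mi), truth, ignore_attr = TRUE)
  expect_equal(attr(mi, "read_type"), "internal")
})

test_that("edit-distance diagnostic flags inflation and handles toy cases", {
  # one gene, two UMIs one edit apart: a single observed distance of 1
  toy <- data.frame(gene = "g1", umi = c("AAAAAAAA", "AAAAAAAT"),
                    stringsAsFactors = FALSE)
  d <- edit_distance_diagnostic(toy, n_null_draws = 5, seed = 1)
  expect_true(d$computable)
  expect_identical(d$observed, 1L)
  # near-identical UMIs within genes vs a diverse pool: small p, observed < null
  set.seed(33)
  base <- random_dna(30, 8)
  infl <- do.call(rbind, lapply(seq_along(base), function(i) {
    mut <- base[i]; substr(mut, 1, 1) <- "A"
    data.frame(gene = paste0("g", i), umi = c(base[i], mut),
               stringsAsFactors = FALSE)
  }))
  di <- edit_distance_diagnostic(infl, n_null_draws = 10, seed = 2)
  expect_lt(mean(di$observed), mean(di$null))
  expect_lt(di$p_value, 0.01)
  expect_true(all(abs(sum(di$observed_distribution) - 1) < 1e-12))
  # not computable when every gene has a single UMI
  single <- data.frame(gene = c("g1", "g2"), umi = c("AAAAAAAA", "CCCCCCCC"))
  expect_false(edit_distance_diagnostic(single)$computable)
  # hamming variant agrees with levenshtein on equal-length strings here
  dh <- edit_distance_diagnostic(toy, n_null_draws = 5, seed = 1,
                                 metric = "hamming")
  expect_identical(dh$observed, 1L)
})

test_that("null-calibrated diagnostic does not over-reject on random UMIs", {
  set.seed(35)
  rejections <- vapply(1:40, function(k) {
    d <- data.frame(gene = rep(paste0("g", 1:8), each = 6),
                    umi = random_dna(48, 8), stringsAsFactors = FALSE)
    edit_distance_diagnostic(d, n_null_draws = 5)$p_value < 0.05
  }, logical(1))
  # 3 s.d. above the nominal 5% level for 40 replicates
  expect_lte(mean(rejections), 0.05 + 3 * sqrt(0.05 * 0.95 / 40))
})
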