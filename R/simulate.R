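# Ground-truth read simulator.
#
# Generates a small uniform-random genome with single-interval gene models,
# per-cell paired 5' reads (UMI reads with configurable strand-invasion and
# intra-TSO tagmentation rates, internal reads, genomic background reads),
# planted heterozygous SNPs, the matching alignments (the simulator is its
# own aligner), an exome-style truth VCF and per-read/per-variant truth
# tables.  Everything is deterministic given the seed.

#' Simulation configuration
#'
#' @param seed RNG seed; the whole dataset is reproducible from it.
#' @param n_chroms,chrom_len genome shape (contigs of equal length, bp).
#' @param n_genes,gene_len single-interval gene models laid out with gaps,
#'   round-robin across contigs, on random strands.
#' @param n_cells,reads_per_cell number of cells and cDNA molecules
#'   (pre-PCR) per cell.
#' @param frac_umi_reads fraction of molecules that are 5' UMI reads.
#' @param p_invasion probability that a UMI read is a strand-invasion
#'   artifact (its UMI copies the upstream genomic sequence).
#' @param p_tso_tagmentation probability that a UMI read presents its motif
#'   on mate 2 (tagmentation cut inside the TSO).
#' @param adapter_truncation_weights named weights over retained adapter
#'   suffix lengths for R2-UMI reads.
#' @param r1_partial_prob probability that an R1-UMI read starts with a
#'   truncated (rather than full) adapter.
#' @param p_background fraction of molecules drawn from intergenic
#'   positions.
#' @param n_het_snps planted heterozygous SNV sites (alt allele on ~50% of
#'   a carrier cell's covering molecules).
#' @param p_carrier probability each cell carries a given SNP.
#' @param n_decoy_variants exome VCF records that fail the hard filters and
#'   are never planted in reads.
#' @param error_rate per-base substitution sequencing-error rate.
#' @param read_len read length of the cDNA portion (bp).
#' @param frag_len fragment length (distance between the two mate 5' ends
#'   plus read length).
#' @param duplicate_factor exact-copy PCR duplicates per molecule
#'   (sequencing errors are then drawn independently per copy).
#' @param invasion_motif_weights named weights over the upstream layout of
#'   invasion reads: `none` (UMI match immediately adjacent to the read
#'   start), `ggg` (a GGG tract between the UMI match and the read start,
#'   as left by the annealed riboguanosine tail) and `spacer_ggg` (spacer
#'   plus GGG between them).
#' @param oligo an [oligo_config()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L, chrom_len = 100000L,
                       n_genes = 40L, gene_len = 1000L,
                       n_cells = 8L, reads_per_cell = 1000L,
                       frac_umi_reads = 0.6,
                       p_invasion = 0.05,
                       p_tso_tagmentation = 0.05,
                       adapter_truncation_weights = c(`2` = 1, `3` = 1, `4` = 1),
                       r1_partial_prob = 0.25,
                       p_background = 0.05,
                       n_het_snps = 50L,
                       p_carrier = 0.5,
                       n_decoy_variants = 10L,
                       error_rate = 0.001,
                       read_len = 75L,
                       frag_len = read_len + 60L,
                       duplicate_factor = 1L,
                       invasion_motif_weights = c(none = 0.5, ggg = 0.25,
                                                  spacer_ggg = 0.25),
                       oligo = oligo_config()) {
  probs <- c(frac_umi_reads, p_invasion, p_tso_tagmentation, p_background,
             r1_partial_prob, p_carrier)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]",
                                       call. = FALSE)
  if (frac_umi_reads + p_background > 1)
    stop("frac_umi_reads + p_background must be <= 1", call. = FALSE)
  if (read_len < 25L) stop("read_len must be >= 25", call. = FALSE)
  if (frag_len < read_len) stop("frag_len must be >= read_len", call. = FALSE)
  if (gene_len < frag_len) stop("gene_len must be >= frag_len", call. = FALSE)
  margin <- 100L; gap <- 50L
  per_chrom <- ceiling(n_genes / n_chroms)
  if (chrom_len < read_len + 20L)
    stop("chrom_len too small for read_len plus 20-bp upstream context",
         call. = FALSE)
  if (2L * margin + per_chrom * (gene_len + gap) > chrom_len)
    stop("chrom_len too small for the requested gene layout", call. = FALSE)
  stopifnot(all(names(adapter_truncation_weights) %in% as.character(1:nchar(oligo$adapter))))
  stopifnot(setequal(names(invasion_motif_weights), c("none", "ggg", "spacer_ggg")))
  structure(list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                 chrom_len = as.integer(chrom_len),
                 n_genes = as.integer(n_genes), gene_len = as.integer(gene_len),
                 n_cells = as.integer(n_cells),
                 reads_per_cell = as.integer(reads_per_cell),
                 frac_umi_reads = frac_umi_reads, p_invasion = p_invasion,
                 p_tso_tagmentation = p_tso_tagmentation,
                 adapter_truncation_weights = adapter_truncation_weights,
                 r1_partial_prob = r1_partial_prob,
                 p_background = p_background,
                 n_het_snps = as.integer(n_het_snps), p_carrier = p_carrier,
                 n_decoy_variants = as.integer(n_decoy_variants),
                 error_rate = error_rate, read_len = as.integer(read_len),
                 frag_len = as.integer(frag_len),
                 duplicate_factor = as.integer(duplicate_factor),
                 invasion_motif_weights = invasion_motif_weights,
                 margin = margin, gap = gap,
                 oligo = oligo),
            class = "sim_config")
}

#' Simulate a complete ground-truth dataset
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_dataset`: a list with `config`, `genome`
#'   (named character vector of contig sequences), `chrom_lens`,
#'   `annotation`, `pairs` (FASTQ records as sequenced), `alignments`
#'   (post-extraction alignment records at the true positions, mate 1 being
#'   the 5'-end cDNA mate), `exome_variants`, and `truth` (per-read table,
#'   per-variant table, per-variant-per-cell support table).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  oligo <- config$oligo
  rl <- config$read_len; frag <- config$frag_len

  # --- genome and annotation ---
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  genome <- vapply(chroms, function(ch)
    paste(sample(DNA_BASES, config$chrom_len, replace = TRUE), collapse = ""),
    character(1))
  chrom_lens <- stats::setNames(rep(config$chrom_len, config$n_chroms), chroms)

  gchrom_idx <- rep(seq_len(config$n_chroms), length.out = config$n_genes)
  slot <- stats::ave(seq_len(config$n_genes), gchrom_idx, FUN = seq_along) - 1L
  gstart <- config$margin + slot * (config$gene_len + config$gap)
  annotation <- data.frame(chrom = chroms[gchrom_idx], start = gstart,
                           end = gstart + config$gene_len,
                           gene = sprintf("g%04d", seq_len(config$n_genes)),
                           strand = sample(c("+", "-"), config$n_genes,
                                           replace = TRUE),
                           stringsAsFactors = FALSE)

  # intergenic intervals with margins, for background reads
  ig <- do.call(rbind, lapply(chroms, function(ch) {
    g <- annotation[annotation$chrom == ch, , drop = FALSE]
    bounds <- sort(c(config$margin, g$start, g$end,
                     config$chrom_len - config$margin))
    s <- bounds[seq(1, length(bounds), by = 2L)]
    e <- bounds[seq(2, length(bounds), by = 2L)]
    keep <- (e - s) >= frag
    if (!any(keep)) return(NULL)
    data.frame(chrom = ch, start = s[keep], end = e[keep],
               stringsAsFactors = FALSE)
  }))

  # --- molecules ---
  cells <- sprintf("c%03d", seq_len(config$n_cells))
  nm <- config$n_cells * config$reads_per_cell
  cell <- rep(cells, each = config$reads_per_cell)
  u <- stats::runif(nm)
  class <- ifelse(u < config$frac_umi_reads, "umi",
                  ifelse(u < config$frac_umi_reads + config$p_background,
                         "background", "internal"))
  is_umi <- class == "umi"
  is_r2 <- is_umi & stats::runif(nm) < config$p_tso_tagmentation
  is_inv <- is_umi & stats::runif(nm) < config$p_invasion
  inv_motif <- rep(NA_character_, nm)
  inv_motif[is_inv] <- sample(names(config$invasion_motif_weights),
                              sum(is_inv), replace = TRUE,
                              prob = config$invasion_motif_weights)

  gene_i <- rep(NA_integer_, nm)
  in_gene <- class != "background"
  gene_i[in_gene] <- sample.int(config$n_genes, sum(in_gene), replace = TRUE)

  # fragment placement
  fs <- integer(nm); chrom <- character(nm); strand <- character(nm)
  off_max <- config$gene_len - frag
  fs[in_gene] <- annotation$start[gene_i[in_gene]] +
    sample.int(off_max + 1L, sum(in_gene), replace = TRUE) - 1L
  chrom[in_gene] <- annotation$chrom[gene_i[in_gene]]
  strand[in_gene] <- annotation$strand[gene_i[in_gene]]
  # internal reads come off both strands of the fragmented cDNA
  internal <- class == "internal"
  strand[internal] <- sample(c("+", "-"), sum(internal), replace = TRUE)
  nbg <- sum(!in_gene)
  if (nbg > 0L) {
    if (is.null(ig)) stop("no intergenic room for background reads", call. = FALSE)
    pick <- sample.int(nrow(ig), nbg, replace = TRUE,
                       prob = ig$end - ig$start - frag + 1L)
    fs[!in_gene] <- ig$start[pick] +
      vapply(ig$end[pick] - ig$start[pick] - frag + 1L,
             function(w) sample.int(w, 1L), integer(1)) - 1L
    chrom[!in_gene] <- ig$chrom[pick]
    strand[!in_gene] <- sample(c("+", "-"), nbg, replace = TRUE)
  }
  fe <- fs + frag
  # cDNA (5'-end) mate interval and the opposite mate interval, 0-based
  a1 <- ifelse(strand == "+", fs, fe - rl); b1 <- a1 + rl
  a2 <- ifelse(strand == "+", fe - rl, fs); b2 <- a2 + rl
  rs5 <- ifelse(strand == "+", fs, fe)  # 5' coordinate (exclusive end on -)

  # --- UMIs: sampled without replacement within each (cell, gene) ---
  umi <- rep(NA_character_, nm)
  iu <- which(is_umi)
  grp <- paste(cell[iu], gene_i[iu])
  for (ix in split(iu, grp)) {
    umi[ix] <- kmer_from_code(sample.int(65536L, length(ix)) - 1L, 8L)
  }

  # --- strand-invasion: plant motifs, then copy the upstream sequence ---
  umi_gap <- integer(nm)
  plant <- function(ch, pos0, s) {   # overwrite genome[ch][pos0, pos0+len)
    substr(genome[[ch]], pos0 + 1L, pos0 + nchar(s)) <<- s
  }
  for (i in which(is_inv & inv_motif != "none")) {
    motif <- if (inv_motif[i] == "ggg") "GGG" else paste0(oligo$spacer, "GGG")
    umi_gap[i] <- nchar(motif)
    if (strand[i] == "+") plant(chrom[i], rs5[i] - nchar(motif), motif)
    else plant(chrom[i], rs5[i], revcomp(motif))
  }
  inv_p <- which(is_inv & strand == "+")
  inv_m <- which(is_inv & strand == "-")
  umi[inv_p] <- substring(genome[chrom[inv_p]],
                          rs5[inv_p] - umi_gap[inv_p] - 7L,
                          rs5[inv_p] - umi_gap[inv_p])
  umi[inv_m] <- revcomp(substring(genome[chrom[inv_m]],
                                  rs5[inv_m] + umi_gap[inv_m] + 1L,
                                  rs5[inv_m] + umi_gap[inv_m] + 8L))

  # --- planted heterozygous SNPs (and decoy exome records) ---
  nsnp <- config$n_het_snps
  snp <- NULL
  carrier <- matrix(FALSE, 0, config$n_cells)
  if (nsnp > 0L) {
    pos0 <- integer(0); schrom <- character(0)
    while (length(pos0) < nsnp) {
      g <- sample.int(config$n_genes, nsnp, replace = TRUE)
      p <- annotation$start[g] + 20L +
        sample.int(config$gene_len - 40L, nsnp, replace = TRUE) - 1L
      keep <- !duplicated(paste(annotation$chrom[g], p)) &
        !(paste(annotation$chrom[g], p) %in% paste(schrom, pos0))
      schrom <- c(schrom, annotation$chrom[g][keep])
      pos0 <- c(pos0, p[keep])
    }
    schrom <- schrom[seq_len(nsnp)]; pos0 <- pos0[seq_len(nsnp)]
    ref <- substring(genome[schrom], pos0 + 1L, pos0 + 1L)
    alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1L),
                  character(1), USE.NAMES = FALSE)
    carrier <- matrix(stats::runif(nsnp * config$n_cells) < config$p_carrier,
                      nsnp, config$n_cells, dimnames = list(NULL, cells))
    snp <- data.frame(chrom = schrom, pos0 = pos0, ref = ref, alt = alt,
                      stringsAsFactors = FALSE)
  }

  # --- cDNA sequences (genome-forward), with SNP alleles planted ---
  cdna1 <- substring(genome[chrom], a1 + 1L, b1)
  cdna2 <- substring(genome[chrom], a2 + 1L, b2)
  alt_events <- list()
  if (nsnp > 0L) {
    cell_i <- match(cell, cells)
    for (s in seq_len(nsnp)) {
      on_chr <- chrom == snp$chrom[s]
      c1 <- on_chr & a1 <= snp$pos0[s] & snp$pos0[s] < b1
      c2 <- on_chr & a2 <= snp$pos0[s] & snp$pos0[s] < b2
      covered <- which(c1 | c2)
      if (length(covered) == 0L) next
      cand <- covered[carrier[s, cell_i[covered]]]
      has_alt <- cand[stats::runif(length(cand)) < 0.5]
      i1 <- intersect(has_alt, which(c1))
      i2 <- intersect(has_alt, which(c2))
      substr(cdna1[i1], snp$pos0[s] - a1[i1] + 1L,
             snp$pos0[s] - a1[i1] + 1L) <- snp$alt[s]
      substr(cdna2[i2], snp$pos0[s] - a2[i2] + 1L,
             snp$pos0[s] - a2[i2] + 1L) <- snp$alt[s]
      alt_events[[length(alt_events) + 1L]] <-
        data.frame(snp = s, mol = covered,
                   alt = covered %in% has_alt,
                   m1 = covered %in% which(c1), m2 = covered %in% which(c2))
    }
  }

  # --- technical motif assembly ---
  adapter <- oligo$adapter
  suffix_len <- integer(nm)
  ir1 <- which(is_umi & !is_r2)
  suffix_len[ir1] <- nchar(adapter)
  part <- ir1[stats::runif(length(ir1)) < config$r1_partial_prob]
  min_sfx <- oligo$r1_min_adapter_suffix %||% 2L
  if (length(part) > 0L) {
    suffix_len[part] <- sample(seq.int(min_sfx, nchar(adapter) - 1L),
                               length(part), replace = TRUE)
  }
  ir2 <- which(is_r2)
  if (length(ir2) > 0L) {
    lens <- as.integer(names(config$adapter_truncation_weights))
    suffix_len[ir2] <- sample(lens, length(ir2), replace = TRUE,
                              prob = config$adapter_truncation_weights)
  }
  motif <- rep("", nm)
  iumi <- which(is_umi)
  if (length(iumi) > 0L) {
    motif[iumi] <- paste0(substring(adapter,
                                    nchar(adapter) - suffix_len[iumi] + 1L,
                                    nchar(adapter)),
                          umi[iumi], oligo$spacer, "GGG")
  }

  # --- duplicate molecules into reads, orient, add errors ---
  dup <- config$duplicate_factor
  ridx <- rep(seq_len(nm), each = dup)
  read_id <- paste0(cell[ridx], "_m", formatC(ridx, width = 7, flag = "0"),
                    "_d", rep(seq_len(dup), times = nm))
  read1_cdna <- ifelse(strand == "+", cdna1, revcomp(cdna1))[ridx]
  read2 <- ifelse(strand == "+", revcomp(cdna2), cdna2)[ridx]
  motif_r <- motif[ridx]
  r1_full <- paste0(motif_r, read1_cdna)         # motif-bearing mate
  r1_full <- mutate_seqs(r1_full, config$error_rate)
  read2 <- mutate_seqs(read2, config$error_rate)
  mlen <- nchar(motif_r)
  umi_obs <- rep(NA_character_, length(ridx))
  iu_r <- which(is_umi[ridx])
  umi_obs[iu_r] <- substring(r1_full[iu_r], suffix_len[ridx][iu_r] + 1L,
                             suffix_len[ridx][iu_r] + 8L)
  cdna_obs <- substring(r1_full, mlen + 1L)
  swap <- is_r2[ridx]
  seq1 <- ifelse(swap, read2, r1_full)
  seq2 <- ifelse(swap, r1_full, read2)
  pairs <- data.frame(read_id = read_id, seq1 = seq1,
                      qual1 = strrep("I", nchar(seq1)),
                      seq2 = seq2, qual2 = strrep("I", nchar(seq2)),
                      stringsAsFactors = FALSE)

  # --- alignments: mate 1 = 5'-end cDNA read (post-extraction geometry) ---
  fwd1 <- ifelse(strand[ridx] == "+", cdna_obs, revcomp(cdna_obs))
  fwd2 <- ifelse(strand[ridx] == "+", revcomp(read2), read2)
  gene_lab <- ifelse(is.na(gene_i), NA_character_,
                     annotation$gene[gene_i])
  alignments <- rbind(
    data.frame(read_id = read_id, chrom = chrom[ridx], start = a1[ridx],
               end = b1[ridx], strand = strand[ridx], mate = 1L, mapq = 255L,
               umi = umi_obs, gene = gene_lab[ridx], cell = cell[ridx],
               seq = fwd1, stringsAsFactors = FALSE),
    data.frame(read_id = read_id, chrom = chrom[ridx], start = a2[ridx],
               end = b2[ridx], strand = ifelse(strand[ridx] == "+", "-", "+"),
               mate = 2L, mapq = 255L, umi = umi_obs, gene = gene_lab[ridx],
               cell = cell[ridx], seq = fwd2, stringsAsFactors = FALSE))

  # --- truth tables ---
  truth_reads <- data.frame(
    read_id = read_id, cell = cell[ridx], molecule = ridx,
    gene = ifelse(is.na(gene_lab[ridx]), "background", gene_lab[ridx]),
    chrom = chrom[ridx], start = a1[ridx], end = b1[ridx],
    strand = strand[ridx],
    read_class = c("internal", "background")[match(class[ridx],
                                                   c("internal", "background"))],
    true_umi = umi[ridx], is_invasion = is_inv[ridx],
    invasion_motif = inv_motif[ridx],
    adapter_suffix_len = ifelse(is_umi[ridx], suffix_len[ridx], NA_integer_),
    stringsAsFactors = FALSE)
  truth_reads$read_class[is_umi[ridx]] <-
    ifelse(is_r2[ridx][is_umi[ridx]], "umi_r2", "umi_r1")

  truth_variants <- NULL; truth_support <- NULL
  exome <- empty_variants()
  if (nsnp > 0L) {
    truth_variants <- data.frame(
      chrom = snp$chrom, pos = snp$pos0 + 1L, ref = snp$ref, alt = snp$alt,
      carriers = apply(carrier, 1L, function(z) paste(cells[z], collapse = ",")),
      stringsAsFactors = FALSE)
    ev <- if (length(alt_events)) do.call(rbind, alt_events) else
      data.frame(snp = integer(0), mol = integer(0), alt = logical(0),
                 m1 = logical(0), m2 = logical(0))
    grid <- expand.grid(snp = seq_len(nsnp), cell = cells,
                        stringsAsFactors = FALSE)
    ev$cell <- cell[ev$mol]
    ev$nrec <- (ev$m1 + ev$m2) * dup
    key <- paste(ev$snp, ev$cell)
    gkey <- paste(grid$snp, grid$cell)
    agg_cov <- tapply(ev$nrec, key, sum)
    agg_alt <- tapply(ev$nrec * ev$alt, key, sum)
    grid$n_cover <- as.integer(ifelse(is.na(agg_cov[gkey]), 0L, agg_cov[gkey]))
    grid$n_alt <- as.integer(ifelse(is.na(agg_alt[gkey]), 0L, agg_alt[gkey]))
    grid$carrier <- carrier[cbind(grid$snp, match(grid$cell, cells))]
    truth_support <- data.frame(chrom = snp$chrom[grid$snp],
                                pos = snp$pos0[grid$snp] + 1L,
                                cell = grid$cell, carrier = grid$carrier,
                                n_cover = grid$n_cover, n_alt = grid$n_alt,
                                stringsAsFactors = FALSE)
    # exome VCF: planted SNPs pass the hard filters, decoys fail them
    pass <- data.frame(chrom = snp$chrom, pos = snp$pos0 + 1L, ref = snp$ref,
                       alt = snp$alt, qual = 500,
                       dp = 100L,
                       QD = stats::runif(nsnp, 5, 30),
                       FS = stats::runif(nsnp, 0, 10),
                       SOR = stats::runif(nsnp, 0.5, 2.5),
                       MQ = stats::runif(nsnp, 50, 60),
                       MQRankSum = stats::runif(nsnp, -2, 2),
                       ReadPosRankSum = stats::runif(nsnp, -2, 2),
                       stringsAsFactors = FALSE)
    exome <- pass
    nd <- config$n_decoy_variants
    if (nd > 0L) {
      g <- sample.int(config$n_genes, nd, replace = TRUE)
      dpos0 <- annotation$start[g] + 20L +
        sample.int(config$gene_len - 40L, nd, replace = TRUE) - 1L
      dref <- substring(genome[annotation$chrom[g]], dpos0 + 1L, dpos0 + 1L)
      dalt <- vapply(dref, function(r) sample(setdiff(DNA_BASES, r), 1L),
                     character(1), USE.NAMES = FALSE)
      decoy <- data.frame(chrom = annotation$chrom[g], pos = dpos0 + 1L,
                          ref = dref, alt = dalt, qual = 50,
                          dp = 30L,
                          QD = stats::runif(nd, 0, 1.9),   # fails QD > 2
                          FS = stats::runif(nd, 61, 100),  # fails FS < 60
                          SOR = stats::runif(nd, 0.5, 2.5),
                          MQ = stats::runif(nd, 50, 60),
                          MQRankSum = stats::runif(nd, -2, 2),
                          ReadPosRankSum = stats::runif(nd, -2, 2),
                          stringsAsFactors = FALSE)
      exome <- rbind(exome, decoy)
    }
    exome <- exome[order(match(exome$chrom, chroms), exome$pos), , drop = FALSE]
    rownames(exome) <- NULL
  }

  structure(list(config = config, genome = genome, chrom_lens = chrom_lens,
                 annotation = annotation, pairs = pairs,
                 alignments = alignments, exome_variants = exome,
                 truth = list(reads = truth_reads, variants = truth_variants,
                              support = truth_support)),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated 5' UMI dataset\n")
  cat(sprintf("  genome: %d contig(s) x %d bp; %d genes; %d cells\n",
              length(x$genome), x$config$chrom_len, nrow(x$annotation),
              x$config$n_cells))
  cat(sprintf("  reads: %d pairs (%s)\n", nrow(x$pairs),
              paste(sprintf("%s=%d", names(table(x$truth$reads$read_class)),
                            as.integer(table(x$truth$reads$read_class))),
                    collapse = ", ")))
  cat(sprintf("  invasion reads: %d; planted SNPs: %d\n",
              sum(x$truth$reads$is_invasion),
              if (is.null(x$truth$variants)) 0L else nrow(x$truth$variants)))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Writes genome FASTA, BED6 annotation, paired FASTQ, SAM alignments,
#' exome VCF and the TSV truth tables into `dir`.
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, a named character vector of the written paths.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             annotation = file.path(dir, "annotation.bed"),
             fastq1 = file.path(dir, "reads_R1.fastq"),
             fastq2 = file.path(dir, "reads_R2.fastq"),
             alignments = file.path(dir, "alignments.sam"),
             exome_vcf = file.path(dir, "exome.vcf"),
             truth_reads = file.path(dir, "truth_reads.tsv"),
             truth_variants = file.path(dir, "truth_variants.tsv"),
             truth_support = file.path(dir, "truth_support.tsv"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$genome),
                              paths["genome"])
  write_annotation(sim$annotation, paths["annotation"])
  write_fastq_pairs(sim$pairs, paths["fastq1"], paths["fastq2"])
  write_alignments_sam(sim$alignments, paths["alignments"], sim$chrom_lens)
  write_vcf_records(sim$exome_variants, paths["exome_vcf"])
  write_tsv_report(sim$truth$reads, paths["truth_reads"])
  if (!is.null(sim$truth$variants)) {
    write_tsv_report(sim$truth$variants, paths["truth_variants"])
    write_tsv_report(sim$truth$support, paths["truth_support"])
  }
  invisible(paths)
}

#' Downsample read pairs without replacement
#'
#' Mirrors FASTQ-level downsampling with a fixed seed: sampling is without
#' replacement, input order is preserved, and requesting at least the input
#' size returns the input unchanged.
#'
#' @param pairs data.frame of read pairs.
#' @param n_reads number of pairs to keep (clamped to the input size).
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return the downsampled pairs data.frame.
#' @export
downsample_pairs <- function(pairs, n_reads, seed = NULL) {
  if (n_reads < 0) stop("n_reads must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(pairs)
  if (n_reads >= n) return(pairs)
  keep <- sort(sample.int(n, n_reads))
  pairs[keep, , drop = FALSE]
}

#' Downsample a FASTQ pair on disk
#'
#' @param path1,path2 input FASTQ pair.
#' @param n_reads pairs to keep.
#' @param out1,out2 output paths.
#' @param seed RNG seed.
#' @return invisibly, the number of pairs written.
#' @export
downsample_fastq <- function(path1, path2, n_reads, out1, out2, seed = NULL) {
  pairs <- read_fastq_pairs(path1, path2)
  kept <- downsample_pairs(pairs, n_reads, seed)
  write_fastq_pairs(kept, out1, out2)
  invisible(nrow(kept))
}

#' Error-free per-cell variant calls from simulator truth
#'
#' The idealised calls a perfect caller would emit for one cell: one record
#' per planted SNP the cell carries, with `dp` equal to the cell's read
#' coverage at the site.  Used to benchmark the classification logic
#' independently of any caller.
#'
#' @param sim a [simulate_dataset()] result.
#' @param cell cell id.
#' @return a variant data.frame (see [read_vcf_records()]).
#' @export
truth_calls_for_cell <- function(sim, cell) {
  sup <- sim$truth$support
  if (is.null(sup)) return(empty_variants())
  sup <- sup[sup$cell == cell & sup$carrier, , drop = FALSE]
  tv <- sim$truth$variants
  idx <- match(paste(sup$chrom, sup$pos), paste(tv$chrom, tv$pos))
  out <- data.frame(chrom = sup$chrom, pos = sup$pos, ref = tv$ref[idx],
                    alt = tv$alt[idx], qual = 99, dp = sup$n_cover,
                    stringsAsFactors = FALSE)
  for (k in VCF_INFO_KEYS) out[[k]] <- NA_real_
  out[out$dp > 0L, , drop = FALSE]
}
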