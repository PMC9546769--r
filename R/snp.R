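# Per-cell SNP benchmarking against an exome-derived reference.

MITO_CONTIGS <- c("chrM", "chrMT", "MT", "M")

#' Apply GATK-style hard filters to exome variants
#'
#' Retains SNVs satisfying QD > 2, FS < 60, SOR < 3, MQ > 40,
#' MQRankSum > -12.5 and ReadPosRankSum > -8 (strict inequalities;
#' a missing annotation passes its criterion when
#' `missing_passes = TRUE`).  Indels are excluded.
#'
#' @param variants variant data.frame (see [read_vcf_records()]).
#' @param capture optional capture intervals (data.frame `chrom`, `start`,
#'   `end`, 0-based half-open); variants outside are dropped.
#' @param missing_passes whether a missing annotation passes its criterion.
#' @return an `exome_reference`: list with `variants` and `capture`.
#' @export
hard_filter_exome <- function(variants, capture = NULL,
                              missing_passes = TRUE) {
  v <- variants
  snv <- nchar(v$ref) == 1L & nchar(v$alt) == 1L & v$ref != v$alt &
    v$alt %in% DNA_BASES
  v <- v[snv, , drop = FALSE]
  crit <- function(x, pass) {
    ok <- pass(x)
    if (missing_passes) ok[is.na(x)] <- TRUE else ok[is.na(x)] <- FALSE
    ok
  }
  keep <- crit(v$QD, function(x) x > 2) &
    crit(v$FS, function(x) x < 60) &
    crit(v$SOR, function(x) x < 3) &
    crit(v$MQ, function(x) x > 40) &
    crit(v$MQRankSum, function(x) x > -12.5) &
    crit(v$ReadPosRankSum, function(x) x > -8)
  v <- v[keep, , drop = FALSE]
  if (!is.null(capture)) v <- v[in_intervals(v$chrom, v$pos, capture), ,
                                drop = FALSE]
  rownames(v) <- NULL
  structure(list(variants = v, capture = capture), class = "exome_reference")
}

# is 1-based position inside any 0-based half-open interval of `iv`?
in_intervals <- function(chrom, pos, iv) {
  if (length(chrom) == 0L) return(logical(0))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  s <- GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(iv$start + 1L, iv$end))
  GenomicRanges::countOverlaps(q, s, ignore.strand = TRUE) > 0L
}

#' Read coverage at variant positions
#'
#' Number of primary mapped alignment records overlapping each 1-based
#' position.
#'
#' @param alignments alignment data.frame.
#' @param chrom,pos vectors of positions (1-based).
#' @return integer coverage vector.
#' @export
coverage_at <- function(alignments, chrom, pos) {
  if (length(chrom) == 0L) return(integer(0))
  if (nrow(alignments) == 0L) return(rep(0L, length(chrom)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  s <- GenomicRanges::GRanges(alignments$chrom,
                              IRanges::IRanges(alignments$start + 1L,
                                               alignments$end))
  GenomicRanges::countOverlaps(q, s, ignore.strand = TRUE)
}

#' Per-cell reference SNP list
#'
#' The exome SNPs "expressed" in the cell: those whose position is covered
#' by strictly more than `min_reads` of the cell's RNA reads.
#'
#' @param exome an [hard_filter_exome()] result.
#' @param cell_alignments the cell's alignment records.
#' @param min_reads strict coverage threshold (default: more than 2 reads).
#' @return the subset of exome variants forming the cell's reference list.
#' @export
reference_list_for_cell <- function(exome, cell_alignments, min_reads = 2L) {
  v <- exome$variants
  cov <- coverage_at(cell_alignments, v$chrom, v$pos)
  v[cov > min_reads, , drop = FALSE]
}

#' Classify one cell's RNA SNP calls against the reference list
#'
#' Cell SNPs are restricted to the exome capture intervals (and
#' non-mitochondrial contigs).  TP = cell SNPs with `DP > min_dp` that
#' match the reference list; FN = reference list minus TP; FP = remaining
#' cell SNPs with `DP > min_dp`.  TP and FP are additionally reported at
#' `QUAL > qual_threshold`.
#'
#' @param cell_variants the cell's variant calls (data.frame).
#' @param ref_list the cell's reference list
#'   (see [reference_list_for_cell()]).
#' @param capture capture intervals (0-based half-open data.frame), or
#'   `NULL` to skip the restriction.
#' @param min_dp strict depth threshold.
#' @param qual_threshold strict quality threshold for the QUAL-filtered
#'   tallies.
#' @param match_alt require the alt allele to agree (not just the
#'   position).
#' @param cell cell id recorded in the output.
#' @param depth read depth label recorded in the output (NA = full).
#' @return one-row data.frame of class `snp_bench_result` with columns
#'   `cell`, `depth`, `n_reference`, `n_total_cell_snps`, `n_tp`,
#'   `n_tp_qual`, `n_fn`, `n_fp`, `n_fp_qual`, `pct_tp`.
#' @export
classify_cell_snps <- function(cell_variants, ref_list, capture = NULL,
                               min_dp = 2L, qual_threshold = 20,
                               match_alt = TRUE, cell = NA_character_,
                               depth = NA_integer_) {
  v <- cell_variants
  v <- v[!(v$chrom %in% MITO_CONTIGS), , drop = FALSE]
  v <- v[nchar(v$ref) == 1L & nchar(v$alt) == 1L & v$ref != v$alt, ,
         drop = FALSE]
  if (!is.null(capture)) v <- v[in_intervals(v$chrom, v$pos, capture), ,
                                drop = FALSE]
  v <- v[!is.na(v$dp) & v$dp > min_dp, , drop = FALSE]
  keymk <- function(d) if (match_alt) paste(d$chrom, d$pos, d$alt)
    else paste(d$chrom, d$pos)
  in_ref <- keymk(v) %in% keymk(ref_list)
  hi_q <- !is.na(v$qual) & v$qual > qual_threshold
  n_ref <- nrow(ref_list)
  n_tp <- sum(in_ref)
  res <- data.frame(cell = cell, depth = depth,
                    n_reference = n_ref,
                    n_total_cell_snps = nrow(v),
                    n_tp = n_tp,
                    n_tp_qual = sum(in_ref & hi_q),
                    n_fn = n_ref - n_tp,
                    n_fp = sum(!in_ref),
                    n_fp_qual = sum(!in_ref & hi_q),
                    pct_tp = if (n_ref > 0L) 100 * n_tp / n_ref else NA_real_,
                    stringsAsFactors = FALSE)
  class(res) <- c("snp_bench_result", class(res))
  res
}

#' Minimal pileup variant caller for simulated cells
#'
#' Calls a site when at least `min_alt_reads` non-reference reads support
#' one alternative base and the alt fraction is at least `min_alt_frac`.
#' QUAL is the Phred-scaled upper tail of a binomial sequencing-error test
#' at the site depth.  Intended for end-to-end benchmarking on simulated
#' data; real call sets from any caller are accepted by
#' [classify_cell_snps()] directly.
#'
#' @param alignments the cell's alignment records (with `seq` in
#'   genome-forward orientation).
#' @param genome named character vector of contig sequences.
#' @param min_alt_reads minimum alt-supporting reads.
#' @param min_alt_frac minimum alt fraction of the site depth.
#' @param error_rate assumed per-base error rate for the QUAL model.
#' @return a variant data.frame (chrom, pos, ref, alt, qual, dp).
#' @export
call_cell_snps <- function(alignments, genome, min_alt_reads = 2L,
                           min_alt_frac = 0.2, error_rate = 0.01) {
  a <- alignments[!is.na(alignments$seq) & alignments$seq != "*", ,
                  drop = FALSE]
  out <- empty_variants()
  if (nrow(a) == 0L) return(out)
  refseq <- substring(genome[a$chrom], a$start + 1L, a$end)
  differs <- which(a$seq != refseq & nchar(a$seq) == nchar(refseq))
  if (length(differs) == 0L) return(out)
  ev <- vector("list", length(differs))
  for (k in seq_along(differs)) {
    i <- differs[k]
    rc <- strsplit(refseq[i], "", fixed = TRUE)[[1L]]
    sc <- strsplit(a$seq[i], "", fixed = TRUE)[[1L]]
    mm <- which(rc != sc & sc %in% DNA_BASES)
    if (length(mm) == 0L) next
    ev[[k]] <- data.frame(chrom = a$chrom[i], pos = a$start[i] + mm,
                          ref = rc[mm], alt = sc[mm],
                          stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, ev)
  if (is.null(ev) || nrow(ev) == 0L) return(out)
  key <- paste(ev$chrom, ev$pos, ev$alt)
  tab <- ev[!duplicated(key), , drop = FALSE]
  tab$n_alt <- as.integer(table(key)[paste(tab$chrom, tab$pos, tab$alt)])
  tab$dp <- coverage_at(a, tab$chrom, tab$pos)
  keep <- tab$n_alt >= min_alt_reads & tab$n_alt / tab$dp >= min_alt_frac
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab) == 0L) return(out)
  p <- stats::pbinom(tab$n_alt - 1L, tab$dp, error_rate, lower.tail = FALSE)
  tab$qual <- pmin(255, -10 * log10(pmax(p, 1e-26)))
  res <- data.frame(chrom = tab$chrom, pos = tab$pos, ref = tab$ref,
                    alt = tab$alt, qual = tab$qual, dp = tab$dp,
                    stringsAsFactors = FALSE)
  for (k in VCF_INFO_KEYS) res[[k]] <- NA_real_
  res <- res[order(res$chrom, res$pos, res$alt), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' SNP benchmark across downsampled read depths
#'
#' For each requested depth the cell's reads are downsampled without
#' replacement (by read id, both mates kept together), variants are
#' re-called with [call_cell_snps()], the per-depth reference list is
#' rebuilt from the downsampled coverage, and the classification is
#' recomputed.  A depth exceeding the available reads is computed on the
#' full data and flagged.
#'
#' @param cell_alignments the cell's alignment records.
#' @param genome named contig sequences.
#' @param exome an [hard_filter_exome()] result.
#' @param depths read depths (number of read pairs).
#' @param seed RNG seed.
#' @param min_dp,qual_threshold classification thresholds.
#' @param cell cell id for the output rows.
#' @param ... passed to [call_cell_snps()].
#' @return data.frame with one `snp_bench_result` row per depth plus a
#'   `clamped` flag.
#' @export
depth_curve <- function(cell_alignments, genome, exome, depths, seed = NULL,
                        min_dp = 2L, qual_threshold = 20,
                        cell = NA_character_, ...) {
  if (any(depths < 0)) stop("depths must be nonnegative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(cell_alignments$read_id)
  rows <- lapply(depths, function(d) {
    clamped <- d > length(ids)
    a <- if (d >= length(ids)) cell_alignments else {
      keep <- sample(ids, d)
      cell_alignments[cell_alignments$read_id %in% keep, , drop = FALSE]
    }
    calls <- call_cell_snps(a, genome, ...)
    ref <- reference_list_for_cell(exome, a)
    res <- classify_cell_snps(calls, ref, exome$capture, min_dp,
                              qual_threshold, cell = cell, depth = d)
    res$clamped <- clamped
    res
  })
  do.call(rbind, rows)
}

#' Pooled SNP benchmark over aggregated cells
#'
#' Samples `k` cells, merges their reads, and runs calling and
#' classification on the pooled read set (the reference list is built from
#' the pooled coverage).
#'
#' @param alignments multi-cell alignment records (with a `cell` column).
#' @param genome named contig sequences.
#' @param exome an [hard_filter_exome()] result.
#' @param k number of cells to pool.
#' @param seed RNG seed.
#' @param min_dp,qual_threshold classification thresholds.
#' @param ... passed to [call_cell_snps()].
#' @return a `snp_bench_result` row; the sampled cell ids are in the
#'   `cells` attribute.
#' @export
aggregate_cells <- function(alignments, genome, exome, k, seed = NULL,
                            min_dp = 2L, qual_threshold = 20, ...) {
  cells <- sort(unique(alignments$cell))
  if (k > length(cells)) stop("k exceeds the number of cells", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pick <- sort(sample(cells, k))
  a <- alignments[alignments$cell %in% pick, , drop = FALSE]
  calls <- call_cell_snps(a, genome, ...)
  ref <- reference_list_for_cell(exome, a)
  res <- classify_cell_snps(calls, ref, exome$capture, min_dp, qual_threshold,
                            cell = sprintf("pool_of_%d", k))
  attr(res, "cells") <- pick
  res
}
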