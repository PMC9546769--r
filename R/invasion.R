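# Strand-invasion artifact detection, quantification and filtering.
#
# A strand-invasion artifact arises when the TSO anneals to an internal
# genomic/cDNA sequence instead of the appended C-tail: the read's "UMI"
# then duplicates the genomic sequence upstream of the read start.  Such
# reads are recognised by matching the UMI against the strand-aware 20-bp
# upstream context, allowing 0-3 consecutive 5' mismatches and optionally
# requiring the GGG / spacer+GGG motif left by the annealed TSO tail.

#' Attach the strand-aware upstream genomic context to UMI reads
#'
#' Keeps mate-1 records that carry a UMI.  For a + read starting at `start`
#' the context is `genome[start-window, start)`; for a - read ending at
#' `end` it is the reverse complement of `genome[end, end+window)`.  The
#' context string is therefore written in the read's own orientation with
#' its last character adjacent to the read start.  Reads whose window runs
#' off the contig edge (or whose contig is absent from the genome) are
#' dropped and counted.
#'
#' @param alignments alignment data.frame (see [read_alignments()]).
#' @param genome named character vector of contig sequences, or a
#'   `DNAStringSet`.
#' @param window upstream context width (bp).
#' @return data.frame of aligned UMI reads with `read_start` (5'
#'   coordinate) and `upstream` columns; attributes `n_dropped_edge` and
#'   `n_dropped_chrom` count excluded reads.
#' @export
annotate_upstream <- function(alignments, genome, window = 20L) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  r <- alignments[alignments$mate == 1L & !is.na(alignments$umi), ,
                  drop = FALSE]
  known <- r$chrom %in% names(genome)
  n_chrom <- sum(!known)
  if (n_chrom > 0L) {
    warning(sprintf("%d read(s) on contigs absent from the genome dropped",
                    n_chrom))
    r <- r[known, , drop = FALSE]
  }
  clen <- nchar(genome)[r$chrom]
  plus <- r$strand == "+"
  fits <- ifelse(plus, r$start - window >= 0L, r$end + window <= clen)
  n_edge <- sum(!fits)
  r <- r[fits, , drop = FALSE]
  plus <- plus[fits]
  up <- character(nrow(r))
  up[plus] <- substring(genome[r$chrom[plus]], r$start[plus] - window + 1L,
                        r$start[plus])
  up[!plus] <- revcomp(substring(genome[r$chrom[!plus]], r$end[!plus] + 1L,
                                 r$end[!plus] + window))
  r$read_start <- ifelse(plus, r$start, r$end)
  r$upstream <- up
  attr(r, "n_dropped_edge") <- n_edge
  attr(r, "n_dropped_chrom") <- n_chrom
  r
}

#' Collapse PCR duplicates of 5' UMI reads
#'
#' Reads sharing the same UMI sequence, mapping position (5' coordinate and
#' strand) and adjacent read-start sequence are collapsed to one
#' representative (the first encountered); the operation is idempotent.
#'
#' @param reads data.frame from [annotate_upstream()].
#' @return the deduplicated data.frame.
#' @export
dedup_5p <- function(reads) {
  key <- paste(reads$umi, reads$chrom, reads$read_start, reads$strand,
               reads$upstream, sep = "\r")
  reads[!duplicated(key), , drop = FALSE]
}

#' Match a UMI against its upstream context
#'
#' For mismatch level `m`, the query is the 3' `(8-m)`-suffix of the UMI
#' followed by the motif string (empty, `GGG`, or spacer+`GGG`); a match at
#' level `m` is an exact occurrence of that query anywhere within the
#' upstream window (or, with `adjacent_only`, ending exactly at the read
#' start).  Returns the smallest matching level, or `NA` when none
#' matches at level `<= max_mismatch`.
#'
#' @param umi,upstream character vectors (recycled to a common length);
#'   UMIs must be 8 nt.
#' @param max_mismatch maximum number of consecutive 5' mismatches
#'   forgiven, 0-3.
#' @param motif `"none"`, `"GGG"` or `"spacer_GGG"`.
#' @param spacer spacer sequence (used when `motif = "spacer_GGG"`).
#' @param adjacent_only require the query to end at the read start instead
#'   of anywhere in the window.
#' @return integer vector of minimal matching levels (NA = no match).
#' @export
match_umi_upstream <- function(umi, upstream, max_mismatch = 3L,
                               motif = c("none", "GGG", "spacer_GGG"),
                               spacer = "CTAAC", adjacent_only = FALSE) {
  motif <- match.arg(motif)
  if (max_mismatch < 0L || max_mismatch > 3L)
    stop("max_mismatch must be in 0..3", call. = FALSE)
  if (any(nchar(umi) != 8L)) stop("UMIs must be 8 nt", call. = FALSE)
  n <- max(length(umi), length(upstream))
  umi <- rep_len(umi, n); upstream <- rep_len(upstream, n)
  mstr <- switch(motif, none = "", GGG = "GGG",
                 spacer_GGG = paste0(spacer, "GGG"))
  res <- rep(NA_integer_, n)
  todo <- seq_len(n)
  for (m in 0:max_mismatch) {
    if (length(todo) == 0L) break
    query <- paste0(substring(umi[todo], m + 1L), mstr)
    hit <- if (adjacent_only) {
      endsWith(upstream[todo], query)
    } else {
      vapply(seq_along(todo), function(i)
        grepl(query[i], upstream[todo[i]], fixed = TRUE), logical(1))
    }
    res[todo[hit]] <- m
    todo <- todo[!hit]
  }
  res
}

#' Analytic random-match probability
#'
#' Probability that a fixed query of length `q = 8 - m + len(motif)`
#' occurs in a `window`-long i.i.d. uniform-base sequence, approximated as
#' `1 - (1 - 4^-q)^(window - q + 1)`.
#'
#' @param m mismatch level(s).
#' @param motif_len motif length added to the query (0, 3, or
#'   `len(spacer)+3`).
#' @param window upstream window width.
#' @return numeric vector of probabilities.
#' @export
invasion_null_prob <- function(m, motif_len = 0L, window = 20L) {
  q <- 8L - m + motif_len
  1 - (1 - 4^-q)^(window - q + 1L)
}

#' Quantify UMI-to-upstream matches on deduplicated reads
#'
#' For every mismatch level 0-3 and motif mode (none / GGG / spacer+GGG),
#' counts deduplicated UMI reads whose UMI matches the upstream context at
#' that level or lower, with the analytic uniform-base null alongside.
#'
#' @param reads deduplicated reads from [dedup_5p()].
#' @param oligo an [oligo_config()] (supplies the spacer).
#' @param max_mismatch highest mismatch level reported.
#' @param window upstream window width used during annotation.
#' @param adjacent_only passed to [match_umi_upstream()].
#' @return an `invasion_report`: list with `n_dedup_reads`, `table`
#'   (motif x level counts, percentages, null percentages) and, when the
#'   reads carry a `feature` column, a `per_feature` breakdown.
#' @export
invasion_report <- function(reads, oligo = oligo_config(), max_mismatch = 3L,
                            window = 20L, adjacent_only = FALSE) {
  n <- nrow(reads)
  modes <- c("none", "GGG", "spacer_GGG")
  mlen <- c(none = 0L, GGG = 3L,
            spacer_GGG = nchar(oligo$spacer) + 3L)
  tab <- do.call(rbind, lapply(modes, function(mode) {
    lev <- if (n > 0L)
      match_umi_upstream(reads$umi, reads$upstream, max_mismatch, mode,
                         oligo$spacer, adjacent_only)
    else integer(0)
    data.frame(motif = mode, mismatch = 0:max_mismatch,
               n_match = vapply(0:max_mismatch, function(m)
                 sum(!is.na(lev) & lev <= m), integer(1)),
               null_pct = 100 * invasion_null_prob(0:max_mismatch,
                                                   mlen[[mode]], window),
               stringsAsFactors = FALSE)
  }))
  tab$pct <- if (n > 0L) 100 * tab$n_match / n else NA_real_
  tab <- tab[, c("motif", "mismatch", "n_match", "pct", "null_pct")]
  per_feature <- NULL
  if (n > 0L && "feature" %in% names(reads)) {
    lev0 <- match_umi_upstream(reads$umi, reads$upstream, max_mismatch,
                               "none", oligo$spacer, adjacent_only)
    per_feature <- do.call(rbind, lapply(split(seq_len(n), reads$feature),
                                         function(ix) {
      data.frame(feature = reads$feature[ix[1L]], n = length(ix),
                 n_match0 = sum(!is.na(lev0[ix]) & lev0[ix] == 0L),
                 pct_match0 = 100 * mean(!is.na(lev0[ix]) & lev0[ix] == 0L),
                 stringsAsFactors = FALSE)
    }))
    rownames(per_feature) <- NULL
  }
  structure(list(n_dedup_reads = n, table = tab, per_feature = per_feature,
                 window = window, adjacent_only = adjacent_only),
            class = "invasion_report")
}

#' @export
print.invasion_report <- function(x, ...) {
  cat(sprintf("Strand-invasion report (%d deduplicated UMI reads, %d-bp window)\n",
              x$n_dedup_reads, x$window))
  if (x$n_dedup_reads == 0L) {
    cat("  no reads: percentages undefined\n")
    return(invisible(x))
  }
  print(transform(x$table, pct = round(pct, 3), null_pct = signif(null_pct, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Remove strand-invasion reads
#'
#' Discards reads whose UMI matches the upstream context at
#' `<= max_mismatch` consecutive 5' mismatches (no motif requirement by
#' default, matching the production filter's `max.mismatch = 1`
#' behaviour).  Applied per read, before deduplication and counting.
#'
#' @param reads data.frame from [annotate_upstream()].
#' @param max_mismatch mismatch forgiveness level, 0-3.
#' @param motif,spacer optional motif conditioning, see
#'   [match_umi_upstream()].
#' @return list with `retained` (data.frame) and `n_removed`.
#' @export
filter_invasion <- function(reads, max_mismatch = 1L, motif = "none",
                            spacer = "CTAAC") {
  lev <- if (nrow(reads) > 0L)
    match_umi_upstream(reads$umi, reads$upstream, max_mismatch, motif, spacer)
  else integer(0)
  bad <- !is.na(lev)
  list(retained = reads[!bad, , drop = FALSE], n_removed = sum(bad))
}

#' Nucleotide profile adjacent to the read start
#'
#' Samples up to `n_sample` deduplicated reads without replacement and
#' tallies the base composition at the `window` positions immediately 5'
#' of the read start (the last `window` characters of the upstream
#' context).
#'
#' @param reads deduplicated reads from [dedup_5p()].
#' @param window number of positions profiled.
#' @param n_sample reads sampled.
#' @param seed RNG seed (`NULL`: current RNG state).
#' @return 4 x `window` matrix of base frequencies; columns named by
#'   offset (-window .. -1), each column summing to 1.
#' @export
readstart_profile <- function(reads, window = 6L, n_sample = 500000L,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(reads)
  if (n > n_sample) reads <- reads[sort(sample.int(n, n_sample)), , drop = FALSE]
  tail6 <- substring(reads$upstream, nchar(reads$upstream) - window + 1L)
  mat <- matrix(0, 4L, window,
                dimnames = list(DNA_BASES, sprintf("%d", -(window:1))))
  if (nrow(reads) == 0L) return(mat)
  ch <- matrix(unlist(strsplit(tail6, "", fixed = TRUE)), ncol = window,
               byrow = TRUE)
  for (j in seq_len(window)) {
    t <- table(factor(ch[, j], levels = DNA_BASES))
    mat[, j] <- as.numeric(t) / sum(t)
  }
  mat
}

#' Assign reads to exonic/intronic/intergenic features
#'
#' Largest-overlap, unstranded assignment against the annotation intervals
#' (rows may carry a `type` column, `"exon"`/`"intron"`; absent means
#' exon).  Also reports, per read, whether its strand opposes the assigned
#' gene's strand (antisense diagnostic).
#'
#' @param reads alignment-record data.frame.
#' @param annotation annotation data.frame (see [read_annotation()]).
#' @param min_overlap_frac minimum overlap fraction of the read length.
#' @return `reads` with `feature` (`exonic`/`intronic`/`intergenic`),
#'   `feature_gene` and `antisense` columns.
#' @export
assign_features <- function(reads, annotation, min_overlap_frac = 0.25) {
  type <- if ("type" %in% names(annotation)) annotation$type else
    rep("exon", nrow(annotation))
  rgr <- GenomicRanges::GRanges(reads$chrom,
                                IRanges::IRanges(reads$start + 1L, reads$end))
  agr <- GenomicRanges::GRanges(annotation$chrom,
                                IRanges::IRanges(annotation$start + 1L,
                                                 annotation$end))
  ov <- GenomicRanges::findOverlaps(rgr, agr, ignore.strand = TRUE)
  w <- GenomicRanges::width(IRanges::pintersect(
    rgr[S4Vectors::queryHits(ov)], agr[S4Vectors::subjectHits(ov)]))
  frac <- w / (reads$end - reads$start)[S4Vectors::queryHits(ov)]
  keep <- frac >= min_overlap_frac
  qh <- S4Vectors::queryHits(ov)[keep]; sh <- S4Vectors::subjectHits(ov)[keep]
  wk <- w[keep]
  best <- tapply(seq_along(qh), qh, function(ix) ix[which.max(wk[ix])])
  reads$feature <- "intergenic"
  reads$feature_gene <- NA_character_
  reads$antisense <- NA
  if (length(best) > 0L) {
    ri <- as.integer(names(best)); ai <- sh[unlist(best)]
    reads$feature[ri] <- ifelse(type[ai] == "intron", "intronic", "exonic")
    reads$feature_gene[ri] <- annotation$gene[ai]
    reads$antisense[ri] <- reads$strand[ri] != annotation$strand[ai]
  }
  reads
}
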