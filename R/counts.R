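# Per-gene molecule counting and the UMI edit-distance diagnostic.

#' Assign alignment records to genes by exonic overlap
#'
#' featureCounts-style assignment: a read is assigned to a gene when at
#' least `min_overlap_frac` of its aligned length overlaps the gene's
#' exonic intervals; reads reaching the threshold for more than one gene
#' are discarded as ambiguous.  UMI reads are assigned stranded (read
#' strand must equal gene strand), internal reads unstranded.
#'
#' @param alignments alignment data.frame (mate-1 records are used).
#' @param annotation annotation data.frame; rows with a `type` column other
#'   than `"exon"` are ignored.
#' @param stranded require read strand to match gene strand.
#' @param min_overlap_frac minimum overlap fraction of the aligned length.
#' @return the mate-1 records with the `gene` column replaced by the
#'   assignment (`NA` = unassigned or ambiguous).
#' @export
assign_genes <- function(alignments, annotation, stranded = FALSE,
                         min_overlap_frac = 0.25) {
  r <- alignments[alignments$mate == 1L, , drop = FALSE]
  exons <- annotation
  if ("type" %in% names(exons)) exons <- exons[exons$type == "exon", ,
                                               drop = FALSE]
  rgr <- GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$start + 1L, r$end))
  egr <- GenomicRanges::GRanges(exons$chrom,
                                IRanges::IRanges(exons$start + 1L, exons$end))
  ov <- GenomicRanges::findOverlaps(rgr, egr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  if (stranded) {
    keep <- r$strand[qh] == exons$strand[sh]
    qh <- qh[keep]; sh <- sh[keep]
  }
  w <- pmin(r$end[qh], exons$end[sh]) - pmax(r$start[qh], exons$start[sh])
  # per (read, gene) total exonic overlap, then the fraction threshold
  key <- paste(qh, exons$gene[sh], sep = "\r")
  agg <- tapply(w, key, sum)
  kread <- as.integer(sub("\r.*", "", names(agg)))
  kgene <- sub(".*\r", "", names(agg))
  frac <- as.numeric(agg) / (r$end - r$start)[kread]
  ok <- frac >= min_overlap_frac
  kread <- kread[ok]; kgene <- kgene[ok]
  nhit <- table(kread)
  unambig <- as.integer(names(nhit)[nhit == 1L])
  r$gene <- NA_character_
  sel <- kread %in% unambig
  r$gene[kread[sel]] <- kgene[sel]
  r
}

# Directional single-linkage collapse of a UMI multiset: an edge runs from
# a to b when hamming(a, b) == 1 and count(a) >= 2*count(b) - 1; nodes are
# processed in descending count, ties broken lexicographically.  Returns
# the number of connected components.
directional_components <- function(umis) {
  cnt <- table(umis)
  u <- names(cnt)
  n <- length(u)
  if (n <= 1L) return(n)
  cnt <- as.integer(cnt)
  ord <- order(-cnt, u)
  u <- u[ord]; cnt <- cnt[ord]
  ch <- do.call(rbind, strsplit(u, "", fixed = TRUE))
  hd1 <- function(i, j) sum(ch[i, ] != ch[j, ]) == 1L
  visited <- rep(FALSE, n)
  ncomp <- 0L
  for (root in seq_len(n)) {
    if (visited[root]) next
    ncomp <- ncomp + 1L
    queue <- root; visited[root] <- TRUE
    while (length(queue) > 0L) {
      i <- queue[1L]; queue <- queue[-1L]
      for (j in which(!visited)) {
        if (cnt[i] >= 2L * cnt[j] - 1L && hd1(i, j)) {
          visited[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
  }
  ncomp
}

#' Count molecules per gene and cell from UMI reads
#'
#' `unique`: number of distinct UMI sequences per (gene, cell).
#' `directional`: network-adjacency collapse -- UMIs within Hamming
#' distance 1 are merged when the larger count satisfies
#' `count(a) >= 2*count(b) - 1`, and components are counted.
#'
#' @param reads data.frame of UMI reads with `gene`, `cell` and `umi`
#'   columns (unassigned reads are ignored).
#' @param method `"unique"` or `"directional"`.
#' @param genes,cells optional row/column universe for the output matrix
#'   (defaults to the ids observed).
#' @return a [gene_count_matrix()] with `read_type = "umi"`.
#' @export
count_molecules <- function(reads, method = c("unique", "directional"),
                            genes = NULL, cells = NULL) {
  method <- match.arg(method)
  r <- reads[!is.na(reads$gene) & !is.na(reads$umi), , drop = FALSE]
  genes <- genes %||% sort(unique(r$gene))
  cells <- cells %||% sort(unique(r$cell))
  m <- matrix(0L, length(genes), length(cells),
              dimnames = list(genes, cells))
  if (nrow(r) > 0L) {
    key <- split(r$umi, list(factor(r$gene, genes), factor(r$cell, cells)),
                 sep = "\r")
    nonempty <- key[lengths(key) > 0L]
    vals <- vapply(nonempty, function(us) {
      if (method == "unique") length(unique(us)) else directional_components(us)
    }, integer(1))
    gk <- sub("\r.*", "", names(nonempty))
    ck <- sub(".*\r", "", names(nonempty))
    m[cbind(match(gk, genes), match(ck, cells))] <- vals
  }
  gene_count_matrix(m, "umi")
}

#' Count internal (non-UMI) reads per gene and cell
#'
#' Unstranded featureCounts-style assignment of internal reads followed by
#' a plain read count per (gene, cell).
#'
#' @param alignments alignment records of internal reads.
#' @param annotation annotation data.frame.
#' @param min_overlap_frac minimum exonic overlap fraction.
#' @param genes,cells optional output universe.
#' @return a [gene_count_matrix()] with `read_type = "internal"`.
#' @export
count_internal <- function(alignments, annotation, min_overlap_frac = 0.25,
                           genes = NULL, cells = NULL) {
  a <- assign_genes(alignments, annotation, stranded = FALSE,
                    min_overlap_frac = min_overlap_frac)
  a <- a[!is.na(a$gene), , drop = FALSE]
  genes <- genes %||% sort(unique(annotation$gene))
  cells <- cells %||% sort(unique(a$cell))
  m <- matrix(0L, length(genes), length(cells),
              dimnames = list(genes, cells))
  if (nrow(a) > 0L) {
    t <- table(factor(a$gene, genes), factor(a$cell, cells))
    m[] <- as.integer(t)
  }
  gene_count_matrix(m, "internal")
}

#' UMI edit-distance diagnostic against a pooled-resampling null
#'
#' Observed: pairwise edit distances between the distinct UMIs assigned to
#' the same gene.  Null: the same per-gene set sizes drawn from the pooled
#' UMI set across genes, repeated `n_null_draws` times.  If UMIs attach to
#' genes at random the two distributions coincide; an excess of small
#' observed distances indicates UMI inflation (PCR/sequencing-error
#' families surviving deduplication).  Compared by a two-sided
#' Wilcoxon rank-sum test.
#'
#' @param umi_sets data.frame with `gene` and `umi` columns (one row per
#'   deduplicated UMI; a `cell` column, if present, is combined with the
#'   gene so pooling respects cells).
#' @param n_null_draws null resampling repetitions.
#' @param seed RNG seed (`NULL`: current RNG state).
#' @param metric `"levenshtein"` (edit distance) or `"hamming"`.
#' @return an `edit_distance_diagnostic`: observed/null distance vectors,
#'   their distributions over 0..8, the rank-sum p-value, and pair counts.
#'   `computable = FALSE` when no gene has two UMIs.
#' @export
edit_distance_diagnostic <- function(umi_sets, n_null_draws = 10L,
                                     seed = NULL,
                                     metric = c("levenshtein", "hamming")) {
  metric <- match.arg(metric)
  if (!is.null(seed)) set.seed(seed)
  grp <- if ("cell" %in% names(umi_sets))
    paste(umi_sets$gene, umi_sets$cell) else umi_sets$gene
  sets <- lapply(split(umi_sets$umi, grp), unique)
  sizes <- lengths(sets)
  if (all(sizes < 2L)) {
    return(structure(list(computable = FALSE), class = "edit_distance_diagnostic"))
  }
  dist_fun <- if (metric == "levenshtein") {
    function(us) as.integer(utils::adist(us)[lower.tri(diag(length(us)))])
  } else {
    function(us) {
      ch <- do.call(rbind, strsplit(us, "", fixed = TRUE))
      n <- length(us)
      out <- integer(0)
      for (i in seq_len(n - 1L))
        for (j in (i + 1L):n)
          out <- c(out, sum(ch[i, ] != ch[j, ]))
      out
    }
  }
  obs <- unlist(lapply(sets[sizes >= 2L], dist_fun), use.names = FALSE)
  pool <- unlist(sets, use.names = FALSE)
  null <- unlist(lapply(seq_len(n_null_draws), function(k) {
    unlist(lapply(sizes[sizes >= 2L], function(s)
      dist_fun(sample(pool, s))), use.names = FALSE)
  }), use.names = FALSE)
  wt <- stats::wilcox.test(obs, null, exact = FALSE)
  distr <- function(d) as.numeric(table(factor(d, levels = 0:8)) / length(d))
  structure(list(computable = TRUE,
                 observed = obs, null = null,
                 observed_distribution = distr(obs),
                 null_distribution = distr(null),
                 statistic = unname(wt$statistic), p_value = wt$p.value,
                 n_pairs = c(observed = length(obs), null = length(null)),
                 metric = metric),
            class = "edit_distance_diagnostic")
}

#' @export
print.edit_distance_diagnostic <- function(x, ...) {
  cat("UMI edit-distance diagnostic\n")
  if (!isTRUE(x$computable)) {
    cat("  not computable: no gene carries two UMIs\n")
    return(invisible(x))
  }
  cat(sprintf("  %d observed pairs vs %d null pairs (%s distance)\n",
              x$n_pairs[["observed"]], x$n_pairs[["null"]], x$metric))
  cat(sprintf("  mean distance: observed %.3f, null %.3f\n",
              mean(x$observed), mean(x$null)))
  cat(sprintf("  two-sided rank-sum p = %.3g\n", x$p_value))
  invisible(x)
}
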