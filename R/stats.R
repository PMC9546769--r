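# Gene-detection, saturation, diversity and correlation statistics.

#' Genes detected per cell at read thresholds
#'
#' @param mat a [gene_count_matrix()] (or plain matrix).
#' @param thresholds strict read thresholds; a gene is detected in a cell
#'   when its count is strictly greater than the threshold.
#' @return data.frame with `cell`, `threshold`, `n_genes` and `read_type`.
#' @export
genes_detected <- function(mat, thresholds = c(0L, 5L)) {
  rt <- attr(mat, "read_type") %||% NA_character_
  m <- unclass(mat)
  out <- do.call(rbind, lapply(thresholds, function(th) {
    data.frame(cell = colnames(m) %||% character(0),
               threshold = th,
               n_genes = as.integer(colSums(m > th)),
               stringsAsFactors = FALSE)
  }))
  out$read_type <- rt
  rownames(out) <- NULL
  out
}

#' Gene-detection saturation across read depths
#'
#' For each cell and depth, reads are downsampled without replacement and
#' the number of genes with strictly more than `threshold` reads is
#' recounted.
#'
#' @param reads data.frame of gene-assigned reads with `cell` and `gene`
#'   columns (one row per read; unassigned rows are ignored).
#' @param depths read depths, ascending.
#' @param seed RNG seed (`NULL`: current RNG state).
#' @param thresholds strict detection thresholds.
#' @return data.frame with `cell`, `depth`, `threshold`, `n_genes`.
#' @export
saturation_curve <- function(reads, depths, seed = NULL,
                             thresholds = c(0L, 5L)) {
  if (is.unsorted(depths)) stop("depths must be sorted ascending", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  r <- reads[!is.na(reads$gene), , drop = FALSE]
  out <- list()
  for (cl in sort(unique(r$cell))) {
    g <- r$gene[r$cell == cl]
    for (d in depths) {
      gs <- if (d >= length(g)) g else sample(g, d)
      cnt <- table(gs)
      for (th in thresholds) {
        out[[length(out) + 1L]] <- data.frame(
          cell = cl, depth = d, threshold = th,
          n_genes = sum(cnt > th), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(cell = character(0), depth = integer(0),
                      threshold = integer(0), n_genes = integer(0)))
  do.call(rbind, out)
}

#' Resampled gene-diversity statistic per cell type
#'
#' Each iteration samples `n_cells` cells of a type without replacement
#' and counts the genes detected (count > 0) in strictly more than
#' `min_cells` of the sampled cells.  Cell types with fewer than `n_cells`
#' cells are excluded with a warning.
#'
#' @param mat a [gene_count_matrix()]; for the usual UMI-plus-internal
#'   usage, sum the two matrices first.
#' @param cell_types named character vector mapping cell id to type (or a
#'   vector aligned with `colnames(mat)`).
#' @param n_cells cells sampled per iteration.
#' @param n_iter iterations.
#' @param min_cells strict supporting-cell threshold.
#' @param seed RNG seed (`NULL`: current RNG state).
#' @return a `diversity_result`: list with `values` (data.frame
#'   `cell_type`, `iteration`, `n_genes`) and `summary` (median and IQR
#'   per type).
#' @export
gene_diversity <- function(mat, cell_types, n_cells = 10L, n_iter = 100L,
                           min_cells = 2L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- unclass(mat)
  if (is.null(names(cell_types))) {
    stopifnot(length(cell_types) == ncol(m))
    names(cell_types) <- colnames(m)
  }
  cell_types <- cell_types[colnames(m)]
  vals <- list()
  for (ty in sort(unique(unname(cell_types)))) {
    cols <- which(cell_types == ty)
    if (length(cols) < n_cells) {
      warning(sprintf("cell type '%s' has %d < %d cells; excluded",
                      ty, length(cols), n_cells))
      next
    }
    ng <- vapply(seq_len(n_iter), function(it) {
      pick <- sample(cols, n_cells)
      sum(rowSums(m[, pick, drop = FALSE] > 0L) > min_cells)
    }, numeric(1))
    vals[[ty]] <- data.frame(cell_type = ty, iteration = seq_len(n_iter),
                             n_genes = as.integer(ng),
                             stringsAsFactors = FALSE)
  }
  values <- if (length(vals)) do.call(rbind, vals) else
    data.frame(cell_type = character(0), iteration = integer(0),
               n_genes = integer(0))
  rownames(values) <- NULL
  summ <- if (nrow(values) > 0L) {
    do.call(rbind, lapply(split(values, values$cell_type), function(d)
      data.frame(cell_type = d$cell_type[1L],
                 median = stats::median(d$n_genes),
                 iqr = stats::IQR(d$n_genes), stringsAsFactors = FALSE)))
  } else data.frame(cell_type = character(0), median = numeric(0),
                    iqr = numeric(0))
  rownames(summ) <- NULL
  structure(list(values = values, summary = summ, n_cells = n_cells,
                 n_iter = n_iter, min_cells = min_cells),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf("Gene diversity: %d cells resampled %d times, genes in > %d cells\n",
              x$n_cells, x$n_iter, x$min_cells))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Cell-to-cell Kendall correlation on shared genes
#'
#' Kendall's tau-b rank correlation (tie-corrected) between cells, using
#' only genes expressed in all compared units: with `groups`, the shared
#' gene set is fixed to genes with a positive summed count in every group;
#' without, each pair uses the genes positive in both of its cells.
#'
#' @param mat a [gene_count_matrix()] or plain matrix.
#' @param cells cells to compare (default: all columns).
#' @param groups optional named character vector mapping cell to group.
#' @return symmetric correlation matrix with unit diagonal; `NA` marks a
#'   pair with an empty shared gene set.
#' @export
cell_correlation <- function(mat, cells = NULL, groups = NULL) {
  m <- unclass(mat)
  cells <- cells %||% colnames(m)
  if (length(cells) < 2L) stop("need at least 2 cells", call. = FALSE)
  m <- m[, cells, drop = FALSE]
  shared_fixed <- NULL
  if (!is.null(groups)) {
    groups <- groups[cells]
    gs <- vapply(split(seq_along(cells), unname(groups)), function(ix)
      rowSums(m[, ix, drop = FALSE]) > 0L, logical(nrow(m)))
    shared_fixed <- which(rowSums(gs) == ncol(gs))
  }
  k <- length(cells)
  out <- matrix(NA_real_, k, k, dimnames = list(cells, cells))
  diag(out) <- 1
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      sh <- shared_fixed %||% which(m[, i] > 0L & m[, j] > 0L)
      if (length(sh) == 0L) next
      out[i, j] <- out[j, i] <-
        stats::cor(m[sh, i], m[sh, j], method = "kendall")
    }
  }
  out
}
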