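# Readers/writers for the standard formats the pipeline touches.  All other
# modules are format-agnostic: they consume the plain data.frame record
# types produced here.
#
# Coordinate convention: 0-based half-open everywhere internally; converted
# at the SAM (1-based pos) and VCF (1-based pos) boundaries.

#' Read a pair of synchronized FASTQ files
#'
#' @param path1,path2 FASTQ files for mate 1 and mate 2, records
#'   synchronized by order.
#' @return data.frame with columns `read_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2` (one row per pair).
#' @export
read_fastq_pairs <- function(path1, path2) {
  r1 <- read_fastq_one(path1)
  r2 <- read_fastq_one(path2)
  if (nrow(r1) != nrow(r2)) {
    stop(sprintf("FASTQ record counts differ: %d in %s vs %d in %s",
                 nrow(r1), path1, nrow(r2), path2), call. = FALSE)
  }
  data.frame(read_id = r1$id, seq1 = r1$seq, qual1 = r1$qual,
             seq2 = r2$seq, qual2 = r2$qual, stringsAsFactors = FALSE)
}

read_fastq_one <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ss <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stop(sprintf("malformed FASTQ %s: %s", path,
                                     conditionMessage(e)), call. = FALSE))
  ids <- sub("\\s.*$", "", names(ss))
  ids <- sub("/[12]$", "", ids)
  data.frame(id = ids, seq = as.character(ss),
             qual = as.character(S4Vectors::mcols(ss)$qualities),
             stringsAsFactors = FALSE)
}

#' Write a pair of FASTQ files
#'
#' @param pairs data.frame as returned by [read_fastq_pairs()].
#' @param path1,path2 output paths.
#' @return invisibly, the pair count written.
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  write_fastq_one(pairs$read_id, pairs$seq1, pairs$qual1, path1)
  write_fastq_one(pairs$read_id, pairs$seq2, pairs$qual2, path2)
  invisible(nrow(pairs))
}

write_fastq_one <- function(ids, seqs, quals, path) {
  n <- length(ids)
  if (n == 0L) { writeLines(character(0), path); return(invisible(0L)) }
  lines <- character(4L * n)
  lines[seq(1L, by = 4L, length.out = n)] <- paste0("@", ids)
  lines[seq(2L, by = 4L, length.out = n)] <- seqs
  lines[seq(3L, by = 4L, length.out = n)] <- "+"
  lines[seq(4L, by = 4L, length.out = n)] <- quals
  writeLines(lines, path)
  invisible(n)
}

# ---- alignments (SAM/BAM) --------------------------------------------------

empty_alignments <- function() {
  data.frame(read_id = character(0), chrom = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             mate = integer(0), mapq = integer(0), umi = character(0),
             gene = character(0), cell = character(0), seq = character(0),
             stringsAsFactors = FALSE)
}

# Reference-space width of a CIGAR string (M/D/N/=/X consume reference).
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1L]]
    n <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Read mapped primary alignments from SAM/BAM
#'
#' Unmapped and secondary/supplementary records are excluded; only primary
#' alignments of mapped reads enter downstream stages.
#'
#' @param path a BAM file, or a SAM text file (converted on the fly).
#' @param region optional region string `"chrom:start-end"` (1-based,
#'   inclusive); requires a BAM index.
#' @return data.frame of alignment records with 0-based half-open `start`,
#'   `end`, `strand` (+/-), `mate` (1/2), `mapq`, and optional `umi`,
#'   `gene`, `cell`, `seq` columns (NA where absent).
#' @export
read_alignments <- function(path, region = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
  }
  param_args <- list(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar", "seq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    tag = c("RX", "XT", "CB"))
  if (!is.null(region)) {
    if (!file.exists(paste0(bam, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", bam))) {
      stop("region requested but no index found for ", bam, call. = FALSE)
    }
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1L]]
    if (length(m) != 4L) stop("malformed region: ", region, call. = FALSE)
    param_args$which <- GenomicRanges::GRanges(
      m[2L], IRanges::IRanges(as.integer(m[3L]), as.integer(m[4L])))
  }
  res <- Rsamtools::scanBam(bam, param = do.call(Rsamtools::ScanBamParam,
                                                 param_args))[[1L]]
  n <- length(res$qname)
  if (n == 0L) return(empty_alignments())
  start0 <- res$pos - 1L
  width <- cigar_ref_width(res$cigar)
  mate <- ifelse(bitwAnd(res$flag, 128L) > 0L, 2L, 1L)
  umi <- res$tag$RX %||% rep(NA_character_, n)
  # fall back on the <name>_<umi> read-name convention
  miss <- is.na(umi)
  cand <- sub("^.*_", "", res$qname[miss])
  umi[miss][grepl("^[ACGTN]{8}$", cand)] <- cand[grepl("^[ACGTN]{8}$", cand)]
  data.frame(read_id = res$qname, chrom = as.character(res$rname),
             start = start0, end = start0 + width,
             strand = as.character(res$strand), mate = mate,
             mapq = as.integer(res$mapq),
             umi = umi,
             gene = res$tag$XT %||% rep(NA_character_, n),
             cell = res$tag$CB %||% rep(NA_character_, n),
             seq = as.character(res$seq),
             stringsAsFactors = FALSE)
}

#' Write alignment records as SAM text
#'
#' Records are written as primary, mapped, paired records with the sequence
#' in genome-forward orientation and an all-match CIGAR.  UMI, gene and
#' cell labels travel in the `RX`, `XT` and `CB` tags.
#'
#' @param aln alignment data.frame (see [read_alignments()]).
#' @param path output `.sam` path.
#' @param chrom_lens named integer vector of contig lengths for the header.
#' @param sort write records sorted by (chrom, start) so the file can be
#'   converted/indexed directly.
#' @return invisibly, `path`.
#' @export
write_alignments_sam <- function(aln, path, chrom_lens, sort = TRUE) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lens),
                   as.integer(chrom_lens)))
  if (nrow(aln) > 0L && sort) {
    aln <- aln[order(match(aln$chrom, names(chrom_lens)), aln$start,
                     aln$read_id, aln$mate), , drop = FALSE]
  }
  recs <- character(0)
  if (nrow(aln) > 0L) {
    flag <- 1L + ifelse(aln$mate == 2L, 128L, 64L) +
      ifelse(aln$strand == "-", 16L, 0L)
    seq <- if ("seq" %in% names(aln)) aln$seq else rep("*", nrow(aln))
    seq[is.na(seq)] <- "*"
    cigar <- ifelse(seq == "*", paste0(aln$end - aln$start, "M"),
                    paste0(nchar(seq), "M"))
    tags <- paste0(ifelse(is.na(aln$umi), "", paste0("\tRX:Z:", aln$umi)),
                   ifelse(is.na(aln$gene), "", paste0("\tXT:Z:", aln$gene)),
                   ifelse(is.na(aln$cell), "", paste0("\tCB:Z:", aln$cell)))
    recs <- paste0(aln$read_id, "\t", flag, "\t", aln$chrom, "\t",
                   aln$start + 1L, "\t", aln$mapq, "\t", cigar,
                   "\t*\t0\t0\t", seq, "\t*", tags)
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

# ---- variants (VCF) --------------------------------------------------------

VCF_INFO_KEYS <- c("QD", "FS", "SOR", "MQ", "MQRankSum", "ReadPosRankSum")

empty_variants <- function() {
  df <- data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                   alt = character(0), qual = numeric(0), dp = integer(0),
                   stringsAsFactors = FALSE)
  for (k in VCF_INFO_KEYS) df[[k]] <- numeric(0)
  df
}

#' Read variant records from a VCF file
#'
#' Multi-allelic records are decomposed into biallelic records.  `DP` and
#' the hard-filter annotations (QD, FS, SOR, MQ, MQRankSum, ReadPosRankSum)
#' are pulled from INFO where present.
#'
#' @param path VCF file (plain or bgzipped).
#' @return data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `qual`, `dp` and one numeric column per annotation (NA where absent).
#' @export
read_vcf_records <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(empty_variants())
  info_num <- function(key) {
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = key)))
  }
  df <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                   ref = fix$REF, alt = fix$ALT,
                   qual = suppressWarnings(as.numeric(fix$QUAL)),
                   dp = suppressWarnings(as.integer(vcfR::extract.info(v, "DP"))),
                   stringsAsFactors = FALSE)
  for (k in VCF_INFO_KEYS) df[[k]] <- info_num(k)
  # decompose multi-allelic ALT fields
  nalt <- lengths(strsplit(df$alt, ",", fixed = TRUE))
  if (any(nalt > 1L)) {
    idx <- rep(seq_len(nrow(df)), nalt)
    df <- df[idx, , drop = FALSE]
    df$alt <- unlist(strsplit(fix$ALT, ",", fixed = TRUE))
    rownames(df) <- NULL
  }
  df
}

#' Write variant records as a minimal VCF v4.2 file
#'
#' @param variants data.frame as returned by [read_vcf_records()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_vcf_records <- function(variants, path) {
  hdr <- c("##fileformat=VCFv4.2",
           '##INFO=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           sprintf('##INFO=<ID=%s,Number=1,Type=Float,Description="%s">',
                   VCF_INFO_KEYS, VCF_INFO_KEYS),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  recs <- character(0)
  if (nrow(variants) > 0L) {
    info <- vapply(seq_len(nrow(variants)), function(i) {
      parts <- character(0)
      if (!is.na(variants$dp[i]))
        parts <- c(parts, sprintf("DP=%d", as.integer(variants$dp[i])))
      for (k in VCF_INFO_KEYS) {
        val <- variants[[k]][i]
        if (!is.null(val) && !is.na(val))
          parts <- c(parts, sprintf("%s=%.4g", k, val))
      }
      if (length(parts) == 0L) "." else paste(parts, collapse = ";")
    }, character(1))
    qual <- ifelse(is.na(variants$qual), ".",
                   formatC(variants$qual, format = "g", digits = 6))
    recs <- paste(variants$chrom, variants$pos, ".", variants$ref,
                  variants$alt, qual, ".", info, sep = "\t")
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

# ---- annotation (BED6) -----------------------------------------------------

#' Read a gene annotation from BED6
#'
#' Single-interval gene models: one BED record per gene with the gene id in
#' the name field and the gene strand in the strand field.
#'
#' @param path BED6 file.
#' @return data.frame `chrom`, `start` (0-based), `end`, `gene`, `strand`.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             gene = if (!is.null(gr$name)) gr$name else
               sprintf("feature%04d", seq_along(gr)),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write a gene annotation as BED6
#'
#' @param annotation data.frame as returned by [read_annotation()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_annotation <- function(annotation, path) {
  writeLines(paste(annotation$chrom, annotation$start, annotation$end,
                   annotation$gene, 0L, annotation$strand, sep = "\t"),
             path)
  invisible(path)
}

annotation_granges <- function(annotation) {
  GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(annotation$start + 1L, annotation$end),
    strand = annotation$strand, gene = annotation$gene)
}

# ---- gene x cell count matrices -------------------------------------------

#' Construct a gene-by-cell count matrix
#'
#' @param counts integer matrix, genes in rows, cells in columns; dimnames
#'   required and unique.
#' @param read_type `"umi"`, `"internal"` or `"both"`.
#' @return a `gene_count_matrix` (an integer matrix with a `read_type`
#'   attribute).
#' @export
gene_count_matrix <- function(counts, read_type = c("umi", "internal", "both")) {
  read_type <- match.arg(read_type)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and cell colnames", call. = FALSE)
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(colnames(counts))) stop("duplicate cell ids", call. = FALSE)
  if (any(counts < 0L, na.rm = TRUE)) stop("negative counts", call. = FALSE)
  structure(counts, read_type = read_type, class = c("gene_count_matrix",
                                                     class(counts)))
}

#' Read a gene-by-cell count matrix from TSV
#'
#' @param path TSV with a header line; first column `gene`, one column per
#'   cell.
#' @param read_type matrix flavour recorded on the object.
#' @return a [gene_count_matrix()].
#' @export
read_count_matrix <- function(path, read_type = "umi") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  gene_count_matrix(m, read_type)
}

#' Write a gene-by-cell count matrix as TSV
#'
#' @param mat a [gene_count_matrix()] or plain matrix.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_count_matrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), as.data.frame(unclass(mat)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a data.frame report as TSV with a header line
#'
#' @param df data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_tsv_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
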