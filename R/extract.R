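# UMI extraction by motif grammar.
#
# Read 1 of a UMI read starts with a full or truncated 5' adapter, the
# 8-nt UMI, the spacer (spacer dialect only) and the GG anchor.  When a
# tagmentation event falls inside the TSO, the motif shows up on read 2
# behind a short (2-4 nt) adapter suffix instead; such pairs are rescued
# and their mates swapped so the UMI-bearing cDNA is always read 1
# downstream.

#' Compile the read-1 motif grammar
#'
#' The matcher accepts reads that begin with an adapter suffix of length at
#' least `len(adapter) - maxN` (maxN is `len - 2` for the `"spacer"`
#' dialect, `len - 4` for `"ss3"`), followed by 8 arbitrary bases, the
#' spacer (spacer dialect only), then the `GG` anchor.  Longer adapter
#' suffixes win when several match.  Adapter, spacer and anchor matching is
#' exact.
#'
#' @param oligo an [oligo_config()].
#' @param dialect `"spacer"` (adapter+UMI+spacer+GG) or `"ss3"`
#'   (adapter+UMI+GG).
#' @return a function `f(seqs)` returning a data.frame with `match`,
#'   `suffix_len`, `umi` and `trim_len` per input sequence.
#' @export
compile_r1_grammar <- function(oligo, dialect = c("spacer", "ss3")) {
  dialect <- match.arg(dialect)
  spacer <- if (dialect == "ss3") "" else oligo$spacer
  if (dialect == "spacer" && !nzchar(spacer))
    stop("the spacer dialect requires a non-empty spacer", call. = FALSE)
  min_sfx <- oligo$r1_min_adapter_suffix %||%
    (if (dialect == "ss3") 4L else 2L)
  compile_grammar(oligo, spacer, suffix_lens = seq.int(nchar(oligo$adapter),
                                                       min_sfx))
}

#' Compile the read-2 rescue grammar
#'
#' Matches a short retained adapter suffix (2-4 nt by default) followed by
#' the UMI, spacer and anchor at the start of read 2.
#'
#' @inheritParams compile_r1_grammar
#' @return a matcher function as in [compile_r1_grammar()].
#' @export
compile_r2_grammar <- function(oligo, dialect = c("spacer", "ss3")) {
  dialect <- match.arg(dialect)
  spacer <- if (dialect == "ss3") "" else oligo$spacer
  lens <- sort(unique(nchar(oligo$r2_adapter_suffixes)), decreasing = TRUE)
  compile_grammar(oligo, spacer, suffix_lens = lens)
}

# Shared matcher: tries adapter suffix lengths in the given order (longest
# first) and reports the first that matches suffix + 8N + spacer + anchor
# as a prefix of the read.
compile_grammar <- function(oligo, spacer, suffix_lens) {
  adapter <- oligo$adapter
  anchor <- oligo$anchor
  ulen <- oligo$umi_len
  slen <- nchar(spacer)
  alen <- nchar(anchor)
  function(seqs) {
    n <- length(seqs)
    suffix_len <- rep(NA_integer_, n)
    umi <- rep(NA_character_, n)
    todo <- rep(TRUE, n)
    for (L in suffix_lens) {
      if (!any(todo)) break
      sfx <- substr(adapter, nchar(adapter) - L + 1L, nchar(adapter))
      need <- L + ulen + slen + alen
      i <- which(todo & nchar(seqs) >= need)
      if (length(i) == 0L) next
      ok <- substr(seqs[i], 1L, L) == sfx &
        (slen == 0L | substr(seqs[i], L + ulen + 1L, L + ulen + slen) == spacer) &
        substr(seqs[i], L + ulen + slen + 1L, need) == anchor
      hit <- i[ok]
      suffix_len[hit] <- L
      umi[hit] <- substr(seqs[hit], L + 1L, L + ulen)
      todo[hit] <- FALSE
    }
    trim <- suffix_len + ulen + slen + alen
    data.frame(match = !is.na(suffix_len), suffix_len = suffix_len,
               umi = umi, trim_len = trim, stringsAsFactors = FALSE)
  }
}

#' Extract UMIs from read pairs
#'
#' The read-1 grammar is tested on mate 1; only if it fails is the read-2
#' rescue grammar tested on mate 2.  On a read-2 match the mates are
#' swapped in the output so that the UMI-bearing cDNA is mate 1.  The
#' matched technical sequence (adapter suffix + UMI + spacer + anchor) is
#' trimmed from the UMI-bearing mate, and the UMI is appended to the read
#' name after `"_"`.
#'
#' @param pairs data.frame of read pairs (see [read_fastq_pairs()]).
#' @param oligo an [oligo_config()].
#' @param dialect grammar dialect, see [compile_r1_grammar()].
#' @return list with `umi_pairs` (trimmed, reoriented pairs plus `umi`,
#'   `source` and `suffix_len` columns), `non_umi_pairs`, and `counters`
#'   (`n_r1_umi`, `n_r2_umi`, `n_non_umi`).
#' @export
extract_umis <- function(pairs, oligo = oligo_config(),
                         dialect = c("spacer", "ss3")) {
  dialect <- match.arg(dialect)
  g1 <- compile_r1_grammar(oligo, dialect)
  g2 <- compile_r2_grammar(oligo, dialect)
  m1 <- g1(pairs$seq1)
  m2 <- g2(pairs$seq2)
  r1 <- m1$match
  r2 <- !r1 & m2$match
  none <- !r1 & !r2
  trim_tail <- function(s, k) substring(s, k + 1L)

  take <- function(idx, swapped, m) {
    if (length(idx) == 0L) {
      out <- pairs[0, , drop = FALSE]
      out$umi <- character(0); out$source <- character(0)
      out$suffix_len <- integer(0)
      return(out)
    }
    p <- pairs[idx, , drop = FALSE]
    if (swapped) {
      p <- data.frame(read_id = p$read_id, seq1 = p$seq2, qual1 = p$qual2,
                      seq2 = p$seq1, qual2 = p$qual1, stringsAsFactors = FALSE)
    }
    k <- m$trim_len[idx]
    p$seq1 <- trim_tail(p$seq1, k)
    p$qual1 <- trim_tail(p$qual1, k)
    p$umi <- m$umi[idx]
    p$read_id <- paste(p$read_id, p$umi, sep = "_")
    p$source <- if (swapped) "R2" else "R1"
    p$suffix_len <- m$suffix_len[idx]
    p
  }
  umi_pairs <- rbind(take(which(r1), FALSE, m1), take(which(r2), TRUE, m2))
  umi_pairs <- umi_pairs[order(c(which(r1), which(r2))), , drop = FALSE]
  rownames(umi_pairs) <- NULL
  list(umi_pairs = umi_pairs,
       non_umi_pairs = pairs[none, , drop = FALSE],
       counters = c(n_r1_umi = sum(r1), n_r2_umi = sum(r2),
                    n_non_umi = sum(none)))
}

#' Crop reads and drop short pairs
#'
#' Both mates are cropped to at most `max_len` bp; pairs in which either
#' mate is `min_len` bp or shorter (strictly greater than `min_len`
#' survives) are dropped.
#'
#' @param pairs read-pair data.frame (plain or UMI-extracted).
#' @param max_len maximum retained length (bp).
#' @param min_len strict minimum length (bp); a `min_len`-bp mate is
#'   dropped.
#' @return the cropped, filtered pairs data.frame.
#' @export
crop_and_filter <- function(pairs, max_len = 75L, min_len = 25L) {
  pairs$seq1 <- substr(pairs$seq1, 1L, max_len)
  pairs$qual1 <- substr(pairs$qual1, 1L, max_len)
  pairs$seq2 <- substr(pairs$seq2, 1L, max_len)
  pairs$qual2 <- substr(pairs$qual2, 1L, max_len)
  keep <- nchar(pairs$seq1) > min_len & nchar(pairs$seq2) > min_len
  pairs[keep, , drop = FALSE]
}
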