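# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement nucleotide strings
#'
#' Vectorised reverse complement over character vectors (alphabet ACGTN).
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

#' Random DNA strings
#'
#' @param n number of strings.
#' @param len length of each string (scalar or vector of length `n`).
#' @return character vector of `n` random ACGT strings.
#' @export
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  len <- rep_len(len, n)
  vapply(len, function(l) paste(sample(DNA_BASES, l, replace = TRUE), collapse = ""),
         character(1))
}

# k-mer from integer code in 0 .. 4^k - 1 (A=0, C=1, G=2, T=3), vectorised.
kmer_from_code <- function(code, k) {
  if (length(code) == 0L) return(character(0))
  m <- matrix("", nrow = length(code), ncol = k)
  x <- code
  for (j in k:1) {
    m[, j] <- DNA_BASES[(x %% 4L) + 1L]
    x <- x %/% 4L
  }
  apply(m, 1L, paste, collapse = "")
}

# Substitution errors at a fixed per-base rate; substituted base is uniform
# over the three alternatives.  Returns the mutated strings.
mutate_seqs <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  lens <- nchar(seqs)
  nerr <- stats::rbinom(length(seqs), lens, rate)
  hit <- which(nerr > 0L)
  for (i in hit) {
    pos <- sample.int(lens[i], nerr[i])
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

# Stop unless all strings are over the ACGTN alphabet.
check_alphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside ACGTN (first offender: %s)",
                 what, x[which(bad)[1L]]), call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
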