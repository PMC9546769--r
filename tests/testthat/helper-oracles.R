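# Independent brute-force oracles used to validate the fast implementations,
# plus tiny fixture builders.  Oracles deliberately use the most literal
# formulation available, not the code paths they check.

# Kendall tau-b by exhaustive pair enumeration with explicit tie terms.
taub_oracle <- function(x, y) {
  n <- length(x)
  C <- 0L; D <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) C <- C + 1L else if (s < 0) D <- D + 1L
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- sum(sapply(table(x), function(t) t * (t - 1) / 2))
  ty <- sum(sapply(table(y), function(t) t * (t - 1) / 2))
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# Literal (m, offset) enumeration for the UMI-vs-upstream match.
match_oracle <- function(umi, upstream, max_mismatch = 3L, motif_str = "",
                         adjacent_only = FALSE) {
  for (m in 0:max_mismatch) {
    query <- paste0(substring(umi, m + 1L), motif_str)
    q <- nchar(query)
    w <- nchar(upstream)
    offsets <- if (adjacent_only) (w - q + 1L) else seq_len(w - q + 1L)
    for (o in offsets) {
      if (substr(upstream, o, o + q - 1L) == query) return(m)
    }
  }
  NA_integer_
}

# Literal read-1 grammar matcher: tries every admissible adapter suffix
# length explicitly, longest first.
r1_brute <- function(seq, oligo, dialect = "spacer") {
  spacer <- if (dialect == "ss3") "" else oligo$spacer
  min_sfx <- if (dialect == "ss3") 4L else 2L
  ad <- oligo$adapter
  for (L in seq.int(nchar(ad), min_sfx)) {
    pre <- paste0(substr(ad, nchar(ad) - L + 1L, nchar(ad)), strrep(".", 8L),
                  spacer, oligo$anchor)
    if (grepl(paste0("^", pre), seq)) {
      return(list(match = TRUE, suffix_len = L,
                  umi = substr(seq, L + 1L, L + 8L)))
    }
  }
  list(match = FALSE, suffix_len = NA_integer_, umi = NA_character_)
}

make_pairs <- function(seq1, seq2, ids = sprintf("r%03d", seq_along(seq1))) {
  data.frame(read_id = ids, seq1 = seq1, qual1 = strrep("I", nchar(seq1)),
             seq2 = seq2, qual2 = strrep("I", nchar(seq2)),
             stringsAsFactors = FALSE)
}

make_aln <- function(chrom, start, end, strand, umi = NA_character_,
                     gene = NA_character_, cell = "c001",
                     seq = NA_character_, mate = 1L,
                     read_id = sprintf("r%03d", seq_along(chrom))) {
  data.frame(read_id = read_id, chrom = chrom, start = start, end = end,
             strand = strand, mate = mate, mapq = 255L, umi = umi,
             gene = gene, cell = cell, seq = seq, stringsAsFactors = FALSE)
}

# Small cached simulations shared within a test run.
sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(key, maker) {
  if (!exists(key, envir = sim_cache)) assign(key, maker(), envir = sim_cache)
  get(key, envir = sim_cache)
}
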