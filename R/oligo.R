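#' Describe a TSO motif grammar (adapter / UMI / spacer / anchor)
#'
#' Declarative description of the technical sequence a template-switching
#' oligo leaves at the 5' end of a UMI read: a PCR adapter (possibly
#' truncated), an 8-nt UMI, an optional fixed spacer, and the riboguanosine
#' anchor.  Two grammar dialects are supported downstream: `"spacer"`
#' (adapter + UMI + 5-nt spacer + GG) and `"ss3"` (Smart-seq3-style,
#' adapter + UMI + GG, no spacer).
#'
#' @param adapter 5' adapter sequence preceding the UMI.
#' @param umi_len UMI length; fixed at 8 nt.
#' @param spacer fixed spacer between UMI and anchor (`""` for the ss3
#'   dialect).
#' @param anchor anchor matched after the spacer. `"GG"`: the remaining
#'   guanosine of the rGrGrG tail is treated as template and left on the
#'   read.
#' @param r1_min_adapter_suffix minimum retained adapter suffix length when
#'   matching read 1 (`NULL`: dialect default, 2 for `"spacer"`, 4 for
#'   `"ss3"`).
#' @param r2_adapter_suffixes adapter suffixes searched at the start of
#'   read 2 for intra-TSO tagmentation rescue; must be true suffixes of
#'   `adapter`.
#' @return an object of class `oligo_config`.
#' @examples
#' oligo_config()          # spacer-TSO defaults (CTAAC spacer)
#' oligo_config(spacer = "")  # ss3-style, no spacer
#' @export
oligo_config <- function(adapter = "AAGCAGTGGTATCAACGCAGAGT",
                         umi_len = 8L,
                         spacer = "CTAAC",
                         anchor = "GG",
                         r1_min_adapter_suffix = NULL,
                         r2_adapter_suffixes = c("GAGT", "AGT", "GT")) {
  stopifnot(is.character(adapter), length(adapter) == 1L, nchar(adapter) >= 4L)
  check_alphabet(adapter, "adapter")
  if (umi_len != 8L) stop("umi_len must be 8", call. = FALSE)
  stopifnot(is.character(spacer), length(spacer) == 1L)
  if (nzchar(spacer)) check_alphabet(spacer, "spacer")
  if (!nzchar(anchor)) stop("anchor must be non-empty", call. = FALSE)
  check_alphabet(anchor, "anchor")
  ok <- vapply(r2_adapter_suffixes, function(s)
    identical(substr(adapter, nchar(adapter) - nchar(s) + 1L, nchar(adapter)), s),
    logical(1))
  if (!all(ok)) {
    stop("r2_adapter_suffixes must be true suffixes of the adapter: ",
         paste(r2_adapter_suffixes[!ok], collapse = ", "), call. = FALSE)
  }
  structure(list(adapter = adapter,
                 umi_len = as.integer(umi_len),
                 spacer = spacer,
                 anchor = anchor,
                 r1_min_adapter_suffix = r1_min_adapter_suffix,
                 r2_adapter_suffixes = as.character(r2_adapter_suffixes)),
            class = "oligo_config")
}

#' @export
print.oligo_config <- function(x, ...) {
  cat("TSO motif grammar\n")
  cat("  adapter:", x$adapter, sprintf("(%d nt)\n", nchar(x$adapter)))
  cat("  UMI:    ", x$umi_len, "nt\n")
  cat("  spacer: ", if (nzchar(x$spacer)) x$spacer else "<none>", "\n")
  cat("  anchor: ", x$anchor, "\n")
  cat("  R2 adapter suffixes:", paste(x$r2_adapter_suffixes, collapse = " | "), "\n")
  invisible(x)
}

# Full technical prefix (untruncated adapter) in front of the cDNA.  The
# third riboguanosine shows up on the read, so the template prefix ends GGG
# while the grammar anchors on GG.
oligo_full_motif <- function(oligo) {
  paste0(oligo$adapter, "%UMI%", oligo$spacer, "GGG")
}
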