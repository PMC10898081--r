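`%||%` <- function(x, y) if (is.null(x)) y else x

#' Reverse-complement a DNA string (character convenience wrapper)
#'
#' @param x character vector of DNA sequences (ACGTN).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

DNA_BASES <- c("A", "C", "G", "T")

stop_pos <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
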