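#' Reverse complement of a DNA string
#'
#' @param seq DNA string over A,C,G,T,N (case-insensitive).
#' @return Reverse-complemented uppercase string.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  x <- chartr("ACGTNacgtn", "TGCANTGCAN", seq)
  paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
}

# split a DNA string into a character vector of single bases
seq_chars <- function(seq) strsplit(toupper(seq), "", fixed = TRUE)[[1L]]

# assert a string is DNA over the allowed alphabet
check_dna <- function(seq, allow_n = TRUE, what = "sequence") {
  chars <- seq_chars(seq)
  alphabet <- c("A", "C", "G", "T", if (allow_n) "N")
  bad <- setdiff(unique(chars), alphabet)
  if (length(bad) > 0L) {
    stop(sprintf("%s contains non-DNA characters: %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(toupper(seq))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
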