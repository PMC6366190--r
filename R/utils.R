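# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#'
#' Vectorised over `x`; keeps the DNA alphabet (T, not U). `N` maps to `N`.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- chartr("ACGTUacgtu", "TGCAAtgcaa", x)
  vapply(strsplit(out, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

# normalize raw sequence text to the internal DNA alphabet
norm_dna <- function(x) {
  x <- chartr("u", "t", tolower(x))
  toupper(x)
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad))
    stop(what, " contains letters outside {A,C,G,T,U,N}: ",
         x[which(bad)[1L]], call. = FALSE)
  invisible(x)
}
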