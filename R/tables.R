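#' Published grapevine copper-stress count tables
#'
#' The known- and novel-miRNA differential-expression tables of the
#' grapevine copper-stress study bundled with the package, transcribed
#' with their printed normalised values, fold changes, p-values and
#' significance labels.  Counts are raw reads per library; the printed
#' columns allow numeric round-trip checks against [ac_de()].
#'
#' @param which `"known"` (119 miRNAs) or `"novel"` (54 miRNAs).
#' @return data.frame with columns `id`, `sequence`, `ck`, `ck_std`,
#'   `cu`, `cu_std`, `log2fc`, `pvalue` (printed value; 0 means below
#'   the printed precision), `sig_label`, `regulation`.
#' @examples
#' head(cu_count_table("known"))
#' @export
cu_count_table <- function(which = c("known", "novel")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   sprintf("cu_stress_%s_counts.tsv", which),
                   package = "cumira", mustWork = TRUE)
  out <- read.delim(f, stringsAsFactors = FALSE)
  out$pvalue <- as.numeric(out$pvalue)
  out
}

#' Library totals of the copper-stress study
#'
#' Raw sequencing depth of the two libraries (control and Cu-treated);
#' these are the denominators of the reads-per-million normalisation of
#' [cu_count_table()].
#'
#' @return named numeric vector `c(ck = 10581133, cu = 9856414)`.
#' @export
cu_library_sizes <- function() {
  c(ck = 10581133, cu = 9856414)
}
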