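#' Default parameters of the built-in folding engine
#'
#' Pseudo-energy model of the internal base-pair maximisation engine:
#' per-pair energies (`e_gc`, `e_au`, `e_gu`, pseudo-kcal/mol), a
#' `stack` bonus for each pair stacked directly on another, a `hairpin`
#' loop-opening penalty, and the minimum hairpin loop size `min_loop`.
#' A perfect 20-bp GC stem-loop scores 20(-3) + 19(-1) + 2 = -77 under
#' the defaults, comfortably below the -40 calibration mark.
#'
#' @return named list of engine parameters.
#' @export
fold_params <- function() {
  list(e_gc = -3, e_au = -2, e_gu = -1, stack = -1, hairpin = 2, min_loop = 3L)
}

#' Predict an RNA secondary structure
#'
#' Folds a sequence into a dot-bracket structure with a pseudo minimum
#' free energy.  The default engine is the package's own
#' dynamic-programming base-pair maximisation with stacking bonus and
#' loop penalties (see [fold_params()]); `engine = "vienna"` swaps in
#' the ViennaRNA `RNAfold` thermodynamic engine when the binary is on
#' the PATH.  Both engines are deterministic for a fixed input.
#'
#' @param sequence a single RNA/DNA string over \{A,C,G,U,T,N\}.
#' @param engine `"internal"` (default) or `"vienna"`.
#' @param params engine parameters for the internal engine.
#' @return list with `structure` (dot-bracket, same length as the
#'   input), `mfe` (<= 0 for any paired structure) and `engine`.
#' @examples
#' fold_rna("GGGGGGGGGGAAAACCCCCCCCCC")
#' @export
fold_rna <- function(sequence, engine = c("internal", "vienna"),
                     params = fold_params()) {
  engine <- match.arg(engine)
  stopifnot(length(sequence) == 1L)
  sequence <- norm_dna(sequence)
  assert_dna(sequence)
  if (engine == "vienna") {
    bin <- Sys.which("RNAfold")
    if (!nzchar(bin)) stop("RNAfold not found on PATH", call. = FALSE)
    out <- system2(bin, c("--noPS"), input = sequence, stdout = TRUE)
    m <- regmatches(out[2L], regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)", out[2L]))[[1L]]
    return(list(structure = m[2L], mfe = as.numeric(m[3L]), engine = "vienna"))
  }
  res <- .fold_engine(sequence, params$e_gc, params$e_au, params$e_gu,
                      params$stack, params$hairpin, as.integer(params$min_loop))
  list(structure = res$structure, mfe = res$mfe, engine = "internal")
}

# pairing partner table from a dot-bracket string; NA = unpaired
pair_table <- function(structure) {
  ch <- strsplit(structure, "")[[1L]]
  n <- length(ch)
  partner <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced dot-bracket structure", call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack) > 0L) stop("unbalanced dot-bracket structure", call. = FALSE)
  partner
}
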