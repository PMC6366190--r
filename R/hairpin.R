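#' Exact genomic matches of a tag
#'
#' Finds every exact occurrence of a tag on both strands of a genome;
#' minus-strand hits are occurrences of the tag's reverse complement on
#' the plus strand, reported in plus-strand coordinates.  A tag with
#' more occurrences than `max_loci` is treated as repetitive and
#' discarded (zero rows, `attr(, "reason") == "repetitive"`).
#'
#' @param tag tag sequence (>= 18 nt).
#' @param genome named character vector (or `DNAStringSet`) of genome
#'   sequences.
#' @param max_loci repetitiveness cap (default 16).
#' @return data.frame with `seqname`, `start` (0-based), `end`
#'   (half-open), `strand`.
#' @export
map_exact <- function(tag, genome, max_loci = 16L) {
  stopifnot(nchar(tag) >= 18L)
  if (!is(genome, "DNAStringSet")) genome <- Biostrings::DNAStringSet(unlist(genome))
  hits_for <- function(pattern, strand) {
    mh <- Biostrings::vmatchPattern(pattern, genome)
    n <- vapply(mh, length, 0L)
    if (sum(n) == 0L) return(NULL)
    data.frame(seqname = rep(names(genome), n),
               start = unlist(lapply(mh, IRanges::start), use.names = FALSE) - 1L,
               end = unlist(lapply(mh, IRanges::end), use.names = FALSE),
               strand = strand)
  }
  out <- rbind(hits_for(tag, "+"), hits_for(revcomp(tag), "-"))
  if (is.null(out))
    out <- data.frame(seqname = character(), start = integer(),
                      end = integer(), strand = character())
  if (nrow(out) > max_loci) {
    out <- out[0L, , drop = FALSE]
    attr(out, "reason") <- "repetitive"
  }
  rownames(out) <- NULL
  out
}

#' Excise candidate precursor windows around a mapped tag
#'
#' For each flank length f, two windows are cut: one extending f
#' upstream of the mature locus and 20 nt downstream, and one extending
#' 20 nt upstream and f downstream (the mature sequence may sit on
#' either precursor arm).  Windows are clipped at sequence ends;
#' minus-strand windows are reverse-complemented so the excised
#' sequence always reads 5' to 3' with the mature tag on it.
#'
#' @param locus one row of [map_exact()] output (or an equivalent list).
#' @param genome named character vector of genome sequences.
#' @param flank_lengths integer vector of flank sizes (default
#'   `c(100, 150, 200)`).
#' @return data.frame with `seqname`, `window_start`, `window_end`
#'   (0-based half-open, plus-strand coordinates), `strand`, `sequence`,
#'   `mature_offset` (0-based offset of the mature tag within the
#'   returned sequence) and `mature_length`.
#' @export
excise_windows <- function(locus, genome, flank_lengths = c(100L, 150L, 200L)) {
  stopifnot(all(flank_lengths > 0L))
  if (is(genome, "DNAStringSet")) genome <- as.character(genome)
  chrom <- genome[[locus$seqname]]
  L <- nchar(chrom)
  res <- lapply(flank_lengths, function(f) {
    w <- rbind(c(locus$start - f, locus$end + 20L),
               c(locus$start - 20L, locus$end + f))
    w[, 1L] <- pmax(w[, 1L], 0L)
    w[, 2L] <- pmin(w[, 2L], L)
    data.frame(window_start = w[, 1L], window_end = w[, 2L])
  })
  res <- unique(do.call(rbind, res))
  seqs <- substr(rep(chrom, nrow(res)), res$window_start + 1L, res$window_end)
  if (locus$strand == "-") {
    seqs <- revcomp(seqs)
    offset <- res$window_end - locus$end
  } else {
    offset <- locus$start - res$window_start
  }
  data.frame(seqname = locus$seqname, window_start = res$window_start,
             window_end = res$window_end, strand = locus$strand,
             sequence = seqs, mature_offset = offset,
             mature_length = locus$end - locus$start, row.names = NULL)
}

#' Hairpin screening metrics
#'
#' Computes the quantities used to screen candidate miRNA precursors:
#' length, GC percentage, adjusted MFE (`AMFE = MFE / length x 100`) and
#' the minimal folding free energy index (`MFEI = AMFE / GC%`).  Since
#' the MFE of a paired structure is negative, screening uses the MFEI
#' magnitude with the conventional strict threshold |MFEI| > 0.80.
#' When the mature position is supplied, duplex statistics (unpaired
#' mature bases, arm, loop count) are computed from the structure.
#'
#' @param sequence precursor sequence.
#' @param structure dot-bracket structure of the same length.
#' @param mfe folding (pseudo-)energy, kcal/mol.
#' @param mature_offset,mature_length optional 0-based offset and length
#'   of the mature miRNA within `sequence`.
#' @return list with `length`, `gc_percent`, `amfe`, `mfei` and (when
#'   the mature position is given) `duplex_mismatches`, `arm`,
#'   `n_loops`, `mature_in_loop`.
#' @examples
#' hairpin_metrics(strrep("GC", 50), strrep(".", 100), -45)
#' @export
hairpin_metrics <- function(sequence, structure, mfe,
                            mature_offset = NULL, mature_length = NULL) {
  n <- nchar(sequence)
  stopifnot(nchar(structure) == n)
  gc <- 100 * nchar(gsub("[^GCgc]", "", sequence)) / n
  if (gc == 0) stop("MFEI undefined: GC content is zero", call. = FALSE)
  amfe <- mfe / n * 100
  out <- list(length = n, gc_percent = gc, amfe = amfe, mfei = amfe / gc)
  if (!is.null(mature_offset)) {
    partner <- pair_table(structure)
    idx <- (mature_offset + 1L):(mature_offset + mature_length)
    if (mature_offset < 0L || max(idx) > n)
      stop("mature region outside the precursor", call. = FALSE)
    p <- partner[idx]
    out$duplex_mismatches <- sum(is.na(p))
    out$arm <- if (all(is.na(p))) NA_character_
               else if (mean(p[!is.na(p)]) > mean(idx)) "5p" else "3p"
    loops <- gregexpr("\\(\\.*\\)", structure)[[1L]]
    n_loops <- if (loops[1L] == -1L) 0L else length(loops)
    out$n_loops <- n_loops
    in_loop <- FALSE
    if (n_loops >= 1L) {
      for (k in seq_len(n_loops)) {
        lo <- loops[k] + 1L
        hi <- loops[k] + attr(loops, "match.length")[k] - 2L
        if (hi >= lo && any(idx >= lo & idx <= hi)) in_loop <- TRUE
      }
    }
    # a mature region spanning both arms necessarily crosses the loop
    ch <- strsplit(structure, "")[[1L]][idx]
    if (any(ch == "(") && any(ch == ")")) in_loop <- TRUE
    out$mature_in_loop <- in_loop
  }
  out
}

#' Trim an excised window down to the local stem-loop
#'
#' Precursor windows carry flanking sequence whose own base pairing
#' would fail the single-stem-loop criterion, so the stem-loop that
#' actually contains the mature tag is cut out before validation: from
#' each terminal loop of the folded window, the stem is extended
#' outward through stacked and bulged pairs and stopped at multiloop
#' branches; the maximal such stem whose span covers the mature region
#' is returned.
#'
#' @param sequence,structure folded window and its dot-bracket.
#' @param mature_offset,mature_length 0-based mature position within
#'   the window.
#' @return `NULL` when no stem-loop spans the mature region, else a
#'   list with `sequence` (the stem-loop subsequence), `offset` (its
#'   0-based start within the window) and `mature_offset` (rebased).
#' @export
excise_hairpin <- function(sequence, structure, mature_offset, mature_length) {
  partner <- pair_table(structure)
  ch <- strsplit(structure, "")[[1L]]
  loops <- gregexpr("\\(\\.*\\)", structure)[[1L]]
  if (loops[1L] == -1L) return(NULL)
  m_lo <- mature_offset + 1L
  m_hi <- mature_offset + mature_length
  best <- NULL
  for (k in seq_along(loops)) {
    i <- loops[k]                                      # closing pair 5' side
    j <- i + attr(loops, "match.length")[k] - 1L       # closing pair 3' side
    # extend outward while the next enclosing pair nests directly
    repeat {
      a <- i - 1L
      while (a >= 1L && ch[a] == ".") a <- a - 1L
      if (a < 1L || ch[a] != "(") break
      b <- partner[a]
      if (b < j) break
      gap <- if (b > j + 1L) ch[(j + 1L):(b - 1L)] else character(0)
      if (any(gap != ".")) break                       # multiloop branch
      i <- a; j <- b
    }
    if (i <= m_lo && j >= m_hi) {
      if (is.null(best) || (j - i) > (best$j - best$i)) best <- list(i = i, j = j)
    }
  }
  if (is.null(best)) return(NULL)
  list(sequence = substr(sequence, best$i, best$j), offset = best$i - 1L,
       mature_offset = mature_offset - (best$i - 1L))
}

#' Validate a candidate hairpin against annotation criteria
#'
#' A folded candidate passes when (a) the mature region lies entirely
#' on one arm with no base in the terminal loop, (b) at most
#' `max_duplex_mismatch` mature bases are unpaired against the opposite
#' arm, (c) the structure contains exactly one terminal loop, and (d)
#' |MFEI| exceeds `mfei_min`.  All failed criteria are reported.
#'
#' @param candidate list with `sequence`, `structure`, `mfe`,
#'   `mature_offset`, `mature_length` (as produced by combining
#'   [excise_windows()] and [fold_rna()]).
#' @param criteria list of thresholds: `max_duplex_mismatch` (default 4)
#'   and `mfei_min` (default 0.80, strict).
#' @return list with `pass` (logical), `reasons` (character vector of
#'   failed criteria, empty when passing) and `metrics`.
#' @export
validate_hairpin <- function(candidate,
                             criteria = list(max_duplex_mismatch = 4L,
                                             mfei_min = 0.80)) {
  met <- hairpin_metrics(candidate$sequence, candidate$structure, candidate$mfe,
                         candidate$mature_offset, candidate$mature_length)
  reasons <- character(0)
  if (met$mature_in_loop || is.na(met$arm))
    reasons <- c(reasons, "mature in loop")
  if (met$duplex_mismatches > criteria$max_duplex_mismatch)
    reasons <- c(reasons, "duplex mismatches")
  if (met$n_loops != 1L)
    reasons <- c(reasons, "not a single terminal loop")
  if (!(abs(met$mfei) > criteria$mfei_min))
    reasons <- c(reasons, "MFEI not exceeding threshold")
  list(pass = length(reasons) == 0L, reasons = reasons, metrics = met)
}
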