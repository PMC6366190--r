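#' Read a mature-miRNA reference FASTA
#'
#' Headers are taken up to the first whitespace as the miRNA name
#' (miRBase style, e.g. `vvi-miR156b`).  U is normalised to T.
#'
#' @param path FASTA file of mature miRNA sequences.
#' @return data.frame with columns `name`, `family`, `sequence`.
#' @export
read_mature_fasta <- function(path) {
  seqs <- read_sequences(path, format = "fasta")
  name <- sub("\\s.*$", "", seqs$id)
  if (anyDuplicated(name)) stop("duplicate reference names", call. = FALSE)
  data.frame(name = name, family = mirna_family(name), sequence = seqs$sequence)
}

#' 5'-anchored mismatch count between a tag and a reference
#'
#' Both sequences are aligned at their 5' ends and compared position by
#' position over the overlap (Hamming, no indels); 3' overhanging bases
#' on either side are ignored.  Mature-miRNA sequence variants are
#' predominantly 3'-length variants, which this geometry accommodates.
#'
#' @param tag,ref DNA strings.
#' @param max_overhang maximum tolerated length difference (default 2);
#'   beyond it the comparison is rejected.
#' @return `NULL` when the length difference exceeds `max_overhang`,
#'   otherwise a list with `total` mismatches, `first16` (mismatches at
#'   reference positions 1-16) and the 1-based mismatch `positions` on
#'   the reference.
#' @examples
#' anchored_mismatches("TGACAGAAGAGAGTGAGCAC", "TGACAGAAGAGAGTGAGCAA")
#' @export
anchored_mismatches <- function(tag, ref, max_overhang = 2L) {
  stopifnot(nzchar(tag), nzchar(ref))
  if (abs(nchar(tag) - nchar(ref)) > max_overhang) return(NULL)
  n <- min(nchar(tag), nchar(ref))
  a <- strsplit(substr(tag, 1L, n), "")[[1L]]
  b <- strsplit(substr(ref, 1L, n), "")[[1L]]
  pos <- which(a != b)
  list(total = length(pos), first16 = sum(pos <= 16L), positions = pos)
}

#' Assign a tag to the best-matching known mature miRNA
#'
#' A reference is admissible when the tag has at most `max_first16`
#' mismatches within its first 16 nt and at most `max_total` mismatches
#' overall (5'-anchored comparison, see [anchored_mismatches()]).  Among
#' admissible references the one with the fewest total mismatches wins;
#' ties break by fewest first-16 mismatches, then lexicographic name, so
#' the result never depends on reference order.
#'
#' @param tag tag sequence.
#' @param references data.frame with `name` and `sequence` columns (see
#'   [read_mature_fasta()]).
#' @param max_total,max_first16 mismatch ceilings (defaults 3 and 1).
#' @param max_overhang see [anchored_mismatches()].
#' @return `NULL` if no reference is admissible, else a list with
#'   `reference`, `total`, `first16`, `positions` and `co_optimal` (all
#'   names tied with the winner).
#' @export
match_known <- function(tag, references, max_total = 3L, max_first16 = 1L,
                        max_overhang = 2L) {
  stopifnot(nrow(references) > 0L)
  hits <- lapply(seq_len(nrow(references)), function(i) {
    mm <- anchored_mismatches(tag, references$sequence[i], max_overhang)
    if (is.null(mm) || mm$total > max_total || mm$first16 > max_first16) return(NULL)
    c(i = i, total = mm$total, first16 = mm$first16)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) return(NULL)
  ord <- order(hits[, "total"], hits[, "first16"], references$name[hits[, "i"]])
  hits <- hits[ord, , drop = FALSE]
  best <- hits[1L, ]
  co <- hits[hits[, "total"] == best["total"] & hits[, "first16"] == best["first16"], ,
             drop = FALSE]
  i <- best[["i"]]
  mm <- anchored_mismatches(tag, references$sequence[i], max_overhang)
  list(reference = references$name[i], total = mm$total, first16 = mm$first16,
       positions = mm$positions, co_optimal = references$name[co[, "i"]])
}

#' Match a set of tags against the mature reference
#'
#' Applies [match_known()] to every tag and returns one row per matched
#' tag.  Counts of tags assigned to the same reference are summed by
#' [aggregate_known_counts()].
#'
#' @param tags tag data.frame (`sequence`, `count`, optionally per-library
#'   count columns).
#' @param references mature reference data.frame.
#' @param ... passed to [match_known()].
#' @return data.frame of matches: `sequence`, `reference`, `total`,
#'   `first16`, plus any count columns of `tags`.
#' @export
match_known_tags <- function(tags, references, ...) {
  res <- lapply(seq_len(nrow(tags)), function(i) {
    m <- match_known(tags$sequence[i], references, ...)
    if (is.null(m)) return(NULL)
    cbind(tags[i, setdiff(names(tags), "sequence"), drop = FALSE],
          data.frame(sequence = tags$sequence[i], reference = m$reference,
                     total = m$total, first16 = m$first16))
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(sequence = character(), reference = character(),
                      total = integer(), first16 = integer())
  rownames(out) <- NULL
  out
}

#' Sum per-reference counts over matched tags
#'
#' @param matches output of [match_known_tags()].
#' @param count_cols names of the count columns to sum.
#' @return data.frame with one row per reference.
#' @export
aggregate_known_counts <- function(matches, count_cols) {
  if (nrow(matches) == 0L)
    return(cbind(data.frame(reference = character()),
                 as.data.frame(setNames(rep(list(integer()), length(count_cols)),
                                        count_cols))))
  agg <- stats::aggregate(matches[count_cols], by = list(reference = matches$reference), sum)
  agg[order(agg$reference), , drop = FALSE]
}

#' Family key of miRNA names
#'
#' The family is `"miR"` plus the leading integer of the name, so letter
#' suffixes and -5p/-3p arms collapse into one family (`vvi-miR3623-3p`
#' and `vvi-miR3623-5p` are both `miR3623`).
#'
#' @param names character vector of miRNA names.
#' @return character vector of family keys; unparseable names map to
#'   `"unknown"` with a warning.
#' @export
mirna_family <- function(names) {
  m <- regmatches(names, regexpr("miR[0-9]+", names))
  out <- rep("unknown", length(names))
  ok <- grepl("miR[0-9]+", names)
  out[ok] <- m
  if (any(!ok))
    warning("unparseable miRNA name(s): ",
            paste(utils::head(names[!ok], 3L), collapse = ", "), call. = FALSE)
  out
}

#' Group miRNA names into families
#'
#' @param names character vector of miRNA names.
#' @return named list, family key to member names.
#' @examples
#' group_families(c("vvi-miR156b", "vvi-miR156c", "vvi-miR3623-3p"))
#' @export
group_families <- function(names) {
  split(names, mirna_family(names))
}
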