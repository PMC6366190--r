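#' Read small-RNA sequences from FASTA or FASTQ
#'
#' Reads a (possibly gzip-compressed) FASTA or FASTQ file through
#' Biostrings and returns the records in file order.  Sequences are
#' upper-cased and U is normalised to T so that all downstream
#' comparisons run over the DNA alphabet.
#'
#' @param path path to the sequence file.
#' @param format `"fasta"`, `"fastq"`, or `"auto"` (decided from the file
#'   extension, `.fq`/`.fastq` meaning FASTQ).
#' @return a data.frame with columns `id`, `sequence` and, for FASTQ,
#'   `quality` (Phred string of the same length as the sequence).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">r1", "ucgg", ">r2", "ACGTACGTACGTACGTACGT"), fa)
#' read_sequences(fa)$sequence
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    base <- sub("\\.(gz|bz2)$", "", path)
    format <- if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE)) "fastq" else "fasta"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "fastq") {
    seqs <- Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE)
    # Biostrings nul-pads short quality strings; surface that as the
    # contract violation it is
    qual <- tryCatch(as.character(S4Vectors::mcols(seqs)$qualities),
                     error = function(e)
                       stop("FASTQ quality length differs from sequence length",
                            call. = FALSE))
    sq <- norm_dna(as.character(seqs))
    bad <- nchar(qual) != nchar(sq)
    if (any(bad))
      stop("FASTQ record ", which(bad)[1L],
           ": quality length differs from sequence length", call. = FALSE)
    out <- data.frame(id = names(seqs) %||% as.character(seq_along(seqs)),
                      sequence = sq, quality = qual)
  } else {
    seqs <- Biostrings::readBStringSet(path, format = "fasta")
    out <- data.frame(id = names(seqs), sequence = norm_dna(as.character(seqs)))
  }
  if (any(nchar(out$sequence) == 0L))
    stop("empty sequence in record ", which(nchar(out$sequence) == 0L)[1L],
         call. = FALSE)
  assert_dna(out$sequence)
  rownames(out) <- NULL
  out
}

#' Trim the 3' adapter from reads
#'
#' Removes the read suffix starting at the leftmost exact match of the
#' first `min_overlap` bases of the 3' adapter.  Reads with no adapter
#' hit are returned as `NA` (the caller discards them by default, since
#' an insert shorter than the read implies the adapter must be present).
#'
#' @param sequence character vector of read sequences (DNA alphabet).
#' @param adapter3 the 3' adapter sequence.
#' @param min_overlap minimum adapter prefix that must match exactly
#'   (default 8).
#' @return character vector of trimmed inserts; `NA` where the adapter
#'   seed was not found, `""` where the read starts with the adapter.
#' @examples
#' trim_adapter("ACGTACGTACGTACGTACGTTGGAATTCTCGG", "TGGAATTCTCGGGTGCCAAGG")
#' @export
trim_adapter <- function(sequence, adapter3, min_overlap = 8L) {
  if (!nzchar(adapter3)) stop("adapter3 must be non-empty", call. = FALSE)
  if (min_overlap < 1L) stop("min_overlap must be >= 1", call. = FALSE)
  seed <- substr(norm_dna(adapter3), 1L, min_overlap)
  pos <- regexpr(seed, sequence, fixed = TRUE)
  out <- ifelse(pos > 0L, substr(sequence, 1L, pos - 1L), NA_character_)
  out
}

#' Length filter for cleaned small-RNA tags
#'
#' @param sequence character vector.
#' @param min_len,max_len inclusive bounds (defaults 18 and 30 nt, the
#'   gel-excised size range of typical plant small-RNA libraries).
#' @return logical vector, `TRUE` where the length is within bounds.
#' @export
length_filter <- function(sequence, min_len = 18L, max_len = 30L) {
  if (min_len > max_len) stop("min_len must be <= max_len", call. = FALSE)
  n <- nchar(sequence)
  n >= min_len & n <= max_len
}

#' Collapse cleaned reads into unique tags
#'
#' One tag per distinct sequence, with its read count.  The sum of the
#' counts always equals the number of input reads.
#'
#' @param sequence character vector of cleaned (trimmed, length-filtered)
#'   read sequences.
#' @param library optional library label stored as an attribute.
#' @return data.frame with columns `sequence` and `count`, ordered by
#'   decreasing count then sequence.
#' @examples
#' collapse_tags(c("ACGT", "ACGT", "TTTT"))
#' @export
collapse_tags <- function(sequence, library = NULL) {
  if (length(sequence) == 0L) {
    out <- data.frame(sequence = character(), count = integer())
  } else {
    tab <- table(sequence)
    out <- data.frame(sequence = names(tab), count = as.integer(tab))
    out <- out[order(-out$count, out$sequence), , drop = FALSE]
    rownames(out) <- NULL
  }
  if (!is.null(library)) attr(out, "library") <- library
  out
}

#' Partition tags into contaminant categories
#'
#' A tag is removed into the first matching category in precedence
#' order (exact sequence membership), or into `polyA` when its fraction
#' of A bases reaches `polyA_fraction`.  Kept plus removed tags always
#' partition the input.
#'
#' @param tags data.frame from [collapse_tags()].
#' @param contaminant_sets named list of character vectors of contaminant
#'   sequences (e.g. `rRNA`, `tRNA`, `snRNA`, `snoRNA`, ...).
#' @param polyA_fraction fraction of A bases at or above which a tag
#'   counts as a polyA tail (default 0.8).
#' @param precedence category order applied when a tag occurs in several
#'   sets; defaults to the order of `contaminant_sets`.
#' @return list with elements `kept` (tag data.frame) and `removed`
#'   (named list of tag data.frames per category, including `polyA`).
#' @export
filter_contaminants <- function(tags, contaminant_sets, polyA_fraction = 0.8,
                                precedence = names(contaminant_sets)) {
  stopifnot(polyA_fraction > 0, polyA_fraction <= 1)
  precedence <- intersect(precedence, names(contaminant_sets))
  cat_of <- rep(NA_character_, nrow(tags))
  for (cat in precedence) {
    hit <- is.na(cat_of) & tags$sequence %in% contaminant_sets[[cat]]
    cat_of[hit] <- cat
  }
  n_a <- nchar(gsub("[^A]", "", tags$sequence))
  polya <- is.na(cat_of) & n_a / nchar(tags$sequence) >= polyA_fraction
  cat_of[polya] <- "polyA"
  removed <- lapply(c(precedence, "polyA"), function(cat) {
    out <- tags[which(cat_of %in% cat), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  names(removed) <- c(precedence, "polyA")
  kept <- tags[is.na(cat_of), , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, removed = removed)
}

#' Per-category library summary
#'
#' Unique-tag and total-read counts per category with percentages of the
#' library total, in the style of a small-RNA category distribution
#' table.
#'
#' @param tags_by_category named list of tag data.frames
#'   (`sequence`/`count`), one element per category.
#' @param library_total total reads of the library (> 0); categories may
#'   not cover it completely, the remainder being unannotated.
#' @return data.frame with columns `category`, `unique`, `unique_pct`,
#'   `total`, `total_pct`.
#' @examples
#' summarize_categories(list(known_miRNA = data.frame(
#'   sequence = "TGACAGAAGAGAGTGAGCAC", count = 593973L)), 10581133)
#' @export
summarize_categories <- function(tags_by_category, library_total) {
  stopifnot(library_total > 0)
  uni <- vapply(tags_by_category, nrow, 0L)
  tot <- vapply(tags_by_category, function(x) sum(as.numeric(x$count)), 0)
  if (sum(tot) > library_total)
    stop("category totals exceed the library total", call. = FALSE)
  data.frame(category = names(tags_by_category),
             unique = as.integer(uni),
             unique_pct = round(100 * uni / library_total, 2),
             total = tot,
             total_pct = round(100 * tot / library_total, 2),
             row.names = NULL)
}

#' Write collapsed tags as FASTA
#'
#' Headers follow the collapsed-read convention `tag<serial>_x<count>`.
#'
#' @param tags data.frame with `sequence` and `count`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(tags, path) {
  headers <- sprintf(">tag%d_x%d", seq_len(nrow(tags)), tags$count)
  writeLines(as.vector(rbind(headers, tags$sequence)), path)
  invisible(path)
}
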