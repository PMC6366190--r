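#' Scan a transcript for miRNA complementary sites
#'
#' Slides the reverse complement of the miRNA along the transcript and,
#' at each offset, counts non-complementary positions; G:U wobbles are
#' counted as mismatches when `wobble_is_mismatch` (the plain
#' mismatch-count acceptance rule) or tallied separately otherwise.
#' Sites with fewer than `max_mismatches` mismatches are emitted,
#' sorted by (mismatches, position).  No bulges or gaps are considered.
#' The Allen-style score is computed for every emitted site as an
#' annotation, not a filter.
#'
#' @param mirna miRNA sequence (19-25 nt, DNA alphabet).
#' @param transcript transcript sequence.
#' @param max_mismatches exclusive mismatch ceiling (default 4: sites
#'   with 4 or more mismatches are rejected).
#' @param wobble_is_mismatch count G:U pairs as mismatches (default
#'   TRUE).
#' @param mirna_name,transcript_id labels carried into the output.
#' @return data.frame with `mirna`, `transcript`, `start`, `end`
#'   (0-based half-open on the transcript), `mismatches`, `wobbles`,
#'   `allen_score`, `site` (transcript subsequence, 5'->3').
#' @export
scan_targets <- function(mirna, transcript, max_mismatches = 4L,
                         wobble_is_mismatch = TRUE,
                         mirna_name = "mirna", transcript_id = "transcript") {
  mirna <- norm_dna(mirna); transcript <- norm_dna(transcript)
  L <- nchar(mirna); n <- nchar(transcript)
  stopifnot(L >= 19L, L <= 25L)
  empty <- data.frame(mirna = character(), transcript = character(),
                      start = integer(), end = integer(),
                      mismatches = integer(), wobbles = integer(),
                      allen_score = numeric(), site = character())
  if (n < L) return(empty)
  rc <- strsplit(revcomp(mirna), "")[[1L]]
  tr <- strsplit(transcript, "")[[1L]]
  n_off <- n - L + 1L
  mism <- integer(n_off); wob <- integer(n_off)
  # site position q (1..L) pairs miRNA position L-q+1; in terms of the
  # reverse complement rc, Watson-Crick iff site[q] == rc[q] and G:U iff
  # (rc[q] == C & site[q] == T) or (rc[q] == A & site[q] == G)
  for (q in seq_len(L)) {
    sq <- tr[q:(q + n_off - 1L)]
    wc <- sq == rc[q]
    gu <- (rc[q] == "C" & sq == "T") | (rc[q] == "A" & sq == "G")
    mism <- mism + as.integer(!wc & !gu)
    wob <- wob + as.integer(gu)
  }
  total <- if (wobble_is_mismatch) mism + wob else mism
  keep <- which(total < max_mismatches)
  if (length(keep) == 0L) return(empty)
  keep <- keep[order(total[keep], keep)]
  sites <- substr(rep(transcript, length(keep)), keep, keep + L - 1L)
  data.frame(mirna = mirna_name, transcript = transcript_id,
             start = keep - 1L, end = keep + L - 1L,
             mismatches = total[keep], wobbles = wob[keep],
             allen_score = vapply(sites, function(s) allen_score(mirna, s), 0,
                                  USE.NAMES = FALSE),
             site = sites, row.names = NULL)
}

#' Allen-style complementarity score
#'
#' Penalty sum over the miRNA/target duplex: 1 per mismatch, 0.5 per
#' G:U wobble, with every penalty doubled at miRNA positions 2-13
#' (1-based from the miRNA 5' end, the seed-proximal core of the
#' cited plant target-prediction convention).  0 is a perfect
#' complement; lower is better.
#'
#' @param mirna miRNA sequence.
#' @param site target site sequence (same length, transcript 5'->3').
#' @return numeric score.
#' @examples
#' allen_score("TGACAGAAGAGAGTGAGCAC", revcomp("TGACAGAAGAGAGTGAGCAC"))
#' @export
allen_score <- function(mirna, site) {
  mirna <- norm_dna(mirna); site <- norm_dna(site)
  L <- nchar(mirna)
  if (nchar(site) != L) stop("site and miRNA lengths differ", call. = FALSE)
  m <- strsplit(mirna, "")[[1L]]
  s <- strsplit(site, "")[[1L]]
  score <- 0
  for (p in seq_len(L)) {
    t <- s[L - p + 1L]  # target base pairing miRNA position p
    wc <- t == chartr("ACGT", "TGCA", m[p])
    gu <- (m[p] == "G" && t == "T") || (m[p] == "T" && t == "G")
    pen <- if (wc) 0 else if (gu) 0.5 else 1
    if (p >= 2L && p <= 13L) pen <- pen * 2
    score <- score + pen
  }
  score
}

#' Summarise cleavage-clone positions over a target site
#'
#' Converts cloned mRNA 5'-end coordinates (RLM-RACE products) into
#' positions along the miRNA-complementary site, counted 1-based from
#' the miRNA 5' end, and tallies count and fraction per position.
#' Clones outside a 100-nt window centred on the site are discarded.
#'
#' @param clone_coords integer vector of clone 5'-end transcript
#'   coordinates (0-based).
#' @param site one row of [scan_targets()] output (or a list with
#'   `start` and `end`).
#' @return data.frame with `position`, `count`, `fraction`; fractions
#'   sum to 1 over the retained clones.
#' @export
summarize_cleavage <- function(clone_coords, site) {
  stopifnot(length(clone_coords) >= 1L)
  centre <- (site$start + site$end) / 2
  keep <- clone_coords[abs(clone_coords - centre) <= 50]
  if (length(keep) == 0L)
    return(data.frame(position = integer(), count = integer(),
                      fraction = numeric()))
  pos <- site$end - keep  # 1-based from the miRNA 5' end
  tab <- table(pos)
  data.frame(position = as.integer(names(tab)), count = as.integer(tab),
             fraction = as.integer(tab) / length(keep), row.names = NULL)
}

#' miRNA-target network edge list
#'
#' @param sites data.frame of accepted sites ([scan_targets()] output,
#'   possibly concatenated over miRNAs and transcripts).
#' @return list with `edges` (unique `mirna`/`transcript` pairs) and
#'   `degree` (per-node edge counts).
#' @export
export_network <- function(sites) {
  edges <- unique(sites[, c("mirna", "transcript"), drop = FALSE])
  rownames(edges) <- NULL
  nodes <- c(edges$mirna, edges$transcript)
  degree <- if (length(nodes)) table(nodes) else table(character())
  list(edges = edges,
       degree = data.frame(node = names(degree), degree = as.integer(degree),
                           row.names = NULL))
}
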