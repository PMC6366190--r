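plant_tag <- function(chrom, tag, pos) {   # pos is 0-based insertion point
  paste0(substr(chrom, 1L, pos), tag, substr(chrom, pos + 1L, nchar(chrom)))
}

test_that("exact mapping finds planted loci on both strands and caps repeats", {
  set.seed(31)
  tag <- rand_seq(21L)
  chrom <- plant_tag(rand_seq(1000L), tag, 500L)
  g <- c(chr1 = chrom)
  loci <- map_exact(tag, g)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$start, 500L)
  expect_equal(loci$strand, "+")
  # minus strand: plant the reverse complement
  g2 <- c(chr1 = plant_tag(rand_seq(600L), revcomp(tag), 100L))
  loci2 <- map_exact(tag, g2)
  expect_equal(loci2$strand, "-")
  expect_equal(loci2$start, 100L)
  # absent tag
  expect_equal(nrow(map_exact(rand_seq(21L), g)), 0L)
  # repetitive: planted at 3 loci with cap 2
  g3 <- c(chr1 = paste0(rand_seq(50L), tag, rand_seq(50L), tag,
                        rand_seq(50L), tag, rand_seq(50L)))
  loci3 <- map_exact(tag, g3, max_loci = 2L)
  expect_equal(nrow(loci3), 0L)
  expect_equal(attr(loci3, "reason"), "repetitive")
})

test_that("window excision arithmetic, clipping, and strand round trip", {
  set.seed(32)
  tag <- rand_seq(21L)
  chrom <- plant_tag(rand_seq(1200L), tag, 500L)
  g <- c(chr1 = chrom)
  locus <- map_exact(tag, g)[1L, ]
  wins <- excise_windows(locus, g, flank_lengths = 100L)
  expect_equal(nchar(wins$sequence), rep(21L + 120L, 2L))
  expect_equal(nrow(excise_windows(locus, g, flank_lengths = c(100L, 150L, 200L))), 6L)
  # mature offset points at the tag in every window
  for (k in seq_len(nrow(wins)))
    expect_equal(substr(wins$sequence[k], wins$mature_offset[k] + 1L,
                        wins$mature_offset[k] + 21L), tag)
  # clipping near the contig start
  g5 <- c(chr1 = plant_tag(rand_seq(200L), tag, 5L))
  w5 <- excise_windows(map_exact(tag, g5)[1L, ], g5, flank_lengths = 100L)
  expect_true(all(w5$window_start >= 0L))
  # strand round trip: excising the minus-strand locus of the reverse
  # complement yields windows containing the tag itself
  gm <- c(chr1 = plant_tag(rand_seq(1200L), revcomp(tag), 600L))
  lm <- map_exact(tag, gm)[1L, ]
  wm <- excise_windows(lm, gm, flank_lengths = 100L)
  for (k in seq_len(nrow(wm)))
    expect_equal(substr(wm$sequence[k], wm$mature_offset[k] + 1L,
                        wm$mature_offset[k] + 21L), tag)
})

test_that("hairpin validation accepts planted hairpins and names failed criteria", {
  set.seed(33)
  mature <- rand_seq(21L)
  pre <- make_perfect_hairpin(mature)
  f <- fold_rna(pre)
  v <- validate_hairpin(list(sequence = pre, structure = f$structure, mfe = f$mfe,
                             mature_offset = 0L, mature_length = 21L))
  expect_true(v$pass)
  expect_equal(v$reasons, character(0))
  expect_equal(v$metrics$arm, "5p")
  # mature spanning the loop
  v2 <- validate_hairpin(list(sequence = pre, structure = f$structure, mfe = f$mfe,
                              mature_offset = 15L, mature_length = 21L))
  expect_false(v2$pass)
  expect_true("mature in loop" %in% v2$reasons)
  # five unpaired mature bases: artificial structure with a 5-nt gap in the arm
  st <- paste0(strrep("(", 10), ".....", strrep("(", 6), "....",
               strrep(")", 6), ".....", strrep(")", 10))
  sq <- paste0(strrep("G", 10), strrep("A", 5), strrep("G", 6), "AAAA",
               strrep("C", 6), strrep("A", 5), strrep("C", 10))
  v3 <- validate_hairpin(list(sequence = sq, structure = st, mfe = -30,
                              mature_offset = 0L, mature_length = 21L))
  expect_false(v3$pass)
  expect_true("duplex mismatches" %in% v3$reasons)
})

test_that("hairpin excision recovers a planted stem-loop from a flanked window", {
  set.seed(35)
  mature <- rand_seq(21L)
  pre <- make_perfect_hairpin(mature)
  window <- paste0(rand_seq(60L), pre, rand_seq(60L))
  f <- fold_rna(window)
  hp <- excise_hairpin(window, f$structure, 60L, 21L)
  expect_false(is.null(hp))
  expect_equal(substr(hp$sequence, hp$mature_offset + 1L,
                      hp$mature_offset + 21L), mature)
  f2 <- fold_rna(hp$sequence)
  v <- validate_hairpin(list(sequence = hp$sequence, structure = f2$structure,
                             mfe = f2$mfe, mature_offset = hp$mature_offset,
                             mature_length = 21L))
  expect_false("mature in loop" %in% v$reasons)
  expect_false("not a single terminal loop" %in% v$reasons)
  # an unstructured window yields nothing
  expect_null(excise_hairpin(strrep("A", 60), strrep(".", 60), 10L, 21L))
})

test_that("windows from hairpin-free random sequence do not pass validation", {
  set.seed(34)
  passes <- 0L; total <- 0L
  for (s in 1:5) {
    tag <- rand_seq(21L)
    g <- c(chr = plant_tag(rand_seq(2000L), tag, 1000L))
    wins <- excise_windows(map_exact(tag, g)[1L, ], g)
    for (k in seq_len(nrow(wins))) {
      f <- fold_rna(wins$sequence[k])
      v <- validate_hairpin(list(sequence = wins$sequence[k],
                                 structure = f$structure, mfe = f$mfe,
                                 mature_offset = wins$mature_offset[k],
                                 mature_length = 21L))
      total <- total + 1L
      passes <- passes + v$pass
    }
  }
  expect_gt(total, 0L)
  expect_lte(passes / total, 0.1)
})
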