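test_that("FASTA and FASTQ reading preserves order and normalises the alphabet", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">r1 first", "ucgg", ">r2", "ACGTACGTACGTACGTACGT"), fa)
  rec <- read_sequences(fa)
  expect_equal(rec$id, c("r1 first", "r2"))
  expect_equal(rec$sequence[1L], "TCGG")

  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@a", "ACGUacgu", "+", "IIIIIIII"), fq)
  rec <- read_sequences(fq)
  expect_equal(rec$sequence, "ACGTACGT")
  expect_equal(rec$quality, "IIIIIIII")
})

test_that("FASTQ with mismatched quality length is rejected", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@a", "ACGTACGT", "+", "III"), fq)
  expect_error(read_sequences(fq), "quality")
})

test_that("adapter trimming removes the suffix at the leftmost seed match", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  insert <- "ACGTACGTACGTACGTACGTA"
  expect_equal(trim_adapter(paste0(insert, adapter), adapter), insert)
  # no adapter hit -> NA (discarded downstream)
  expect_true(is.na(trim_adapter("ACGTACGTACGTACGTACGTACG", adapter)))
  # read is pure adapter -> empty insert, removed by the length filter
  trimmed <- trim_adapter(adapter, adapter)
  expect_equal(trimmed, "")
  expect_false(length_filter(trimmed))
  expect_error(trim_adapter("ACGT", ""), "adapter3")
  expect_error(trim_adapter("ACGT", "ACGT", min_overlap = 0L), "min_overlap")
})

test_that("length filter uses inclusive 18-30 nt boundaries", {
  expect_equal(length_filter(strrep("A", c(17, 18, 30, 31))),
               c(FALSE, TRUE, TRUE, FALSE))
  expect_error(length_filter("ACGT", min_len = 20, max_len = 19), "min_len")
})

test_that("tag collapsing conserves counts and is idempotent", {
  a <- strrep("A", 21); c_ <- strrep("C", 21)
  tags <- collapse_tags(c(a, a, c_))
  expect_equal(tags$count[tags$sequence == a], 2L)
  expect_equal(tags$count[tags$sequence == c_], 1L)
  expect_equal(nrow(collapse_tags(character(0))), 0L)

  tags <- collapse_tags(rep(a, 1000L))
  expect_equal(nrow(tags), 1L)
  expect_equal(tags$count, 1000L)

  set.seed(41)
  reads <- replicate(500, rand_seq(sample(18:24, 1L)))
  tags <- collapse_tags(reads)
  expect_equal(sum(tags$count), length(reads))          # conservation
  again <- collapse_tags(tags$sequence)
  expect_equal(sort(again$sequence), sort(tags$sequence))
  expect_true(all(again$count == 1L))                   # idempotent on uniques
})

test_that("contaminant filtering partitions tags by precedence and polyA", {
  tags <- collapse_tags(c("ACGTACGTACGTACGTAC", strrep("A", 21),
                          "TTTTACGTACGTACGTACGT"))
  sets <- list(rRNA = "ACGTACGTACGTACGTAC", tRNA = "ACGTACGTACGTACGTAC")
  res <- filter_contaminants(tags, sets, polyA_fraction = 0.8)
  expect_equal(res$removed$rRNA$sequence, "ACGTACGTACGTACGTAC")  # precedence
  expect_equal(nrow(res$removed$tRNA), 0L)
  expect_equal(res$removed$polyA$sequence, strrep("A", 21))
  expect_equal(res$kept$sequence, "TTTTACGTACGTACGTACGT")        # 20% A: kept
  # kept + removed partition the input exactly
  n_removed <- sum(vapply(res$removed, nrow, 0L))
  expect_equal(nrow(res$kept) + n_removed, nrow(tags))
  expect_equal(sum(res$kept$count) + sum(vapply(res$removed, function(x) sum(x$count), 0)),
               sum(tags$count))
})

test_that("category summaries reproduce printed percentages and stay consistent", {
  # one category holding the whole library
  one <- summarize_categories(list(all = data.frame(sequence = "A", count = 100L)), 100)
  expect_equal(one$total_pct, 100)
  # the known-miRNA control row of the published distribution table
  s <- summarize_categories(list(known_miRNA = data.frame(
    sequence = "x", count = 593973L)), 10581133)
  expect_equal(s$total_pct, 5.61)
  # empty category
  s <- summarize_categories(list(none = data.frame(sequence = character(),
                                                   count = integer())), 10)
  expect_equal(s$total, 0)
  expect_equal(s$total_pct, 0)
  expect_error(summarize_categories(list(a = data.frame(sequence = "x", count = 11L)),
                                    10), "exceed")
  # percentages over a random partition sum to ~100 after rounding
  set.seed(5)
  counts <- as.integer(rmultinom(1, 10000, rep(1, 7)))
  cats <- lapply(counts, function(k) data.frame(sequence = as.character(seq_len(k)),
                                                count = rep(1L, k)))
  names(cats) <- paste0("c", 1:7)
  s <- summarize_categories(cats, 10000)
  expect_lt(abs(sum(s$total_pct) - 100), 0.05)
})

test_that("collapsed FASTA round-trips through the reader", {
  tags <- collapse_tags(c(strrep("ACG", 7), strrep("ACG", 7), strrep("TGC", 7)))
  f <- withr::local_tempfile(fileext = ".fa")
  write_collapsed_fasta(tags, f)
  rec <- read_sequences(f)
  expect_equal(rec$sequence, tags$sequence)
  expect_match(rec$id[1L], "^tag1_x2$")
})
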