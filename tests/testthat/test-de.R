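test_that("point probability matches exact rational values and the integer-log oracle", {
  for (cs in exact_point_cases) {
    got <- ac_point_probability(cs$x, cs$y, cs$n1, cs$n2)
    expect_equal(got, cs$p, tolerance = 1e-12, info = paste(cs$x, cs$y))
  }
  expect_equal(ac_point_probability(2, 1, 100, 100), 3 / 16)
  expect_equal(ac_point_probability(0, 0, 300, 100), 300 / 400)
  # broad grid against the independent integer-log route
  for (n1 in c(100, 1e6)) for (n2 in c(100, 1e6)) {
    for (x in c(0L, 1L, 7L, 25L)) for (y in c(0L, 3L, 25L)) {
      if (x + y > 50L) next
      expect_equal(log(ac_point_probability(x, y, n1, n2)),
                   oracle_log_point(x, y, n1, n2), tolerance = 1e-10)
    }
  }
})

test_that("the conditional distribution normalises to one", {
  for (x in c(0L, 3L, 40L)) {
    s <- sum(ac_point_probability(x, 0:2000, 10581133, 9856414))
    expect_equal(s, 1, tolerance = 1e-9)
  }
})

test_that("two-sided p-values are symmetric, bounded, and monotone in the tail", {
  set.seed(3)
  for (k in 1:25) {
    x <- rpois(1, 50); y <- rpois(1, 20)
    p1 <- ac_two_sided_p(x, y, 1e6, 9e5)
    p2 <- ac_two_sided_p(y, x, 9e5, 1e6)
    expect_identical(p1, p2)           # exact orientation symmetry
    expect_gt(p1, 0); expect_lte(p1, 1)
  }
  expect_equal(ac_two_sided_p(17, 17, 1e6, 1e6), 1)  # symmetric pair clamps to 1
  expect_equal(ac_two_sided_p(0, 0, 1e6, 9e5), 1)    # both-zero convention
  # upper tail D(y >= t | x) non-increasing in t
  up <- vapply(0:60, function(t)
    sum(ac_point_probability(10, t:4000, 1e6, 1e6)), 0)
  expect_true(all(diff(up) <= 1e-12))
})

test_that("normalisation reproduces printed standardised values", {
  expect_equal(round(normalize_rpm(60, 10581133), 4), 5.6705)
  expect_equal(normalize_rpm(0, 9856414), 0.01)
  expect_equal(round(normalize_rpm(100147, 9856414), 3), 10160.592)
  expect_error(normalize_rpm(-1, 10), "negative")
  expect_error(normalize_rpm(1, 0), "library_total")
})

test_that("log2 fold changes reproduce printed values", {
  expect_equal(log2_fold_change(1.4204, 5.6705), -1.9972, tolerance = 1e-3)
  expect_equal(log2_fold_change(3, 3), 0)
  expect_equal(log2_fold_change(1.4204, 0.01), 7.1502, tolerance = 1e-3)
  expect_error(log2_fold_change(0, 1), "positive")
})

test_that("significance labels follow the table-legend rule", {
  expect_equal(unlist(classify_de(-1.997, 1.96e-7)), c(sig_label = "**", regulation = "down"))
  expect_equal(classify_de(-0.948, 2.22e-39)$sig_label, "ns")
  expect_equal(unlist(classify_de(-1.772, 0.0488)), c(sig_label = "*", regulation = "down"))
  expect_equal(classify_de(2.15, 6.38e-9)$regulation, "up")
})

test_that("ac_de preserves order, rejects duplicates, handles degenerate pairs", {
  sz <- cu_library_sizes()
  pairs <- data.frame(id = c("b", "a", "z"), ck = c(21L, 0L, 0L),
                      cu = c(0L, 10L, 0L))
  tab <- run_de_table(pairs, sz)
  expect_equal(tab$id, c("b", "a", "z"))          # stable order
  expect_equal(tab$pvalue[3L], 1)
  expect_equal(tab$sig_label[3L], "ns")
  expect_equal(tab$pvalue[1L], 1.03e-6, tolerance = 0.01)
  expect_equal(tab$pvalue[2L], 6.565e-4, tolerance = 0.01)
  expect_error(ac_de(data.frame(id = c("a", "a"), ck = 1:2, cu = 1:2), sz),
               "duplicate")
  expect_equal(nrow(run_de_table(data.frame(id = character(), ck = integer(),
                                            cu = integer()), sz)), 0L)
})

test_that("ac_de methods print, summarise and plot", {
  fit <- ac_de(data.frame(id = letters[1:4], ck = c(100L, 5L, 0L, 30L),
                          cu = c(10L, 6L, 12L, 31L)), c(1e6, 1e6))
  expect_output(print(fit), "differentially expressed")
  s <- summary(fit)
  expect_s3_class(s, "summary.ac_de")
  expect_output(print(s), "labels")
  expect_equal(nrow(as.data.frame(fit)), 4L)
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("ddCt relative expression", {
  expect_equal(ddct_relative_expression(20, 20, 20, 20), 1)
  expect_equal(ddct_relative_expression(21, 20, 20, 20), 0.5)
  expect_equal(ddct_relative_expression(25, 20, 24, 20), 0.5)
})

test_that("hypergeometric enrichment agrees with fisher.test", {
  set.seed(8)
  universe <- sprintf("g%03d", 1:60)
  term_map <- list(t1 = sample(universe, 12), t2 = sample(universe, 25),
                   t3 = sample(universe, 4))
  selected <- sample(universe, 15)
  res <- enrich_hypergeometric(selected, universe, term_map)
  expect_true(all(res$k <= pmin(res$K, res$n)))
  for (i in seq_len(nrow(res))) {
    r <- res[i, ]
    ft <- fisher.test(matrix(c(r$k, r$K - r$k, r$n - r$k,
                               r$N - r$K - r$n + r$k), 2L), alternative = "greater")
    expect_equal(r$pvalue, ft$p.value, tolerance = 1e-12)
  }
  # the whole term selected, term absent elsewhere: smallest achievable p
  res <- enrich_hypergeometric(term_map$t3, universe, term_map["t3"])
  K <- 4; N <- 60; n <- 4
  expect_equal(res$pvalue, 1 / choose(N, K), tolerance = 1e-12)
  # no member selected with positive expectation: large p
  sel <- setdiff(universe, term_map$t2)[1:10]
  res <- enrich_hypergeometric(sel, universe, term_map["t2"])
  expect_gte(res$pvalue, 0.5)
  expect_error(enrich_hypergeometric("a", character(0), list(t = "a")), "universe")
  expect_error(enrich_hypergeometric("zz", universe, term_map), "subset")
})

test_that("enrichment type-I error is near nominal under uniform selection", {
  set.seed(9)
  universe <- sprintf("g%03d", 1:200)
  term <- list(t = universe[1:40])
  rej <- vapply(1:1000, function(i) {
    sel <- sample(universe, 30)
    enrich_hypergeometric(sel, universe, term)$pvalue < 0.05
  }, TRUE)
  expect_lte(mean(rej), 0.075)   # discrete test is conservative
  expect_gte(mean(rej), 0.01)
})
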