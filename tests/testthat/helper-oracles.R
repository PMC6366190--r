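# Independent oracles used across the suite.  These deliberately avoid
# the code paths of the implementation: structure enumeration instead of
# dynamic programming, integer-log products instead of lgamma, explicit
# per-offset scanning instead of vectorised column sweeps.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

oracle_pairs_ok <- function(a, b) paste0(a, b) %in% c("CG", "GC", "AT", "TA", "GT", "TG")

oracle_pair_energy <- function(a, b, par = fold_params()) {
  p <- paste0(a, b)
  if (p %in% c("CG", "GC")) par$e_gc
  else if (p %in% c("AT", "TA")) par$e_au
  else par$e_gu
}

# energy of a given pair list under the engine's declared model
oracle_struct_energy <- function(seq, pairs, par = fold_params()) {
  ch <- strsplit(seq, "")[[1L]]
  if (!length(pairs)) return(0)
  e <- 0
  for (p in pairs) {
    i <- p[1L]; j <- p[2L]
    hairpin <- !any(vapply(pairs, function(q) q[1L] > i && q[2L] < j, TRUE))
    e <- e + oracle_pair_energy(ch[i], ch[j], par) + par$hairpin * hairpin
    if (any(vapply(pairs, function(q) q[1L] == i + 1L && q[2L] == j - 1L, TRUE)))
      e <- e + par$stack
  }
  e
}

dotbracket_pairs <- function(structure) {
  ch <- strsplit(structure, "")[[1L]]
  stack <- integer(0); out <- list()
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      out[[length(out) + 1L]] <- c(stack[length(stack)], i)
      stack <- stack[-length(stack)]
    }
  }
  out
}

# exhaustive enumeration of all nested structures; returns the minimum
# model energy (min_loop = 3 hard-coded as in the engine defaults)
oracle_fold_min <- function(seq, par = fold_params()) {
  ch <- strsplit(seq, "")[[1L]]
  n <- length(ch)
  best <- 0
  enum <- function(a, b, acc, cont) {
    if (a >= b) { cont(acc); return(invisible()) }
    enum(a + 1L, b, acc, cont)
    ks <- if (a + par$min_loop + 1L <= b) (a + par$min_loop + 1L):b else integer(0)
    for (k in ks) if (oracle_pairs_ok(ch[a], ch[k]))
      enum(a + 1L, k - 1L, c(acc, list(c(a, k))),
           function(acc2) enum(k + 1L, b, acc2, cont))
    invisible()
  }
  enum(1L, n, list(), function(acc) best <<- min(best, oracle_struct_energy(seq, acc, par)))
  best
}

# log point probability via explicit integer-log products (no lgamma)
oracle_log_point <- function(x, y, N1, N2) {
  r <- N2 / N1
  lc <- if (y > 0) sum(log(seq.int(x + 1, x + y))) - sum(log(seq_len(y))) else 0
  y * log(r) + lc - (x + y + 1) * log1p(r)
}

# brute-force target-site scan: one offset at a time, explicit base pairing
oracle_scan <- function(mirna, transcript, max_mismatches = 4L,
                        wobble_is_mismatch = TRUE) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  m <- strsplit(mirna, "")[[1L]]
  L <- length(m)
  tr <- strsplit(transcript, "")[[1L]]
  hits <- list()
  for (off in seq_len(length(tr) - L + 1L)) {
    site <- tr[off:(off + L - 1L)]
    mm <- 0L; wb <- 0L
    for (p in seq_len(L)) {
      t <- site[L - p + 1L]
      if (t == comp[[m[p]]]) next
      if ((m[p] == "G" && t == "T") || (m[p] == "T" && t == "G")) wb <- wb + 1L
      else mm <- mm + 1L
    }
    total <- if (wobble_is_mismatch) mm + wb else mm
    if (total < max_mismatches)
      hits[[length(hits) + 1L]] <- data.frame(start = off - 1L, mismatches = total,
                                              wobbles = wb)
  }
  if (!length(hits)) return(data.frame(start = integer(), mismatches = integer(),
                                       wobbles = integer()))
  do.call(rbind, hits)
}

# exact point-probability values computed with exact rational arithmetic
# (integer powers and binomials over a common denominator) and frozen here
exact_point_cases <- list(
  list(x = 0L, y = 0L, n1 = 100, n2 = 100, p = 5.00000000000000000e-01),
  list(x = 2L, y = 1L, n1 = 100, n2 = 100, p = 1.87500000000000000e-01),
  list(x = 5L, y = 0L, n1 = 100, n2 = 93, p = 1.93488940244159677e-02),
  list(x = 0L, y = 7L, n1 = 1000000, n2 = 931500, p = 3.14139331189833022e-03),
  list(x = 10L, y = 40L, n1 = 100, n2 = 1000000, p = 1.02200255214276498e-34),
  list(x = 25L, y = 25L, n1 = 1000000, n2 = 1000000, p = 5.61375863296085242e-02),
  list(x = 3L, y = 17L, n1 = 1000000, n2 = 100, p = 1.13760863138227067e-65),
  list(x = 50L, y = 0L, n1 = 1000000, n2 = 931500, p = 2.62645318086077557e-15),
  list(x = 13L, y = 29L, n1 = 100, n2 = 100, p = 2.90114386189088691e-03),
  list(x = 1L, y = 1L, n1 = 1000000, n2 = 9999, p = 1.94099194314259864e-02),
  list(x = 21L, y = 0L, n1 = 10581133, n2 = 9856414, p = 5.13186118375145656e-07),
  list(x = 0L, y = 10L, n1 = 10581133, n2 = 9856414, p = 3.52374997894692630e-04))

# a perfect synthetic hairpin: mature + loop + reverse complement
make_perfect_hairpin <- function(mature, loop = "GAATTCGA") {
  paste0(mature, loop, revcomp(mature))
}
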