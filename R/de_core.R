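#' Reads-per-million normalisation with zero floor
#'
#' `count x 1e6 / library_total` for positive counts; zero counts map to
#' the `zero_floor` constant so that fold changes against an undetected
#' miRNA remain defined.
#'
#' @param count integer vector of read counts (>= 0).
#' @param library_total total reads of the library (> 0).
#' @param zero_floor value substituted for zero counts (default 0.01).
#' @return numeric vector of normalised expression values.
#' @examples
#' normalize_rpm(c(60, 0), 10581133)
#' @export
normalize_rpm <- function(count, library_total, zero_floor = 0.01) {
  if (any(count < 0)) stop("negative count", call. = FALSE)
  if (library_total <= 0) stop("library_total must be > 0", call. = FALSE)
  ifelse(count > 0, count * 1e6 / library_total, zero_floor)
}

#' Log2 fold change of normalised expression
#'
#' @param std_cu,std_ck normalised expression in treatment and control
#'   (both > 0; apply the zero floor first).
#' @return `log2(std_cu / std_ck)`.
#' @export
log2_fold_change <- function(std_cu, std_ck) {
  if (any(std_cu <= 0) || any(std_ck <= 0))
    stop("normalised values must be positive (apply the zero floor first)",
         call. = FALSE)
  log2(std_cu / std_ck)
}

# log point probability log p(y | x) for library-size ratio r = N2/N1:
#   p(y|x) = r^y (x+y)! / (x! y! (1+r)^(x+y+1))
ac_log_point <- function(y, x, log_r, log1p_r) {
  y * log_r + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1p_r
}

#' Audic-Claverie point probability
#'
#' Probability of observing `y` reads of a tag in a library of `N2`
#' total reads given `x` reads in a library of `N1` total reads, under
#' the Poisson sampling model:
#' `p(y|x) = (N2/N1)^y (x+y)! / (x! y! (1+N2/N1)^(x+y+1))`.
#' Evaluated in log space via log-gamma, so counts up to at least 1e7
#' are safe from overflow.
#'
#' @param x,y observed counts (>= 0), vectorised.
#' @param N1,N2 library totals (> 0).
#' @return numeric vector of probabilities.
#' @examples
#' ac_point_probability(2, 1, 100, 100)  # 3/16
#' @export
ac_point_probability <- function(x, y, N1, N2) {
  stopifnot(all(x >= 0), all(y >= 0), N1 > 0, N2 > 0)
  r <- N2 / N1
  exp(ac_log_point(y, x, log(r), log1p(r)))
}

# one-orientation tails at the observed count y, conditioning on x with
# ratio r = N_other/N_cond.  Log-space accumulation in chunks; summation
# stops when the last chunk contributes < rel_tol of the partial sum.
ac_tails <- function(x, y, r, rel_tol = 1e-12, chunk = 2048L) {
  log_r <- log(r); l1p <- log1p(r)
  lse <- function(cur, lp) {
    # cur is a log partial sum (or -Inf); lp a vector of log terms
    m <- max(cur, lp)
    if (!is.finite(m)) return(-Inf)
    m + log(sum(exp(c(cur, lp) - m)))
  }
  # lower tail: t = y, y-1, ..., 0
  lo <- -Inf
  t_hi <- y
  repeat {
    if (t_hi < 0) break
    ts <- seq.int(t_hi, max(0, t_hi - chunk + 1L))
    lp <- ac_log_point(ts, x, log_r, l1p)
    new <- lse(lo, lp)
    if (is.finite(new) && is.finite(lo) && new - lo < rel_tol) { lo <- new; break }
    lo <- new
    t_hi <- t_hi - chunk
  }
  # upper tail: t = y, y+1, ... until the tail contribution is negligible
  up <- -Inf
  t_lo <- y
  repeat {
    ts <- seq.int(t_lo, t_lo + chunk - 1L)
    lp <- ac_log_point(ts, x, log_r, l1p)
    new <- lse(up, lp)
    # geometric bound once past the mode: stop when the chunk added < rel_tol
    if (is.finite(new) && is.finite(up) && new - up < rel_tol &&
        lp[chunk] < lp[1L]) { up <- new; break }
    up <- new
    t_lo <- t_lo + chunk
    if (t_lo > y + 5e7) break  # safety valve, never reached for real totals
  }
  c(lower = lo, upper = up)  # log scale
}

#' Audic-Claverie two-sided p-value
#'
#' Two-sided significance of a count difference between two libraries.
#' For each orientation (conditioning on `x` with ratio `N2/N1`, and on
#' `y` with ratio `N1/N2`) the lower and upper cumulative tails at the
#' observed other count are summed (to relative tolerance 1e-12, in log
#' space) and doubled at the smaller tail; the reported p-value is the
#' minimum over the two orientations, clamped to at most 1.  A pair with
#' both counts zero is defined as p = 1.  The orientation symmetry
#' `ac_two_sided_p(x, y, N1, N2) == ac_two_sided_p(y, x, N2, N1)` holds
#' exactly by construction.
#'
#' @param x,y observed counts (vectorised).
#' @param N1,N2 library totals.
#' @return numeric vector of p-values in (0, 1].
#' @examples
#' ac_two_sided_p(21, 0, 10581133, 9856414)  # about 1.03e-6
#' @export
ac_two_sided_p <- function(x, y, N1, N2) {
  stopifnot(all(x >= 0), all(y >= 0), N1 > 0, N2 > 0)
  one <- function(x, y) {
    if (x == 0 && y == 0) return(1)
    p <- Inf
    for (o in 1:2) {
      tl <- if (o == 1) ac_tails(x, y, N2 / N1) else ac_tails(y, x, N1 / N2)
      p <- min(p, 2 * exp(min(tl)))
    }
    min(1, max(p, .Machine$double.xmin))
  }
  mapply(one, x, y)
}

#' Significance labels for differential expression
#'
#' Implements the table-legend rule of two-library small-RNA studies:
#' `**` when |log2FC| >= `fc_thresh` and p < `alpha_strong`, `*` when
#' |log2FC| >= `fc_thresh` and `alpha_strong` <= p < `alpha_weak`,
#' otherwise `ns`.  Regulation is `up`/`down` by the fold-change sign
#' for labelled entries and `none` otherwise.
#'
#' @param log2fc,pvalue numeric vectors.
#' @param fc_thresh fold-change threshold (default 1).
#' @param alpha_strong,alpha_weak p-value thresholds (defaults 0.01 and
#'   0.05).
#' @return data.frame with `sig_label` and `regulation`.
#' @export
classify_de <- function(log2fc, pvalue, fc_thresh = 1,
                        alpha_strong = 0.01, alpha_weak = 0.05) {
  stopifnot(alpha_strong <= alpha_weak)
  lab <- ifelse(abs(log2fc) >= fc_thresh & pvalue < alpha_strong, "**",
         ifelse(abs(log2fc) >= fc_thresh & pvalue < alpha_weak, "*", "ns"))
  reg <- ifelse(lab == "ns", "none", ifelse(log2fc < 0, "down", "up"))
  data.frame(sig_label = lab, regulation = reg)
}

#' Relative expression by the 2^-ddCt method
#'
#' @param ct_target_trt,ct_ref_trt,ct_target_ctl,ct_ref_ctl cycle
#'   threshold values of target and reference gene under treatment and
#'   control.
#' @return `2^-((ct_target_trt - ct_ref_trt) - (ct_target_ctl - ct_ref_ctl))`.
#' @examples
#' ddct_relative_expression(25, 20, 24, 20)  # 0.5
#' @export
ddct_relative_expression <- function(ct_target_trt, ct_ref_trt,
                                     ct_target_ctl, ct_ref_ctl) {
  stopifnot(is.finite(ct_target_trt), is.finite(ct_ref_trt),
            is.finite(ct_target_ctl), is.finite(ct_ref_ctl))
  2^-((ct_target_trt - ct_ref_trt) - (ct_target_ctl - ct_ref_ctl))
}

#' Hypergeometric (one-sided Fisher) term enrichment
#'
#' Over-representation p-value per term for a selection of ids within a
#' universe, from the exact hypergeometric upper tail of the 2x2 table.
#'
#' @param selected character vector of selected ids (subset of
#'   `universe`).
#' @param universe character vector of all ids.
#' @param term_map named list mapping term id to the ids annotated with
#'   it.
#' @return data.frame with `term`, `k` (selected in term), `K` (universe
#'   in term), `n` (selection size), `N` (universe size), `pvalue`,
#'   ordered by p-value.
#' @export
enrich_hypergeometric <- function(selected, universe, term_map) {
  universe <- unique(universe)
  selected <- unique(selected)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  if (!all(selected %in% universe))
    stop("selected ids must be a subset of the universe", call. = FALSE)
  N <- length(universe); n <- length(selected)
  rows <- lapply(names(term_map), function(tm) {
    members <- intersect(term_map[[tm]], universe)
    K <- length(members)
    k <- length(intersect(members, selected))
    data.frame(term = tm, k = k, K = K, n = n, N = N,
               pvalue = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  out[order(out$pvalue, out$term), , drop = FALSE]
}
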