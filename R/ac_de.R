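#' Exact two-library differential expression test
#'
#' Fits the full differential-expression analysis of a two-library
#' count experiment: reads-per-million normalisation with zero floor,
#' log2 fold change, exact Audic-Claverie two-sided p-value per tag,
#' and significance labelling.  This is the single-replicate exact-test
#' counterpart of replicate-based count models; no multiple-testing
#' correction is applied.
#'
#' @param pairs data.frame with columns `id`, `ck` (control counts) and
#'   `cu` (treatment counts); an optional `sequence` column is carried
#'   through.
#' @param sizes numeric vector of length 2 with the library totals,
#'   `c(ck, cu)` (control first).
#' @param zero_floor substituted for zero normalised counts (default
#'   0.01).
#' @param fc_thresh,alpha_strong,alpha_weak labelling thresholds, see
#'   [classify_de()].
#' @return an object of class `"ac_de"`; its `$table` holds one row per
#'   input pair (input order preserved) with `ck_std`, `cu_std`,
#'   `log2fc`, `pvalue`, `sig_label`, `regulation`.
#' @examples
#' fit <- ac_de(data.frame(id = "vvi-miR397a", ck = 21, cu = 0),
#'              sizes = c(10581133, 9856414))
#' fit$table$pvalue  # about 1.03e-6
#' @seealso [run_de_table()] for the plain data.frame interface,
#'   [cu_count_table()] for the bundled worked-example data.
#' @export
ac_de <- function(pairs, sizes, zero_floor = 0.01, fc_thresh = 1,
                  alpha_strong = 0.01, alpha_weak = 0.05) {
  stopifnot(is.data.frame(pairs), all(c("id", "ck", "cu") %in% names(pairs)),
            length(sizes) == 2L, all(sizes > 0))
  if (anyDuplicated(pairs$id))
    stop("duplicate id: ", pairs$id[duplicated(pairs$id)][1L], call. = FALSE)
  ck_std <- normalize_rpm(pairs$ck, sizes[1L], zero_floor)
  cu_std <- normalize_rpm(pairs$cu, sizes[2L], zero_floor)
  log2fc <- log2_fold_change(cu_std, ck_std)
  pvalue <- ac_two_sided_p(pairs$ck, pairs$cu, sizes[1L], sizes[2L])
  cls <- classify_de(log2fc, pvalue, fc_thresh, alpha_strong, alpha_weak)
  tab <- data.frame(id = pairs$id)
  if ("sequence" %in% names(pairs)) tab$sequence <- pairs$sequence
  tab <- cbind(tab, data.frame(ck = pairs$ck, ck_std = ck_std,
                               cu = pairs$cu, cu_std = cu_std,
                               log2fc = log2fc, pvalue = pvalue), cls)
  structure(list(table = tab,
                 sizes = setNames(as.numeric(sizes), c("ck", "cu")),
                 thresholds = list(zero_floor = zero_floor,
                                   fc_thresh = fc_thresh,
                                   alpha_strong = alpha_strong,
                                   alpha_weak = alpha_weak),
                 call = match.call()),
            class = "ac_de")
}

#' @export
print.ac_de <- function(x, ...) {
  cat("Audic-Claverie two-library differential expression\n")
  cat(sprintf("  library totals: ck = %s, cu = %s\n",
              format(x$sizes[["ck"]], big.mark = ","),
              format(x$sizes[["cu"]], big.mark = ",")))
  n <- nrow(x$table)
  de <- sum(x$table$sig_label != "ns")
  cat(sprintf("  %d tags tested, %d differentially expressed (|log2FC| >= %g, p < %g)\n",
              n, de, x$thresholds$fc_thresh, x$thresholds$alpha_weak))
  cat(sprintf("    up: %d   down: %d\n",
              sum(x$table$regulation == "up"), sum(x$table$regulation == "down")))
  invisible(x)
}

#' @export
summary.ac_de <- function(object, ...) {
  tab <- object$table
  out <- list(n = nrow(tab),
              labels = table(factor(tab$sig_label, c("**", "*", "ns"))),
              regulation = table(factor(tab$regulation, c("up", "down", "none"))),
              top = head(tab[order(tab$pvalue), ], 10L),
              thresholds = object$thresholds)
  class(out) <- "summary.ac_de"
  out
}

#' @export
print.summary.ac_de <- function(x, ...) {
  cat(sprintf("%d tags; labels: ** %d, * %d, ns %d; up %d, down %d\n",
              x$n, x$labels[["**"]], x$labels[["*"]], x$labels[["ns"]],
              x$regulation[["up"]], x$regulation[["down"]]))
  cat("Top tags by p-value:\n")
  print(x$top, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.ac_de <- function(x, ...) x$table

#' Volcano plot of an `ac_de` fit
#'
#' @param x an [ac_de()] object.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ac_de <- function(x, ...) {
  tab <- x$table
  logp <- -log10(pmax(tab$pvalue, 1e-320))
  col <- ifelse(tab$sig_label == "ns", "grey50",
                ifelse(tab$regulation == "up", "firebrick", "steelblue"))
  graphics::plot(tab$log2fc, logp, col = col, pch = 16,
                 xlab = expression(log[2] ~ "fold change (cu/ck)"),
                 ylab = expression(-log[10] ~ "p"), ...)
  graphics::abline(v = c(-1, 1) * x$thresholds$fc_thresh, lty = 2, col = "grey70")
  graphics::abline(h = -log10(x$thresholds$alpha_weak), lty = 2, col = "grey70")
  invisible(x)
}

#' Differential-expression table for a list of count pairs
#'
#' Plain-function interface around [ac_de()]: normalise, fold change,
#' exact two-sided p, classify, preserving input order.
#'
#' @inheritParams ac_de
#' @param ... passed to [ac_de()].
#' @return the per-tag results data.frame.
#' @export
run_de_table <- function(pairs, sizes, ...) {
  ac_de(pairs, sizes, ...)$table
}
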