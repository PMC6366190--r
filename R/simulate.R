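#' Simulation configuration
#'
#' Study-design parameters of the synthetic two-library experiment the
#' generator emulates: one control and one treated library of unequal
#' depth, planted hairpin loci expressed at known rates, a configurable
#' number of truly differentially expressed miRNAs, and contaminant
#' background for the filtering stages to work on.
#'
#' @param seed RNG seed (always explicit).
#' @param n_mirnas number of planted miRNA hairpin loci.
#' @param n_de number of truly differentially expressed miRNAs
#'   (`n_de <= n_mirnas`).
#' @param log2fc true fold-change magnitude of the DE miRNAs (log2).
#' @param n1,n2 library totals used for normalisation and count
#'   sampling (control and treatment).
#' @param baseline_rpm range of baseline expression (reads per million)
#'   the planted miRNAs are drawn from.
#' @param contaminant_fraction fraction of emitted reads drawn from the
#'   contaminant decoy sets.
#' @param adapter 3' adapter ligated onto every emitted read.
#' @param dispersion extra-Poisson dispersion knob; 0 (the default)
#'   gives pure Poisson sampling, matching the sampling model of the
#'   exact test.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_mirnas = 50L, n_de = 10L, log2fc = 2,
                       n1 = 1e6, n2 = 1e6, baseline_rpm = c(50, 500),
                       contaminant_fraction = 0.3,
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       dispersion = 0) {
  stopifnot(n_de <= n_mirnas, n1 > 0, n2 > 0,
            contaminant_fraction >= 0, contaminant_fraction < 1)
  structure(list(seed = as.integer(seed), n_mirnas = as.integer(n_mirnas),
                 n_de = as.integer(n_de), log2fc = log2fc, n1 = n1, n2 = n2,
                 baseline_rpm = baseline_rpm,
                 contaminant_fraction = contaminant_fraction,
                 adapter = adapter, dispersion = dispersion),
            class = "sim_config")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

#' Generate a toy genome with planted miRNA hairpins
#'
#' Embeds `n_mirnas` hairpin precursors in a single synthetic
#' chromosome: each precursor is a random 21-nt mature arm, an 8-12 nt
#' loop, and the mature arm's reverse complement carrying up to two
#' planted G:U wobbles, separated by random spacer sequence.  The
#' first `n_de` miRNAs alternate up-/down-regulation at the configured
#' fold change; the rest are null.  Deterministic for a fixed seed.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named character vector), `truth`
#'   (data.frame: `name`, `mature`, `seqname`, `start`, `end`, `strand`,
#'   `precursor_start`, `precursor_end`, `rpm_ck`, `rpm_cu`,
#'   `true_log2fc`, `de`) and `config`.
#' @export
make_toy_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$n_mirnas
  matures <- character(n)
  repeat {
    matures <- vapply(seq_len(n), function(i) rand_dna(21L), "")
    if (!anyDuplicated(matures)) break
  }
  parts <- character(0)
  pos <- 0L
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    spacer <- rand_dna(sample(120:220, 1L))
    loop <- rand_dna(sample(8:12, 1L))
    star <- strsplit(revcomp(matures[i]), "")[[1L]]
    # plant up to 2 G:U wobbles: a C opposite a mature G becomes T
    cpos <- which(star == "C")
    nw <- min(length(cpos), sample(0:2, 1L))
    if (nw > 0L) star[sample(cpos, nw)] <- "T"
    star <- paste(star, collapse = "")
    pre <- paste0(matures[i], loop, star)
    parts <- c(parts, spacer, pre)
    p0 <- pos + nchar(spacer)
    truth[[i]] <- data.frame(name = sprintf("sim_mir_%02d", i),
                             mature = matures[i], seqname = "chrsim",
                             start = p0, end = p0 + 21L, strand = "+",
                             precursor_start = p0,
                             precursor_end = p0 + nchar(pre))
    pos <- p0 + nchar(pre)
  }
  parts <- c(parts, rand_dna(150L))
  truth <- do.call(rbind, truth)
  # expression ground truth
  base <- runif(n, config$baseline_rpm[1L], config$baseline_rpm[2L])
  fc <- rep(0, n)
  if (config$n_de > 0L)
    fc[seq_len(config$n_de)] <- config$log2fc * rep_len(c(1, -1), config$n_de)
  truth$rpm_ck <- base
  truth$rpm_cu <- base * 2^fc
  truth$true_log2fc <- fc
  truth$de <- abs(fc) >= 1
  genome <- c(chrsim = paste(parts, collapse = ""))
  list(genome = genome, truth = truth, config = config)
}

# decoy contaminant sets the filtering stages can act on
make_decoys <- function(n_per_set = 12L) {
  list(rRNA = vapply(seq_len(n_per_set), function(i) rand_dna(sample(18:30, 1L)), ""),
       tRNA = vapply(seq_len(n_per_set), function(i) rand_dna(sample(18:30, 1L)), ""))
}

#' Simulate two small-RNA libraries from planted ground truth
#'
#' Per miRNA and library, the read count is Poisson with mean
#' `true_RPM x N / 1e6` (a dispersion knob adds gamma noise to the rate
#' when nonzero).  Each read is emitted as the mature sequence with the
#' 3' adapter appended, mixed with contaminant background reads drawn
#' from planted rRNA/tRNA decoy sets.  True counts are recorded.
#'
#' @param truth the truth table of [make_toy_genome()], or the full
#'   list it returns (in which case `config` and the genome are taken
#'   from it).
#' @param config a [sim_config()].
#' @param dir optional directory; when given, `reads_ck.fastq`,
#'   `reads_cu.fastq`, `genome.fa`, `mature_ref.fa`, `truth.tsv` and
#'   `contaminants.tsv` are written there.
#' @return list with `reads` (per-library data.frames `id`, `sequence`,
#'   `quality`), `counts` (`name`, `ck`, `cu` true counts),
#'   `contaminants` (the decoy sets) and `config`.
#' @export
simulate_libraries <- function(truth, config = sim_config(), dir = NULL) {
  genome <- NULL
  if (!is.data.frame(truth) && is.list(truth) && !is.null(truth$truth)) {
    genome <- truth$genome
    config <- truth$config
    truth <- truth$truth
  }
  set.seed(config$seed + 1L)
  decoys <- make_decoys()
  n <- nrow(truth)
  draw <- function(rpm, total) {
    mu <- rpm * total / 1e6
    if (config$dispersion > 0)
      mu <- mu * stats::rgamma(length(mu), shape = 1 / config$dispersion,
                               scale = config$dispersion)
    rpois(length(mu), mu)
  }
  counts <- data.frame(name = truth$name,
                       ck = draw(truth$rpm_ck, config$n1),
                       cu = draw(truth$rpm_cu, config$n2))
  emit <- function(cnt) {
    mir_reads <- rep(paste0(truth$mature, config$adapter), cnt)
    n_cont <- if (config$contaminant_fraction > 0)
      rpois(1L, sum(cnt) * config$contaminant_fraction / (1 - config$contaminant_fraction))
    else 0L
    cont <- if (n_cont > 0L)
      paste0(sample(unlist(decoys), n_cont, replace = TRUE), config$adapter)
    else character(0)
    reads <- sample(c(mir_reads, cont))
    data.frame(id = sprintf("read_%06d", seq_along(reads)), sequence = reads,
               quality = strrep("I", nchar(reads)))
  }
  reads <- list(ck = emit(counts$ck), cu = emit(counts$cu))
  out <- list(reads = reads, counts = counts, contaminants = decoys,
              config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fastq(reads$ck, file.path(dir, "reads_ck.fastq"))
    write_fastq(reads$cu, file.path(dir, "reads_cu.fastq"))
    if (!is.null(genome))
      writeLines(as.vector(rbind(paste0(">", names(genome)), unname(genome))),
                 file.path(dir, "genome.fa"))
    writeLines(as.vector(rbind(paste0(">", truth$name), truth$mature)),
               file.path(dir, "mature_ref.fa"))
    write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cont <- data.frame(category = rep(names(decoys), lengths(decoys)),
                       sequence = unlist(decoys, use.names = FALSE))
    write.table(cont, file.path(dir, "contaminants.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(counts, file.path(dir, "true_counts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}

#' Write reads as FASTQ
#'
#' @param reads data.frame with `id`, `sequence`, `quality`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- as.vector(rbind(paste0("@", reads$id), reads$sequence,
                           "+", reads$quality))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate null count pairs for test calibration
#'
#' Independent `x ~ Poisson(rate x N1/1e6)` and
#' `y ~ Poisson(rate x N2/1e6)` pairs sharing a common expression rate:
#' the null of the two-library exact test.
#'
#' @param n_pairs number of pairs.
#' @param rate common expression rate (reads per million, > 0).
#' @param N1,N2 library totals.
#' @param seed RNG seed.
#' @return data.frame with columns `x` and `y`.
#' @export
simulate_null_pairs <- function(n_pairs, rate, N1, N2, seed = 1L) {
  stopifnot(rate > 0)
  set.seed(seed)
  data.frame(x = rpois(n_pairs, rate * N1 / 1e6),
             y = rpois(n_pairs, rate * N2 / 1e6))
}
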