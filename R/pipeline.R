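#' Pipeline configuration with documented defaults
#'
#' All stage thresholds of the small-RNA pipeline in one flat list.
#' Paths may stay `NULL` until the stage that needs them runs.
#'
#' @param ... overrides of the default keys (unknown keys are an
#'   error).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # paths
    reads_ck = NULL, reads_cu = NULL, genome = NULL, mature_ref = NULL,
    contaminants = NULL, transcripts = NULL, term_map = NULL,
    outdir = "cumira_out",
    # library totals used for normalisation
    n_ck = NULL, n_cu = NULL,
    # preprocessing
    adapter = "TGGAATTCTCGGGTGCCAAGG", min_overlap = 8L,
    min_len = 18L, max_len = 30L, polyA_fraction = 0.8,
    # known matching
    max_total_mm = 3L, max_first16_mm = 1L, max_overhang = 2L,
    # novel discovery
    max_loci = 16L, flanks = c(100L, 150L, 200L),
    max_duplex_mismatch = 4L, mfei_min = 0.80, engine = "internal",
    # differential expression
    zero_floor = 0.01, fc_thresh = 1, alpha_strong = 0.01, alpha_weak = 0.05,
    # target prediction
    max_mismatches = 4L, wobble_is_mismatch = TRUE,
    # simulate stage
    sim_n_mirnas = 50L, sim_n_de = 10L,
    seed = 1L)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' @param config a [pipeline_config()].
#' @return character vector of problems, empty when the configuration
#'   is usable; each problem names the offending key.
#' @export
validate_config <- function(config) {
  p <- character(0)
  chk <- function(cond, msg) if (isTRUE(cond)) p <<- c(p, msg)
  chk(!is.null(config$n_ck) && config$n_ck <= 0, "n_ck: library total must be > 0")
  chk(!is.null(config$n_cu) && config$n_cu <= 0, "n_cu: library total must be > 0")
  chk(config$min_len > config$max_len, "min_len/max_len: empty length window")
  chk(config$polyA_fraction <= 0 || config$polyA_fraction > 1,
      "polyA_fraction: must be in (0, 1]")
  chk(config$min_overlap < 1, "min_overlap: must be >= 1")
  chk(config$alpha_weak < config$alpha_strong,
      "alpha ordering: alpha_weak must be >= alpha_strong")
  chk(config$zero_floor <= 0, "zero_floor: must be > 0")
  chk(config$mfei_min < 0, "mfei_min: must be >= 0")
  chk(!config$engine %in% c("internal", "vienna"), "engine: unknown engine")
  p
}

log_stage <- function(config, stage, ...) {
  msg <- sprintf("[%s] %s", stage, paste(sprintf("%s=%s", names(c(...)), c(...)),
                                         collapse = " "))
  cat(msg, "\n", sep = "", file = file.path(config$outdir, "run.log"),
      append = TRUE)
  message(msg)
}

out_path <- function(config, name) file.path(config$outdir, name)

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run a pipeline stage
#'
#' Orchestrates the analysis stages over the files named in the
#' configuration, writing stage TSVs and a run log (with input/output
#' record counts per stage) under `config$outdir`.
#'
#' Stages: `simulate` (generate a toy genome and two read libraries
#' with ground truth), `preprocess` (trim, length-filter, collapse,
#' contaminant-partition both libraries; writes the per-category
#' summary), `known` (assign tags to the mature reference), `novel`
#' (map unannotated tags, excise and fold precursor windows, screen
#' hairpins), `de` (exact differential expression on a counts table),
#' `targets` (complementarity scan of miRNAs against transcripts plus
#' the network edge list), `enrich` (term enrichment of the DE set)
#' and `report` (collate stage outputs).
#'
#' @param subcommand stage name, see Details.
#' @param config a [pipeline_config()].
#' @return invisibly, a named list of the artifact paths written.
#' @export
run_pipeline <- function(subcommand = c("preprocess", "known", "novel", "de",
                                        "targets", "enrich", "simulate",
                                        "report"),
                         config = pipeline_config()) {
  subcommand <- match.arg(subcommand)
  probs <- validate_config(config)
  if (length(probs)) stop("invalid config: ", paste(probs, collapse = "; "),
                          call. = FALSE)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  need <- function(key) {
    v <- config[[key]]
    if (is.null(v)) stop("config key '", key, "' required for stage ",
                         subcommand, call. = FALSE)
    if (is.character(v) && !file.exists(v))
      stop("missing input for '", key, "': ", v, call. = FALSE)
    v
  }
  switch(subcommand,
         simulate = stage_simulate(config),
         preprocess = stage_preprocess(config, need),
         known = stage_known(config, need),
         novel = stage_novel(config, need),
         de = stage_de(config, need),
         targets = stage_targets(config, need),
         enrich = stage_enrich(config, need),
         report = stage_report(config))
}

stage_simulate <- function(config) {
  sc <- sim_config(seed = config$seed, n_mirnas = config$sim_n_mirnas,
                   n_de = config$sim_n_de,
                   n1 = config$n_ck %||% 1e6, n2 = config$n_cu %||% 1e6,
                   adapter = config$adapter)
  sim <- make_toy_genome(sc)
  simulate_libraries(sim, dir = config$outdir)
  log_stage(config, "simulate", n_mirnas = sc$n_mirnas, seed = sc$seed)
  invisible(list(genome = out_path(config, "genome.fa"),
                 reads_ck = out_path(config, "reads_ck.fastq"),
                 reads_cu = out_path(config, "reads_cu.fastq"),
                 truth = out_path(config, "truth.tsv")))
}

preprocess_one <- function(config, path, label) {
  reads <- read_sequences(path)
  trimmed <- trim_adapter(reads$sequence, config$adapter, config$min_overlap)
  clean <- trimmed[!is.na(trimmed) &
                     length_filter(trimmed, config$min_len, config$max_len)]
  tags <- collapse_tags(clean, library = label)
  contam <- if (!is.null(config$contaminants)) {
    tab <- read.delim(config$contaminants)
    split(tab$sequence, tab$category)
  } else list()
  parts <- filter_contaminants(tags, contam, config$polyA_fraction)
  log_stage(config, paste0("preprocess:", label),
            raw = nrow(reads), trimmed = sum(!is.na(trimmed)),
            clean = length(clean), tags = nrow(tags),
            kept = nrow(parts$kept))
  list(tags = tags, parts = parts, n_raw = nrow(reads))
}

stage_preprocess <- function(config, need) {
  res <- list(ck = preprocess_one(config, need("reads_ck"), "ck"),
              cu = preprocess_one(config, need("reads_cu"), "cu"))
  paths <- list()
  for (lib in names(res)) {
    kept <- res[[lib]]$parts$kept
    paths[[lib]] <- out_path(config, sprintf("tags_%s.fa", lib))
    write_collapsed_fasta(kept, paths[[lib]])
    summ <- summarize_categories(
      c(res[[lib]]$parts$removed, list(unannotated = kept)),
      library_total = max(res[[lib]]$n_raw, 1L))
    write_tsv(summ, out_path(config, sprintf("categories_%s.tsv", lib)))
  }
  # merged per-tag count table across the two libraries
  merged <- merge(res$ck$parts$kept, res$cu$parts$kept,
                  by = "sequence", all = TRUE, suffixes = c("_ck", "_cu"))
  merged[is.na(merged)] <- 0L
  names(merged) <- c("sequence", "ck", "cu")
  paths$tags <- write_tsv(merged, out_path(config, "tags.tsv"))
  invisible(paths)
}

stage_known <- function(config, need) {
  tags <- read.delim(out_path(config, "tags.tsv"))
  refs <- read_mature_fasta(need("mature_ref"))
  matches <- match_known_tags(tags, refs, max_total = config$max_total_mm,
                              max_first16 = config$max_first16_mm,
                              max_overhang = config$max_overhang)
  counts <- aggregate_known_counts(matches, c("ck", "cu"))
  names(counts)[1L] <- "id"
  log_stage(config, "known", tags = nrow(tags), matched = nrow(matches),
            references = nrow(counts))
  write_tsv(matches, out_path(config, "known_matches.tsv"))
  write_tsv(counts, out_path(config, "known_counts.tsv"))
  unann <- tags[!tags$sequence %in% matches$sequence, , drop = FALSE]
  write_tsv(unann, out_path(config, "unannotated_tags.tsv"))
  invisible(list(matches = out_path(config, "known_matches.tsv"),
                 counts = out_path(config, "known_counts.tsv"),
                 unannotated = out_path(config, "unannotated_tags.tsv")))
}

stage_novel <- function(config, need) {
  tags <- read.delim(out_path(config, "unannotated_tags.tsv"))
  genome_df <- read_sequences(need("genome"))
  genome <- setNames(genome_df$sequence, sub("\\s.*$", "", genome_df$id))
  cand_rows <- list(); struct_lines <- character(0); counts <- list()
  for (i in seq_len(nrow(tags))) {
    loci <- map_exact(tags$sequence[i], genome, config$max_loci)
    if (nrow(loci) == 0L) next
    found <- FALSE
    for (j in seq_len(nrow(loci))) {
      wins <- excise_windows(loci[j, ], genome, config$flanks)
      for (k in seq_len(nrow(wins))) {
        wf <- fold_rna(wins$sequence[k], engine = config$engine)
        hp <- excise_hairpin(wins$sequence[k], wf$structure,
                             wins$mature_offset[k], wins$mature_length[k])
        if (is.null(hp)) {
          cand_rows[[length(cand_rows) + 1L]] <- data.frame(
            sequence = tags$sequence[i], seqname = wins$seqname[k],
            start = wins$window_start[k] + 1L, end = wins$window_end[k],
            strand = wins$strand[k], precursor_length = NA_integer_,
            mfe = wf$mfe, amfe = NA_real_, gc_percent = NA_real_,
            mfei = NA_real_, pass = FALSE,
            reasons = "no stem-loop spanning mature")
          next
        }
        fr <- fold_rna(hp$sequence, engine = config$engine)
        cand <- list(sequence = hp$sequence, structure = fr$structure,
                     mfe = fr$mfe, mature_offset = hp$mature_offset,
                     mature_length = wins$mature_length[k])
        v <- validate_hairpin(cand,
                              criteria = list(max_duplex_mismatch = config$max_duplex_mismatch,
                                              mfei_min = config$mfei_min))
        cand_rows[[length(cand_rows) + 1L]] <- data.frame(
          sequence = tags$sequence[i], seqname = wins$seqname[k],
          start = wins$window_start[k] + 1L, end = wins$window_end[k],
          strand = wins$strand[k], precursor_length = v$metrics$length,
          mfe = fr$mfe, amfe = v$metrics$amfe, gc_percent = v$metrics$gc_percent,
          mfei = v$metrics$mfei, pass = v$pass,
          reasons = paste(v$reasons, collapse = ";"))
        if (v$pass && !found) {
          found <- TRUE
          struct_lines <- c(struct_lines, paste0(">", tags$sequence[i]),
                            hp$sequence, fr$structure)
        }
      }
    }
    if (found)
      counts[[length(counts) + 1L]] <-
        data.frame(id = paste0("novel_", tags$sequence[i]),
                   sequence = tags$sequence[i],
                   ck = tags$ck[i], cu = tags$cu[i])
  }
  cands <- if (length(cand_rows)) do.call(rbind, cand_rows) else
    data.frame(sequence = character())
  novel <- if (length(counts)) do.call(rbind, counts) else
    data.frame(id = character(), sequence = character(),
               ck = integer(), cu = integer())
  log_stage(config, "novel", tags = nrow(tags), candidates = nrow(cands),
            novel = nrow(novel))
  write_tsv(cands, out_path(config, "novel_candidates.tsv"))
  writeLines(struct_lines, out_path(config, "novel_structures.txt"))
  write_tsv(novel, out_path(config, "novel_counts.tsv"))
  invisible(list(candidates = out_path(config, "novel_candidates.tsv"),
                 counts = out_path(config, "novel_counts.tsv")))
}

stage_de <- function(config, need) {
  sizes <- c(need("n_ck"), need("n_cu"))
  counts_path <- out_path(config, "known_counts.tsv")
  if (!file.exists(counts_path)) counts_path <- out_path(config, "tags.tsv")
  if (!file.exists(counts_path))
    stop("missing input for 'counts': run the known or preprocess stage first",
         call. = FALSE)
  pairs <- read.delim(counts_path)
  if (!"id" %in% names(pairs)) pairs$id <- pairs$sequence
  fit <- ac_de(pairs[, intersect(c("id", "sequence", "ck", "cu"), names(pairs))],
               sizes = sizes,
               zero_floor = config$zero_floor, fc_thresh = config$fc_thresh,
               alpha_strong = config$alpha_strong, alpha_weak = config$alpha_weak)
  out <- format_de_table(fit$table)
  log_stage(config, "de", pairs = nrow(out),
            labelled = sum(fit$table$sig_label != "ns"))
  write_tsv(out, out_path(config, "de.tsv"))
  invisible(list(de = out_path(config, "de.tsv"), fit = fit))
}

#' Format a differential-expression table for reporting
#'
#' Applies the precision classes of the published tables: normalised
#' values to 4 decimals, log2 fold change to 7 decimals, p-values to
#' 4 significant figures.
#'
#' @param tab the `$table` of an [ac_de()] fit.
#' @return data.frame of formatted character columns.
#' @export
format_de_table <- function(tab) {
  out <- tab
  out$ck_std <- sprintf("%.4f", tab$ck_std)
  out$cu_std <- sprintf("%.4f", tab$cu_std)
  out$log2fc <- sprintf("%.7f", tab$log2fc)
  out$pvalue <- signif(tab$pvalue, 4)
  out
}

stage_targets <- function(config, need) {
  mir_path <- out_path(config, "novel_counts.tsv")
  mirnas <- if (file.exists(mir_path)) read.delim(mir_path) else
    stop("no miRNA table found; run the novel stage first", call. = FALSE)
  tr <- read_sequences(need("transcripts"))
  sites <- list()
  for (i in seq_len(nrow(mirnas))) {
    L <- nchar(mirnas$sequence[i])
    if (L < 19L || L > 25L) next
    for (j in seq_len(nrow(tr))) {
      s <- scan_targets(mirnas$sequence[i], tr$sequence[j],
                        max_mismatches = config$max_mismatches,
                        wobble_is_mismatch = config$wobble_is_mismatch,
                        mirna_name = mirnas$id[i],
                        transcript_id = sub("\\s.*$", "", tr$id[j]))
      if (nrow(s)) sites[[length(sites) + 1L]] <- s
    }
  }
  sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(mirna = character(), transcript = character(),
               start = integer(), end = integer(), mismatches = integer(),
               wobbles = integer(), allen_score = numeric(), site = character())
  net <- export_network(sites)
  log_stage(config, "targets", mirnas = nrow(mirnas), sites = nrow(sites),
            edges = nrow(net$edges))
  write_tsv(sites, out_path(config, "target_sites.tsv"))
  write_tsv(net$edges, out_path(config, "network_edges.tsv"))
  write_tsv(net$degree, out_path(config, "network_degree.tsv"))
  invisible(list(sites = out_path(config, "target_sites.tsv"),
                 edges = out_path(config, "network_edges.tsv")))
}

stage_enrich <- function(config, need) {
  de <- read.delim(out_path(config, "de.tsv"))
  tm <- read.delim(need("term_map"))
  term_map <- split(tm$id, tm$term)
  sel <- de$id[de$sig_label != "ns"]
  res <- enrich_hypergeometric(sel, de$id, term_map)
  log_stage(config, "enrich", selected = length(sel), terms = nrow(res))
  write_tsv(res, out_path(config, "enrichment.tsv"))
  invisible(list(enrichment = out_path(config, "enrichment.tsv")))
}

stage_report <- function(config) {
  arts <- c("categories_ck.tsv", "categories_cu.tsv", "known_counts.tsv",
            "novel_counts.tsv", "de.tsv", "target_sites.tsv",
            "network_edges.tsv", "enrichment.tsv")
  present <- arts[file.exists(file.path(config$outdir, arts))]
  log_stage(config, "report", artifacts = length(present))
  writeLines(present, out_path(config, "report_manifest.txt"))
  invisible(list(manifest = out_path(config, "report_manifest.txt")))
}
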