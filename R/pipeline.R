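.default_pipeline_config <- list(
  window_width = 100, step = 50, threshold = 2, class_filter = "all",
  scale_override = NULL, max_dist = 100000, tss_dist = 2500,
  lnc_near = 5000, top_k = 20, motif_width = 10, motif_both_strands = TRUE,
  dialect = "bed", feature_format = "tsv",
  n_initial_ip = NULL, n_initial_control = NULL, genome = NULL,
  verbose = FALSE)

# merge user config (list or JSON path) over defaults; unknown keys kept
.load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  utils::modifyList(.default_pipeline_config, config)
}

.log <- function(verbose, ...) if (verbose) message("[chipscan] ", sprintf(...))

#' Run the full ChIP-seq analysis pipeline
#'
#' Stages, in order: read alignments and features; mapping statistics per
#' dataset; depth scale factor (control/IP mapped reads, unless
#' `scale_override`); window grid; per-window counts and scores (written
#' as bedGraph); peak calling, merging and ranking; 100 kb nearest-feature
#' annotation with location classes and lncRNA tiers; class summary; and,
#' when a genome FASTA is configured, consensus motif discovery on the
#' top-`top_k` peak sequences. Reruns with an identical config produce
#' byte-identical outputs.
#'
#' @param config an R list or a JSON file path. Required keys: `ip`,
#'   `control` (alignment files), `features` (catalog), `out_dir`.
#'   Optional keys and defaults: window_width 100, step 50, threshold 2,
#'   class_filter "all", scale_override NULL, max_dist 100000, tss_dist
#'   2500, lnc_near 5000, top_k 20, motif_width 10, motif_both_strands
#'   TRUE, dialect "bed", feature_format "tsv", genome NULL (motif stage
#'   skipped when absent), n_initial_ip / n_initial_control (default: the
#'   number of mapped reads), verbose FALSE.
#' @return a `run_report` list: mapping_stats (ip/control), scale_factor,
#'   peaks (ranked annotated `peak_set`), class_summary, motif (or NULL),
#'   files, provenance.
#' @export
run_pipeline <- function(config) {
  cfg <- .load_config(config)
  for (key in c("ip", "control", "features", "out_dir"))
    if (is.null(cfg[[key]])) stop("config key missing: ", key)
  for (key in c("ip", "control", "features"))
    if (!file.exists(cfg[[key]])) stop("input not found (", key, "): ",
                                       cfg[[key]])
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  v <- isTRUE(cfg$verbose)

  .log(v, "reading alignments (%s)", cfg$dialect)
  ip <- read_alignments(cfg$ip, cfg$dialect)
  ct <- read_alignments(cfg$control, cfg$dialect)
  catalog <- read_features(cfg$features, cfg$feature_format)

  stats_ip <- mapping_stats(ip, cfg$n_initial_ip %||% nrow(ip))
  stats_ct <- mapping_stats(ct, cfg$n_initial_control %||% nrow(ct))
  scale <- if (!is.null(cfg$scale_override))
    structure(list(value = cfg$scale_override,
                   n_mapped_control = NA, n_mapped_ip = NA,
                   display = sprintf("%.2f", cfg$scale_override)),
              class = "scale_factor")
  else compute_scale_factor(nrow(ct), nrow(ip))
  .log(v, "scale factor %s", scale$display)

  genome <- NULL
  if (!is.null(cfg$genome)) {
    if (!file.exists(cfg$genome)) stop("input not found (genome): ",
                                       cfg$genome)
    genome <- Biostrings::readDNAStringSet(cfg$genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
    chrom_lengths <- stats::setNames(Biostrings::width(genome),
                                     names(genome))
  } else {
    # infer chromosome extents from the data
    ends <- c(tapply(ip$end, ip$chrom, max), tapply(ct$end, ct$chrom, max),
              tapply(catalog$end, catalog$chrom, max))
    chrom_lengths <- tapply(unname(ends), names(ends), max)
  }
  grid <- make_windows(chrom_lengths, cfg$window_width, cfg$step)
  .log(v, "%d windows", nrow(grid$windows))

  ipc <- count_reads(grid, ip, cfg$class_filter)
  ctc <- count_reads(grid, ct, cfg$class_filter)
  scores <- window_scores(ipc, ctc, scale)
  f_track <- file.path(cfg$out_dir, "window_scores.bedGraph")
  write_bedgraph(grid, scores, f_track)

  peaks <- call_peaks(grid, ip, ct, scale, cfg$threshold, cfg$class_filter)
  peaks <- rank_peaks(peaks)
  .log(v, "%d peaks at threshold %g", nrow(peaks), cfg$threshold)
  peaks <- annotate_peaks(peaks, catalog, cfg$max_dist, cfg$tss_dist,
                          cfg$lnc_near)
  f_peaks <- file.path(cfg$out_dir, "peaks.tsv")
  write_peak_table(peaks, f_peaks)

  cls <- summarize_classes(peaks)
  f_cls <- file.path(cfg$out_dir, "class_summary.tsv")
  utils::write.table(
    data.frame(kind = c(rep("location", 5), rep("lnc", 3)),
               class = c(names(cls$location), names(cls$lnc)),
               count = c(cls$location, cls$lnc)),
    f_cls, sep = "\t", quote = FALSE, row.names = FALSE)

  motif <- NULL
  f_motif <- NULL
  if (nrow(peaks) == 0) {
    warning("empty peak set: motif stage skipped")
  } else if (is.null(genome)) {
    .log(v, "no genome FASTA configured: motif stage skipped")
  } else if (nrow(peaks) < 2) {
    warning("fewer than 2 peaks: motif stage skipped")
  } else {
    top <- utils::head(peaks, cfg$top_k)
    seqs <- peak_sequences(top, genome)
    seqs <- seqs[nchar(seqs) >= cfg$motif_width]
    if (length(seqs) >= 2) {
      motif <- discover_motif(seqs, width = cfg$motif_width,
                              both_strands = cfg$motif_both_strands)
      f_motif <- file.path(cfg$out_dir, "motif.txt")
      write_motif_report(motif, f_motif)
      .log(v, "motif consensus %s", motif$consensus)
    } else warning("top peaks shorter than the motif width: motif stage skipped")
  }

  report <- structure(list(
    mapping_stats = list(ip = stats_ip, control = stats_ct),
    scale_factor = scale, peaks = peaks, class_summary = cls, motif = motif,
    files = c(peaks = f_peaks, track = f_track, classes = f_cls,
              motif = if (is.null(f_motif)) NA_character_ else f_motif),
    provenance = list(package_version = as.character(
      utils::packageVersion("chipscan")),
      config = cfg[order(names(cfg))])),
    class = "run_report")
  f_report <- file.path(cfg$out_dir, "run_report.json")
  jsonlite::write_json(list(
    mapping_stats = list(ip = unclass(stats_ip), control = unclass(stats_ct)),
    scale_factor = list(value = scale$value, display = scale$display),
    n_peaks = nrow(peaks), class_summary = cls,
    motif_consensus = if (is.null(motif)) NULL else motif$consensus,
    provenance = report$provenance),
    f_report, auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_report <- function(x, ...) {
  cat("== chipscan run report ==\n")
  cat("-- IP --\n"); print(x$mapping_stats$ip)
  cat("-- control --\n"); print(x$mapping_stats$control)
  print(x$scale_factor)
  print(x$peaks)
  cat("location classes:", paste(names(x$class_summary$location),
                                 x$class_summary$location, sep = "=",
                                 collapse = " "), "\n")
  cat("lnc tiers:", paste(names(x$class_summary$lnc), x$class_summary$lnc,
                          sep = "=", collapse = " "), "\n")
  if (!is.null(x$motif)) print(x$motif)
  invisible(x)
}

#' Run the qPCR arithmetic over a Ct table
#'
#' Expression records are processed with the delta-delta-Ct method against
#' `reference_gene` and `calibrator_sample`; ChIP records (roles chip_ip /
#' chip_input / chip_prei) are converted to percent input and fold
#' enrichment over `reference_locus`.
#'
#' @param ct_path Ct CSV (see [read_ct_table()]).
#' @param config list with optional keys reference_gene ("Gapdh"),
#'   reference_locus ("Gapdh_promoter"), calibrator_sample (first sample),
#'   input_fraction (1), subtract_background (TRUE), out (results CSV
#'   path).
#' @return data.frame of results (one row per target), invisibly written
#'   to `config$out` when set.
#' @export
run_qpcr <- function(ct_path, config = list()) {
  tab <- read_ct_table(ct_path)
  ref_gene <- config$reference_gene %||% "Gapdh"
  ref_locus <- config$reference_locus %||% "Gapdh_promoter"
  input_fraction <- config$input_fraction %||% 1
  subtract <- config$subtract_background %||% TRUE
  rows <- list()

  expr <- tab[tab$role == "expression", , drop = FALSE]
  if (nrow(expr)) {
    if (!any(expr$target == ref_gene))
      stop("reference gene '", ref_gene, "' absent from the Ct table")
    calib <- config$calibrator_sample %||% sort(unique(expr$sample))[1]
    for (s in sort(unique(expr$sample))) {
      for (g in sort(setdiff(unique(expr$target), ref_gene))) {
        if (!any(expr$sample == s & expr$target == g)) next
        r <- relative_expression_ddct(tab, g, ref_gene, s, calib)
        rows[[length(rows) + 1]] <- data.frame(
          kind = "expression", sample = s, target = g, value = r$fold,
          sem = r$fold_sem, unit = "fold_vs_calibrator",
          stringsAsFactors = FALSE)
      }
    }
  }

  chip <- tab[tab$role != "expression", , drop = FALSE]
  if (nrow(chip)) {
    pct_of <- function(s, locus) {
      ip <- .ct_cell(tab, s, locus, "chip_ip")$mean
      input <- .ct_cell(tab, s, locus, "chip_input")$mean
      prei <- tryCatch(.ct_cell(tab, s, locus, "chip_prei")$mean,
                       error = function(e) NA_real_)
      c(ip = percent_input(ip, input, input_fraction),
        prei = if (is.na(prei)) 0 else
          percent_input(prei, input, input_fraction))
    }
    for (s in sort(unique(chip$sample))) {
      loci <- sort(unique(chip$target[chip$sample == s]))
      if (!ref_locus %in% loci)
        stop("reference locus '", ref_locus, "' absent for sample '", s, "'")
      ref <- pct_of(s, ref_locus)
      for (locus in loci) {
        p <- pct_of(s, locus)
        rows[[length(rows) + 1]] <- data.frame(
          kind = "chip", sample = s, target = locus, value = p[["ip"]],
          sem = NA_real_, unit = "pct_input", stringsAsFactors = FALSE)
        rows[[length(rows) + 1]] <- data.frame(
          kind = "chip", sample = s, target = locus,
          value = fold_enrichment(p, ref, subtract), sem = NA_real_,
          unit = "fold_over_reference", stringsAsFactors = FALSE)
      }
    }
  }

  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(), sample = character(),
               target = character(), value = numeric(), sem = numeric(),
               unit = character(), stringsAsFactors = FALSE)
  if (!is.null(config$out))
    utils::write.csv(out, config$out, row.names = FALSE)
  out
}

#' Command-line entry point
#'
#' Subcommands: `run -c config.json`, `simulate -c sim.json -o dir`,
#' `qpcr ct.csv [-c config.json]`, `stats reads.bed --initial N`.
#' A ready-to-use front-end script ships at
#' `system.file("cli", "chipscan.R", package = "chipscan")`.
#'
#' @param args character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit code: 0 ok, 1 user error, 2 internal error.
#' @export
chipscan_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: chipscan <run|simulate|qpcr|stats> [options]",
                 "  run      -c config.json",
                 "  simulate -c sim.json -o out_dir  (keys: seed, ...)",
                 "  qpcr     ct.csv [-c config.json]",
                 "  stats    reads.bed --initial N [--dialect bed]",
                 sep = "\n")
  if (!length(args)) { message(usage); return(1L) }
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i[1] < length(args)) args[i[1] + 1] else default
  }
  tryCatch({
    cmd <- args[1]
    if (cmd == "run") {
      cfgp <- opt("-c"); if (is.null(cfgp)) stop("run: -c config.json required")
      rep <- run_pipeline(cfgp)
      print(rep)
    } else if (cmd == "simulate") {
      cfgp <- opt("-c"); outd <- opt("-o")
      if (is.null(cfgp) || is.null(outd))
        stop("simulate: -c sim.json and -o out_dir required")
      keys <- jsonlite::read_json(cfgp, simplifyVector = TRUE)
      cfg <- do.call(simulation_config, keys)
      simulate_dataset(cfg, outd)
      message("simulated dataset written to ", outd)
    } else if (cmd == "qpcr") {
      if (length(args) < 2) stop("qpcr: ct.csv required")
      cfgp <- opt("-c")
      cfg <- if (is.null(cfgp)) list() else
        jsonlite::read_json(cfgp, simplifyVector = TRUE)
      res <- run_qpcr(args[2], cfg)
      utils::write.csv(res, stdout(), row.names = FALSE)
    } else if (cmd == "stats") {
      if (length(args) < 2) stop("stats: reads file required")
      reads <- read_alignments(args[2], opt("--dialect", "bed"))
      n0 <- as.numeric(opt("--initial", nrow(reads)))
      print(mapping_stats(reads, n0))
    } else stop("unknown subcommand: ", cmd)
    0L
  }, error = function(e) {
    message("chipscan error: ", conditionMessage(e))
    1L
  })
}
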