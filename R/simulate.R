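# run `code` under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv()) else
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               N = c("A", "C", "G", "T"))

# one random concrete instantiation of an IUPAC string
.instantiate_iupac <- function(code) {
  paste(vapply(strsplit(toupper(code), "")[[1]], function(ch) {
    opts <- .IUPAC[[ch]]
    if (is.null(opts)) stop("unsupported IUPAC code: ", ch)
    opts[sample.int(length(opts), 1)]
  }, character(1)), collapse = "")
}

#' Simulation configuration
#'
#' The stated world of the generator: a blastocyst-stem-cell-style ChIP
#' experiment with 50 nt reads, 100/50 bp windows, an expected control
#' depth of 20 reads per window, planted peaks of fold 8 and width 300 bp
#' split over the five location classes as 2 TSS / 8 O / 3 DD / 6 DU /
#' 2 I, a planted ANAGAAGTGG motif at each peak center, and a 5-copy
#' near-identical repeat family (500 bp, 2% divergence) driving
#' multi-mapped reads.
#'
#' @param seed mandatory integer seed; every downstream generator derives
#'   its stream from it.
#' @param peak_spec data.frame with columns location_class
#'   (TSS/O/DU/DD/I), fold (>= 0) and width (bp); default the 21-peak
#'   class split above at fold 8, width 300.
#' @param motif IUPAC string planted at peak centers (default
#'   "ANAGAAGTGG").
#' @param read_length read length in bp (default 50).
#' @param window_depth expected control read count per full window
#'   (default 20).
#' @param window_width,step window grid the depth refers to (default
#'   100/50).
#' @param lnc_every every k-th featured block's gene is a lncRNA (default
#'   3; 0 disables lncRNAs).
#' @param repeat_family list(n_copies, copy_length, divergence).
#' @param n_chroms blocks are distributed round-robin over this many
#'   chromosomes (default 2).
#' @return a `sim_config` list.
#' @export
simulation_config <- function(seed,
                              peak_spec = NULL,
                              motif = "ANAGAAGTGG",
                              read_length = 50,
                              window_depth = 20,
                              window_width = 100,
                              step = 50,
                              lnc_every = 3,
                              repeat_family = list(n_copies = 5,
                                                   copy_length = 500,
                                                   divergence = 0.02),
                              n_chroms = 2) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (is.null(peak_spec)) {
    cls <- c(rep("TSS", 2), rep("O", 8), rep("DD", 3), rep("DU", 6),
             rep("I", 2))
    # interleave so both chromosomes carry a mix of classes
    cls <- cls[order(seq_along(cls) %% 2, seq_along(cls))]
    peak_spec <- data.frame(location_class = cls, fold = 8, width = 300,
                            stringsAsFactors = FALSE)
  }
  stopifnot(all(peak_spec$location_class %in% c("TSS", "O", "DU", "DD", "I")),
            all(peak_spec$fold >= 0), all(peak_spec$width > 0),
            read_length <= window_width,
            repeat_family$divergence >= 0, repeat_family$divergence < 1)
  structure(list(seed = as.integer(seed), peak_spec = peak_spec,
                 motif = motif, read_length = read_length,
                 window_depth = window_depth, window_width = window_width,
                 step = step, lnc_every = lnc_every,
                 repeat_family = repeat_family, n_chroms = n_chroms),
            class = "sim_config")
}

# geometry constants of the block layout (bp)
.BLOCK <- list(featured_size = 40000, intergenic_size = 180000,
               feature_off = 16000, feature_len = 8000,
               repeat_off = 2000,
               tss_gap = 1000, body_off = 4000, distal_gap = 10000)

#' Generate a synthetic genome, feature catalog and truth-table stub
#'
#' The genome is i.i.d. uniform ACGT, organized in blocks, one per
#' requested peak: featured blocks (40 kb) carry one 8 kb gene and the
#' peak placed with the geometry its intended location class requires
#' (1 kb from the TSS for TSS, mid-body for O, a 10 kb gap for DU/DD);
#' intergenic blocks (180 kb) carry the peak at their center, > 100 kb
#' from every feature. Gene strands are drawn at random; every
#' `lnc_every`-th featured gene is a lncRNA, the rest protein_coding.
#' Near-identical repeat copies are written into the margins of the first
#' `n_copies` featured blocks. Deterministic per seed.
#'
#' @param config a `sim_config`.
#' @return a `sim_genome` list: genome (named character), chrom_lengths,
#'   catalog (`feature_catalog`), repeats (data.frame), truth (planned
#'   peaks: chrom/start/end/intended class/fold/width), config.
#' @export
generate_genome <- function(config) {
  .with_seed(config$seed, {
    B <- .BLOCK
    spec <- config$peak_spec
    n <- nrow(spec)
    chrom_of <- if (n) rep_len(paste0("chr", seq_len(config$n_chroms)), n) else
      character(0)
    # per-block geometry, blocks laid consecutively per chromosome
    strand <- sample(c("+", "-"), n, replace = TRUE)
    featured <- spec$location_class != "I"
    size <- ifelse(featured, B$featured_size, B$intergenic_size)
    block_start <- numeric(n)
    chrom_lengths <- stats::setNames(numeric(config$n_chroms),
                                     paste0("chr", seq_len(config$n_chroms)))
    for (i in seq_len(n)) {
      block_start[i] <- chrom_lengths[chrom_of[i]]
      chrom_lengths[chrom_of[i]] <- chrom_lengths[chrom_of[i]] + size[i]
    }
    chrom_lengths[chrom_lengths == 0] <- B$featured_size  # no empty chrom

    catalog <- NULL
    truth <- NULL
    feat_no <- 0L
    lnc_count <- 0L
    for (i in seq_len(n)) {
      b0 <- block_start[i]
      wd <- spec$width[i]
      cls <- spec$location_class[i]
      if (featured[i]) {
        feat_no <- feat_no + 1L
        fs <- b0 + B$feature_off
        fe <- fs + B$feature_len
        is_lnc <- config$lnc_every > 0 && feat_no %% config$lnc_every == 0
        if (is_lnc) lnc_count <- lnc_count + 1L
        catalog <- rbind(catalog, data.frame(
          feature_id = sprintf("SYNG%04d", feat_no),
          name = if (is_lnc) sprintf("SynLnc%d", lnc_count) else
            sprintf("SynGene%d", feat_no),
          biotype = if (is_lnc) "lncRNA" else "protein_coding",
          chrom = chrom_of[i], start = fs, end = fe, strand = strand[i],
          stringsAsFactors = FALSE))
        plus <- strand[i] == "+"
        ps <- switch(cls,
          TSS = if (plus) fs - B$tss_gap - wd else fe + B$tss_gap,
          O = if (plus) fs + B$body_off else fs + B$tss_gap,
          DU = if (plus) fs - B$distal_gap - wd else fe + B$distal_gap,
          DD = if (plus) fe + B$distal_gap else fs - B$distal_gap - wd)
      } else {
        ps <- b0 + size[i] / 2 - wd / 2
      }
      truth <- rbind(truth, data.frame(
        peak_id = sprintf("planted_%02d", i), chrom = chrom_of[i],
        start = ps, end = ps + wd, intended_class = cls,
        fold = spec$fold[i], width = wd, stringsAsFactors = FALSE))
    }
    if (is.null(truth))
      truth <- data.frame(peak_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          intended_class = character(), fold = numeric(),
                          width = numeric(), stringsAsFactors = FALSE)
    if (is.null(catalog))
      catalog <- data.frame(feature_id = character(), name = character(),
                            biotype = character(), chrom = character(),
                            start = numeric(), end = numeric(),
                            strand = character(), stringsAsFactors = FALSE)
    catalog$tss <- ifelse(catalog$strand == "+", catalog$start,
                          catalog$end - 1)
    class(catalog) <- c("feature_catalog", "data.frame")

    genome <- lapply(chrom_lengths, function(L)
      paste(sample(DNA_BASES, L, replace = TRUE), collapse = ""))

    # near-identical repeat family in featured-block margins
    rf <- config$repeat_family
    repeats <- NULL
    if (rf$n_copies > 0) {
      host <- which(featured)[seq_len(min(rf$n_copies, sum(featured)))]
      if (length(host) < rf$n_copies)
        warning("only ", length(host), " featured block(s) available; ",
                "repeat family reduced from ", rf$n_copies, " copies")
      rf$n_copies <- length(host)
      master <- sample(DNA_BASES, rf$copy_length, replace = TRUE)
      for (k in seq_along(host)) {
        copy <- master
        mut <- which(stats::runif(rf$copy_length) < rf$divergence)
        if (length(mut))
          copy[mut] <- vapply(copy[mut], function(b)
            sample(setdiff(DNA_BASES, b), 1), character(1))
        ch <- chrom_of[host[k]]
        rs <- block_start[host[k]] + B$repeat_off
        substr(genome[[ch]], rs + 1, rs + rf$copy_length) <-
          paste(copy, collapse = "")
        repeats <- rbind(repeats, data.frame(
          copy = k, chrom = ch, start = rs, end = rs + rf$copy_length,
          stringsAsFactors = FALSE))
      }
    }
    structure(list(genome = genome, chrom_lengths = chrom_lengths,
                   catalog = catalog, repeats = repeats, truth = truth,
                   config = config),
              class = "sim_genome")
  })
}

#' Plant the motif at peak centers and finalize the truth table
#'
#' One concrete instantiation of the configured IUPAC motif (degenerate
#' positions drawn independently per peak) is written into the genome at
#' each planted peak's center; the truth table gains the instance string,
#' its offset, and the intended lncRNA tier (computed from the generator's
#' own geometry: gap to the nearest planted lncRNA, 5 kb / 100 kb
#' boundaries inclusive). Deterministic per seed.
#'
#' @param sim a `sim_genome` from [generate_genome()].
#' @return the updated `sim_genome`.
#' @export
plant_peaks_and_motif <- function(sim) {
  config <- sim$config
  .with_seed(config$seed + 1L, {
    truth <- sim$truth
    mw <- nchar(config$motif)
    truth$motif_instance <- NA_character_
    truth$motif_start <- NA_real_
    truth$lnc_tier <- NA_character_
    lnc <- sim$catalog[sim$catalog$biotype == "lncRNA", , drop = FALSE]
    for (i in seq_len(nrow(truth))) {
      inst <- .instantiate_iupac(config$motif)
      ms <- floor((truth$start[i] + truth$end[i]) / 2) - floor(mw / 2)
      substr(sim$genome[[truth$chrom[i]]], ms + 1, ms + mw) <- inst
      truth$motif_instance[i] <- inst
      truth$motif_start[i] <- ms
      li <- lnc$chrom == truth$chrom[i]
      gap <- if (any(li))
        min(interval_gap(truth$start[i], truth$end[i],
                         lnc$start[li], lnc$end[li])) else Inf
      truth$lnc_tier[i] <- if (gap <= 5000) "lnc_within_5kb" else
        if (gap <= 100000) "lnc_within_100kb" else "other"
    }
    sim$truth <- truth
    sim
  })
}

#' Simulate IP and control read sets with known truth
#'
#' Control reads start uniformly at a Poisson rate of
#' `window_depth / (window_width + read_length - 1)` per bp, so the
#' expected number of reads overlapping one full window equals
#' `window_depth`. The IP track adds `(fold - 1)` times that local rate
#' across each planted peak (total intensity `fold` x background). Reads
#' whose true origin lies inside a repeat copy are labelled `repeated`
#' and re-assigned to a uniformly drawn copy of the family at the same
#' offset (multi-mapper randomization); all other reads are `unique`.
#' Deterministic per seed.
#'
#' @param sim a planted `sim_genome`.
#' @param depth expected control reads per full window; default from the
#'   config.
#' @return list(ip, control): aligned-read data.frames with an extra
#'   `origin_repeat` logical column (truth label).
#' @export
simulate_reads <- function(sim, depth = NULL) {
  config <- sim$config
  if (is.null(depth)) depth <- config$window_depth
  stopifnot(depth > 0)
  rl <- config$read_length
  rate <- depth / (config$window_width + rl - 1)
  .with_seed(config$seed + 2L, {
    one_track <- function(ip) {
      starts <- numeric(0)
      chrom <- character(0)
      for (ch in names(sim$chrom_lengths)) {
        L <- sim$chrom_lengths[[ch]]
        span <- max(L - rl + 1, 1)
        nb <- stats::rpois(1, rate * span)
        st <- floor(stats::runif(nb) * span)
        if (ip && !is.null(sim$truth)) {
          tr <- sim$truth[sim$truth$chrom == ch & sim$truth$fold > 1, ,
                          drop = FALSE]
          for (i in seq_len(nrow(tr))) {
            lo <- max(tr$start[i] - rl + 1, 0)
            hi <- min(tr$end[i] - 1, span - 1)
            if (hi < lo) next
            ne <- stats::rpois(1, (tr$fold[i] - 1) * rate * (hi - lo + 1))
            st <- c(st, lo + floor(stats::runif(ne) * (hi - lo + 1)))
          }
        }
        starts <- c(starts, st)
        chrom <- c(chrom, rep(ch, length(st)))
      }
      reads <- data.frame(chrom = chrom, start = starts, end = starts + rl,
                          strand = sample(c("+", "-"), length(starts),
                                          replace = TRUE),
                          name = sprintf("%s_%06d",
                                         if (ip) "ip" else "ct",
                                         seq_along(starts)),
                          mapping_class = rep("unique", length(starts)),
                          origin_repeat = rep(FALSE, length(starts)),
                          stringsAsFactors = FALSE)
      rep_tab <- sim$repeats
      if (!is.null(rep_tab) && nrow(rep_tab)) {
        for (k in seq_len(nrow(rep_tab))) {
          inside <- reads$chrom == rep_tab$chrom[k] &
            reads$start >= rep_tab$start[k] & reads$start < rep_tab$end[k] &
            !reads$origin_repeat
          if (!any(inside)) next
          off <- reads$start[inside] - rep_tab$start[k]
          dest <- sample.int(nrow(rep_tab), sum(inside), replace = TRUE)
          reads$chrom[inside] <- rep_tab$chrom[dest]
          reads$start[inside] <- rep_tab$start[dest] + off
          reads$end[inside] <- reads$start[inside] + rl
          reads$mapping_class[inside] <- "repeated"
          reads$origin_repeat[inside] <- TRUE
        }
      }
      reads
    }
    list(ip = one_track(TRUE), control = one_track(FALSE))
  })
}

#' Simulate a replicate Ct table with known truth
#'
#' For each design row, `Ct = base_ct - log2(true_quantity) + noise` with
#' Gaussian noise of sd `ct_sd`, `replicates` independent draws per cell.
#' Quantities are relative (a reference gene/locus at quantity 1 gives
#' `Ct = base_ct` on average). Deterministic per seed.
#'
#' @param design data.frame with columns sample, target, role,
#'   true_quantity (> 0).
#' @param seed integer seed.
#' @param base_ct baseline cycle threshold (default 22).
#' @param ct_sd replicate noise sd in cycles (default 0.1).
#' @param replicates draws per cell (default 3, the usual triplicate).
#' @return a `ct_table` data.frame (one row per replicate).
#' @export
simulate_ct_table <- function(design, seed, base_ct = 22, ct_sd = 0.1,
                              replicates = 3) {
  stopifnot(all(design$true_quantity > 0), replicates >= 1)
  .with_seed(seed, {
    rows <- lapply(seq_len(nrow(design)), function(i) {
      data.frame(sample = design$sample[i], target = design$target[i],
                 role = design$role[i],
                 ct = base_ct - log2(design$true_quantity[i]) +
                   stats::rnorm(replicates, 0, ct_sd),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    class(out) <- c("ct_table", "data.frame")
    out
  })
}

#' Simulate planted-motif peak sequences
#'
#' `n` uniform-background random sequences of length `len`, each with one
#' concrete instantiation of the IUPAC `motif` written at a random offset
#' (the generator behind motif-recovery testing).
#'
#' @param n number of sequences (default 20, a typical top-peak set).
#' @param len sequence length in bp (default 150).
#' @param motif IUPAC string (default "ANAGAAGTGG").
#' @param seed integer seed.
#' @return list(sequences, offsets (1-based), instances).
#' @export
simulate_motif_sequences <- function(n = 20, len = 150,
                                     motif = "ANAGAAGTGG", seed) {
  mw <- nchar(motif)
  stopifnot(len >= mw, n >= 1)
  .with_seed(seed, {
    seqs <- character(n)
    offs <- integer(n)
    inst <- character(n)
    for (i in seq_len(n)) {
      s <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
      o <- sample.int(len - mw + 1L, 1)
      w <- .instantiate_iupac(motif)
      substr(s, o, o + mw - 1L) <- w
      seqs[i] <- s
      offs[i] <- o
      inst[i] <- w
    }
    list(sequences = seqs, offsets = offs, instances = inst)
  })
}

#' Generate a complete synthetic dataset on disk
#'
#' Runs the whole generator (genome, catalog, repeats, planted peaks and
#' motif, IP/control reads, Ct table) and writes: `genome.fa`,
#' `features.tsv`, `ip.bed`, `control.bed`, `truth.tsv`, `ct.csv`.
#' Byte-identical across reruns with the same config.
#'
#' @param config a `sim_config`.
#' @param out_dir output directory (created if needed).
#' @param ct_design optional Ct design (see [simulate_ct_table()]);
#'   default a small expression design with true folds 1, 0.2 and 4
#'   against a Gapdh reference.
#' @return invisibly, the `sim_genome` with `$reads` attached.
#' @export
simulate_dataset <- function(config, out_dir, ct_design = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- plant_peaks_and_motif(generate_genome(config))
  sim$reads <- simulate_reads(sim)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(sim$genome)),
    file.path(out_dir, "genome.fa"))
  write_features(sim$catalog, file.path(out_dir, "features.tsv"))
  write_alignments(sim$reads$ip, file.path(out_dir, "ip.bed"))
  write_alignments(sim$reads$control, file.path(out_dir, "control.bed"))
  utils::write.table(sim$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (is.null(ct_design))
    ct_design <- data.frame(
      sample = rep(c("control_cells", "knockdown"), each = 3),
      target = rep(c("Gapdh", "TargetA", "TargetB"), 2),
      role = "expression",
      true_quantity = c(1, 1, 1, 1, 0.2, 4),
      stringsAsFactors = FALSE)
  ct <- simulate_ct_table(ct_design, seed = config$seed + 3L)
  utils::write.csv(ct, file.path(out_dir, "ct.csv"), row.names = FALSE)
  invisible(sim)
}
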