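# fixtures are built in code at test time; oracles here are deliberately
# naive re-implementations, independent of the package internals

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# three BED6 reads, one repeated-class (score 1)
bed3_fixture <- function() {
  write_lines_tmp(c("chr1\t100\t150\tr1\t0\t+",
                    "chr1\t200\t250\tr2\t1\t-",
                    "chr2\t0\t50\tr3\t0\t+"), ".bed")
}

# five genes on two chromosomes (3 on chr1, 2 on chr2), one lncRNA
features_tsv_fixture <- function() {
  write_lines_tmp(c(
    "feature_id\tname\tbiotype\tchrom\tstart1\tend1\tstrand",
    "g1\tGeneA\tprotein_coding\tchr1\t1001\t2000\t+",
    "g2\tGeneB\tprotein_coding\tchr1\t5001\t8000\t-",
    "g3\tLncA\tlncRNA\tchr1\t20001\t22000\t+",
    "g4\tGeneC\tprotein_coding\tchr2\t1001\t4000\t+",
    "g5\tGeneD\tother\tchr2\t9001\t9500\t-"), ".tsv")
}

# quick catalog builder (0-based half-open input)
make_catalog <- function(chrom, start, end, strand,
                         biotype = "protein_coding", id = NULL) {
  n <- length(chrom)
  df <- data.frame(
    feature_id = if (is.null(id)) sprintf("f%03d", seq_len(n)) else id,
    name = if (is.null(id)) sprintf("f%03d", seq_len(n)) else id,
    biotype = rep_len(biotype, n), chrom = chrom,
    start = start, end = end, strand = strand, stringsAsFactors = FALSE)
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  class(df) <- c("feature_catalog", "data.frame")
  df
}

make_reads <- function(chrom, start, end, mapping_class = "unique") {
  data.frame(chrom = chrom, start = start, end = end,
             strand = rep("+", length(chrom)),
             name = sprintf("r%04d", seq_along(chrom)),
             mapping_class = rep_len(mapping_class, length(chrom)),
             stringsAsFactors = FALSE)
}

# oracle: per-window counts by direct double loop over reads and windows
brute_count <- function(grid, reads, class_filter = "all") {
  if (class_filter == "unique_only")
    reads <- reads[reads$mapping_class == "unique", , drop = FALSE]
  if (class_filter == "repeated_only")
    reads <- reads[reads$mapping_class == "repeated", , drop = FALSE]
  w <- grid$windows
  counts <- numeric(nrow(w))
  for (r in seq_len(nrow(reads))) {
    for (j in seq_len(nrow(w))) {
      if (reads$chrom[r] == w$chrom[j] &&
          reads$start[r] < w$end[j] && w$start[j] < reads$end[r])
        counts[j] <- counts[j] + 1
    }
  }
  counts
}

# oracle: nearest feature by linear scan (gap; ties by TSS distance then id)
brute_nearest <- function(peak, catalog, max_dist = 100000) {
  best <- NULL
  for (i in seq_len(nrow(catalog))) {
    if (catalog$chrom[i] != peak$chrom) next
    gap <- max(0, catalog$start[i] - peak$end, peak$start - catalog$end[i])
    if (gap > max_dist) next
    tss <- catalog$tss[i]
    td <- if (tss >= peak$start && tss < peak$end) 0 else
      min(abs(peak$start - tss), abs(peak$end - 1 - tss))
    cand <- list(i = i, gap = gap, td = td, id = catalog$feature_id[i])
    if (is.null(best) || gap < best$gap ||
        (gap == best$gap && (td < best$td ||
                             (td == best$td && cand$id < best$id))))
      best <- cand
  }
  best
}

# planted-peak overlap check against a truth table
peaks_hit_truth <- function(peaks, truth) {
  vapply(seq_len(nrow(truth)), function(i)
    any(peaks$chrom == truth$chrom[i] & peaks$start < truth$end[i] &
          peaks$end > truth$start[i]), logical(1))
}

# consensus-vs-IUPAC match count, allowing the reverse complement (the
# search is strand-symmetric so orientation is not identifiable)
motif_match_count <- function(consensus, iupac) {
  pat <- strsplit(iupac, "")[[1]]
  count1 <- function(cons) {
    got <- strsplit(cons, "")[[1]]
    if (length(got) != length(pat)) return(0L)
    sum(pat == "N" | pat == got)
  }
  max(count1(consensus), count1(chipscan::reverse_complement(consensus)))
}

# inline Ct table builder: make_ct(list(sample, target, role, ct), ...)
make_ct <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(sample = r[[1]], target = r[[2]], role = r[[3]],
               ct = as.numeric(r[[4]]), stringsAsFactors = FALSE)))
  class(out) <- c("ct_table", "data.frame")
  out
}

# small 5-peak simulation world for module-level tests
small_sim_config <- function(seed, fold = 8, width = 300) {
  simulation_config(
    seed = seed,
    peak_spec = data.frame(
      location_class = c("TSS", "O", "DU", "DD", "I"),
      fold = fold, width = width, stringsAsFactors = FALSE),
    repeat_family = list(n_copies = 3, copy_length = 500, divergence = 0.02))
}
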