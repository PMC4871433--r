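#' Mapping statistics in the style of a sequencing QC table
#'
#' Percentages of mapped, uniquely mapped and multiply mapped ("repeated")
#' reads are all reported relative to the *initial* number of
#' quality-filtered reads and rounded to two decimals. (Published tables of
#' this kind sometimes footnote the unique/repeated rows as percentages of
#' mapped reads, but the printed numbers only reproduce with the initial
#' count as denominator; that arithmetic is used here.)
#'
#' @param reads aligned-read data.frame (see [read_alignments()]), or NULL
#'   when passing counts directly via [mapping_stats_from_counts()].
#' @param n_initial initial number of quality-filtered reads (>= n mapped).
#' @return a `mapping_stats` list: n_initial, n_mapped, n_unique,
#'   n_repeated, pct_mapped, pct_unique, pct_repeated.
#' @export
mapping_stats <- function(reads, n_initial) {
  mapping_stats_from_counts(
    n_initial = n_initial,
    n_unique = sum(reads$mapping_class == "unique"),
    n_repeated = sum(reads$mapping_class == "repeated"))
}

#' @rdname mapping_stats
#' @param n_unique,n_repeated counts of uniquely / multiply mapped reads.
#' @export
mapping_stats_from_counts <- function(n_initial, n_unique, n_repeated) {
  if (n_initial <= 0) stop("n_initial must be > 0 (percentages undefined)")
  n_mapped <- n_unique + n_repeated
  if (n_mapped > n_initial)
    stop("mapped reads (", n_mapped, ") exceed n_initial (", n_initial, ")")
  pct <- function(x) round(100 * x / n_initial, 2)
  structure(list(n_initial = n_initial, n_mapped = n_mapped,
                 n_unique = n_unique, n_repeated = n_repeated,
                 pct_mapped = pct(n_mapped), pct_unique = pct(n_unique),
                 pct_repeated = pct(n_repeated)),
            class = "mapping_stats")
}

#' @export
print.mapping_stats <- function(x, ...) {
  cat(sprintf("initial reads: %d\nmapped: %d (%.2f%%)\nunique: %d (%.2f%%)\nrepeated: %d (%.2f%%)\n",
              x$n_initial, x$n_mapped, x$pct_mapped, x$n_unique, x$pct_unique,
              x$n_repeated, x$pct_repeated))
  invisible(x)
}

#' Depth-normalization scale factor for the IP track
#'
#' The IP window counts are multiplied by `n_mapped_control / n_mapped_ip`
#' so both tracks are on the control's depth. The exact (unrounded) ratio
#' is used throughout the pipeline; `display` holds the conventional
#' two-decimal form.
#'
#' @param n_mapped_control,n_mapped_ip mapped read counts (> 0).
#' @return a `scale_factor` list: value, n_mapped_control, n_mapped_ip,
#'   display.
#' @export
compute_scale_factor <- function(n_mapped_control, n_mapped_ip) {
  if (n_mapped_ip <= 0 || n_mapped_control <= 0)
    stop("mapped read counts must be > 0")
  v <- n_mapped_control / n_mapped_ip
  structure(list(value = v, n_mapped_control = n_mapped_control,
                 n_mapped_ip = n_mapped_ip,
                 display = sprintf("%.2f", v)),
            class = "scale_factor")
}

#' @export
print.scale_factor <- function(x, ...) {
  cat(sprintf("scale factor %s (= %d / %d, exact %.6f)\n", x$display,
              x$n_mapped_control, x$n_mapped_ip, x$value))
  invisible(x)
}

#' Overlapping fixed-width window grid
#'
#' Windows of `width` bp every `step` bp (default 100/50, i.e. 2x tiled)
#' per chromosome: starts 0, step, 2*step, ...; generation stops once
#' `start + width` would pass the chromosome end, except that a chromosome
#' shorter than `width` yields the single truncated window `[0, L)`.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param width window width in bp (default 100).
#' @param step distance between window starts in bp (default 50, <= width).
#' @return a `window_grid` list: `windows` (data.frame chrom/start/end),
#'   `chrom_lengths`, `width`, `step`.
#' @export
make_windows <- function(chrom_lengths, width = 100, step = 50) {
  stopifnot(width > 0, step > 0, step <= width)
  if (length(chrom_lengths) && is.null(names(chrom_lengths)))
    stop("chrom_lengths must be named by chromosome")
  pieces <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    if (L <= 0) return(NULL)
    if (L < width) {
      data.frame(chrom = ch, start = 0, end = L, stringsAsFactors = FALSE)
    } else {
      starts <- seq(0, L - width, by = step)
      data.frame(chrom = ch, start = starts, end = starts + width,
                 stringsAsFactors = FALSE)
    }
  })
  windows <- if (length(pieces)) do.call(rbind, pieces) else
    data.frame(chrom = character(), start = numeric(), end = numeric())
  structure(list(windows = windows, chrom_lengths = chrom_lengths,
                 width = width, step = step),
            class = "window_grid")
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("window grid: %d windows (%d bp, step %d) on %d chromosome(s)\n",
              nrow(x$windows), x$width, x$step, length(x$chrom_lengths)))
  invisible(x)
}

.filter_class <- function(reads, class_filter) {
  switch(class_filter,
         all = reads,
         unique_only = reads[reads$mapping_class == "unique", , drop = FALSE],
         repeated_only = reads[reads$mapping_class == "repeated", , drop = FALSE],
         stop("unknown class_filter: ", class_filter))
}

#' Count reads per window (any-overlap semantics)
#'
#' A read increments every window its interval overlaps by at least 1 bp,
#' so with a 2x tiled grid most reads count in two windows. Reads on
#' chromosomes absent from the grid are skipped and tallied in the
#' `skipped` attribute.
#'
#' @param grid a `window_grid`.
#' @param reads aligned-read data.frame.
#' @param class_filter `"all"`, `"unique_only"` or `"repeated_only"`.
#' @return numeric vector of counts aligned with `grid$windows`, with
#'   attribute `skipped` (number of off-grid reads).
#' @export
count_reads <- function(grid, reads, class_filter = "all") {
  reads <- .filter_class(reads, class_filter)
  w <- grid$windows
  counts <- numeric(nrow(w))
  on_grid <- reads$chrom %in% unique(w$chrom)
  skipped <- sum(!on_grid)
  reads <- reads[on_grid, , drop = FALSE]
  if (nrow(reads)) {
    for (ch in unique(reads$chrom)) {
      wi <- which(w$chrom == ch)
      ri <- reads$chrom == ch
      counts[wi] <- counts[wi] + IRanges::countOverlaps(
        .as_iranges(w$start[wi], w$end[wi]),
        .as_iranges(reads$start[ri], reads$end[ri]))
    }
  }
  attr(counts, "skipped") <- skipped
  counts
}

#' Per-window IP/control enrichment score
#'
#' `score = scaled_ip / control` with pseudocounts: the IP count is first
#' multiplied by the depth scale factor, then any IP count of zero is
#' replaced by 1; a control count of zero is replaced by 1. Zeros are
#' replaced on both sides so every window has a finite, positive ratio.
#'
#' @param ip_counts,control_counts aligned per-window count vectors.
#' @param scale a `scale_factor` (or a bare positive number).
#' @return numeric vector of window scores.
#' @export
window_scores <- function(ip_counts, control_counts, scale) {
  if (length(ip_counts) != length(control_counts))
    stop("ip and control count vectors have different lengths (",
         length(ip_counts), " vs ", length(control_counts), ")")
  s <- if (inherits(scale, "scale_factor")) scale$value else as.numeric(scale)
  stopifnot(s > 0)
  num <- ifelse(ip_counts == 0, 1, ip_counts * s)
  den <- pmax(control_counts, 1)
  num / den
}

#' Call peaks as merged runs of enriched windows
#'
#' Windows scoring `>= threshold` are seeds; seeds whose intervals overlap
#' or abut are merged into one peak spanning their union. Each peak's final
#' score is recomputed on the merged area: reads overlapping the area are
#' counted once each (per track, under `class_filter`), the IP count is
#' scaled, zeros are pseudocounted to 1 on both sides, and the ratio taken.
#'
#' @param grid a `window_grid`.
#' @param ip_reads,control_reads aligned-read data.frames.
#' @param scale a `scale_factor`; default NULL computes
#'   `n(control)/n(ip)` from the supplied read sets.
#' @param threshold minimum window score for a seed (default 2, the
#'   conventional lowest reporting cut).
#' @param class_filter read class restriction, as in [count_reads()].
#' @return a `peak_set` data.frame: chrom, start, end, score, reads_ip,
#'   reads_control (unranked; see [rank_peaks()]).
#' @export
call_peaks <- function(grid, ip_reads, control_reads, scale = NULL,
                       threshold = 2, class_filter = "all") {
  stopifnot(threshold > 0)
  if (is.null(scale))
    scale <- compute_scale_factor(nrow(control_reads), nrow(ip_reads))
  sval <- if (inherits(scale, "scale_factor")) scale$value else as.numeric(scale)
  ipc <- count_reads(grid, ip_reads, class_filter)
  ctc <- count_reads(grid, control_reads, class_filter)
  sc <- window_scores(ipc, ctc, sval)
  w <- grid$windows
  seed <- sc >= threshold
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      score = numeric(), reads_ip = numeric(),
                      reads_control = numeric(), stringsAsFactors = FALSE)
  if (!any(seed)) {
    class(empty) <- c("peak_set", "data.frame")
    return(empty)
  }
  ip_f <- .filter_class(ip_reads, class_filter)
  ct_f <- .filter_class(control_reads, class_filter)
  out <- list()
  for (ch in unique(w$chrom[seed])) {
    si <- seed & w$chrom == ch
    merged <- IRanges::reduce(.as_iranges(w$start[si], w$end[si]))
    ms <- IRanges::start(merged) - 1L
    me <- IRanges::end(merged)
    cnt_area <- function(reads) {
      ri <- reads$chrom == ch
      IRanges::countOverlaps(IRanges::IRanges(ms + 1L, me),
                             .as_iranges(reads$start[ri], reads$end[ri]))
    }
    n_ip <- cnt_area(ip_f)
    n_ct <- cnt_area(ct_f)
    score <- ifelse(n_ip == 0, 1, n_ip * sval) / pmax(n_ct, 1)
    out[[ch]] <- data.frame(chrom = ch, start = as.numeric(ms),
                            end = as.numeric(me), score = score,
                            reads_ip = n_ip, reads_control = n_ct,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("peak_set", "data.frame")
  res
}

#' Rank peaks from high to low score
#'
#' Ties are broken by chromosome (lexicographic) then start (ascending),
#' so ranking is deterministic. Ranks 1..N are added in sorted order.
#'
#' @param peaks a `peak_set`.
#' @return the same `peak_set`, sorted, with a `rank` column.
#' @export
rank_peaks <- function(peaks) {
  ord <- order(-peaks$score, peaks$chrom, peaks$start)
  out <- peaks[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("peak_set", "data.frame")
  out
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak set: %d peak(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}
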