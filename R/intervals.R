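#' Genomic interval tables
#'
#' All coordinates inside the package are 0-based half-open `[start, end)`.
#' External formats that are 1-based inclusive (GFF3, the peak table, the
#' minimal SAM dialect) are converted at the I/O boundary only, so that
#' `end1 - start1 + 1 == end0 - start0` always holds.
#'
#' `genomic_intervals()` builds a validated data frame with columns
#' `chrom`, `start`, `end`, `strand`.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start,end integer-like vectors, 0-based half-open; `start < end`.
#' @param strand one of `"+"`, `"-"`, `"*"` (unspecified); recycled.
#' @return a data.frame with columns chrom/start/end/strand.
#' @examples
#' genomic_intervals("chr1", 0, 100)
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*") {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  strand <- rep_len(as.character(strand), length(chrom))
  if (any(is.na(chrom) | !nzchar(chrom)))
    stop("chromosome names must be non-empty")
  if (any(!strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*'")
  bad <- which(!(start >= 0 & start < end))
  if (length(bad))
    stop("invalid interval(s) at index ", paste(utils::head(bad, 5), collapse = ", "),
         ": need 0 <= start < end")
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

# 0-based half-open -> IRanges (1-based inclusive), same width
.as_iranges <- function(start0, end0) {
  IRanges::IRanges(start = as.integer(start0) + 1L, end = as.integer(end0))
}

#' Gap between two interval sets (vectorized, half-open coordinates)
#'
#' 0 when the intervals overlap or are book-ended; otherwise the number of
#' bases strictly between them.
#' @param s1,e1,s2,e2 numeric vectors of starts/ends (0-based half-open).
#' @return numeric vector of gaps in bp.
#' @keywords internal
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s2 - e1, s1 - e2))
}

# TRUE where intervals share >= 1 bp
.overlaps <- function(s1, e1, s2, e2) (s1 < e2) & (s2 < e1)
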