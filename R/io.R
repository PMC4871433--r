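#' Read aligned reads from BED6 or a minimal SAM dialect
#'
#' Each record becomes one aligned read with a `mapping_class` of
#' `"unique"` or `"repeated"` (reads placed at one best position vs reads
#' assigned to one of several equally good positions).
#'
#' Dialects:
#' * `bed`: whitespace-separated BED6 (`chrom start end name score strand`);
#'   coordinates are 0-based half-open and taken verbatim; by convention the
#'   score column carries the mapping class: 0 = unique, 1 = repeated.
#' * `minimal_sam`: header lines (`@...`) are skipped; the first six fields
#'   `QNAME FLAG RNAME POS MAPQ CIGAR` are used. POS is converted from
#'   1-based; MAPQ 0 means repeated; the reference span is the sum of
#'   M/D/N/=/X CIGAR lengths; FLAG bit 0x10 sets the minus strand.
#'
#' Unknown chromosomes are not an error at read time (they are screened
#' later against the window grid).
#'
#' @param path file to read.
#' @param dialect `"bed"` or `"minimal_sam"`.
#' @return data.frame with columns chrom, start, end, strand, name,
#'   mapping_class; zero rows for an empty file.
#' @export
read_alignments <- function(path, dialect = c("bed", "minimal_sam")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      strand = character(), name = character(),
                      mapping_class = character(), stringsAsFactors = FALSE)
  if (dialect == "minimal_sam") lines_keep <- !startsWith(lines, "@") else
    lines_keep <- rep(TRUE, length(lines))
  lines_keep <- lines_keep & nzchar(trimws(lines))
  idx <- which(lines_keep)
  if (!length(idx)) return(empty)
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(fields)
  need <- if (dialect == "bed") 6L else 6L
  bad <- which(nf < need)
  if (length(bad))
    stop(sprintf("malformed %s line %d in %s: expected >= %d fields, got %d",
                 dialect, idx[bad[1]], path, need, nf[bad[1]]))
  m <- matrix(unlist(lapply(fields, `[`, seq_len(need))), ncol = need, byrow = TRUE)
  if (dialect == "bed") {
    start <- suppressWarnings(as.numeric(m[, 2]))
    end <- suppressWarnings(as.numeric(m[, 3]))
    score <- suppressWarnings(as.numeric(m[, 5]))
    bad <- which(is.na(start) | is.na(end) | is.na(score) | start < 0 | start >= end)
    if (length(bad))
      stop(sprintf("malformed bed line %d in %s", idx[bad[1]], path))
    data.frame(chrom = m[, 1], start = start, end = end,
               strand = ifelse(m[, 6] %in% c("+", "-"), m[, 6], "*"),
               name = m[, 4],
               mapping_class = ifelse(score >= 1, "repeated", "unique"),
               stringsAsFactors = FALSE)
  } else {
    pos <- suppressWarnings(as.numeric(m[, 4]))
    mapq <- suppressWarnings(as.numeric(m[, 5]))
    span <- vapply(m[, 6], .cigar_ref_span, numeric(1), USE.NAMES = FALSE)
    bad <- which(is.na(pos) | pos < 1 | is.na(mapq) | is.na(span) | span <= 0)
    if (length(bad))
      stop(sprintf("malformed minimal_sam line %d in %s", idx[bad[1]], path))
    flag <- suppressWarnings(as.integer(m[, 2]))
    data.frame(chrom = m[, 3], start = pos - 1, end = pos - 1 + span,
               strand = ifelse(!is.na(flag) & bitwAnd(flag, 16L) > 0L, "-", "+"),
               name = m[, 1],
               mapping_class = ifelse(mapq == 0, "repeated", "unique"),
               stringsAsFactors = FALSE)
  }
}

.cigar_ref_span <- function(cigar) {
  if (is.na(cigar) || cigar == "*") return(NA_real_)
  ops <- gregexpr("([0-9]+)([MIDNSHP=X])", cigar)[[1]]
  if (ops[1] == -1) return(NA_real_)
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  n <- as.numeric(sub("[A-Z=]$", "", toks))
  op <- sub("^[0-9]+", "", toks)
  sum(n[op %in% c("M", "D", "N", "=", "X")])
}

#' Write aligned reads as BED6
#'
#' Score column encodes the mapping class (0 unique, 1 repeated), the
#' convention `read_alignments(dialect = "bed")` expects.
#' @param reads data.frame as returned by [read_alignments()].
#' @param path output file.
#' @export
write_alignments <- function(reads, path) {
  df <- data.frame(reads$chrom, format_bp(reads$start), format_bp(reads$end),
                   if (is.null(reads$name)) "." else reads$name,
                   ifelse(reads$mapping_class == "repeated", 1L, 0L),
                   ifelse(reads$strand %in% c("+", "-"), reads$strand, "."))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# integers printed without scientific notation
format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a feature catalog (genes/lncRNAs) from GFF3 or TSV
#'
#' Features carry a strand-aware transcription start site (TSS): position
#' `start` on `+`, `end - 1` on `-` (0-based). Records without a strand are
#' rejected with a warning because their TSS is undefined.
#'
#' * `gff3`: standard 9-column; the biotype is taken from the attribute key
#'   `biotype` (default `"other"` when absent); coordinates converted from
#'   1-based inclusive.
#' * `tsv`: header `feature_id name biotype chrom start1 end1 strand` with
#'   1-based inclusive start1/end1.
#'
#' @param path file to read.
#' @param format `"gff3"` or `"tsv"`.
#' @return data.frame with columns feature_id, name, biotype, chrom, start,
#'   end, strand, tss (0-based), of class `feature_catalog`.
#' @export
read_features <- function(path, format = c("gff3", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, quote = "")
    need <- c("feature_id", "name", "biotype", "chrom", "start1", "end1", "strand")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("feature TSV missing column(s): ",
                           paste(miss, collapse = ", "))
    out <- data.frame(feature_id = as.character(df$feature_id),
                      name = as.character(df$name),
                      biotype = as.character(df$biotype),
                      chrom = as.character(df$chrom),
                      start = df$start1 - 1, end = as.numeric(df$end1),
                      strand = as.character(df$strand),
                      stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines)) {
      out <- data.frame(feature_id = character(), name = character(),
                        biotype = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        strand = character(), stringsAsFactors = FALSE)
    } else {
      f <- strsplit(lines, "\t", fixed = TRUE)
      if (any(lengths(f) < 9)) stop("malformed GFF3 line ",
                                    which(lengths(f) < 9)[1], " in ", path)
      m <- matrix(unlist(lapply(f, `[`, 1:9)), ncol = 9, byrow = TRUE)
      attr_get <- function(attrs, key, default) {
        hit <- regmatches(attrs, regexpr(paste0("(^|;)\\s*", key, "=[^;]*"), attrs))
        if (!length(hit)) return(default)
        sub(paste0("^.*", key, "="), "", hit)
      }
      ids <- vapply(m[, 9], attr_get, character(1), key = "ID",
                    default = "", USE.NAMES = FALSE)
      nms <- vapply(m[, 9], attr_get, character(1), key = "Name",
                    default = "", USE.NAMES = FALSE)
      bty <- vapply(m[, 9], attr_get, character(1), key = "biotype",
                    default = "other", USE.NAMES = FALSE)
      ids[!nzchar(ids)] <- paste0("feature_", which(!nzchar(ids)))
      nms[!nzchar(nms)] <- ids[!nzchar(nms)]
      out <- data.frame(feature_id = ids, name = nms, biotype = bty,
                        chrom = m[, 1], start = as.numeric(m[, 4]) - 1,
                        end = as.numeric(m[, 5]), strand = m[, 7],
                        stringsAsFactors = FALSE)
    }
  }
  bad_bty <- !out$biotype %in% c("protein_coding", "lncRNA", "other")
  if (any(bad_bty))
    stop("unknown biotype(s): ", paste(unique(out$biotype[bad_bty]), collapse = ", "))
  no_strand <- !out$strand %in% c("+", "-")
  if (any(no_strand)) {
    warning(sum(no_strand), " feature record(s) without strand rejected (TSS undefined)")
    out <- out[!no_strand, , drop = FALSE]
  }
  out$tss <- ifelse(out$strand == "+", out$start, out$end - 1)
  rownames(out) <- NULL
  class(out) <- c("feature_catalog", "data.frame")
  out
}

#' Write a feature catalog as TSV (1-based inclusive coordinates)
#' @param features a `feature_catalog`.
#' @param path output file.
#' @export
write_features <- function(features, path) {
  df <- data.frame(feature_id = features$feature_id, name = features$name,
                   biotype = features$biotype, chrom = features$chrom,
                   start1 = format_bp(features$start + 1),
                   end1 = format_bp(features$end), strand = features$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# columns of the serialized peak table, in order
.peak_table_cols <- c("peak_no", "code", "chrom", "start1", "end1", "score",
                      "reads_ip", "reads_control", "feature", "biotype",
                      "distance_to_tss", "location_class", "lnc_tier")

#' Write a ranked, annotated peak table as TSV
#'
#' Coordinates are serialized 1-based inclusive (`start1 = start + 1`,
#' `end1 = end`), the style of published peak tables; internal storage
#' stays 0-based half-open. Scores are printed with full double precision
#' (`%.17g`) so the table round-trips losslessly through
#' [read_peak_table()].
#'
#' @param peaks a `peak_set` data.frame (annotation columns optional).
#' @param path output file.
#' @export
write_peak_table <- function(peaks, path) {
  n <- nrow(peaks)
  get <- function(col, default) {
    if (!is.null(peaks[[col]])) peaks[[col]] else rep(default, n)
  }
  df <- data.frame(peak_no = get("rank", seq_len(max(n, 0))),
                   code = get("code", "."),
                   chrom = peaks$chrom,
                   start1 = format_bp(peaks$start + 1),
                   end1 = format_bp(peaks$end),
                   score = sprintf("%.17g", peaks$score),
                   reads_ip = get("reads_ip", NA_real_),
                   reads_control = get("reads_control", NA_real_),
                   feature = get("feature", "."),
                   biotype = get("feature_biotype", "."),
                   distance_to_tss = get("distance_to_tss", NA_real_),
                   location_class = get("location_class", "."),
                   lnc_tier = get("lnc_tier", "."),
                   stringsAsFactors = FALSE)
  if (n == 0) df <- df[0, , drop = FALSE]
  names(df) <- .peak_table_cols
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a peak table written by [write_peak_table()]
#' @param path TSV written by [write_peak_table()].
#' @return a `peak_set` data.frame (0-based half-open coordinates).
#' @export
read_peak_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = c(chrom = "character", code = "character",
                                         feature = "character"))
  miss <- setdiff(.peak_table_cols, names(df))
  if (length(miss)) stop("peak table missing column(s): ",
                         paste(miss, collapse = ", "))
  out <- data.frame(chrom = df$chrom, start = as.numeric(df$start1) - 1,
                    end = as.numeric(df$end1), score = as.numeric(df$score),
                    reads_ip = df$reads_ip, reads_control = df$reads_control,
                    rank = df$peak_no, code = df$code,
                    feature = df$feature, feature_biotype = df$biotype,
                    distance_to_tss = df$distance_to_tss,
                    location_class = df$location_class, lnc_tier = df$lnc_tier,
                    stringsAsFactors = FALSE)
  class(out) <- c("peak_set", "data.frame")
  out
}

#' Write a per-window score track as bedGraph
#' @param grid a `window_grid` (see [make_windows()]).
#' @param scores numeric vector aligned with `grid$windows`.
#' @param path output file.
#' @export
write_bedgraph <- function(grid, scores, path) {
  w <- grid$windows
  stopifnot(length(scores) == nrow(w))
  df <- data.frame(w$chrom, format_bp(w$start), format_bp(w$end),
                   sprintf("%.17g", scores))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
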