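DNA_BASES <- c("A", "C", "G", "T")

# encode an ACGTN string as integers 1..4 (N -> NA)
.encode_dna <- function(x) {
  v <- match(strsplit(toupper(x), "")[[1]], c(DNA_BASES, "N"))
  if (anyNA(v)) stop("non-ACGTN character in sequence")
  v[v == 5L] <- NA_integer_
  v
}

#' Reverse complement of DNA strings
#' @param x character vector over ACGTN.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# all width-length words of one sequence (N-containing words excluded);
# offsets are 1-based starts on the forward strand
.candidate_words <- function(seq_enc, width, both_strands) {
  L <- length(seq_enc)
  n <- L - width + 1L
  starts <- seq_len(n)
  mat <- matrix(seq_enc[outer(starts, 0:(width - 1L), `+`)], nrow = n)
  ok <- !apply(is.na(mat), 1, any)
  fwd <- list(mat = mat[ok, , drop = FALSE], start = starts[ok],
              strand = rep("+", sum(ok)))
  if (!both_strands) return(fwd)
  rc <- matrix(5L - mat[ok, rev(seq_len(width)), drop = FALSE], ncol = width)
  list(mat = rbind(fwd$mat, rc),
       start = c(fwd$start, fwd$start),
       strand = c(fwd$strand, rep("-", nrow(rc))))
}

# per-column Hertz-Stormo information content for count column `cnt`
.col_ic <- function(cnt, n, background, pseudocount) {
  f <- (cnt + pseudocount) / (n + 4 * pseudocount)
  term <- ifelse(f > 0, f * log2(f / background), 0)
  sum(term)
}

#' Hertz-Stormo information content of a count matrix
#'
#' `IC = sum_w sum_b f_bw log2(f_bw / p_b)` in bits, with
#' `f = (count + pseudocount) / (n + 4 pseudocount)` per column. IC is
#' non-negative and 0 exactly when every column's frequencies equal the
#' background (at pseudocount 0).
#'
#' @param count_matrix 4 x width matrix of non-negative counts (rows
#'   A, C, G, T).
#' @param background length-4 strictly positive probability vector.
#' @param pseudocount per-cell smoothing added before normalizing
#'   (default 0).
#' @return total bits across columns.
#' @export
information_content <- function(count_matrix, background = rep(0.25, 4),
                                pseudocount = 0) {
  stopifnot(nrow(count_matrix) == 4, all(count_matrix >= 0),
            all(background > 0), abs(sum(background) - 1) < 1e-9)
  tot <- colSums(count_matrix)
  if (any(tot == 0)) stop("zero-total column in count matrix")
  sum(vapply(seq_len(ncol(count_matrix)), function(j)
    .col_ic(count_matrix[, j], tot[j], background, pseudocount), numeric(1)))
}

#' Majority-rule consensus string of a frequency matrix
#'
#' Per column: the base whose frequency is `>= majority_threshold`
#' (default 0.5), else `N` (any residue).
#'
#' @param freq_matrix 4 x width column-stochastic matrix (rows A, C, G, T).
#' @param majority_threshold minimum frequency to call a base.
#' @return consensus string over ACGTN.
#' @export
consensus_string <- function(freq_matrix, majority_threshold = 0.5) {
  stopifnot(nrow(freq_matrix) == 4)
  paste(vapply(seq_len(ncol(freq_matrix)), function(j) {
    b <- which.max(freq_matrix[, j])
    if (freq_matrix[b, j] >= majority_threshold) DNA_BASES[b] else "N"
  }, character(1)), collapse = "")
}

#' Greedy matrix-building consensus motif discovery
#'
#' A CONSENSUS-style information-content maximizing beam search: seed
#' matrices are built from every `width`-length word of the first sequence
#' (both strands when `both_strands`); each subsequent cycle extends every
#' retained matrix with the word of the next sequence that maximizes
#' Hertz-Stormo information content, keeping the `beam` best distinct
#' matrices per cycle. The highest-IC complete matrix (one member site per
#' input sequence) is returned. The procedure is fully deterministic given
#' the input order; `seed` is accepted for interface stability but no
#' randomness is used.
#'
#' @param sequences character vector (>= 2) of ACGTN strings, each at
#'   least `width` long. N is allowed but N-containing words are excluded
#'   from seeding/extension.
#' @param width motif width in bp (default 10).
#' @param both_strands also consider reverse-complement words (default
#'   TRUE).
#' @param beam number of matrices retained per cycle (default 50).
#' @param pseudocount per-cell smoothing for frequencies and IC during the
#'   search (default 0.25).
#' @param background length-4 base probability vector (default uniform).
#' @param seed unused; kept for call compatibility.
#' @return a `motif_model` list: width, count_matrix, freq_matrix,
#'   background, pseudocount, consensus, information_content,
#'   member_sites (data.frame seq_index/offset/strand, offset 1-based on
#'   the forward strand).
#' @export
discover_motif <- function(sequences, width = 10, both_strands = TRUE,
                           beam = 50, pseudocount = 0.25,
                           background = rep(0.25, 4), seed = NULL) {
  if (length(sequences) < 2) stop("need at least 2 sequences")
  short <- which(nchar(sequences) < width)
  if (length(short))
    stop("sequence ", short[1], " is shorter than the motif width (",
         nchar(sequences[short[1]]), " < ", width, ")")
  enc <- lapply(sequences, .encode_dna)
  cands <- lapply(enc, .candidate_words, width = width,
                  both_strands = both_strands)
  if (any(vapply(cands, function(x) nrow(x$mat) == 0, logical(1))))
    stop("a sequence has no N-free word of the requested width")

  # beam states: count matrix (4 x width), member sites
  w1 <- cands[[1]]
  states <- lapply(seq_len(nrow(w1$mat)), function(i) {
    C <- matrix(0L, 4, width)
    C[cbind(w1$mat[i, ], seq_len(width))] <- 1L
    list(C = C,
         sites = data.frame(seq_index = 1L, offset = w1$start[i],
                            strand = w1$strand[i], stringsAsFactors = FALSE),
         ic = information_content(C, background, pseudocount))
  })
  # keep every first-cycle word: one-hot seed matrices all tie on IC under a
  # uniform background, so pruning here would discard sites arbitrarily
  states <- .prune_beam(states, length(states))

  for (i in seq_along(sequences)[-1]) {
    wi <- cands[[i]]
    n_members <- i - 1L
    cand_states <- list()
    scores <- numeric(0)
    origin <- integer(0)
    word <- integer(0)
    for (s in seq_along(states)) {
      C <- states[[s]]$C
      # IC of each column after adding one count of each base
      tbl <- matrix(0, 4, width)
      for (j in seq_len(width)) for (b in 1:4) {
        cc <- C[, j]
        cc[b] <- cc[b] + 1L
        tbl[b, j] <- .col_ic(cc, n_members + 1L, background, pseudocount)
      }
      sc <- rowSums(matrix(tbl[cbind(as.vector(wi$mat),
                                     rep(seq_len(width), each = nrow(wi$mat)))],
                           nrow = nrow(wi$mat)))
      scores <- c(scores, sc)
      origin <- c(origin, rep(s, nrow(wi$mat)))
      word <- c(word, seq_len(nrow(wi$mat)))
    }
    ord <- order(-scores, origin, word)
    keep <- utils::head(ord, beam * 4L)  # oversample before dedup
    new_states <- lapply(keep, function(k) {
      s <- states[[origin[k]]]
      C <- s$C
      C[cbind(wi$mat[word[k], ], seq_len(width))] <-
        C[cbind(wi$mat[word[k], ], seq_len(width))] + 1L
      list(C = C,
           sites = rbind(s$sites,
                         data.frame(seq_index = i, offset = wi$start[word[k]],
                                    strand = wi$strand[word[k]],
                                    stringsAsFactors = FALSE)),
           ic = scores[k])
    })
    states <- .prune_beam(new_states, beam)
  }

  best <- states[[1]]
  n <- length(sequences)
  freq <- sweep(best$C + pseudocount, 2, n + 4 * pseudocount, `/`)
  structure(list(width = width, count_matrix = best$C, freq_matrix = freq,
                 background = background, pseudocount = pseudocount,
                 consensus = consensus_string(freq),
                 information_content = information_content(best$C, background,
                                                           pseudocount),
                 member_sites = best$sites),
            class = "motif_model")
}

# order by IC (desc, deterministic), drop duplicate matrices, keep top `beam`
.prune_beam <- function(states, beam) {
  ic <- vapply(states, `[[`, numeric(1), "ic")
  ord <- order(-ic, seq_along(states))
  states <- states[ord]
  key <- vapply(states, function(s) paste(s$C, collapse = ","), character(1))
  states <- states[!duplicated(key)]
  utils::head(states, beam)
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("motif model: width %d, consensus %s, IC %.3f bits, %d sites\n",
              x$width, x$consensus, x$information_content,
              nrow(x$member_sites)))
  invisible(x)
}

#' Exact p-value of a motif's best match in a sequence
#'
#' Every window of the sequence is scored by the log-likelihood ratio
#' `sum_j log2(f[base_j, j] / p[base_j])`; the p-value is the probability,
#' under the i.i.d. background model, that a single random window scores at
#' least as high as the best observed window. It is computed exactly by
#' dynamic-programming convolution of the per-column score distributions
#' after discretizing scores to `bin`-sized steps (default 0.01 bits;
#' zero frequencies are floored at -30 bits/column so impossible bases
#' stay strictly below any attainable match).
#'
#' @param motif a `motif_model` (or any list with freq_matrix/background).
#' @param sequence ACGTN string at least `motif$width` long; windows
#'   containing N are not scored.
#' @param bin discretization step in bits (default 0.01).
#' @param both_strands also scan the reverse complement for the best site
#'   (default FALSE; the p-value stays a single-window tail either way).
#' @return list(p_value, best_score (bits), best_offset (1-based, forward
#'   strand), best_strand).
#' @export
best_match_pvalue <- function(motif, sequence, bin = 0.01,
                              both_strands = FALSE) {
  w <- ncol(motif$freq_matrix)
  if (nchar(sequence) < w) stop("sequence shorter than motif width")
  lod <- log2(motif$freq_matrix / motif$background)
  lod[!is.finite(lod)] <- -30            # floor for zero frequencies
  K <- matrix(as.integer(round(lod / bin)), 4, w)

  scan <- function(seq_chr, strand) {
    e <- .encode_dna(seq_chr)
    n <- length(e) - w + 1L
    if (n < 1L) return(NULL)
    starts <- seq_len(n)
    mat <- matrix(e[outer(starts, 0:(w - 1L), `+`)], nrow = n)
    ok <- !apply(is.na(mat), 1, any)
    if (!any(ok)) return(NULL)
    sc <- rowSums(matrix(K[cbind(as.vector(mat[ok, , drop = FALSE]),
                                 rep(seq_len(w), each = sum(ok)))],
                         nrow = sum(ok)))
    i <- which.max(sc)
    off <- starts[ok][i]
    if (strand == "-") off <- nchar(seq_chr) - (off + w - 1L) + 1L
    list(k = sc[i], offset = off, strand = strand)
  }
  hits <- list(scan(sequence, "+"))
  if (both_strands)
    hits <- c(hits, list(scan(reverse_complement(sequence), "-")))
  hits <- Filter(Negate(is.null), hits)
  if (!length(hits)) stop("no N-free window to score")
  best <- hits[[which.max(vapply(hits, `[[`, numeric(1), "k"))]]

  # exact tail P(window score >= best) by convolution over columns
  dist <- c(1)                 # probabilities; index 1 <-> offset `lo`
  lo <- 0L
  for (j in seq_len(w)) {
    kj <- K[, j]
    lo2 <- lo + min(kj)
    hi2 <- lo + length(dist) - 1L + max(kj)
    nd <- numeric(hi2 - lo2 + 1L)
    for (b in 1:4) {
      sh <- kj[b] - min(kj)
      idx <- seq_along(dist) + sh
      nd[idx] <- nd[idx] + dist * motif$background[b]
    }
    dist <- nd
    lo <- lo2
  }
  tail_from <- best$k - lo + 1L
  p <- if (tail_from <= 1L) 1 else if (tail_from > length(dist)) 0 else
    sum(dist[tail_from:length(dist)])
  list(p_value = p, best_score = best$k * bin, best_offset = best$offset,
       best_strand = best$strand)
}

#' Extract peak sequences from a genome
#'
#' @param peaks a `peak_set`.
#' @param genome a named `DNAStringSet`, a named character vector of
#'   chromosome sequences, or a FASTA path.
#' @return character vector of peak sequences (forward strand), named by
#'   `chrom:start1-end1`.
#' @export
peak_sequences <- function(peaks, genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  miss <- setdiff(unique(peaks$chrom), names(genome))
  if (length(miss)) stop("chromosome(s) absent from genome: ",
                         paste(miss, collapse = ", "))
  out <- vapply(seq_len(nrow(peaks)), function(i) {
    as.character(Biostrings::subseq(genome[[peaks$chrom[i]]],
                                    start = peaks$start[i] + 1,
                                    end = peaks$end[i]))
  }, character(1))
  names(out) <- sprintf("%s:%s-%s", peaks$chrom, format_bp(peaks$start + 1),
                        format_bp(peaks$end))
  out
}

#' Write a motif report (count/frequency matrices + consensus) as text
#' @param motif a `motif_model`.
#' @param path output file.
#' @export
write_motif_report <- function(motif, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("consensus\t%s", motif$consensus),
               sprintf("width\t%d", motif$width),
               sprintf("information_content_bits\t%.6f",
                       motif$information_content),
               "", "count_matrix (rows A C G T)"), con)
  utils::write.table(motif$count_matrix, con, sep = "\t", quote = FALSE,
                     row.names = DNA_BASES, col.names = FALSE)
  writeLines(c("", "freq_matrix (rows A C G T)"), con)
  utils::write.table(signif(motif$freq_matrix, 6), con, sep = "\t",
                     quote = FALSE, row.names = DNA_BASES, col.names = FALSE)
  writeLines(c("", "member_sites (seq_index offset strand)"), con)
  utils::write.table(motif$member_sites, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
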