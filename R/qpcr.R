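#' Read a Ct table from CSV
#'
#' Expected columns: `sample`, `target`, `role`, `ct` — one row per
#' replicate. `role` is one of `expression`, `chip_ip`, `chip_input`,
#' `chip_prei`.
#'
#' @param path CSV file.
#' @return data.frame of class `ct_table`.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "target", "role", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("Ct table missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- !df$role %in% c("expression", "chip_ip", "chip_input", "chip_prei")
  if (any(bad)) stop("unknown role(s): ", paste(unique(df$role[bad]),
                                                collapse = ", "))
  if (any(!is.finite(df$ct) | df$ct <= 0))
    stop("Ct values must be finite and positive")
  class(df) <- c("ct_table", "data.frame")
  df
}

# mean/SEM of replicate Cts for one (sample, target, role) cell
.ct_cell <- function(table, sample, target, role) {
  v <- table$ct[table$sample == sample & table$target == target &
                  table$role == role]
  if (!length(v))
    stop(sprintf("no Ct record for sample='%s' target='%s' role='%s'",
                 sample, target, role))
  sem <- if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
  list(mean = mean(v), sem = sem, n = length(v))
}

#' Relative expression by the delta-delta-Ct method
#'
#' `dCt_s = Ct(target, s) - Ct(reference, s)` per sample;
#' `ddCt = dCt(sample) - dCt(calibrator)`; `fold = 2^-ddCt`, assuming an
#' amplification efficiency of exactly 2 per cycle. Replicates are
#' averaged in Ct space first; their SEMs are combined in quadrature in Ct
#' space, and the fold's uncertainty is reported both as that log2-scale
#' SEM and as the delta-method SEM on the fold scale.
#'
#' @param table a `ct_table` (expression-role records are used).
#' @param target gene of interest.
#' @param reference_gene housekeeping reference (e.g. `"Gapdh"`).
#' @param sample sample of interest.
#' @param calibrator_sample sample the fold is expressed relative to.
#' @return list(fold, ddct, sem_ct (SEM of ddCt in cycles),
#'   fold_sem (delta method), fold_lo/fold_hi (fold at ddCt +/- 1 SEM)).
#' @export
relative_expression_ddct <- function(table, target, reference_gene, sample,
                                     calibrator_sample) {
  ts <- .ct_cell(table, sample, target, "expression")
  rs <- .ct_cell(table, sample, reference_gene, "expression")
  tc <- .ct_cell(table, calibrator_sample, target, "expression")
  rc <- .ct_cell(table, calibrator_sample, reference_gene, "expression")
  ddct <- (ts$mean - rs$mean) - (tc$mean - rc$mean)
  sem <- sqrt(ts$sem^2 + rs$sem^2 + tc$sem^2 + rc$sem^2)
  fold <- 2^(-ddct)
  list(fold = fold, ddct = ddct, sem_ct = sem,
       fold_sem = fold * log(2) * sem,
       fold_lo = 2^(-(ddct + sem)), fold_hi = 2^(-(ddct - sem)))
}

#' Percent input from ChIP-qPCR Cts
#'
#' The input Ct is first adjusted for its dilution
#' (`ct_input - log2(1 / input_fraction)` puts a fractional input on the
#' 100% scale), then `%input = 100 * 2^(adjusted_input - ct_ip)`.
#'
#' @param ct_ip mean Ct of the immunoprecipitated sample.
#' @param ct_input mean Ct of the input chromatin.
#' @param input_fraction fraction of chromatin used as input (0 < f <= 1;
#'   default 1).
#' @return percent of input (vectorized).
#' @export
percent_input <- function(ct_ip, ct_input, input_fraction = 1) {
  if (any(input_fraction <= 0 | input_fraction > 1))
    stop("input_fraction must be in (0, 1]")
  adj <- ct_input - log2(1 / input_fraction)
  100 * 2^(adj - ct_ip)
}

#' Fold enrichment of a locus over a reference locus
#'
#' With background subtraction (the default), pre-immune %input is
#' subtracted from IP %input at both loci before the ratio; a negative
#' numerator is clamped to 0 (no enrichment). Without subtraction the raw
#' IP ratio is taken.
#'
#' @param locus numeric: `c(ip = %, prei = %)` for the locus of interest
#'   (`prei` may be absent when not subtracting).
#' @param reference same for the non-binding reference locus.
#' @param subtract_background subtract pre-immune background first
#'   (default TRUE).
#' @return fold enrichment (dimensionless).
#' @export
fold_enrichment <- function(locus, reference, subtract_background = TRUE) {
  if (subtract_background) {
    num <- max(locus[["ip"]] - locus[["prei"]], 0)
    den <- reference[["ip"]] - reference[["prei"]]
  } else {
    num <- locus[["ip"]]
    den <- reference[["ip"]]
  }
  if (den <= 0)
    stop("fold enrichment undefined: reference denominator ", den, " <= 0")
  num / den
}

#' Primer amplification efficiency from a standard-curve slope
#'
#' `E = (10^(-1/slope) - 1) * 100` percent; a slope of -3.3219 Ct per
#' log10 dilution corresponds to perfect doubling (100%). Primers pass QC
#' when 90 <= E <= 110.
#'
#' @param standard_curve_slope Ct change per log10 dilution (< 0).
#' @return list(efficiency (percent), pass (logical)).
#' @export
primer_efficiency <- function(standard_curve_slope) {
  if (standard_curve_slope >= 0)
    stop("standard curve slope must be negative")
  e <- (10^(-1 / standard_curve_slope) - 1) * 100
  list(efficiency = e, pass = e >= 90 && e <= 110)
}
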