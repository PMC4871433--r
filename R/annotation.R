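#' Nearest catalog feature within a distance cutoff
#'
#' Distance is the minimum gap in bp between the peak interval and the
#' feature interval (0 when they overlap or abut). Among features with gap
#' `<= max_dist` (inclusive boundary) the smallest gap wins; ties are
#' broken by smaller edge-to-TSS distance, then lexicographic feature_id.
#' The returned `distance` is the winning gap, signed like
#' `distance_to_tss`: negative when the peak lies 5' (upstream) of the
#' feature's TSS in its orientation.
#'
#' The returned `distance_to_tss` is the minimum distance from either peak
#' edge to the feature's TSS (0 if the TSS falls inside the peak), signed:
#' negative when the peak lies 5' (upstream) of the TSS in the feature's
#' orientation, positive when 3' of it.
#'
#' @param peak one-row data.frame (or list) with chrom/start/end,
#'   0-based half-open.
#' @param catalog a `feature_catalog` (see [read_features()]).
#' @param max_dist maximum gap in bp (default 100000).
#' @return list(feature = one-row data.frame or NULL, distance = gap bp or
#'   NA, distance_to_tss = signed bp or NA).
#' @export
nearest_feature <- function(peak, catalog, max_dist = 100000) {
  fi <- which(catalog$chrom == peak$chrom)
  if (!length(fi))
    return(list(feature = NULL, distance = NA_real_, distance_to_tss = NA_real_))
  f <- catalog[fi, , drop = FALSE]
  gap <- interval_gap(peak$start, peak$end, f$start, f$end)
  keep <- gap <= max_dist
  if (!any(keep))
    return(list(feature = NULL, distance = NA_real_, distance_to_tss = NA_real_))
  f <- f[keep, , drop = FALSE]
  gap <- gap[keep]
  tssd <- .edge_tss_distance(peak, f$tss)
  ord <- order(gap, tssd, f$feature_id)
  i <- ord[1]
  sgn <- .sign_tss(peak, f[i, , drop = FALSE])
  list(feature = f[i, , drop = FALSE], distance = sgn * gap[i],
       distance_to_tss = sgn * tssd[i])
}

# min distance from either peak edge to a TSS; 0 if the TSS is inside
.edge_tss_distance <- function(peak, tss) {
  inside <- tss >= peak$start & tss < peak$end
  d <- pmin(abs(peak$start - tss), abs((peak$end - 1) - tss))
  d[inside] <- 0
  d
}

# -1 when the peak is 5' of the TSS in the feature's orientation, else +1
.sign_tss <- function(peak, feature) {
  t <- feature$tss
  if (t >= peak$start & t < peak$end) return(1)
  before <- peak$end - 1 < t   # peak entirely left of the TSS
  upstream <- if (feature$strand == "+") before else !before
  if (upstream) -1 else 1
}

#' Location class of a peak relative to the feature catalog
#'
#' Five classes with precedence TSS > O > (DU|DD) > I:
#' * `TSS` — a transcription start site lies within `tss_dist` bp
#'   (default 2500, inclusive) of either peak edge;
#' * `O` — the peak overlaps a transcribed feature by >= 1 bp;
#' * `DU` — nearest feature within `max_dist`, peak 5' (upstream) of its
#'   TSS, strand-aware;
#' * `DD` — nearest feature within `max_dist`, peak 3' (downstream) of the
#'   feature's transcribed end;
#' * `I` — intergenic: no feature within `max_dist` (default 100 kb).
#'
#' @inheritParams nearest_feature
#' @param tss_dist TSS-proximity cutoff in bp (default 2500).
#' @return one of `"TSS"`, `"O"`, `"DU"`, `"DD"`, `"I"`.
#' @export
classify_location <- function(peak, catalog, max_dist = 100000,
                              tss_dist = 2500) {
  fi <- which(catalog$chrom == peak$chrom)
  if (!length(fi)) return("I")
  f <- catalog[fi, , drop = FALSE]
  tssd <- .edge_tss_distance(peak, f$tss)
  if (any(tssd <= tss_dist)) return("TSS")
  if (any(.overlaps(peak$start, peak$end, f$start, f$end))) return("O")
  nf <- nearest_feature(peak, catalog, max_dist)
  if (is.null(nf$feature)) return("I")
  if (nf$distance_to_tss < 0) "DU" else "DD"
}

#' lncRNA proximity tier of a peak
#'
#' `lnc_within_5kb` if any lncRNA feature lies within `near` bp (gap,
#' overlap = 0; default 5000, inclusive); else `lnc_within_100kb` if any
#' lies within `max_dist`; else `other`. Tiers are mutually exclusive with
#' the 5 kb tier taking precedence.
#'
#' @inheritParams nearest_feature
#' @param near close-proximity cutoff in bp (default 5000).
#' @return one of `"lnc_within_5kb"`, `"lnc_within_100kb"`, `"other"`.
#' @export
lncrna_tier <- function(peak, catalog, near = 5000, max_dist = 100000) {
  fi <- which(catalog$chrom == peak$chrom & catalog$biotype == "lncRNA")
  if (!length(fi)) return("other")
  gap <- interval_gap(peak$start, peak$end,
                      catalog$start[fi], catalog$end[fi])
  if (any(gap <= near)) return("lnc_within_5kb")
  if (any(gap <= max_dist)) return("lnc_within_100kb")
  "other"
}

#' Annotate a peak set with nearest features, location classes and tiers
#'
#' Adds columns `feature`, `feature_biotype`, `distance` (gap bp),
#' `distance_to_tss` (signed bp), `location_class`, `lnc_tier`.
#'
#' @param peaks a `peak_set`.
#' @param catalog a `feature_catalog`.
#' @param max_dist,tss_dist,lnc_near class cutoffs in bp (defaults
#'   100000 / 2500 / 5000).
#' @return the annotated `peak_set`.
#' @export
annotate_peaks <- function(peaks, catalog, max_dist = 100000,
                           tss_dist = 2500, lnc_near = 5000) {
  n <- nrow(peaks)
  peaks$feature <- rep(NA_character_, n)
  peaks$feature_biotype <- rep(NA_character_, n)
  peaks$distance <- rep(NA_real_, n)
  peaks$distance_to_tss <- rep(NA_real_, n)
  peaks$location_class <- character(n)
  peaks$lnc_tier <- character(n)
  for (i in seq_len(n)) {
    p <- peaks[i, , drop = FALSE]
    nf <- nearest_feature(p, catalog, max_dist)
    if (!is.null(nf$feature)) {
      peaks$feature[i] <- nf$feature$name
      peaks$feature_biotype[i] <- nf$feature$biotype
      peaks$distance[i] <- nf$distance
      peaks$distance_to_tss[i] <- nf$distance_to_tss
    }
    peaks$location_class[i] <- classify_location(p, catalog, max_dist, tss_dist)
    peaks$lnc_tier[i] <- lncrna_tier(p, catalog, lnc_near, max_dist)
  }
  class(peaks) <- c("peak_set", "data.frame")
  peaks
}

#' Count peaks per location class and lncRNA tier
#'
#' @param peaks an annotated `peak_set` (see [annotate_peaks()]).
#' @return list of two named integer vectors, `location` (TSS/O/DU/DD/I)
#'   and `lnc` (lnc_within_5kb/lnc_within_100kb/other); each sums to
#'   `nrow(peaks)`.
#' @export
summarize_classes <- function(peaks) {
  loc_levels <- c("TSS", "O", "DU", "DD", "I")
  lnc_levels <- c("lnc_within_5kb", "lnc_within_100kb", "other")
  if (nrow(peaks) && (any(!peaks$location_class %in% loc_levels) ||
                      any(!peaks$lnc_tier %in% lnc_levels)))
    stop("peaks must be annotated before summarizing")
  loc <- table(factor(peaks$location_class, levels = loc_levels))
  lnc <- table(factor(peaks$lnc_tier, levels = lnc_levels))
  list(location = stats::setNames(as.integer(loc), loc_levels),
       lnc = stats::setNames(as.integer(lnc), lnc_levels))
}
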