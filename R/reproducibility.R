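# Replicate reproducibility metrics.
#
# Three statistics summarise how well two replicates of an accessibility
# library agree:
#   1. alignment reproducibility — Pearson correlation of per-bin read
#      counts (10 kb bins by default);
#   2. open-chromatin reproducibility — Pearson correlation of per-bin mean
#      peak height;
#   3. footprint reproducibility — the proportion of one replicate's
#      footprints that are covered by a footprint of the other replicate,
#      swept over a required-overlap-fraction threshold.

#' Pearson correlation with loud degenerate handling
#'
#' Product-moment correlation of two equal-length vectors. A constant vector
#' makes the correlation undefined; this raises an error rather than
#' silently returning NaN, so degenerate simulations fail visibly.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @param log1p_transform if `TRUE`, correlate `log1p(x)` with `log1p(y)`
#'   (off by default; the metric is defined on raw counts).
#' @return Correlation in `[-1, 1]`.
#' @examples
#' pearson_cor(c(0, 1, 2, 5), c(1, 1, 3, 4))  # 0.9258...
#' @export
pearson_cor <- function(x, y, log1p_transform = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (log1p_transform) { x <- log1p(x); y <- log1p(y) }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: at least one input vector is constant",
         call. = FALSE)
  }
  stats::cor(x, y)
}

#' Alignment reproducibility between two replicates
#'
#' Pearson correlation of per-bin read counts between two replicates over
#' the same genome binning. High values mean reads fall into the same
#' genomic bins in both replicates.
#'
#' @param track1,track2 [binned_track()]s over identical binnings.
#' @param log1p_transform passed to [pearson_cor()].
#' @return Correlation in `[-1, 1]`.
#' @export
alignment_reproducibility <- function(track1, track2,
                                      log1p_transform = FALSE) {
  stopifnot(inherits(track1, "binned_track"), inherits(track2, "binned_track"))
  if (!same_binning(track1$binning, track2$binning)) {
    stop("tracks are defined over different binnings", call. = FALSE)
  }
  pearson_cor(track1$values, track2$values, log1p_transform)
}

#' Per-bin mean peak height of open chromatin regions
#'
#' For each genome bin, the mean per-base peak height: every base covered by
#' an OCR contributes that OCR's height (its score), every uncovered base
#' contributes 0, and the sum is divided by the bin length (default) or by
#' the number of covered bases (`average = "covered"`). OCRs spanning a bin
#' boundary contribute proportionally to each bin.
#'
#' @param ocrs an [interval_set()] whose `score` column holds peak heights
#'   (all non-missing).
#' @param binning a [genome_binning()].
#' @param average `"genome"` (uncovered bases count as height 0) or
#'   `"covered"` (average over covered bases only; empty bins get 0).
#' @return A [binned_track()] of mean heights.
#' @examples
#' b <- genome_binning(c(chr1 = 10000), bin_size = 10000)
#' o <- interval_set("chr1", 0, 5000, score = 2)
#' ocr_mean_height_track(o, b)$values  # 1.0
#' @export
ocr_mean_height_track <- function(ocrs, binning,
                                  average = c("genome", "covered")) {
  average <- match.arg(average)
  stopifnot(inherits(ocrs, "interval_set"),
            inherits(binning, "genome_binning"))
  if (nrow(ocrs) > 0L && anyNA(ocrs$score)) {
    stop("every OCR must carry a height in its score column", call. = FALSE)
  }
  bins <- make_bins(binning)
  nb <- nrow(bins)
  mass <- numeric(nb)
  covered <- numeric(nb)
  if (nrow(ocrs) > 0L) {
    hits <- intersect_intervals(bins, ocrs)
    if (nrow(hits) > 0L) {
      mass <- as.numeric(tapply_sum(hits$overlap * ocrs$score[hits$subject],
                                    hits$query, nb))
      covered <- as.numeric(tapply_sum(hits$overlap, hits$query, nb))
    }
  }
  denom <- if (average == "genome") bins$end - bins$start else covered
  vals <- ifelse(denom > 0, mass / denom, 0)
  binned_track(binning, vals)
}

# Sum `x` by integer group `g` into a length-`n` vector (0 for empty groups).
tapply_sum <- function(x, g, n) {
  out <- numeric(n)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Footprint reproducibility curve
#'
#' For each required overlap fraction t, the proportion of footprints in
#' `fpsA` whose best match in `fpsB` covers at least a fraction t of them
#' (fraction relative to the `fpsA` footprint; see [overlap_fraction()]).
#' Sweeping t from 1% to 100% yields the replicate-overlap curve; the curve
#' is non-increasing by construction.
#'
#' @param fpsA,fpsB footprint [interval_set()]s for the two replicates;
#'   `fpsA` must be non-empty (the proportion is undefined otherwise).
#' @param thresholds strictly increasing fractions in (0, 1]; default 0.01
#'   to 1 in steps of 0.01.
#' @return An `overlap_curve`: list with `thresholds`, `proportions` and
#'   `n_footprints` (the denominator, `nrow(fpsA)`).
#' @export
footprint_overlap_curve <- function(fpsA, fpsB,
                                    thresholds = seq(0.01, 1, by = 0.01)) {
  stopifnot(inherits(fpsA, "interval_set"), inherits(fpsB, "interval_set"))
  if (nrow(fpsA) == 0L) {
    stop("fpsA is empty: overlap proportion undefined", call. = FALSE)
  }
  if (length(thresholds) == 0L || any(thresholds <= 0 | thresholds > 1) ||
      is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing values in (0, 1]",
         call. = FALSE)
  }
  best <- numeric(nrow(fpsA))
  if (nrow(fpsB) > 0L) {
    hits <- intersect_intervals(fpsA, fpsB)
    if (nrow(hits) > 0L) {
      frac <- hits$overlap / (fpsA$end[hits$query] - fpsA$start[hits$query])
      mx <- tapply(frac, hits$query, max)
      best[as.integer(names(mx))] <- as.numeric(mx)
    }
  }
  props <- vapply(thresholds, function(t) mean(best >= t), numeric(1))
  structure(list(thresholds = thresholds, proportions = props,
                 n_footprints = nrow(fpsA)),
            class = "overlap_curve")
}

#' @export
print.overlap_curve <- function(x, ...) {
  cat(sprintf(
    "<overlap_curve> %d footprints; %.3f overlapping at %d%%, %.3f at %d%%\n",
    x$n_footprints, x$proportions[1], round(100 * x$thresholds[1]),
    x$proportions[length(x$proportions)],
    round(100 * x$thresholds[length(x$thresholds)])))
  invisible(x)
}

#' Write an overlap curve as TSV (threshold, proportion)
#'
#' @param curve an `overlap_curve` from [footprint_overlap_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_overlap_curve <- function(curve, path) {
  stopifnot(inherits(curve, "overlap_curve"))
  utils::write.table(
    data.frame(threshold = curve$thresholds,
               proportion = curve$proportions),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
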