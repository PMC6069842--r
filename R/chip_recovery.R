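# ChIP-seq recovery: label motif sites against per-TF ChIP peaks, attach
# footprint scores, rank, and compute per-TF ROC/AUC.
#
# The classification unit is the motif site. A site is chip-positive when
# it overlaps (>= 1 bp) a ChIP peak of its own TF; a peak of another TF
# never confers positivity. Footprinted chip-positive sites are true
# positives, footprinted chip-negative sites false positives, unfootprinted
# chip-positive sites false negatives and the rest true negatives.
#
# Ranking for the ROC places footprinted sites first in descending footprint
# score; sites without a footprint carry no score and are either treated as
# one exchangeable tied block ("expected" mode, the default — the AUC then
# equals the expectation over random orderings of those sites and is
# reproducible) or shuffled into a random strict order under a caller seed
# ("permutation" mode). The AUC is the tie-aware Mann-Whitney statistic,
# which equals the trapezoidal area under the tie-aware ROC curve exactly.

#' Label motif sites against per-TF ChIP truth
#'
#' @param sites an [interval_set()] of motif sites whose `label` column holds
#'   the TF identifier (no missing labels).
#' @param chip_peaks named list of [interval_set()]s, one entry per TF. A TF
#'   present with an empty set is allowed (all its sites become negatives);
#'   a site TF with no entry at all is an error.
#' @param provenance optional list of metadata (motif database, scan p-value
#'   cutoff, ...) carried on the result.
#' @return A `motif_site_table`: data.frame with columns chrom, start, end,
#'   strand, tf, chip_positive and footprint_score (all `NA` until
#'   [assign_footprint_scores()] is called).
#' @export
label_sites <- function(sites, chip_peaks, provenance = NULL) {
  stopifnot(inherits(sites, "interval_set"))
  if (nrow(sites) == 0L) stop("no motif sites supplied", call. = FALSE)
  if (anyNA(sites$label)) {
    stop("every site must carry a TF identifier in its label column",
         call. = FALSE)
  }
  if (!is.list(chip_peaks) || is.null(names(chip_peaks))) {
    stop("chip_peaks must be a named list of interval_set, one per TF",
         call. = FALSE)
  }
  missing_tfs <- setdiff(unique(sites$label), names(chip_peaks))
  if (length(missing_tfs)) {
    stop("no ChIP peak set supplied for TF(s): ",
         paste(sort(missing_tfs), collapse = ", "), call. = FALSE)
  }
  pos <- logical(nrow(sites))
  for (tf in unique(sites$label)) {
    idx <- which(sites$label == tf)
    pk <- chip_peaks[[tf]]
    stopifnot(inherits(pk, "interval_set"))
    if (nrow(pk) == 0L) next
    sub <- as_interval_set(as.data.frame(sites)[idx, , drop = FALSE])
    hits <- intersect_intervals(sub, pk)
    pos[idx[unique(hits$query)]] <- TRUE
  }
  out <- data.frame(chrom = sites$chrom, start = sites$start,
                    end = sites$end, strand = sites$strand,
                    tf = sites$label, chip_positive = pos,
                    footprint_score = NA_real_,
                    stringsAsFactors = FALSE)
  structure(out, class = c("motif_site_table", "data.frame"),
            provenance = provenance, scores_assigned = FALSE)
}

#' @export
print.motif_site_table <- function(x, ...) {
  cat(sprintf(
    "<motif_site_table> %d sites, %d TF(s), %d ChIP-positive%s\n",
    nrow(x), length(unique(x$tf)), sum(x$chip_positive),
    if (isTRUE(attr(x, "scores_assigned"))) ", scores assigned" else ""))
  invisible(x)
}

#' Attach footprint scores to motif sites
#'
#' A site's score is taken over the footprints overlapping it by at least
#' 1 bp: the maximum score by default (the detector-confidence convention)
#' or the mean with `combine = "mean"`. Sites with no overlapping footprint
#' keep a missing score, which marks them as unfootprinted for
#' [confusion_counts()] and [roc_auc()].
#'
#' @param table a `motif_site_table` from [label_sites()].
#' @param footprints a scored [interval_set()]; a missing score on any
#'   footprint is an error.
#' @param combine `"max"` (default) or `"mean"`.
#' @return The table with `footprint_score` filled in.
#' @export
assign_footprint_scores <- function(table, footprints,
                                    combine = c("max", "mean")) {
  combine <- match.arg(combine)
  stopifnot(inherits(table, "motif_site_table"),
            inherits(footprints, "interval_set"))
  if (nrow(footprints) > 0L && anyNA(footprints$score)) {
    stop("every footprint must carry a score", call. = FALSE)
  }
  score <- rep(NA_real_, nrow(table))
  if (nrow(footprints) > 0L) {
    site_set <- as_interval_set(
      data.frame(chrom = table$chrom, start = table$start, end = table$end,
                 stringsAsFactors = FALSE))
    hits <- intersect_intervals(site_set, footprints)
    if (nrow(hits) > 0L) {
      f <- if (combine == "max") max else mean
      agg <- tapply(footprints$score[hits$subject], hits$query, f)
      score[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  table$footprint_score <- score
  attr(table, "scores_assigned") <- TRUE
  table
}

#' Confusion matrix of footprint predictions against ChIP truth
#'
#' @param table a `motif_site_table` after [assign_footprint_scores()].
#' @return Named integer vector `(TP, FP, FN, TN)`; the four cells always
#'   sum to the row count.
#' @export
confusion_counts <- function(table) {
  stopifnot(inherits(table, "motif_site_table"))
  if (!isTRUE(attr(table, "scores_assigned"))) {
    stop("call assign_footprint_scores() before confusion_counts()",
         call. = FALSE)
  }
  fp <- !is.na(table$footprint_score)
  c(TP = sum(table$chip_positive & fp),
    FP = sum(!table$chip_positive & fp),
    FN = sum(table$chip_positive & !fp),
    TN = sum(!table$chip_positive & !fp))
}

# Ranking values for a score vector with missing entries (unfootprinted
# sites). "expected": the missing block becomes one tied value below every
# real score. "permutation": missing entries get distinct values below every
# real score, in an order shuffled by `seed`. Ties among real scores are
# preserved (mid-rank semantics downstream).
ranking_values <- function(scores, mode, seed = NULL) {
  v <- scores
  miss <- is.na(v)
  floor_val <- if (all(miss)) 0 else min(v[!miss]) - 1
  if (mode == "expected") {
    v[miss] <- floor_val
  } else {
    if (is.null(seed)) {
      stop("permutation mode requires a seed for reproducibility",
           call. = FALSE)
    }
    k <- sum(miss)
    if (k > 0L) {
      ord <- with_seed(seed, sample.int(k))
      # distinct values, strictly below floor_val, in shuffled order
      v[miss] <- floor_val - ord
    }
  }
  v
}

#' Rank motif sites for ROC construction
#'
#' Footprinted sites come first, in descending footprint score; sites
#' without a footprint follow. In `"expected"` mode the unfootprinted sites
#' (and any equal-score sites) form exchangeable tied blocks; in
#' `"permutation"` mode the unfootprinted sites are shuffled into a strict
#' random order driven by `seed`.
#'
#' @param table a `motif_site_table` after [assign_footprint_scores()].
#' @param mode `"expected"` (default) or `"permutation"`.
#' @param seed integer, required in permutation mode.
#' @return The table rows in rank order (best first).
#' @export
rank_sites <- function(table, mode = c("expected", "permutation"),
                       seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "motif_site_table"))
  if (!isTRUE(attr(table, "scores_assigned"))) {
    stop("call assign_footprint_scores() before rank_sites()", call. = FALSE)
  }
  v <- ranking_values(table$footprint_score, mode, seed)
  out <- table[order(-v), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-TF ROC curve and AUC
#'
#' The AUC is the Mann-Whitney pair statistic
#' \deqn{AUC = (\#\{pos\ above\ neg\} + \tfrac12\,\#\{tied\ pairs\}) /
#'   (n_{pos} n_{neg})}
#' computed from mid-ranks, and equals the trapezoidal area under the
#' tie-aware ROC curve (tied blocks drawn as diagonal segments) to within
#' 1e-9 by construction.
#'
#' @param table a `motif_site_table` after [assign_footprint_scores()].
#' @param tf TF identifier to evaluate; the table must contain at least one
#'   chip-positive and one chip-negative site for it.
#' @param mode,seed see [rank_sites()].
#' @return A `roc_result`: list with `tf`, `auc`, `curve` (data.frame of
#'   `fpr`, `tpr`, starting at (0,0) and ending at (1,1)), `n_pos`, `n_neg`,
#'   `ranking_mode`, `seed`.
#' @export
roc_auc <- function(table, tf, mode = c("expected", "permutation"),
                    seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "motif_site_table"))
  if (!isTRUE(attr(table, "scores_assigned"))) {
    stop("call assign_footprint_scores() before roc_auc()", call. = FALSE)
  }
  rows <- table[table$tf == tf, , drop = FALSE]
  n_pos <- sum(rows$chip_positive)
  n_neg <- sum(!rows$chip_positive)
  if (n_pos == 0L || n_neg == 0L) {
    stop(sprintf("AUC undefined for TF '%s': %d positive, %d negative sites",
                 tf, n_pos, n_neg), call. = FALSE)
  }
  v <- ranking_values(rows$footprint_score, mode, seed)
  r <- rank(v, ties.method = "average")
  auc <- (sum(r[rows$chip_positive]) - n_pos * (n_pos + 1) / 2) /
    (n_pos * n_neg)

  # tie-aware ROC: one vertex per distinct ranking value, descending
  lev <- sort(unique(v), decreasing = TRUE)
  tp <- cumsum(vapply(lev, function(l) sum(rows$chip_positive & v == l),
                      numeric(1)))
  fp <- cumsum(vapply(lev, function(l) sum(!rows$chip_positive & v == l),
                      numeric(1)))
  curve <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  trap <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                   curve$tpr[-1]) / 2)
  stopifnot(abs(trap - auc) < 1e-9)
  structure(list(tf = tf, auc = auc, curve = curve, n_pos = n_pos,
                 n_neg = n_neg, ranking_mode = mode, seed = seed),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %s: AUC %.4f (%d pos / %d neg, %s mode)\n",
              x$tf, x$auc, x$n_pos, x$n_neg, x$ranking_mode))
  invisible(x)
}

#' Mean AUC across transcription factors
#'
#' @param results non-empty list of `roc_result`s (or a numeric vector of
#'   AUCs).
#' @return Unweighted arithmetic mean of the per-TF AUCs.
#' @export
mean_auc <- function(results) {
  if (length(results) == 0L) stop("no AUC results supplied", call. = FALSE)
  if (is.numeric(results)) return(mean(results))
  mean(vapply(results, function(r) {
    stopifnot(inherits(r, "roc_result"))
    r$auc
  }, numeric(1)))
}

#' Percent improvement in AUC above random
#'
#' Compares two AUCs on the above-random scale (AUC - 0.5):
#' `100 * ((auc_test - 0.5) - (auc_reference - 0.5)) / (auc_reference - 0.5)`.
#' This is one consistent reading of "percent improvement in mean AUC over
#' random"; the definition is recorded in any summary output so downstream
#' consumers know which convention was used.
#'
#' @param auc_test,auc_reference AUCs; the reference must exceed 0.5.
#' @return Percent improvement (0 when the two AUCs are equal).
#' @examples
#' improvement_over_random(0.7, 0.6)  # 100
#' @export
improvement_over_random <- function(auc_test, auc_reference) {
  if (auc_reference <= 0.5) {
    stop("reference AUC must exceed 0.5 (no information above random)",
         call. = FALSE)
  }
  100 * ((auc_test - 0.5) - (auc_reference - 0.5)) / (auc_reference - 0.5)
}

#' Write per-TF AUC results as TSV
#'
#' Columns: tf, auc, n_pos, n_neg, mode, seed.
#' @param results list of `roc_result`s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_auc_table <- function(results, path) {
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(tf = r$tf, auc = r$auc, n_pos = r$n_pos, n_neg = r$n_neg,
               mode = r$ranking_mode,
               seed = if (is.null(r$seed)) NA_integer_ else r$seed,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a JSON summary of a ChIP-recovery evaluation
#'
#' Includes the mean AUC, the per-TF table and any provenance metadata
#' (e.g. the motif-scan p-value cutoff recorded on the site table), plus the
#' convention used by [improvement_over_random()].
#'
#' @param results list of `roc_result`s.
#' @param path output path.
#' @param provenance optional list of metadata.
#' @return `path`, invisibly.
#' @export
write_auc_summary <- function(results, path, provenance = NULL) {
  per_tf <- lapply(results, function(r) {
    list(tf = r$tf, auc = r$auc, n_pos = r$n_pos, n_neg = r$n_neg)
  })
  jsonlite::write_json(
    list(mean_auc = mean_auc(results), per_tf = per_tf,
         improvement_definition =
           "100 * ((auc - 0.5) - (ref - 0.5)) / (ref - 0.5)",
         provenance = provenance),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
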