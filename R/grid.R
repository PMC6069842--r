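# Pipeline-configuration grid harness.
#
# A pipeline configuration is the 8-argument record a footprinting pipeline
# takes: alignment scope and sensitivity, BAM processing (with or without
# PCR duplicate removal), peak size, minimum peak distance, the footprinter,
# and the footprinter's own sub-arguments (bias-correction mode for HINT;
# p-value cutoff and FDR for Wellington). Sub-arguments only exist for
# their footprinter, so grid expansion crosses them conditionally —
# Wellington settings never multiply HINT configurations.
#
# evaluate_config() scores a configuration on a synthetic world through an
# explicit "effects" map stating how each configuration axis transforms the
# world (deduplicate fragments, trim OCRs to the peak-size core, threshold
# footprint scores, ...). The harness measures; it does not run aligners or
# footprinters.

.GRID_AXES <- c("align_scope", "align_sensitivity", "bam_processor",
                "peak_size", "min_dist", "footprinter", "hint_bias_mode",
                "wellington_p_cutoff", "wellington_fdr")
.COND_AXES <- list(hint = "hint_bias_mode",
                   wellington = c("wellington_p_cutoff", "wellington_fdr"))
# order in which effects are applied: mirrors the pipeline's own step order
.AXIS_ORDER <- .GRID_AXES

#' Construct a pipeline configuration
#'
#' @param align_scope `"global"` or `"local"`.
#' @param align_sensitivity `"sensitive"` or `"very-sensitive"`.
#' @param bam_processor `"plain"` (no duplicate removal) or `"dedup"`
#'   (PCR duplicate removal).
#' @param peak_size peak-caller scanning window (bp), > 0.
#' @param min_dist minimum distance between peaks (bp), >= 0.
#' @param footprinter `"hint"` or `"wellington"`.
#' @param hint_bias_mode `"none"`, `"known-enzyme"` or `"estimated"`;
#'   required iff `footprinter = "hint"`.
#' @param wellington_p_cutoff,wellington_fdr numeric in (0, 1); required iff
#'   `footprinter = "wellington"`.
#' @return A `pipeline_config` list holding exactly the arguments that are
#'   meaningful for the chosen footprinter.
#' @export
pipeline_config <- function(align_scope = c("global", "local"),
                            align_sensitivity = c("sensitive",
                                                  "very-sensitive"),
                            bam_processor = c("plain", "dedup"),
                            peak_size = 200, min_dist = 50,
                            footprinter = c("hint", "wellington"),
                            hint_bias_mode = NULL,
                            wellington_p_cutoff = NULL,
                            wellington_fdr = NULL) {
  align_scope <- match.arg(align_scope)
  align_sensitivity <- match.arg(align_sensitivity)
  bam_processor <- match.arg(bam_processor)
  footprinter <- match.arg(footprinter)
  if (!is.numeric(peak_size) || peak_size <= 0) {
    stop("`peak_size` must be > 0", call. = FALSE)
  }
  if (!is.numeric(min_dist) || min_dist < 0) {
    stop("`min_dist` must be >= 0", call. = FALSE)
  }
  cfg <- list(align_scope = align_scope,
              align_sensitivity = align_sensitivity,
              bam_processor = bam_processor, peak_size = peak_size,
              min_dist = min_dist, footprinter = footprinter)
  if (footprinter == "hint") {
    if (is.null(hint_bias_mode) || !is.null(wellington_p_cutoff) ||
        !is.null(wellington_fdr)) {
      stop("footprinter 'hint' takes hint_bias_mode and no Wellington ",
           "arguments", call. = FALSE)
    }
    if (!hint_bias_mode %in% c("none", "known-enzyme", "estimated")) {
      stop("invalid hint_bias_mode", call. = FALSE)
    }
    cfg$hint_bias_mode <- hint_bias_mode
  } else {
    if (!is.null(hint_bias_mode) || is.null(wellington_p_cutoff) ||
        is.null(wellington_fdr)) {
      stop("footprinter 'wellington' takes wellington_p_cutoff and ",
           "wellington_fdr and no HINT arguments", call. = FALSE)
    }
    if (wellington_p_cutoff <= 0 || wellington_p_cutoff >= 1 ||
        wellington_fdr <= 0 || wellington_fdr >= 1) {
      stop("Wellington cutoffs must lie in (0, 1)", call. = FALSE)
    }
    cfg$wellington_p_cutoff <- wellington_p_cutoff
    cfg$wellington_fdr <- wellington_fdr
  }
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  kv <- vapply(names(unclass(x)),
               function(nm) sprintf("%s=%s", nm, x[[nm]]), character(1))
  cat("<pipeline_config>", paste(kv, collapse = " "), "\n")
  invisible(x)
}

#' Expand an argument space into pipeline configurations
#'
#' Cartesian product of the supplied argument values, except that
#' footprinter-specific sub-arguments are crossed only within their own
#' footprinter. The output order is deterministic: configurations are
#' sorted lexicographically by argument name (alphabetical) and, within an
#' argument, by the order the values were supplied.
#'
#' @param space named list mapping argument names (see [pipeline_config()])
#'   to non-empty value vectors. Unknown names are an error.
#' @return List of `pipeline_config`s.
#' @examples
#' expand_grid_configs(list(
#'   bam_processor = c("plain", "dedup"), peak_size = c(200, 500),
#'   footprinter = "hint", hint_bias_mode = "none"))
#' @export
expand_grid_configs <- function(space) {
  if (!is.list(space) || is.null(names(space))) {
    stop("`space` must be a named list of argument values", call. = FALSE)
  }
  unknown <- setdiff(names(space), .GRID_AXES)
  if (length(unknown)) {
    stop("unknown grid argument(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(lengths(space) == 0L)) {
    stop("every argument must have at least one value", call. = FALSE)
  }
  cond_all <- unlist(.COND_AXES, use.names = FALSE)
  if (!"footprinter" %in% names(space) &&
      any(cond_all %in% names(space))) {
    stop("footprinter-specific arguments require a `footprinter` axis",
         call. = FALSE)
  }
  shared <- setdiff(names(space), c("footprinter", cond_all))
  fps <- if ("footprinter" %in% names(space)) space$footprinter else NA
  blocks <- lapply(fps, function(fp) {
    axes <- space[shared]
    if (!is.na(fp)) {
      axes$footprinter <- fp
      axes <- c(axes, space[intersect(.COND_AXES[[fp]], names(space))])
    }
    axes <- axes[order(names(axes))]
    # expand with the first (alphabetical) axis varying slowest
    idx <- expand.grid(rev(lapply(axes, seq_along)),
                       KEEP.OUT.ATTRS = FALSE)
    idx <- idx[, rev(seq_along(axes)), drop = FALSE]
    lapply(seq_len(nrow(idx)), function(i) {
      stats::setNames(lapply(seq_along(axes),
                             function(j) axes[[j]][[idx[i, j]]]),
                      names(axes))
    })
  })
  rows <- unlist(blocks, recursive = FALSE)
  # global lexicographic order across footprinter blocks
  axis_names <- sort(unique(unlist(lapply(rows, names))))
  key <- sapply(axis_names, function(ax) {
    vapply(rows, function(r) {
      if (is.null(r[[ax]])) return(0L)
      vals <- if (ax %in% names(space)) space[[ax]] else r[[ax]]
      match(r[[ax]], vals)
    }, integer(1))
  })
  key <- matrix(key, nrow = length(rows))
  ord <- do.call(order, split(key, col(key)))
  lapply(rows[ord], function(r) do.call(pipeline_config, r))
}

#' Default configuration-effects map for synthetic worlds
#'
#' Each entry states how one configuration axis transforms a
#' `synthetic_truth` before the metrics are computed; all stochastic
#' effects draw from the seed passed by [evaluate_config()]. The default
#' map encodes the mechanisms the configuration axes act through:
#' \describe{
#'   \item{align_scope / align_sensitivity}{less exhaustive alignment
#'     retains slightly fewer fragments (seeded thinning: global 95%,
#'     sensitive 97%, the stricter alternatives 100%).}
#'   \item{bam_processor}{`"dedup"` removes PCR duplicates from both
#'     replicates' fragment lists.}
#'   \item{peak_size}{each OCR is trimmed to its central
#'     `min(peak_size, length)` bp — small scanning windows keep only the
#'     read-dense core — and footprints whose midpoint falls outside a
#'     trimmed OCR are discarded, since footprinting only searches inside
#'     peaks.}
#'   \item{min_dist}{OCRs closer than this gap are merged.}
#'   \item{footprinter}{selects the footprinter; no transformation by
#'     itself.}
#'   \item{hint_bias_mode}{bias re-estimation perturbs footprint scores by
#'     a small seeded jitter (sd 0.1) for the two correction modes.}
#'   \item{wellington_p_cutoff}{footprints below the score corresponding to
#'     the cutoff on the null score distribution (Normal(5, 1)) are
#'     dropped.}
#'   \item{wellington_fdr}{Benjamini-Hochberg selection on the scores'
#'     null p-values at the requested FDR.}
#' }
#'
#' @return Named list of functions `f(world, value, seed)` returning the
#'   transformed world.
#' @export
default_effects <- function() {
  thin <- function(world, rate, seed) {
    if (rate >= 1) return(world)
    for (r in 1:2) {
      nm <- sprintf("fragments_rep%d", r)
      fr <- world[[nm]]
      keep <- with_seed(sub_seed(seed, r),
                        stats::runif(nrow(fr)) < rate)
      world[[nm]] <- fr[keep, , drop = FALSE]
    }
    world
  }
  filter_fp <- function(world, keep_fun) {
    for (r in 1:2) {
      nm <- sprintf("footprints_rep%d", r)
      fp <- world[[nm]]
      if (nrow(fp) == 0L) next
      world[[nm]] <- as_interval_set(
        as.data.frame(fp)[keep_fun(fp), , drop = FALSE], sorted = TRUE)
    }
    world
  }
  list(
    align_scope = function(world, value, seed) {
      thin(world, if (value == "global") 0.95 else 1, seed)
    },
    align_sensitivity = function(world, value, seed) {
      thin(world, if (value == "sensitive") 0.97 else 1, seed)
    },
    bam_processor = function(world, value, seed) {
      if (value == "dedup") {
        world$fragments_rep1 <- deduplicate_fragments(world$fragments_rep1)
        world$fragments_rep2 <- deduplicate_fragments(world$fragments_rep2)
      }
      world
    },
    peak_size = function(world, value, seed) {
      o <- world$ocrs
      len <- o$end - o$start
      core <- pmin(value, len)
      ns <- floor(o$start + (len - core) / 2)
      world$ocrs <- as_interval_set(
        data.frame(chrom = o$chrom, start = ns, end = ns + core,
                   score = o$score, stringsAsFactors = FALSE),
        sorted = TRUE)
      trimmed <- world$ocrs
      filter_fp(world, function(fp) {
        mid <- as_interval_set(data.frame(
          chrom = fp$chrom, start = floor((fp$start + fp$end) / 2),
          end = floor((fp$start + fp$end) / 2) + 1,
          stringsAsFactors = FALSE))
        seq_len(nrow(fp)) %in% intersect_intervals(mid, trimmed)$query
      })
    },
    min_dist = function(world, value, seed) {
      world$ocrs <- merge_intervals(world$ocrs, min_dist = value)
      world
    },
    footprinter = function(world, value, seed) world,
    hint_bias_mode = function(world, value, seed) {
      if (value == "none") return(world)
      for (r in 1:2) {
        nm <- sprintf("footprints_rep%d", r)
        fp <- world[[nm]]
        if (nrow(fp) == 0L) next
        fp$score <- pmax(0, fp$score +
                           with_seed(sub_seed(seed, r),
                                     stats::rnorm(nrow(fp), sd = 0.1)))
        world[[nm]] <- fp
      }
      world
    },
    wellington_p_cutoff = function(world, value, seed) {
      mu <- world$params$score_null_mean
      thr <- stats::qnorm(1 - value, mean = mu, sd = 1)
      filter_fp(world, function(fp) fp$score >= thr)
    },
    wellington_fdr = function(world, value, seed) {
      mu <- world$params$score_null_mean
      filter_fp(world, function(fp) {
        pv <- stats::pnorm(fp$score, mean = mu, sd = 1, lower.tail = FALSE)
        stats::p.adjust(pv, method = "BH") <= value
      })
    }
  )
}

#' Evaluate one pipeline configuration on a synthetic world
#'
#' Applies the configuration's effects to the world (in pipeline step
#' order), then computes the full metric row: alignment reproducibility
#' from the two replicates' binned fragment counts, open-chromatin
#' reproducibility from per-replicate OCR height observations (the shared
#' OCR height plus replicate noise whose scale grows with OCR length —
#' wider windows accumulate more private background), footprint overlap at
#' 1%, per-TF and mean ChIP-recovery AUC (expected mode, replicate 1
#' footprints), and the footprint count.
#'
#' @param config a [pipeline_config()].
#' @param world a `synthetic_truth` from [simulate_world()].
#' @param effects named list of effect functions as in [default_effects()];
#'   every axis present in the configuration must have an entry.
#' @param seed integer seed driving all stochastic effects and
#'   observations.
#' @return A `grid_result`: list with `config`, `alignment_r`, `ocr_r`,
#'   `footprint_overlap_at_1pct`, `mean_auc`, `per_tf_auc`,
#'   `n_footprints`, `provenance`.
#' @export
evaluate_config <- function(config, world, effects = default_effects(),
                            seed = 1) {
  stopifnot(inherits(config, "pipeline_config"),
            inherits(world, "synthetic_truth"))
  axes <- intersect(.AXIS_ORDER, names(unclass(config)))
  missing_fx <- setdiff(axes, names(effects))
  if (length(missing_fx)) {
    stop("effects map has no entry for axis/axes: ",
         paste(missing_fx, collapse = ", "), call. = FALSE)
  }
  for (i in seq_along(axes)) {
    ax <- axes[i]
    world <- effects[[ax]](world, config[[ax]], sub_seed(seed, 100 + i))
  }

  t1 <- bin_fragments(world$fragments_rep1, world$binning)
  t2 <- bin_fragments(world$fragments_rep2, world$binning)
  alignment_r <- alignment_reproducibility(t1, t2)

  # per-replicate OCR height observation: shared height + length-scaled noise
  o <- world$ocrs
  len <- o$end - o$start
  noise_sd <- 0.3 * mean(o$score) * len / max(1, mean(len))
  ocr_tracks <- lapply(1:2, function(r) {
    h <- pmax(0, o$score + with_seed(sub_seed(seed, 200 + r),
                                     stats::rnorm(nrow(o), sd = noise_sd)))
    obs <- as_interval_set(data.frame(chrom = o$chrom, start = o$start,
                                      end = o$end, score = h,
                                      stringsAsFactors = FALSE),
                           sorted = TRUE)
    ocr_mean_height_track(obs, world$binning)
  })
  ocr_r <- alignment_reproducibility(ocr_tracks[[1]], ocr_tracks[[2]])

  fp1 <- world$footprints_rep1
  fp2 <- world$footprints_rep2
  overlap1 <- if (nrow(fp1) == 0L) NA_real_ else
    footprint_overlap_curve(fp1, fp2, thresholds = 0.01)$proportions[1]

  tab <- label_sites(world$sites, world$chip_peaks)
  tab <- assign_footprint_scores(tab, fp1)
  per_tf <- numeric(0)
  for (tf in sort(unique(tab$tf))) {
    n_pos <- sum(tab$chip_positive[tab$tf == tf])
    n_neg <- sum(!tab$chip_positive[tab$tf == tf])
    if (n_pos == 0L || n_neg == 0L) next
    per_tf[tf] <- roc_auc(tab, tf, mode = "expected")$auc
  }
  structure(
    list(config = config, alignment_r = alignment_r, ocr_r = ocr_r,
         footprint_overlap_at_1pct = overlap1,
         mean_auc = mean_auc(per_tf), per_tf_auc = per_tf,
         n_footprints = nrow(fp1),
         provenance = list(seed = seed, world_seed = world$params$seed,
                           axes = axes)),
    class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf(paste0("<grid_result> alignment_r %.3f, ocr_r %.3f, ",
                     "overlap@1%% %.3f, mean AUC %.3f, %d footprints\n"),
              x$alignment_r, x$ocr_r, x$footprint_overlap_at_1pct,
              x$mean_auc, x$n_footprints))
  invisible(x)
}

#' Select the optimal configuration from grid results
#'
#' `objective = "mean_auc"` maximises the mean ChIP-recovery AUC;
#' `objective = "reproducibility"` maximises the mean of the alignment and
#' OCR correlations (the composite reproducibility score). Ties keep the
#' earliest result, so selection is deterministic.
#'
#' @param results non-empty list of `grid_result`s.
#' @param objective `"mean_auc"` or `"reproducibility"`.
#' @return The winning `grid_result`.
#' @export
select_optimal <- function(results,
                           objective = c("mean_auc", "reproducibility")) {
  objective <- match.arg(objective)
  if (length(results) == 0L) stop("no results supplied", call. = FALSE)
  score <- vapply(results, function(r) {
    if (objective == "mean_auc") r$mean_auc
    else mean(c(r$alignment_r, r$ocr_r))
  }, numeric(1))
  results[[which.max(score)]]  # which.max keeps the first maximum
}

#' Summarize grid results
#'
#' @param results non-empty list of `grid_result`s.
#' @return A `grid_summary` with two data.frames: `long` (one row per
#'   (configuration, metric), with the configuration's arguments spread
#'   into columns) and `by_argument` (per argument level and metric: mean
#'   and 95% confidence interval across configurations; the interval is
#'   missing for single-member groups).
#' @export
summarize_grid <- function(results) {
  if (length(results) == 0L) stop("no results supplied", call. = FALSE)
  metrics <- c("alignment_r", "ocr_r", "footprint_overlap_at_1pct",
               "mean_auc", "n_footprints")
  cfg_df <- do.call(rbind, lapply(seq_along(results), function(i) {
    cfg <- unclass(results[[i]]$config)
    row <- stats::setNames(
      as.list(rep(NA_character_, length(.GRID_AXES))), .GRID_AXES)
    for (nm in names(cfg)) row[[nm]] <- as.character(cfg[[nm]])
    data.frame(config_id = i, row, stringsAsFactors = FALSE)
  }))
  long <- do.call(rbind, lapply(seq_along(results), function(i) {
    data.frame(config_id = i, metric = metrics,
               value = vapply(metrics,
                              function(m) as.numeric(results[[i]][[m]]),
                              numeric(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  long <- merge(cfg_df, long, by = "config_id", sort = TRUE)
  by_arg <- list()
  for (ax in .GRID_AXES) {
    levels <- unique(cfg_df[[ax]])
    levels <- levels[!is.na(levels)]
    for (lev in levels) {
      ids <- cfg_df$config_id[!is.na(cfg_df[[ax]]) & cfg_df[[ax]] == lev]
      for (m in metrics) {
        v <- long$value[long$config_id %in% ids & long$metric == m]
        v <- v[!is.na(v)]
        n <- length(v)
        half <- if (n > 1L) stats::qt(0.975, n - 1) * stats::sd(v) / sqrt(n)
                else NA_real_
        by_arg[[length(by_arg) + 1L]] <- data.frame(
          argument = ax, level = lev, metric = m, n = n,
          mean = if (n) mean(v) else NA_real_,
          ci_lo = if (n > 1L) mean(v) - half else NA_real_,
          ci_hi = if (n > 1L) mean(v) + half else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(long = long, by_argument = do.call(rbind, by_arg)),
            class = "grid_summary")
}

#' @export
print.grid_summary <- function(x, ...) {
  cat(sprintf("<grid_summary> %d configuration(s), %d metric rows\n",
              length(unique(x$long$config_id)), nrow(x$long)))
  invisible(x)
}

#' Read a grid specification from YAML or JSON
#'
#' The file maps argument names to value lists, suitable for
#' [expand_grid_configs()]. An illustrative example grid ships at
#' `system.file("extdata", "grid_default.yaml", package = "footprintbench")`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Named list of argument values.
#' @export
read_grid_spec <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported grid spec format (use .yaml or .json)", call. = FALSE)
  }
}

#' Write grid results as TSV and JSON
#'
#' @param results list of `grid_result`s.
#' @param tsv_path,json_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the long-format data.frame written.
#' @export
write_grid_results <- function(results, tsv_path = NULL, json_path = NULL) {
  smry <- summarize_grid(results)
  if (!is.null(tsv_path)) {
    utils::write.table(smry$long, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      lapply(seq_along(results), function(i) {
        r <- results[[i]]
        list(config = unclass(r$config), alignment_r = r$alignment_r,
             ocr_r = r$ocr_r,
             footprint_overlap_at_1pct = r$footprint_overlap_at_1pct,
             mean_auc = r$mean_auc, per_tf_auc = as.list(r$per_tf_auc),
             n_footprints = r$n_footprints, provenance = r$provenance)
      }),
      json_path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(smry$long)
}
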