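# Downsampling harness and saturation models.
#
# Footprint counts grow approximately linearly with read depth, while the
# ChIP-recovery mean AUC grows with diminishing returns; the two standard
# summaries are therefore an ordinary least-squares line (value vs depth in
# millions of reads) and a power law AUC(r) = a * r^b fitted on the log-log
# scale, which can be inverted to project the read depth needed for a
# target AUC.

#' A depth series of a metric measured at several read depths
#'
#' @param depths strictly increasing positive read counts (e.g.
#'   `c(20, 40, ..., 200) * 1e6`).
#' @param values numeric matrix with one row per depth and one column per
#'   replicate sampling (a vector is treated as a one-replicate matrix).
#' @return A `depth_series`.
#' @export
depth_series <- function(depths, values) {
  if (any(depths <= 0) || is.unsorted(depths, strictly = TRUE)) {
    stop("depths must be strictly increasing and positive", call. = FALSE)
  }
  if (is.vector(values)) values <- matrix(values, ncol = 1)
  values <- as.matrix(values)
  if (nrow(values) != length(depths)) {
    stop("values must have one row per depth", call. = FALSE)
  }
  structure(list(depths = as.numeric(depths), values = values),
            class = "depth_series")
}

#' @export
print.depth_series <- function(x, ...) {
  cat(sprintf("<depth_series> %d depths (%g .. %g), %d replicate(s)\n",
              length(x$depths), min(x$depths), max(x$depths),
              ncol(x$values)))
  invisible(x)
}

#' Downsample a collection without replacement
#'
#' Uniform sample of `n_target` items. When `seed` is omitted it defaults
#' to `n_target` itself — the convention of seeding the subsampler with the
#' target read count, which makes each depth's sample reproducible but
#' couples the seed to the depth (so two different depths are not nested
#' subsamples of one another).
#'
#' @param items vector or data.frame (rows are items).
#' @param n_target sample size, at most the number of items.
#' @param seed integer; defaults to `n_target`.
#' @return The sampled items (same type as `items`).
#' @export
downsample <- function(items, n_target, seed = NULL) {
  n <- if (is.data.frame(items)) nrow(items) else length(items)
  if (n_target > n) {
    stop(sprintf("cannot downsample %d items to %d", n, n_target),
         call. = FALSE)
  }
  if (is.null(seed)) seed <- n_target
  idx <- with_seed(seed, sample.int(n, n_target))
  if (is.data.frame(items)) {
    out <- items[idx, , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    items[idx]
  }
}

#' Fit a straight line to a depth series
#'
#' Ordinary least squares of every replicate value on depth expressed in
#' millions of reads (so the slope is in metric units per additional
#' million reads), with an intercept.
#'
#' @param series a [depth_series()] with at least 2 distinct depths.
#' @return A `linear_fit`: list with `slope` (units / million reads),
#'   `intercept`, `r_squared`, and the underlying `fit` (an `lm`).
#' @export
fit_linear <- function(series) {
  stopifnot(inherits(series, "depth_series"))
  if (length(unique(series$depths)) < 2L) {
    stop("need at least 2 distinct depths", call. = FALSE)
  }
  x <- rep(series$depths / 1e6, times = ncol(series$values))
  y <- as.vector(series$values)
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, fit = fit),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf(
    "<linear_fit> slope %.4g per million reads, intercept %.4g, R^2 %.4f\n",
    x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Fit a power law to a depth series
#'
#' Fits `value = a * depth^b` by ordinary least squares of `log(value)` on
#' `log(depth)` (deterministic and closed-form), after averaging replicate
#' values at each depth. Depth is in raw reads.
#'
#' @param series a [depth_series()]; all values must be positive and at
#'   least 2 distinct depths are required.
#' @return A `power_fit`: list with `a` (scale, > 0), `b` (exponent) and
#'   `depth_range` (the fitted depth range, used to flag extrapolation).
#' @export
fit_power <- function(series) {
  stopifnot(inherits(series, "depth_series"))
  if (length(unique(series$depths)) < 2L) {
    stop("need at least 2 distinct depths", call. = FALSE)
  }
  if (any(series$values <= 0)) {
    stop("power fit requires strictly positive values", call. = FALSE)
  }
  m <- rowMeans(series$values)
  fit <- stats::lm(log(m) ~ log(series$depths))
  structure(list(a = unname(exp(stats::coef(fit)[1])),
                 b = unname(stats::coef(fit)[2]),
                 depth_range = range(series$depths)),
            class = "power_fit")
}

#' @export
print.power_fit <- function(x, ...) {
  cat(sprintf("<power_fit> value = %.4g * depth^%.4g (fitted on %g .. %g)\n",
              x$a, x$b, x$depth_range[1], x$depth_range[2]))
  invisible(x)
}

#' Project the read depth needed to reach a target AUC
#'
#' Inverts the fitted power law: `reads = (target / a)^(1/b)`. Requires a
#' positive exponent (otherwise the curve never crosses the target). The
#' result is flagged as an extrapolation when it lies beyond the largest
#' fitted depth — projections to very high AUCs typically are.
#'
#' @param fit a `power_fit` from [fit_power()].
#' @param target_auc positive target value.
#' @return A `read_prediction`: list with `reads` and logical
#'   `extrapolated`.
#' @export
predict_reads_for_auc <- function(fit, target_auc) {
  stopifnot(inherits(fit, "power_fit"))
  if (target_auc <= 0) stop("`target_auc` must be positive", call. = FALSE)
  if (fit$b <= 0) {
    stop("exponent b <= 0: the fitted curve never reaches the target",
         call. = FALSE)
  }
  reads <- (target_auc / fit$a)^(1 / fit$b)
  structure(list(reads = reads,
                 extrapolated = reads > fit$depth_range[2] * (1 + 1e-8),
                 target_auc = target_auc),
            class = "read_prediction")
}

#' @export
print.read_prediction <- function(x, ...) {
  cat(sprintf("<read_prediction> %.4g reads for AUC %.3g%s\n", x$reads,
              x$target_auc,
              if (x$extrapolated) " (extrapolated beyond fitted range)"
              else ""))
  invisible(x)
}

#' Fraction of a reference depth's metric reached at a smaller depth
#'
#' Mean metric value at `at_depth` divided by the mean at
#' `reference_depth`. The default basis is the raw ratio; with
#' `basis = "above_random"` both means are first reduced by 0.5 (the
#' chance-level AUC), which answers the stricter question of how much of
#' the above-random signal is already captured.
#'
#' @param series a [depth_series()].
#' @param at_depth,reference_depth depths present in `series$depths`.
#' @param basis `"raw"` (default) or `"above_random"`.
#' @return The ratio (1 when the two depths coincide).
#' @export
saturation_fraction <- function(series, at_depth, reference_depth,
                                basis = c("raw", "above_random")) {
  basis <- match.arg(basis)
  stopifnot(inherits(series, "depth_series"))
  ia <- match(at_depth, series$depths)
  ir <- match(reference_depth, series$depths)
  if (is.na(ia) || is.na(ir)) {
    stop("both depths must be present in the series", call. = FALSE)
  }
  ma <- mean(series$values[ia, ])
  mr <- mean(series$values[ir, ])
  if (basis == "above_random") { ma <- ma - 0.5; mr <- mr - 0.5 }
  ma / mr
}

#' Read / write a depth series as TSV (depth, replicate, value)
#'
#' @param series a [depth_series()] (writer).
#' @param path file path.
#' @return `path` (writer) or a [depth_series()] (reader).
#' @export
write_depth_series <- function(series, path) {
  stopifnot(inherits(series, "depth_series"))
  df <- data.frame(
    depth = rep(series$depths, times = ncol(series$values)),
    replicate = rep(seq_len(ncol(series$values)),
                    each = length(series$depths)),
    value = sprintf("%.17g", as.vector(series$values)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_depth_series
#' @export
read_depth_series <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("numeric", "integer", "numeric"))
  depths <- sort(unique(tb$depth))
  reps <- sort(unique(tb$replicate))
  vals <- matrix(NA_real_, length(depths), length(reps))
  vals[cbind(match(tb$depth, depths), match(tb$replicate, reps))] <- tb$value
  depth_series(depths, vals)
}

#' Write fit results as JSON
#'
#' Serialises a `linear_fit`, `power_fit` or `read_prediction`, including
#' the fitted depth range and extrapolation flag where applicable.
#'
#' @param fit the fit object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  x <- if (inherits(fit, "linear_fit")) {
    list(type = "linear", slope_per_million_reads = fit$slope,
         intercept = fit$intercept, r_squared = fit$r_squared)
  } else if (inherits(fit, "power_fit")) {
    list(type = "power", a = fit$a, b = fit$b,
         depth_range = fit$depth_range)
  } else if (inherits(fit, "read_prediction")) {
    list(type = "read_prediction", reads = fit$reads,
         target_auc = fit$target_auc, extrapolated = fit$extrapolated)
  } else {
    stop("unsupported fit object", call. = FALSE)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
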