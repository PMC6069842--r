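# Genomic interval data model and arithmetic.
#
# An interval_set is a data.frame with columns chrom, start, end, score,
# strand, label (plus any extra columns a caller attaches) and a "sorted"
# attribute. Coordinates are 0-based half-open: [start, end) covers bases
# start .. end-1, so abutting intervals do not overlap. Overlap queries and
# merging are delegated to IRanges per chromosome after shifting to 1-based
# closed coordinates (start+1 .. end), which preserves half-open semantics
# exactly: [100,200) and [200,300) map to 101..200 and 201..300.

#' Construct a set of genomic intervals
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors of 0-based half-open coordinates;
#'   `start >= 0` and `end > start` for every interval.
#' @param score optional numeric vector (footprint score, peak height, ...).
#' @param strand optional character vector in `+`, `-`, `.`.
#' @param label optional character vector (e.g. a TF name).
#' @param sorted logical; set `TRUE` only if rows are already ordered by
#'   (chrom, start, end, label).
#' @return An `interval_set`: a data.frame with the six columns above and a
#'   `sorted` attribute. Extra columns passed through `...` of
#'   [as_interval_set()] are preserved by all sorting operations.
#' @examples
#' interval_set("chr1", 100, 200, score = 5)
#' @export
interval_set <- function(chrom = character(), start = numeric(),
                         end = numeric(), score = NULL, strand = NULL,
                         label = NULL, sorted = FALSE) {
  n <- max(length(chrom), length(start), length(end))
  recycle <- function(v) {
    if (length(v) == n) v
    else if (length(v) == 1L) rep(v, n)
    else stop("chrom, start and end must have equal length (or length 1)",
              call. = FALSE)
  }
  chrom <- recycle(chrom); start <- recycle(start); end <- recycle(end)
  if (!is.null(score)) score <- recycle(score)
  if (!is.null(strand)) strand <- recycle(strand)
  if (!is.null(label)) label <- recycle(label)
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    score = if (is.null(score)) rep(NA_real_, n) else as.numeric(score),
    strand = if (is.null(strand)) rep(".", n) else as.character(strand),
    label = if (is.null(label)) rep(NA_character_, n) else as.character(label),
    stringsAsFactors = FALSE
  )
  validate_interval_set(df)
  structure(df, class = c("interval_set", "data.frame"), sorted = sorted)
}

#' Coerce a data.frame to an interval_set
#'
#' Missing columns among score/strand/label are filled with defaults; extra
#' columns are kept.
#' @param x data.frame with at least chrom, start, end.
#' @param sorted logical, as in [interval_set()].
#' @return An `interval_set`.
#' @export
as_interval_set <- function(x, sorted = FALSE) {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x))) {
    stop("data.frame must have columns chrom, start, end", call. = FALSE)
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (is.null(x$score)) x$score <- NA_real_
  if (is.null(x$strand)) x$strand <- "."
  if (is.null(x$label)) x$label <- NA_character_
  x$chrom <- as.character(x$chrom)
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  front <- c("chrom", "start", "end", "score", "strand", "label")
  x <- x[, c(front, setdiff(names(x), front)), drop = FALSE]
  rownames(x) <- NULL
  validate_interval_set(x)
  structure(x, class = c("interval_set", "data.frame"), sorted = sorted)
}

validate_interval_set <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (anyNA(df$start) || anyNA(df$end)) {
    stop("interval coordinates must not be NA", call. = FALSE)
  }
  if (any(df$start < 0)) stop("interval start must be >= 0", call. = FALSE)
  bad <- which(df$end <= df$start)
  if (length(bad)) {
    stop(sprintf("interval %d has end <= start (%s:%g-%g)",
                 bad[1], df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]]),
         call. = FALSE)
  }
  if (!all(df$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'", call. = FALSE)
  }
  invisible(df)
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("<interval_set> %d interval(s)%s\n", nrow(x),
              if (isTRUE(attr(x, "sorted"))) ", sorted" else ""))
  if (nrow(x)) print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  invisible(x)
}

#' Number of intervals in a set
#' @param x an `interval_set`.
#' @return Integer count.
#' @export
n_intervals <- function(x) nrow(x)

#' Sort an interval set
#'
#' Orders rows by (chrom, start, end, label); the label tie-break makes
#' sorting deterministic when coordinates coincide.
#' @param x an `interval_set`.
#' @return The same set with rows ordered and `sorted = TRUE`.
#' @export
sort_intervals <- function(x) {
  stopifnot(inherits(x, "interval_set"))
  if (isTRUE(attr(x, "sorted"))) return(x)
  o <- order(x$chrom, x$start, x$end, x$label, method = "radix")
  out <- x[o, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(x), sorted = TRUE)
}

# IRanges view of the rows of `x` lying on one chromosome (1-based closed).
.ir_of <- function(x, idx) {
  IRanges::IRanges(start = x$start[idx] + 1, end = x$end[idx])
}

#' All overlapping pairs between two interval sets
#'
#' Reports every pair (a-interval, b-interval) sharing at least 1 bp under
#' half-open semantics; strand is ignored. Used to match footprints to
#' ChIP-supported binding intervals and motif sites.
#'
#' @param a,b `interval_set`s.
#' @return data.frame with columns `query` (row index into `a`), `subject`
#'   (row index into `b`) and `overlap` (bp, always >= 1), ordered by
#'   (query, subject). Disjoint sets give zero rows.
#' @examples
#' a <- interval_set("chr1", 100, 200)
#' b <- interval_set("chr1", 150, 250)
#' intersect_intervals(a, b)  # one pair, 50 bp
#' @export
intersect_intervals <- function(a, b) {
  stopifnot(inherits(a, "interval_set"), inherits(b, "interval_set"))
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(data.frame(query = integer(), subject = integer(),
                      overlap = numeric()))
  }
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  res <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    ia <- which(a$chrom == chroms[i])
    ib <- which(b$chrom == chroms[i])
    ra <- .ir_of(a, ia)
    rb <- .ir_of(b, ib)
    h <- IRanges::findOverlaps(ra, rb)
    if (length(h) == 0L) next
    qh <- S4Vectors::queryHits(h)
    sh <- S4Vectors::subjectHits(h)
    ov <- IRanges::width(IRanges::pintersect(ra[qh], rb[sh]))
    res[[i]] <- data.frame(query = ia[qh], subject = ib[sh],
                           overlap = as.numeric(ov))
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    return(data.frame(query = integer(), subject = integer(),
                      overlap = numeric()))
  }
  out <- out[order(out$query, out$subject), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge nearby intervals
#'
#' Fuses any run of intervals in which consecutive members are separated by a
#' gap (`next start - previous end`) of at most `min_dist` bp; the bound is
#' inclusive, so `min_dist = 0` fuses only overlapping or abutting intervals.
#' This mirrors a peak caller's minimum-distance argument controlling when
#' adjacent open chromatin peaks are stitched into one region.
#'
#' When every input interval carries a score, a merged interval's score is
#' the length-weighted mean of its members (a merged peak keeps a height);
#' otherwise scores are dropped.
#'
#' @param x an `interval_set`.
#' @param min_dist non-negative gap (bp) at or below which intervals fuse.
#' @return A sorted, non-overlapping `interval_set`.
#' @examples
#' s <- interval_set(c("chr1", "chr1"), c(0, 150), c(100, 300))
#' merge_intervals(s, min_dist = 50)  # one interval [0, 300)
#' @export
merge_intervals <- function(x, min_dist = 0) {
  stopifnot(inherits(x, "interval_set"))
  if (!is.numeric(min_dist) || length(min_dist) != 1L || min_dist < 0) {
    stop("`min_dist` must be a single non-negative number", call. = FALSE)
  }
  x <- sort_intervals(x)
  if (nrow(x) <= 1L) return(x)
  keep_scores <- !anyNA(x$score)
  chroms <- unique(x$chrom)
  parts <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    idx <- which(x$chrom == chroms[i])
    r <- IRanges::reduce(.ir_of(x, idx), min.gapwidth = min_dist + 1,
                         with.revmap = TRUE)
    sc <- rep(NA_real_, length(r))
    if (keep_scores) {
      rv <- S4Vectors::mcols(r)$revmap
      sc <- vapply(seq_along(r), function(k) {
        mem <- idx[rv[[k]]]
        w <- x$end[mem] - x$start[mem]
        sum(x$score[mem] * w) / sum(w)
      }, numeric(1))
    }
    parts[[i]] <- data.frame(chrom = chroms[i],
                             start = IRanges::start(r) - 1,
                             end = IRanges::end(r),
                             score = sc, strand = ".",
                             label = NA_character_,
                             stringsAsFactors = FALSE)
  }
  as_interval_set(do.call(rbind, parts), sorted = TRUE)
}

#' Fraction of an interval covered by another
#'
#' Pairwise overlap fraction, relative to the first argument: the number of
#' shared bases divided by the length of `a`. This matches the replicate
#' footprint question "what fraction of this footprint is covered by a
#' footprint in the other replicate"; a symmetric variant
#' (`mode = "min"`, the smaller of the two directional fractions) is also
#' available. Intervals on different chromosomes have fraction 0.
#'
#' @param a,b `interval_set`s of equal length, or length 1 to be recycled;
#'   row i of `a` is compared with row i of `b`.
#' @param mode `"query"` (default, relative to `a`) or `"min"`.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' overlap_fraction(interval_set("chr1", 100, 200),
#'                  interval_set("chr1", 150, 250))  # 0.5
#' @export
overlap_fraction <- function(a, b, mode = c("query", "min")) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "interval_set"), inherits(b, "interval_set"))
  na <- nrow(a); nb <- nrow(b)
  if (na != nb && na != 1L && nb != 1L) {
    stop("a and b must have equal length (or length 1)", call. = FALSE)
  }
  n <- max(na, nb)
  ia <- if (na == 1L) rep(1L, n) else seq_len(n)
  ib <- if (nb == 1L) rep(1L, n) else seq_len(n)
  ov <- pmax(0, pmin(a$end[ia], b$end[ib]) - pmax(a$start[ia], b$start[ib]))
  ov[a$chrom[ia] != b$chrom[ib]] <- 0
  la <- a$end[ia] - a$start[ia]
  if (mode == "query") ov / la
  else ov / pmax(la, b$end[ib] - b$start[ib])
}

#' Define a fixed genome binning
#'
#' Tiles each chromosome with half-open windows of `bin_size` bp (default
#' 10 kb, the standard window for replicate read-count comparison); the last
#' window of a chromosome may be shorter.
#'
#' @param chrom_sizes named numeric vector (chromosome -> length in bp), or a
#'   two-column data.frame (name, length) as read by [read_chrom_sizes()].
#' @param bin_size window size in bp, > 0.
#' @return A `genome_binning` object.
#' @export
genome_binning <- function(chrom_sizes, bin_size = 10000) {
  if (is.data.frame(chrom_sizes)) {
    cs <- as.numeric(chrom_sizes[[2]])
    names(cs) <- as.character(chrom_sizes[[1]])
    chrom_sizes <- cs
  }
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    stop("chrom_sizes must be named by chromosome", call. = FALSE)
  }
  if (any(chrom_sizes <= 0)) {
    stop("every chromosome length must be > 0", call. = FALSE)
  }
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0) {
    stop("`bin_size` must be a single positive number", call. = FALSE)
  }
  chrom_sizes <- chrom_sizes[order(names(chrom_sizes), method = "radix")]
  n_bins <- ceiling(chrom_sizes / bin_size)
  structure(
    list(chrom_sizes = chrom_sizes, bin_size = bin_size,
         n_bins = n_bins, offsets = cumsum(c(0, n_bins[-length(n_bins)]))),
    class = "genome_binning"
  )
}

#' @export
print.genome_binning <- function(x, ...) {
  cat(sprintf("<genome_binning> %d chromosome(s), bin %g bp, %d bins\n",
              length(x$chrom_sizes), x$bin_size, total_bins(x)))
  invisible(x)
}

#' Total number of bins in a genome binning
#' @param binning a `genome_binning`.
#' @return Integer bin count across all chromosomes.
#' @export
total_bins <- function(binning) {
  stopifnot(inherits(binning, "genome_binning"))
  as.integer(sum(binning$n_bins))
}

#' Materialize the bins of a genome binning as intervals
#'
#' @param binning a `genome_binning`.
#' @return A sorted `interval_set` tiling every chromosome exactly:
#'   `[0,B), [B,2B), ...`, last bin truncated at the chromosome length.
#' @examples
#' make_bins(genome_binning(c(chr1 = 25000), bin_size = 10000))
#' @export
make_bins <- function(binning) {
  stopifnot(inherits(binning, "genome_binning"))
  parts <- lapply(names(binning$chrom_sizes), function(ch) {
    len <- binning$chrom_sizes[[ch]]
    s <- seq(0, len - 1, by = binning$bin_size)
    data.frame(chrom = ch, start = s, end = pmin(s + binning$bin_size, len),
               stringsAsFactors = FALSE)
  })
  as_interval_set(do.call(rbind, parts), sorted = TRUE)
}

# Map (chrom, pos) to a global bin index in 1..total_bins(binning).
# Errors on unknown chromosomes or out-of-range positions.
bin_index <- function(binning, chrom, pos) {
  unknown <- setdiff(unique(chrom), names(binning$chrom_sizes))
  if (length(unknown)) {
    stop("position(s) on chromosome(s) absent from the binning: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  len <- binning$chrom_sizes[chrom]
  if (any(pos < 0 | pos >= len)) {
    stop("position outside chromosome bounds", call. = FALSE)
  }
  as.integer(binning$offsets[match(chrom, names(binning$chrom_sizes))] +
               floor(pos / binning$bin_size) + 1)
}
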